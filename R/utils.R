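# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}

# Quiet selection: like selectAtoms() but returns integer(0) instead of
# erroring; used where an empty species selection is legitimate (waters).
.selectQuiet <- function(topology, ...) {
  tryCatch(selectAtoms(topology, ...), error = function(e) integer(0))
}

# Per-frame distance series between two atoms of a trajectory coords array.
.pairDistanceSeries <- function(coords, i, j) {
  di <- coords[i, , , drop = FALSE]; dj <- coords[j, , , drop = FALSE]
  d <- di - dj
  sqrt(colSums(matrix(d, nrow = 3)^2))
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Left eigenvector of the transition matrix for eigenvalue 1, normalised to
#' sum to 1. Used as the ground-truth oracle for the Markov gate generator.
#'
#' @param P row-stochastic square matrix.
#' @return numeric stationary probability vector.
#' @export
stationaryDistribution <- function(P) {
  if (any(abs(rowSums(P) - 1) > 1e-12))
    stop("transition matrix rows must sum to 1", call. = FALSE)
  e <- eigen(t(P))
  k <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, k])
  v / sum(v)
}
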