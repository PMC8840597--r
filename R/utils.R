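# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded generators do not
#' perturb user code.
#' @noRd
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

vnorm <- function(v) sqrt(sum(v^2))

unit_vector <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

#' Angle a-b-c at vertex b, in degrees
#' @noRd
vertex_angle <- function(a, b, c) {
  u <- a - b
  v <- c - b
  ct <- sum(u * v) / (vnorm(u) * vnorm(v))
  ct <- max(-1, min(1, ct))
  acos(ct) * 180 / pi
}

#' All-pairs Euclidean distances between two coordinate matrices (n x 3)
#' @noRd
cross_dist <- function(xa, xb) {
  xa <- matrix(xa, ncol = 3)
  xb <- matrix(xb, ncol = 3)
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  sqrt(pmax(d2, 0))
}

#' Round half away from zero (so 0.5 -> 1), used for exact-occupancy counts
#' @noRd
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
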