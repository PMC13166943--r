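#' Evaluate an expression under a fixed RNG state
#'
#' Runs \code{expr} with the Mersenne-Twister generator seeded at \code{seed}
#' and restores the caller's RNG state afterwards, so that scene generation
#' never perturbs user-level randomness.
#'
#' @param seed integer seed (kept below 2^31).
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

## shift a matrix by (dr, dc), padding with `fill`
shiftMat <- function(m, dr, dc, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  if (length(rs) == 0 || length(cs) == 0) return(out)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

## neighbor offsets for 4- or 8-connectivity
neighborOffsets <- function(connectivity) {
  stopifnot(connectivity %in% c(4L, 8L))
  off <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (connectivity == 8L)
    off <- c(off, list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
  off
}

## population (1/N) standard deviation
popSd <- function(x) sqrt(mean((x - mean(x))^2))

stopf <- function(...) stop(sprintf(...), call. = FALSE)
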