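## Internal numerical helpers.

## Moore-Penrose pseudo-inverse with the cutoff max(dim) * eps * sigma_max;
## rank deficiency is expected with rare variants, so this is used instead of
## solve().
.pinv <- function(V) {
  s <- svd(V)
  tol <- max(dim(V)) * .Machine$double.eps * max(s$d, 0)
  keep <- s$d > tol
  if (!any(keep)) return(matrix(0, ncol(V), nrow(V)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

.matrixRank <- function(V) {
  s <- svd(V)$d
  tol <- max(dim(V)) * .Machine$double.eps * max(s, 0)
  as.integer(sum(s > tol))
}

## log(exp(a) + exp(b)) elementwise, tolerating -Inf.
.logAddExp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

## log(exp(a) - exp(b)) for a >= b; returns -Inf when the difference
## underflows.
.logSubExp <- function(a, b) {
  d <- -expm1(b - a)
  out <- a + log(pmax(d, 0))
  out[is.infinite(a) & a < 0] <- -Inf
  out
}

## Deterministic per-replicate seed derived from a master seed; a linear
## congruential mix keeps everything inside 32-bit integer range and makes
## experiments reproducible under any replicate schedule.
.deriveSeed <- function(masterSeed, r, stream = 0L) {
  m <- 2147483629
  x <- (as.numeric(masterSeed) %% m) * 48271 + as.numeric(r) * 8191 +
    as.numeric(stream) * 524287 + 1
  as.integer(x %% m) + 1L
}

## Random +/-1 flip matrix (families x nPerm) for the within-family
## permutation null.
.flipMatrix <- function(nFamilies, nPerm) {
  matrix(ifelse(stats::runif(nFamilies * nPerm) < 0.5, -1, 1),
         nrow = nFamilies, ncol = nPerm)
}
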