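#' First discrete prolate spheroidal (Slepian) taper
#'
#' Computes the 0th-order DPSS taper as the leading eigenvector of the
#' tridiagonal matrix that commutes with the spectral-concentration operator
#' (diagonal `((n-1-2t)/2)^2 cos(2 pi W)`, off-diagonal `t (n-t) / 2`,
#' W = nw / n). A shifted power iteration followed by Rayleigh-quotient
#' inverse iteration on the sparse tridiagonal gives O(n) work per step.
#' Results are cached per `(n, nw)`.
#'
#' @param n taper length in samples.
#' @param nw time-bandwidth product (default 1, the single-taper setting).
#' @return Numeric vector of length `n`, sum of squares 1, positive mean.
#' @export
dpss_taper <- function(n, nw = 1) {
  key <- paste0("dpss_", n, "_", nw)
  cached <- .specslope_cache[[key]]
  if (!is.null(cached)) return(cached)
  if (n < 2) stop("taper length must be >= 2")
  w <- nw / n
  t0 <- 0:(n - 1)
  dg <- ((n - 1 - 2 * t0) / 2)^2 * cos(2 * pi * w)
  od <- t0[-1] * (n - t0[-1]) / 2
  tmv <- function(v) {          # tridiagonal matrix-vector product
    r <- dg * v
    r[-n] <- r[-n] + od * v[-1]
    r[-1] <- r[-1] + od * v[-n]
    r
  }
  shift <- (n / 2)^2 + max(od)  # make the target eigenvalue dominant
  v <- rep(1 / sqrt(n), n)
  for (i in 1:50) {
    v <- tmv(v) + shift * v
    v <- v / sqrt(sum(v^2))
  }
  lam <- sum(v * tmv(v))
  A <- Matrix::bandSparse(n, n, k = c(-1, 0, 1),
                          diagonals = list(od, dg - lam, od))
  for (i in 1:4) {              # inverse iteration at the Rayleigh quotient
    v_new <- tryCatch(
      as.numeric(Matrix::solve(A + Matrix::Diagonal(n, 1e-8 * (n / 2)^2), v)),
      error = function(e) NULL)
    if (is.null(v_new)) break
    v <- v_new / sqrt(sum(v_new^2))
  }
  if (sum(v) < 0) v <- -v
  v <- v / sqrt(sum(v^2))
  .specslope_cache[[key]] <- v
  v
}

#' Hann taper (alternative single taper)
#'
#' @param n taper length in samples.
#' @return Numeric vector, sum of squares 1.
#' @export
hann_taper <- function(n) {
  h <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  h / sqrt(sum(h^2))
}
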