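#' @keywords internal
"_PACKAGE"

#' @importFrom stats rpois rnorm runif rlnorm var cor fft sd median
#' @importFrom utils read.delim write.table
NULL

# Discrete Gaussian kernel, unit sum, truncated at +/- 4 SD.
# sd_bins is the SD expressed in bins.
gaussian_kernel <- function(sd_bins) {
  stopifnot(sd_bins > 0)
  half <- ceiling(4 * sd_bins)
  x <- seq(-half, half)
  k <- exp(-x^2 / (2 * sd_bins^2))
  k / sum(k)
}

# Centered convolution with an odd-length kernel, zero-padded edges.
smooth_vector <- function(x, kernel) {
  n <- length(x)
  half <- (length(kernel) - 1L) / 2L
  y <- stats::filter(c(rep(0, half), x, rep(0, half)), kernel, sides = 2)
  as.numeric(y[(half + 1L):(half + n)])
}

#' Draw samples from a von Mises distribution
#'
#' Best-Fisher rejection sampler. Used by the synthetic-session generator to
#' jitter spike phases around click onsets and by calibration tests against
#' the closed-form mean resultant length `besselI(kappa, 1) / besselI(kappa, 0)`.
#'
#' @param n number of draws.
#' @param mu mean direction, radians.
#' @param kappa concentration parameter, >= 0. `kappa = 0` gives the uniform
#'   circular distribution.
#' @return numeric vector of angles in `[0, 2*pi)`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0) return(numeric(0))
  if (kappa < 1e-8) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    if (any(ok)) {
      th <- sign(u3[ok] - 0.5) * acos(f[ok])
      take <- min(sum(ok), n - got)
      out[(got + 1L):(got + take)] <- th[seq_len(take)]
      got <- got + take
    }
  }
  (out + mu) %% (2 * pi)
}

# Half-open interval membership: a <= x < b, vectorised over x.
in_window <- function(x, a, b) x >= a & x < b

# Indices of bins (1-based, bin width dt starting at t0) covered by the
# half-open interval [a, b).
bins_in_interval <- function(a, b, t0, dt, n) {
  i0 <- max(1L, floor((a - t0) / dt) + 1L)
  i1 <- min(n, ceiling((b - t0) / dt))
  if (i1 < i0) integer(0) else i0:i1
}

# Deterministic sub-seed derivation: one top-level seed, documented offsets
# per component so adding a unit does not perturb the others.
sub_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max
}
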