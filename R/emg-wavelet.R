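#' Wavelet empirical-Bayes denoising of EMG
#'
#' A discrete wavelet transform (symmetric least-asymmetric wavelet with 4
#' vanishing moments, periodized) followed by empirical-Bayes posterior-mean
#' shrinkage of the detail coefficients with level-dependent noise
#' estimation: per level, the noise scale is the rescaled median absolute
#' deviation of the detail coefficients; the coefficients are modelled with
#' a spike-and-slab prior (point mass at zero plus a Laplace slab, scale
#' `a = 0.5`) whose mixing weight is estimated per level by marginal
#' maximum likelihood; the posterior mean replaces each coefficient.
#'
#' @name emg_denoise
NULL

# sym4 orthonormal filter bank (least-asymmetric Daubechies, 4 vanishing
# moments, 8 taps).
SYM4_LO <- c(-0.07576571478927333, -0.02963552764599851, 0.49761866763201545,
             0.8037387518059161, 0.29785779560527736, -0.09921954357684722,
             -0.012603967262037833, 0.0322231006040427)
SYM4_HI <- c(-0.0322231006040427, -0.012603967262037833, 0.09921954357684722,
             0.29785779560527736, -0.8037387518059161, 0.49761866763201545,
             0.02963552764599851, -0.07576571478927333)

# One level of the periodized DWT. For even n returns approximation and
# detail coefficients of length n/2; a[k] = sum_m lo[m] x[(2k + L/2 - m) mod n]
# (0-based), the convention of periodized orthonormal transforms.
dwt_step <- function(x) {
  n <- length(x)
  stopifnot(n %% 2 == 0)
  L <- length(SYM4_LO)
  k <- 0:(n / 2 - 1)
  idx <- outer(2 * k + L / 2, 0:(L - 1), "-") %% n + 1  # (n/2) x L
  xm <- matrix(x[idx], nrow = n / 2)
  list(a = as.numeric(xm %*% SYM4_LO), d = as.numeric(xm %*% SYM4_HI))
}

# Inverse of dwt_step: the transform is orthonormal, so the inverse is the
# transpose of the analysis operator.
idwt_step <- function(a, d) {
  n <- 2 * length(a)
  L <- length(SYM4_LO)
  x <- numeric(n)
  k <- 0:(n / 2 - 1)
  for (m in 0:(L - 1)) {
    j <- (2 * k + L / 2 - m) %% n + 1
    contrib <- a * SYM4_LO[m + 1] + d * SYM4_HI[m + 1]
    # accumulate; j indices are distinct within one m because stride 2 < n
    x[j] <- x[j] + contrib
  }
  x
}

#' Multi-level periodized DWT (sym4)
#'
#' @param x Numeric series; length must be divisible by `2^levels`.
#' @param levels Number of decomposition levels.
#' @return List with `a` (coarsest approximation) and `d` (list of detail
#'   vectors, finest first).
#' @export
dwt_sym4 <- function(x, levels) {
  stopifnot(levels >= 1, length(x) %% 2^levels == 0)
  d <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    s <- dwt_step(a)
    a <- s$a
    d[[j]] <- s$d
  }
  list(a = a, d = d)
}

#' @rdname dwt_sym4
#' @param w A list as returned by [dwt_sym4()].
#' @export
idwt_sym4 <- function(w) {
  a <- w$a
  for (j in rev(seq_along(w$d))) a <- idwt_step(a, w$d[[j]])
  a
}

# Posterior mean of u given z ~ N(u, 1) under the spike-and-slab prior
# w * Laplace(a) + (1 - w) * delta_0 (Johnstone-Silverman shrinkage rule).
laplace_post_mean <- function(z, w, a = 0.5) {
  s <- sign(z); z <- abs(z)
  # C1 = exp(-a z) Phi(z - a), C2 = exp(a z) Phi(-z - a), on log scale
  lc1 <- -a * z + pnorm(z - a, log.p = TRUE)
  lc2 <- a * z + pnorm(-z - a, log.p = TRUE)
  m <- pmax(lc1, lc2)
  # marginal density of z under the Laplace slab
  lg <- log(a / 2) + a^2 / 2 + m + log(exp(lc1 - m) + exp(lc2 - m))
  lphi <- dnorm(z, log = TRUE)
  post_odds <- w * exp(lg) / pmax(w * exp(lg) + (1 - w) * exp(lphi), 1e-300)
  mean_nonzero <- z - a * (exp(lc1 - m) - exp(lc2 - m)) /
    (exp(lc1 - m) + exp(lc2 - m))
  s * post_odds * mean_nonzero
}

# Marginal log-likelihood of the mixing weight for one level.
laplace_weight_mll <- function(w, z, a = 0.5) {
  z <- abs(z)
  lc1 <- -a * z + pnorm(z - a, log.p = TRUE)
  lc2 <- a * z + pnorm(-z - a, log.p = TRUE)
  m <- pmax(lc1, lc2)
  g <- (a / 2) * exp(a^2 / 2 + m) * (exp(lc1 - m) + exp(lc2 - m))
  sum(log(w * g + (1 - w) * dnorm(z)))
}

#' Denoise a centred EMG series
#'
#' @param x Numeric series (length >= 16, finite).
#' @param levels Decomposition depth; default
#'   `min(floor(log2(n)) - 4, 10)`.
#' @param a Laplace slab scale (default 0.5).
#' @return Denoised series, same length as `x`.
#' @export
denoise_emg <- function(x, levels = NULL, a = 0.5) {
  n <- length(x)
  if (any(!is.finite(x))) stop("non-finite samples")
  if (n < 16) stop("need at least 16 samples")
  if (is.null(levels)) levels <- max(1L, min(floor(log2(n)) - 4L, 10L))
  # pad by symmetric reflection to a multiple of 2^levels
  block <- 2^levels
  pad <- (block - n %% block) %% block
  xp <- if (pad > 0) c(x, rev(x)[seq_len(pad)]) else x
  w <- dwt_sym4(xp, levels)
  for (j in seq_along(w$d)) {
    d <- w$d[[j]]
    sigma <- mad(d)
    if (sigma <= 0) next
    z <- d / sigma
    wgt <- optimize(function(wi) laplace_weight_mll(wi, z, a),
                    interval = c(1e-4, 1 - 1e-4), maximum = TRUE)$maximum
    w$d[[j]] <- sigma * laplace_post_mean(z, wgt, a)
  }
  idwt_sym4(w)[seq_len(n)]
}
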