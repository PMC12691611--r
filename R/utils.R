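#' @useDynLib mxquant, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats dnorm pnorm qnorm rnorm runif rexp median sd var t.test
#'   optim cor uniroot coef setNames
#' @importFrom utils read.csv write.csv
NULL

# Internal validation helpers -------------------------------------------------

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_positive <- function(x, field, strict = TRUE) {
  if (!is.numeric(x) || length(x) == 0 || anyNA(x) ||
      (strict && any(x <= 0)) || (!strict && any(x < 0))) {
    stop_field(field, if (strict) "must be numeric and > 0" else "must be numeric and >= 0")
  }
  invisible(x)
}

check_fraction <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    stop_field(field, "must be a single value in [0, 1]")
  }
  invisible(x)
}

# Zero-truncated normal -------------------------------------------------------

#' Moment-matched zero-truncated normal parameters
#'
#' Finds parent parameters (mu0, sigma0) such that the normal distribution
#' truncated to `[0, Inf)` has the requested mean and standard deviation.
#' Used by the motility simulator so that configured speed moments are the
#' moments actually generated. Coefficients of variation above that of the
#' folded half-normal (about 0.756) are not representable and raise an error.
#'
#' @param mean,sd target mean and standard deviation of the truncated
#'   distribution (same units).
#' @return list with `mu0`, `sigma0`.
#' @export
truncnorm_match_moments <- function(mean, sd) {
  check_positive(mean, "mean")
  check_positive(sd, "sd", strict = FALSE)
  if (sd == 0) return(list(mu0 = mean, sigma0 = 0))
  if (sd / mean > 0.75) {
    stop_field("sd", "coefficient of variation too large for a zero-truncated normal")
  }
  moments <- function(mu0, s0) {
    a <- -mu0 / s0
    lam <- dnorm(a) / pnorm(a, lower.tail = FALSE)
    m <- mu0 + s0 * lam
    v <- s0^2 * (1 + a * lam - lam^2)
    c(m, sqrt(pmax(v, 0)))
  }
  obj <- function(p) {
    mm <- moments(p[1], exp(p[2]))
    (mm[1] - mean)^2 + (mm[2] - sd)^2
  }
  fit <- optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  out <- list(mu0 = fit$par[1], sigma0 = exp(fit$par[2]))
  mm <- moments(out$mu0, out$sigma0)
  if (max(abs(mm - c(mean, sd)) / c(mean, sd)) > 1e-6) {
    stop("moment matching failed to converge", call. = FALSE)
  }
  out
}

# Inverse-CDF sampler: uses exactly n uniforms, so the RNG stream is
# independent of acceptance rates.
rtruncnorm0 <- function(n, mu0, sigma0) {
  if (sigma0 == 0) return(rep(mu0, n))
  p0 <- pnorm(0, mu0, sigma0)
  qnorm(p0 + runif(n) * (1 - p0), mu0, sigma0)
}

# Reflect-padded separable Gaussian smoothing ---------------------------------

reflect_index <- function(i, n) {
  if (n == 1) return(rep(1L, length(i)))
  period <- 2L * n
  j <- (i - 1L) %% period
  j <- ifelse(j < 0, j + period, j)
  as.integer(ifelse(j < n, j + 1L, period - j))
}

# n x n operator: column j holds the redistribution of mass from source bin j
# under a Gaussian kernel with symmetric (edge-repeating) reflection.
# Columns sum to 1 exactly, so matrix totals are conserved.
gauss_operator <- function(n, sigma_bins) {
  if (sigma_bins <= 0) return(diag(n))
  h <- max(1L, ceiling(4 * sigma_bins))
  off <- (-h):h
  w <- dnorm(off, 0, sigma_bins)
  w <- w / sum(w)
  S <- matrix(0, n, n)
  for (j in seq_len(n)) {
    t_idx <- reflect_index(j + off, n)
    for (k in seq_along(off)) S[t_idx[k], j] <- S[t_idx[k], j] + w[k]
  }
  S
}

# Smooth a matrix with reflect padding; exact mass conservation.
gauss_smooth2d <- function(mat, sigma_row_bins, sigma_col_bins = sigma_row_bins) {
  Sr <- gauss_operator(nrow(mat), sigma_row_bins)
  Sc <- gauss_operator(ncol(mat), sigma_col_bins)
  Sr %*% mat %*% t(Sc)
}

# Otsu threshold --------------------------------------------------------------

# Global automatic threshold on an intensity matrix (EBImage's Otsu criterion).
otsu_threshold <- function(mat) {
  rng <- range(mat, finite = TRUE)
  if (diff(rng) <= 0) return(rng[1])
  EBImage::otsu(EBImage::Image(mat), range = rng, levels = 256)
}

# Misc ------------------------------------------------------------------------

deg2rad <- function(x) x * pi / 180

# wrap angle to [0, 2*pi)
wrap_angle <- function(a) a %% (2 * pi)
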