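#' Fit the steady-state 1:1 binding model to SPR equilibrium responses
#'
#' Nonlinear least squares of `Req = Rmax * C / (K_D + C)` with positivity
#' enforced by log-parameterization (Levenberg-Marquardt). Initialization:
#' `Rmax0 = 1.1 * max(response)`, `K_D0 = median(concentration)`.
#'
#' @param data an [spr_dataset()] or a data frame with columns
#'   `concentration_M` and `response_RU` (>= 4 unique concentrations
#'   spanning at least a 4-fold range).
#' @return object of class `spr_fit`: list with `K_D` (M), `Rmax` (RU),
#'   `rss`, `se` (named, delta-method), `converged`, `reliable` (FALSE when
#'   the fit did not converge or `K_D` falls outside
#'   `[min(C)/100, 100 * max(C)]`).
#' @export
fit_spr_steady_state <- function(data) {
  C <- data$concentration_M; R <- data$response_RU
  if (length(C) < 4) stop("need at least 4 concentrations", call. = FALSE)
  if (anyDuplicated(C)) stop("concentrations must be unique", call. = FALSE)
  check_positive(C, "concentration_M")
  if (max(C) / min(C) < 4) {
    stop("concentration series must span at least a 4-fold range", call. = FALSE)
  }
  df <- data.frame(C = C, R = R)
  start <- list(lRmax = log(1.1 * max(max(R), 1e-6)), lKd = log(median(C)))
  fit <- try(minpack.lm::nlsLM(
    R ~ exp(lRmax) * C / (exp(lKd) + C), data = df, start = start,
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(structure(list(K_D = NA_real_, Rmax = NA_real_, rss = NA_real_,
                          se = c(K_D = NA_real_, Rmax = NA_real_),
                          converged = FALSE, reliable = FALSE),
                     class = "spr_fit"))
  }
  p <- coef(fit)
  K_D <- exp(p[["lKd"]]); Rmax <- exp(p[["lRmax"]])
  vc <- try(stats::vcov(fit), silent = TRUE)
  se <- if (inherits(vc, "try-error")) c(K_D = NA_real_, Rmax = NA_real_) else
    c(K_D = K_D * sqrt(vc["lKd", "lKd"]), Rmax = Rmax * sqrt(vc["lRmax", "lRmax"]))
  conv <- isTRUE(fit$convInfo$isConv)
  reliable <- conv && K_D >= min(C) / 100 && K_D <= 100 * max(C)
  structure(list(K_D = K_D, Rmax = Rmax,
                 rss = sum(stats::resid(fit)^2), se = se,
                 converged = conv, reliable = reliable),
            class = "spr_fit")
}

#' @export
print.spr_fit <- function(x, ...) {
  cat(sprintf("<spr_fit: K_D = %.4g M, Rmax = %.4g RU, RSS = %.3g%s>\n",
              x$K_D, x$Rmax, x$rss,
              if (isTRUE(x$reliable)) "" else ", UNRELIABLE"))
  invisible(x)
}

#' Subtract control (dilution) heats from an ITC titration
#'
#' Elementwise subtraction of a control titration (ligand injected into
#' buffer) from the sample heats; the control is removed from the result.
#'
#' @param data an [itc_dataset()] carrying a control series, unless
#'   `control` is supplied explicitly.
#' @param control optional numeric vector of control heats (kcal/mol of
#'   injectant), same length as the titration.
#' @return an [itc_dataset()] with corrected heats and no control.
#' @export
subtract_dilution <- function(data, control = NULL) {
  stopifnot(inherits(data, "itc_dataset"))
  if (is.null(control)) control <- attr(data, "control")
  if (is.null(control)) stop("no control series available", call. = FALSE)
  if (length(control) != nrow(data)) {
    stop("control series length differs from the titration", call. = FALSE)
  }
  itc_dataset(data$heat_kcal_mol - control,
              attr(data, "cell_volume"), attr(data, "injection_volume"),
              attr(data, "cell_conc"), attr(data, "syringe_conc"),
              control = NULL, meta = attr(data, "meta"))
}

#' Fit the one-set-of-sites model to an ITC titration
#'
#' Least-squares fit of per-injection normalized heats to the
#' one-set-of-sites cumulative-heat model (with volume-displacement
#' corrected concentrations, see [itc_expected_heats()]) plus a constant
#' baseline offset. Positivity of `n` and `K_D` is enforced by
#' log-parameterization; fitting uses Levenberg-Marquardt.
#'
#' @param data a dilution-corrected [itc_dataset()].
#' @param fit_offset also fit a constant residual-heat offset. Default
#'   FALSE: after control-titration subtraction the baseline is zero by
#'   construction, and a free offset trades off strongly against `K_D`.
#'   Enable it for titrations whose dilution heats were never measured.
#' @param exclude_first drop the first injection (a common ITC practice for
#'   diffusion-contaminated first injections); default FALSE.
#' @return object of class `itc_fit`: list with `n`, `K_D` (M), `dH`
#'   (kcal/mol), `offset`, `rss`, `c_parameter`, `converged`,
#'   `low_confidence` (TRUE when the Wiseman c-parameter `n*M_t/K_D` is
#'   below 0.1).
#' @export
fit_itc_one_site <- function(data, fit_offset = FALSE, exclude_first = FALSE) {
  stopifnot(inherits(data, "itc_dataset"))
  q <- data$heat_kcal_mol
  V0 <- attr(data, "cell_volume"); vinj <- attr(data, "injection_volume")
  M0 <- attr(data, "cell_conc"); Xs <- attr(data, "syringe_conc")
  n_inj <- length(q)
  keep <- if (exclude_first) 2:n_inj else seq_len(n_inj)

  offset0 <- mean(utils::tail(q, 3))
  dh0 <- q[1] - offset0
  if (abs(dh0) < 1e-6 || sd(q) < 1e-9) {
    stop("fit degenerate: injection heats carry no binding signal (dH ~ 0)",
         call. = FALSE)
  }
  mr <- data$molar_ratio
  # initial n: molar ratio at which the heat crosses half its initial excess
  half <- offset0 + dh0 / 2
  cross <- which(sign(q - half) != sign(q[1] - half))
  n0 <- if (length(cross)) max(mr[cross[1]], 0.1) else 1
  kd0 <- max(M0 * n0 / 5, 1e-9)

  model_q <- function(ln, lkd, dh, off) {
    h <- itc_expected_heats(exp(ln), exp(lkd), dh, V0, vinj, n_inj, M0, Xs)$heats
    (h + off)[keep]
  }
  df <- data.frame(y = q[keep])
  fit <- try(if (fit_offset) {
    minpack.lm::nlsLM(
      y ~ model_q(ln, lkd, dh, off), data = df,
      start = list(ln = log(n0), lkd = log(kd0), dh = dh0, off = offset0),
      lower = c(log(1e-3), log(1e-12), -Inf, -Inf),
      upper = c(log(1e3), log(1), Inf, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500))
  } else {
    minpack.lm::nlsLM(
      y ~ model_q(ln, lkd, dh, 0), data = df,
      start = list(ln = log(n0), lkd = log(kd0), dh = dh0),
      lower = c(log(1e-3), log(1e-12), -Inf),
      upper = c(log(1e3), log(1), Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500))
  }, silent = TRUE)
  if (inherits(fit, "try-error")) {
    stop("one-set-of-sites fit failed to converge", call. = FALSE)
  }
  p <- coef(fit)
  if (!"off" %in% names(p)) p[["off"]] <- 0
  n_hat <- exp(p[["ln"]]); kd_hat <- exp(p[["lkd"]])
  c_par <- n_hat * M0 / kd_hat
  structure(list(n = n_hat, K_D = kd_hat, dH = p[["dh"]], offset = p[["off"]],
                 rss = sum(stats::resid(fit)^2), c_parameter = c_par,
                 converged = isTRUE(fit$convInfo$isConv),
                 low_confidence = c_par < 0.1),
            class = "itc_fit")
}

#' @export
print.itc_fit <- function(x, ...) {
  cat(sprintf("<itc_fit: n = %.3f, K_D = %.4g M, dH = %.3f kcal/mol, c = %.2g%s>\n",
              x$n, x$K_D, x$dH, x$c_parameter,
              if (isTRUE(x$low_confidence)) ", LOW CONFIDENCE" else ""))
  invisible(x)
}

#' Fold change between two dissociation constants
#'
#' @param kd_a,kd_b dissociation constants, M (both > 0).
#' @return `kd_a / kd_b`.
#' @export
affinity_ratio <- function(kd_a, kd_b) {
  check_positive(kd_a, "kd_a")
  check_positive(kd_b, "kd_b")
  kd_a / kd_b
}
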