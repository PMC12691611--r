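#' Configuration for the steady-state SPR generator
#'
#' @param Rmax maximal response, resonance units (RU).
#' @param K_D dissociation constant, M.
#' @param concentrations analyte concentrations, M (all > 0).
#' @param noise_sd Gaussian response noise SD, RU.
#' @param seed integer RNG seed.
#' @return object of class `spr_sim_config`.
#' @export
spr_sim_config <- function(Rmax = 100, K_D, concentrations = spr_twofold_series(),
                           noise_sd = 2, seed = 1) {
  check_positive(Rmax, "Rmax")
  check_positive(K_D, "K_D")
  check_positive(concentrations, "concentrations")
  check_positive(noise_sd, "noise_sd", strict = FALSE)
  structure(list(Rmax = Rmax, K_D = K_D,
                 concentrations = sort(concentrations),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "spr_sim_config")
}

#' Twofold analyte concentration ladder
#'
#' Doubling series starting at `c_min` up to at least `c_max`; when
#' `extend_to_kd` is given the ladder is extended (by further doublings)
#' until its top concentration reaches at least twice that dissociation
#' constant, so the equilibrium curve is sampled past half-saturation.
#' Defaults give the 31.25-1,000 uM series commonly used for
#' monosaccharide analytes.
#'
#' @param c_min,c_max series bounds, M.
#' @param extend_to_kd optional K_D (M) the series must bracket.
#' @return concentrations in M, ascending.
#' @export
spr_twofold_series <- function(c_min = 31.25e-6, c_max = 1000e-6,
                               extend_to_kd = NULL) {
  check_positive(c_min, "c_min")
  check_positive(c_max, "c_max")
  top <- c_max
  if (!is.null(extend_to_kd)) top <- max(top, 2 * extend_to_kd)
  # keep doubling until the ladder top reaches `top`
  c_min * 2^(0:ceiling(log2(top / c_min) - 1e-9))
}

#' Langmuir 1:1 equilibrium response
#'
#' @param C analyte concentration, M.
#' @param Rmax maximal response, RU.
#' @param K_D dissociation constant, M.
#' @return equilibrium response `Rmax * C / (K_D + C)`, RU.
#' @export
spr_response <- function(C, Rmax, K_D) Rmax * C / (K_D + C)

#' SPR dataset container
#'
#' @param concentration_M analyte concentrations, M.
#' @param response_RU equilibrium responses, RU.
#' @param meta optional named list of metadata (labels, pH, seed, ...).
#' @return object of class `spr_dataset` (a data frame with metadata).
#' @export
spr_dataset <- function(concentration_M, response_RU, meta = list()) {
  if (anyDuplicated(concentration_M)) {
    stop("concentrations must be unique", call. = FALSE)
  }
  check_positive(concentration_M, "concentration_M")
  structure(data.frame(concentration_M = concentration_M,
                       response_RU = response_RU),
            meta = meta, class = c("spr_dataset", "data.frame"))
}

#' Generate a noisy steady-state SPR series
#'
#' @param config a [spr_sim_config()].
#' @return an [spr_dataset()]; metadata records the generating parameters.
#' @export
generate_spr_dataset <- function(config) {
  stopifnot(inherits(config, "spr_sim_config"))
  set.seed(config$seed)
  C <- config$concentrations
  resp <- spr_response(C, config$Rmax, config$K_D) +
    rnorm(length(C), 0, config$noise_sd)
  spr_dataset(C, resp, meta = list(Rmax = config$Rmax, K_D = config$K_D,
                                   noise_sd = config$noise_sd,
                                   seed = config$seed))
}

#' Configuration for the one-set-of-sites ITC generator
#'
#' Geometry defaults follow a standard small-cell titration: 19 sequential
#' 2 uL injections into a 300 uL cell.
#'
#' @param n binding stoichiometry (sites per macromolecule).
#' @param K_D dissociation constant, M.
#' @param dH binding enthalpy, kcal/mol of injectant.
#' @param cell_volume calorimeter cell volume, uL.
#' @param injection_volume volume per injection, uL.
#' @param n_injections number of injections (>= 1).
#' @param cell_conc macromolecule concentration in the cell, M.
#' @param syringe_conc ligand stock concentration in the syringe, M.
#' @param dilution_heat constant per-injection dilution/mixing heat offset,
#'   kcal/mol of injectant.
#' @param noise_sd Gaussian heat noise SD, kcal/mol of injectant.
#' @param seed integer RNG seed.
#' @return object of class `itc_sim_config`.
#' @export
itc_sim_config <- function(n = 1, K_D = 3e-4, dH = -5,
                           cell_volume = 300, injection_volume = 2,
                           n_injections = 19, cell_conc = 1e-3,
                           syringe_conc = 25e-3, dilution_heat = 0,
                           noise_sd = 0, seed = 1) {
  check_positive(n, "n")
  check_positive(K_D, "K_D")
  if (!is.numeric(dH) || length(dH) != 1) stop_field("dH", "must be numeric")
  check_positive(cell_volume, "cell_volume")
  check_positive(injection_volume, "injection_volume")
  if (n_injections < 1) stop_field("n_injections", "must be >= 1")
  check_positive(cell_conc, "cell_conc")
  check_positive(syringe_conc, "syringe_conc")
  check_positive(noise_sd, "noise_sd", strict = FALSE)
  structure(list(n = n, K_D = K_D, dH = dH, cell_volume = cell_volume,
                 injection_volume = injection_volume,
                 n_injections = as.integer(n_injections),
                 cell_conc = cell_conc, syringe_conc = syringe_conc,
                 dilution_heat = dilution_heat, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "itc_sim_config")
}

# Per-injection concentrations under the instantaneous-mix overflow model:
# an injection of volume v mixes into V0 + v, then v overflows, so each
# pre-existing cell species is retained with factor f = V0 / (V0 + v).
itc_concentrations <- function(cell_volume, injection_volume, n_injections,
                               cell_conc, syringe_conc) {
  f <- cell_volume / (cell_volume + injection_volume)
  Mt <- numeric(n_injections); Xt <- numeric(n_injections)
  m_prev <- cell_conc; x_prev <- 0
  for (i in seq_len(n_injections)) {
    m_prev <- m_prev * f
    x_prev <- x_prev * f + syringe_conc * (1 - f)
    Mt[i] <- m_prev; Xt[i] <- x_prev
  }
  list(Mt = Mt, Xt = Xt, f = f)
}

# Equilibrium complex concentration for total site conc S, total ligand X.
complex_conc <- function(S, X, K_D) {
  b <- S + X + K_D
  (b - sqrt(b * b - 4 * S * X)) / 2
}

#' Expected one-set-of-sites injection heats
#'
#' Normalized heat per injection (kcal/mol of injectant) from the
#' one-set-of-sites equilibrium model with per-injection volume-displacement
#' correction of the cell concentrations (instantaneous-mix overflow). The
#' heat of injection i is `dH * V0 * ([MX]_i - f * [MX]_(i-1))` divided by
#' the moles of injectant delivered, where f is the volume retention factor.
#'
#' @param n,K_D,dH model parameters (see [itc_sim_config()]).
#' @param cell_volume,injection_volume,n_injections,cell_conc,syringe_conc
#'   geometry and concentrations (see [itc_sim_config()]).
#' @return list with `heats` (kcal/mol of injectant) and `molar_ratio`
#'   (total ligand over total macromolecule after each injection).
#' @export
itc_expected_heats <- function(n, K_D, dH, cell_volume, injection_volume,
                               n_injections, cell_conc, syringe_conc) {
  cc <- itc_concentrations(cell_volume, injection_volume, n_injections,
                           cell_conc, syringe_conc)
  V0 <- cell_volume * 1e-6            # L
  moles_inj <- syringe_conc * injection_volume * 1e-6
  B <- complex_conc(n * cc$Mt, cc$Xt, K_D)
  B_prev <- c(0, B[-length(B)])
  heats <- dH * V0 * (B - cc$f * B_prev) / moles_inj
  list(heats = heats, molar_ratio = cc$Xt / cc$Mt)
}

#' ITC dataset container
#'
#' @param heats per-injection normalized heats, kcal/mol of injectant.
#' @param cell_volume,injection_volume geometry, uL.
#' @param cell_conc,syringe_conc concentrations, M.
#' @param control optional control-titration heats (same length) used by
#'   [subtract_dilution()].
#' @param meta optional named metadata list.
#' @return object of class `itc_dataset` (a data frame with metadata).
#' @export
itc_dataset <- function(heats, cell_volume, injection_volume,
                        cell_conc, syringe_conc, control = NULL,
                        meta = list()) {
  check_positive(cell_volume, "cell_volume")
  check_positive(injection_volume, "injection_volume")
  check_positive(cell_conc, "cell_conc")
  check_positive(syringe_conc, "syringe_conc")
  if (any(!is.finite(heats))) stop("heats must be finite", call. = FALSE)
  if (!is.null(control) && length(control) != length(heats)) {
    stop("control series length differs from the titration", call. = FALSE)
  }
  cc <- itc_concentrations(cell_volume, injection_volume, length(heats),
                           cell_conc, syringe_conc)
  df <- data.frame(injection = seq_along(heats),
                   molar_ratio = cc$Xt / cc$Mt,
                   heat_kcal_mol = heats)
  structure(df, cell_volume = cell_volume,
            injection_volume = injection_volume,
            cell_conc = cell_conc, syringe_conc = syringe_conc,
            control = control, meta = meta,
            class = c("itc_dataset", "data.frame"))
}

#' Generate a noisy one-set-of-sites ITC titration
#'
#' Injection heats from [itc_expected_heats()] plus a constant dilution
#' heat and Gaussian noise. A matching control series (dilution heat only,
#' with its own noise) is attached for [subtract_dilution()].
#'
#' @param config an [itc_sim_config()].
#' @return an [itc_dataset()] with a control series attached.
#' @export
generate_itc_dataset <- function(config) {
  stopifnot(inherits(config, "itc_sim_config"))
  set.seed(config$seed)
  exp_h <- itc_expected_heats(config$n, config$K_D, config$dH,
                              config$cell_volume, config$injection_volume,
                              config$n_injections, config$cell_conc,
                              config$syringe_conc)
  if (utils::tail(exp_h$molar_ratio, 1) < 1.2 * config$n) {
    warning("syringe_conc too low to approach saturation by the final injection",
            call. = FALSE)
  }
  heats <- exp_h$heats + config$dilution_heat +
    rnorm(config$n_injections, 0, config$noise_sd)
  control <- config$dilution_heat +
    rnorm(config$n_injections, 0, config$noise_sd)
  itc_dataset(heats, config$cell_volume, config$injection_volume,
              config$cell_conc, config$syringe_conc, control = control,
              meta = list(n = config$n, K_D = config$K_D, dH = config$dH,
                          dilution_heat = config$dilution_heat,
                          noise_sd = config$noise_sd, seed = config$seed))
}
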