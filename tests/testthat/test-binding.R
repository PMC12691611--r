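test_that("SPR generator follows the Langmuir curve exactly at zero noise", {
  kd <- 2e-4
  cfg <- spr_sim_config(Rmax = 80, K_D = kd,
                        concentrations = spr_twofold_series(), noise_sd = 0)
  d <- generate_spr_dataset(cfg)
  expect_equal(d$response_RU, 80 * d$concentration_M / (kd + d$concentration_M),
               tolerance = 1e-12)
  # half-saturation
  expect_equal(spr_response(kd, 80, kd), 40)
  # C -> 0 limit
  expect_lt(spr_response(1e-12, 80, kd), 1e-6)
})

test_that("the twofold ladder spans past 2x a requested K_D", {
  s <- spr_twofold_series()
  expect_equal(s, 31.25e-6 * 2^(0:5))
  s2 <- spr_twofold_series(extend_to_kd = 1.055e-3)
  expect_gte(max(s2), 2 * 1.055e-3)
  expect_equal(min(s2), 31.25e-6)
})

test_that("steady-state fit recovers noiseless parameters to 4 sig figs", {
  cfg <- spr_sim_config(Rmax = 100, K_D = 1e-4, noise_sd = 0)
  fit <- fit_spr_steady_state(generate_spr_dataset(cfg))
  expect_equal(fit$K_D, 1e-4, tolerance = 1e-4)
  expect_equal(fit$Rmax, 100, tolerance = 1e-4)
  expect_true(fit$reliable)
  # half-saturation identity: the concentration responding at Rmax/2 is K_D
  half_c <- 1e-4
  expect_equal(spr_response(half_c, fit$Rmax, fit$K_D), fit$Rmax / 2,
               tolerance = 1e-3)
})

test_that("noiseless SPR fits are exact across the parameter plane", {
  for (Rmax in c(10, 100, 1000)) {
    for (kd in c(1e-6, 1e-4, 1e-2)) {
      conc <- spr_twofold_series(c_min = kd / 8, extend_to_kd = kd)
      fit <- fit_spr_steady_state(
        generate_spr_dataset(spr_sim_config(Rmax = Rmax, K_D = kd,
                                            concentrations = conc,
                                            noise_sd = 0)))
      expect_lt(fit$rss, 1e-10)
      expect_equal(fit$K_D, kd, tolerance = 1e-4)
    }
  }
})

test_that("SPR fits are invariant to row order", {
  cfg <- spr_sim_config(Rmax = 100, K_D = 5e-4, noise_sd = 2, seed = 3)
  d <- generate_spr_dataset(cfg)
  shuffled <- d[sample(nrow(d)), ]
  f1 <- fit_spr_steady_state(d)
  f2 <- fit_spr_steady_state(shuffled)
  expect_equal(f1$K_D, f2$K_D, tolerance = 1e-8)
})

test_that("SPR input validation rejects unusable series", {
  expect_error(fit_spr_steady_state(data.frame(concentration_M = c(1e-4, 2e-4),
                                               response_RU = c(1, 2))),
               "at least 4")
  expect_error(fit_spr_steady_state(
    data.frame(concentration_M = c(1, 1.2, 1.5, 2) * 1e-4,
               response_RU = c(1, 2, 3, 4))), "4-fold")
})

test_that("ITC generator matches the independent equilibrium oracle", {
  cfg <- itc_sim_config(n = 1.47, K_D = 3e-4, dH = -5, noise_sd = 0)
  d <- generate_itc_dataset(cfg)
  oracle <- itc_oracle_heats(1.47, 3e-4, -5, 300, 2, 19, 1e-3, 25e-3)
  expect_equal(d$heat_kcal_mol, oracle, tolerance = 1e-9)
})

test_that("zero-enthalpy titrations produce zero heats", {
  cfg <- itc_sim_config(dH = 0, dilution_heat = 0, noise_sd = 0)
  d <- suppressWarnings(generate_itc_dataset(cfg))
  expect_equal(d$heat_kcal_mol, rep(0, 19))
})

test_that("tight binding gives a stoichiometric step from dH to dilution heat", {
  cfg <- itc_sim_config(n = 1, K_D = 1e-9, dH = -8, dilution_heat = 0.3,
                        cell_conc = 1e-3, syringe_conc = 25e-3, noise_sd = 0)
  d <- generate_itc_dataset(cfg)
  pre <- d$heat_kcal_mol[d$molar_ratio < 0.9]
  post <- d$heat_kcal_mol[d$molar_ratio > 1.15]
  expect_true(all(abs(pre - (-8 + 0.3)) < 0.1))
  expect_true(all(abs(post - 0.3) < 0.2))
})

test_that("dilution subtraction removes exactly the control series", {
  cfg <- itc_sim_config(n = 1.2, K_D = 1e-4, dH = -6, dilution_heat = 0.3,
                        noise_sd = 0)
  d <- generate_itc_dataset(cfg)
  corrected <- subtract_dilution(d)
  pure <- itc_expected_heats(1.2, 1e-4, -6, 300, 2, 19, 1e-3, 25e-3)$heats
  expect_equal(corrected$heat_kcal_mol, pure, tolerance = 1e-9)
  # control of zeros leaves data unchanged
  same <- subtract_dilution(d, control = rep(0, 19))
  expect_equal(same$heat_kcal_mol, d$heat_kcal_mol)
  # data equal to control gives all-zero heats
  zero <- subtract_dilution(d, control = d$heat_kcal_mol)
  expect_equal(zero$heat_kcal_mol, rep(0, 19))
  expect_error(subtract_dilution(d, control = rep(0, 5)), "length")
})

test_that("one-set-of-sites fit recovers noiseless parameters within 1%", {
  cfg <- itc_sim_config(n = 1, K_D = 1e-5, dH = -10, cell_conc = 2e-4,
                        syringe_conc = 5e-3, noise_sd = 0)
  fit <- fit_itc_one_site(generate_itc_dataset(cfg))
  expect_equal(fit$n, 1, tolerance = 0.01)
  expect_equal(fit$K_D, 1e-5, tolerance = 0.01)
  expect_equal(fit$dH, -10, tolerance = 0.01)
  expect_false(fit$low_confidence)
})

test_that("flat thermograms are rejected as unidentifiable", {
  cfg <- itc_sim_config(dH = 0, noise_sd = 0)
  d <- suppressWarnings(generate_itc_dataset(cfg))
  expect_error(fit_itc_one_site(d), "degenerate")
})

test_that("ITC fit bias vanishes as noise goes to zero", {
  bias <- vapply(c(0.2, 0.05, 0.005), function(ns) {
    kds <- vapply(1:5, function(s) {
      cfg <- itc_sim_config(n = 1.47, K_D = 3e-4, dH = -5, noise_sd = ns,
                            seed = s)
      fit_itc_one_site(subtract_dilution(generate_itc_dataset(cfg)))$K_D
    }, numeric(1))
    abs(median(kds) - 3e-4) / 3e-4
  }, numeric(1))
  expect_false(is.unsorted(rev(bias)))      # decreasing with noise
  expect_lt(bias[3], 0.01)
})

test_that("a low c-parameter run is flagged low-confidence", {
  cfg <- itc_sim_config(n = 1, K_D = 5e-2, dH = -5, cell_conc = 1e-3,
                        syringe_conc = 0.5, noise_sd = 0)
  fit <- fit_itc_one_site(suppressWarnings(generate_itc_dataset(cfg)))
  expect_true(fit$low_confidence)
})

test_that("affinity ratios reproduce the worked fold-change examples", {
  expect_equal(affinity_ratio(1.040e-2, 1.055e-3), 9.86, tolerance = 0.001)
  expect_equal(affinity_ratio(2.5e-3, 2.5e-3), 1)
  expect_equal(affinity_ratio(2e-3, 1e-3), 2)
  expect_error(affinity_ratio(-1, 1), "kd_a")
})
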