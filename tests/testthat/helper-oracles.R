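# Independent oracles used across tests. These deliberately re-derive
# results through different code paths than the package implementation.

# Optimal assignment by exhaustive permutation search (nr <= nc).
brute_force_assignment <- function(cost) {
  nr <- nrow(cost); nc <- ncol(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(matrix(v, nrow = 1))
    out <- NULL
    for (i in seq_along(v)) {
      rest <- perms(v[-i])
      out <- rbind(out, cbind(v[i], rest))
    }
    out
  }
  subsets <- utils::combn(nc, nr)
  best <- Inf; best_assign <- NULL
  for (s in seq_len(ncol(subsets))) {
    cols <- subsets[, s]
    pm <- perms(cols)
    for (p in seq_len(nrow(pm))) {
      tot <- sum(cost[cbind(seq_len(nr), pm[p, ])])
      if (tot < best) { best <- tot; best_assign <- pm[p, ] }
    }
  }
  list(cost = best, assignment = best_assign)
}

# Per-pixel disc-membership union over every detection, full grid.
brute_force_coverage <- function(traj, arena, grid_pixel_size,
                                 radius = "semi_minor") {
  ps <- grid_pixel_size
  nr <- ceiling(arena[2] / ps); nc <- ceiling(arena[1] / ps)
  raster <- matrix(FALSE, nr, nc)
  rad <- if (radius == "semi_minor") traj$width_um / 2 else traj$width_um
  for (i in seq_len(nrow(traj))) {
    dx2 <- ((seq_len(nc) - 0.5) * ps - traj$x_um[i])^2
    dy2 <- ((seq_len(nr) - 0.5) * ps - traj$y_um[i])^2
    raster <- raster | (outer(dy2, dx2, "+") <= rad[i] * rad[i])
  }
  raster
}

# One-set-of-sites injection heats via numeric equilibrium solution
# (uniroot + Newton polish on the free-ligand concentration) and explicit
# per-injection mixing simulation.
itc_oracle_heats <- function(n, K_D, dH, cell_volume, injection_volume,
                             n_injections, cell_conc, syringe_conc,
                             dilution_heat = 0) {
  f <- cell_volume / (cell_volume + injection_volume)
  V0 <- cell_volume * 1e-6
  moles_inj <- syringe_conc * injection_volume * 1e-6
  Mt <- cell_conc; Xt <- 0; B_prev <- 0
  out <- numeric(n_injections)
  for (i in seq_len(n_injections)) {
    Mt <- Mt * f
    Xt <- Xt * f + syringe_conc * (1 - f)
    S <- n * Mt
    g <- function(x) x + S * x / (K_D + x) - Xt
    x <- uniroot(g, c(0, Xt), tol = .Machine$double.eps)$root
    for (k in 1:5) {                      # Newton polish to machine precision
      gp <- 1 + S * K_D / (K_D + x)^2
      x <- x - g(x) / gp
    }
    B <- S * x / (K_D + x)
    out[i] <- dH * V0 * (B - f * B_prev) / moles_inj + dilution_heat
    B_prev <- B
  }
  out
}

# Match each detection to the nearest ground-truth cell in the same frame.
match_to_truth <- function(det_frame, truth_frame) {
  vapply(seq_len(nrow(det_frame)), function(i) {
    d <- sqrt((truth_frame$x_um - det_frame$x_um[i])^2 +
              (truth_frame$y_um - det_frame$y_um[i])^2)
    truth_frame$cell[which.min(d)]
  }, numeric(1))
}
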