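test_that("pre-stretch sampling matches truncated-normal moments", {
  p <- sim_params(n_sectors = 10000L, mu_pre = 1.10, sigma_pre = 0.05,
                  lambda_min = 1.00, lambda_max = 1.35, seed = 21L)
  cell <- init_cell("circular", p)
  mom <- truncnorm_moments(1.10, 0.05, 1.00, 1.35)
  expect_equal(mean(cell$lambda_pre), mom$mean, tolerance = 0.01)
  expect_equal(sd(cell$lambda_pre), mom$sd, tolerance = 0.01)
  expect_true(all(cell$lambda_pre >= 1.00 & cell$lambda_pre <= 1.35))
})

test_that("cell initialization is deterministic and degenerates at zero spread", {
  p <- sim_params(sigma_pre = 0, seed = 5L)
  cell <- init_cell("circular", p)
  expect_true(all(cell$lambda_pre == p$mu_pre))
  p2 <- sim_params(seed = 9L)
  expect_identical(init_cell("circular", p2), init_cell("circular", p2))
  # circular sectors tile [0, pi) uniformly
  expect_equal(cell$theta, (seq_len(36) - 0.5) * pi / 36)
  expect_equal(sum(cell$width), pi)
})

test_that("spindle cells concentrate orientations about their axis", {
  p <- sim_params(n_sectors = 400L, spindle_sd = 0.2, seed = 3L)
  cell <- init_cell("spindle", p, spindle_axis = pi / 3)
  d <- fold_deg(cell$theta, pi / 3) * pi / 180
  expect_lt(mean(d), 0.25)   # wrapped-normal spread, not uniform (~pi/4)
})

test_that("stretch depolymerizes sectors outside the allowable window", {
  p <- sim_params(lambda_min = 1.00, lambda_max = 1.20, mu_pre = 1.10,
                  sigma_pre = 0)
  cell <- manual_cell(c(0, pi / 4, pi / 2), p)
  st <- apply_stretch(cell, 0.10, p, nu = 1)
  # direct arithmetic: 1.10 * (1 + 0.10 * cos(2 theta))
  expect_equal(st$lambda_total, c(1.21, 1.10, 0.99), tolerance = 1e-12)
  expect_identical(st$intact, c(FALSE, TRUE, FALSE))
  expect_equal(st$rho, c(0, p$rho0, 0))
  # released F-actin credited to the reservoir
  expect_equal(st$reservoir,
               p$reservoir_capacity + 2 * p$rho0 * pi / 3)
  # zero strain changes nothing
  st0 <- apply_stretch(manual_cell(c(0, pi / 4, pi / 2), p), 0, p)
  expect_true(all(st0$intact))
  expect_equal(st0$lambda_total, st0$lambda_pre)
})

test_that("depolymerization matches a brute-force per-sector oracle", {
  p <- sim_params(n_sectors = 10000L, sigma_pre = 0.10, seed = 31L)
  cell <- init_cell("circular", p)
  st <- apply_stretch(cell, 0.05, p, nu = 1)
  lam <- cell$lambda_pre * (1 + 0.05 * (cos(cell$theta)^2 - sin(cell$theta)^2))
  out <- logical(length(lam))
  for (i in seq_along(lam)) {
    out[i] <- lam[i] < p$lambda_min || lam[i] > p$lambda_max
  }
  expect_identical(st$intact, !out)
})

test_that("adhesion stress is tension-only and load-shared", {
  p <- sim_params(sigma_pre = 0)
  cell <- manual_cell(c(0, pi / 4, pi / 2), p)
  st <- apply_stretch(cell, 0.05, p)
  s <- adhesion_stress(st, p)
  expect_equal(attr(s, "load_share"), 1)  # nothing ruptured in tension
  lam <- st$lambda_total
  expect_equal(as.numeric(s), p$k_fiber * p$rho0 * pmax(lam - 1, 0))
  # a compressed-but-intact fiber bears no adhesion tension
  p2 <- sim_params(lambda_min = 0.95, mu_pre = 1.04, sigma_pre = 0)
  comp <- apply_stretch(manual_cell(c(0, pi / 2), p2), 0.05, p2)
  expect_true(all(comp$intact))
  expect_lt(comp$lambda_total[2], 1)
  expect_equal(adhesion_stress(comp, p2)[[2]], 0)
  # depolymerized sectors contribute nothing
  st$rho[1] <- 0; st$intact[1] <- FALSE
  expect_equal(adhesion_stress(st, p)[[1]], 0)
})

test_that("in-band growth follows the saturating exponential closed form", {
  # stress stays inside a wide band throughout growth, so the forward-Euler
  # densities must track rho_max - (rho_max - rho0) exp(-k t)
  p <- sim_params(sigma_pre = 0, s_low = 0.10, s_high = 5, dt = 0.002,
                  duration = 5, n_sectors = 4L)
  cell <- manual_cell(c(0, pi / 8, 3 * pi / 8, pi / 2), p)
  cell <- apply_stretch(cell, 0.05, p)
  n_steps <- round(p$duration / p$dt)
  for (k in seq_len(n_steps)) cell <- step_cell(cell, p$dt, p)
  rho_exact <- p$rho_max - (p$rho_max - p$rho0) * exp(-p$k_poly * p$duration)
  expect_equal(cell$rho[1], rho_exact, tolerance = 1e-3)   # O(dt) accuracy
  # sub-threshold sector (stress below s_low) never grows
  expect_equal(cell$rho[4], p$rho0)
})

test_that("ROCK inhibition blocks all polymerization", {
  p <- sim_params(rock_inhibited = TRUE, seed = 11L)
  out <- simulate_remodeling(p, eps_o = 0.05, keep_densities = TRUE)
  expect_true(all(diff(out$model_fibrosity) <= 1e-12))
  expect_true(all(out$densities <= p$rho0 + 1e-12))
})

test_that("a finite reservoir caps total density gain", {
  cap <- 0.2
  p <- sim_params(sigma_pre = 0, reservoir_finite = TRUE,
                  reservoir_capacity = cap, seed = 2L)
  out <- simulate_remodeling(p, eps_o = 0.05, keep_densities = TRUE)
  gain <- sum((out$densities[nrow(out$densities), ] - out$densities[1, ]) *
                out$cell$width)
  expect_lte(gain, cap + 1e-9)
  expect_gte(out$cell$reservoir, 0)
  # same cell with an unlimited pool grows strictly more
  p_inf <- p; p_inf$reservoir_finite <- FALSE
  out_inf <- simulate_remodeling(p_inf, eps_o = 0.05, keep_densities = TRUE)
  gain_inf <- sum((out_inf$densities[nrow(out_inf$densities), ] -
                     out_inf$densities[1, ]) * out_inf$cell$width)
  expect_gt(gain_inf, gain)
})

test_that("densities stay bounded and depolymerized sectors stay empty", {
  for (s in 1:6) {
    p <- sim_params(sigma_pre = c(0.01, 0.05, 0.3)[(s %% 3) + 1], seed = 40L + s)
    out <- simulate_remodeling(p, eps_o = 0.05, keep_densities = TRUE)
    expect_true(all(out$densities >= 0))
    expect_true(all(out$densities <= p$rho_max + 1e-12))
    expect_true(all(out$densities[nrow(out$densities), out$depolymerized] == 0))
    expect_equal(out$model_fibrosity[1], 1)
  }
})

test_that("expected depolymerized fraction is non-decreasing in pre-stretch spread", {
  sig <- c(0.005, 0.02, 0.06, 0.15, 0.4)
  frac <- vapply(seq_along(sig), function(i) {
    mean(vapply(1:25, function(r) {
      p <- sim_params(sigma_pre = sig[i], seed = 1000L * i + r)
      mean(simulate_remodeling(p, eps_o = 0.05)$depolymerized)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(frac) >= -0.005))   # monotone up to MC jitter
})

test_that("an unstretched control with sub-threshold stress stays flat", {
  p <- sim_params(sigma_pre = 0, seed = 1L)
  out <- simulate_remodeling(p, eps_o = 0)
  expect_true(all(out$model_fibrosity == 1))
  expect_equal(as.character(out$response_class), "flat")
})

test_that("chained stretches reuse the final state", {
  p <- sim_params(seed = 13L)
  first <- simulate_remodeling(p, eps_o = 0.05)
  second <- simulate_remodeling(p, eps_o = 0.10, cell = first$cell)
  # sectors lost in the first stretch stay lost; the second adds more
  expect_true(all(second$depolymerized[first$depolymerized]))
  expect_gte(sum(second$depolymerized), sum(first$depolymerized))
})

test_that("the sweep expresses the three temporal regimes in order", {
  sw <- sweep_prestretch_sd(c(0.01, 0.045, 0.5), n_reps = 15L,
                            base_params = sim_params(seed = 8L), eps_o = 0.05)
  dominant <- colnames(sw$counts)[apply(sw$counts, 1L, which.max)]
  expect_identical(dominant,
                   c("monotonic_reinforcement",
                     "retraction_then_reinforcement",
                     "monotonic_retraction"))
  expect_identical(sum(sw$anomalies), 0L)
})
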