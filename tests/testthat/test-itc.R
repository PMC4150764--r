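proto <- titration_protocol()

test_that("model heats are linear in enthalpy and vanish when dH = 0", {
  p0 <- binding_params(n = 0.5, dh = 0, kd_nM = 200)
  expect_true(all(model_heats(p0, proto)$heat_kcal_per_mol == 0))
  p1 <- binding_params(n = 0.5, dh = -4, kd_nM = 200)
  p2 <- binding_params(n = 0.5, dh = -8, kd_nM = 200)
  expect_equal(model_heats(p2, proto)$heat_kcal_per_mol,
               2 * model_heats(p1, proto)$heat_kcal_per_mol, tolerance = 1e-12)
  two0 <- binding_params(n = c(0.3, 0.3), dh = c(0, 0), kd_nM = c(300, 30))
  expect_true(all(model_heats(two0, proto)$heat_kcal_per_mol == 0))
})

test_that("tight binding saturates at dH before and 0 after the equivalence point", {
  p <- binding_params(n = 0.52, dh = -10, ka = 1e12)  # c >> 1000
  mh <- model_heats(p, proto)
  pre <- mh$heat_kcal_per_mol[mh$molar_ratio < 0.45]
  post <- mh$heat_kcal_per_mol[mh$molar_ratio > 0.62]
  expect_true(all(abs(pre - (-10)) < 0.05))
  expect_true(all(abs(post) < 0.05))
  # total heat evolved ~ n dH M0 V0 (displacement-corrected totals)
  v0 <- 200e-6; xs <- 120e-6
  q_total <- sum(mh$heat_kcal_per_mol * xs * mh$volume_ul * 1e-6)
  m_final <- 10e-6 * prod(1 - mh$volume_ul / 200)
  expect_equal(q_total, 0.52 * (-10) * m_final * v0, tolerance = 0.02)
})

test_that("a two-site model with equal sites degenerates to one site", {
  pa <- binding_params(n = c(0.31, 0.4), dh = c(-8, -8), ka = c(2e6, 2e6))
  pb <- binding_params(n = 0.71, dh = -8, ka = 2e6)
  expect_lt(max(abs(model_heats(pa, proto)$heat_kcal_per_mol -
                      model_heats(pb, proto)$heat_kcal_per_mol)), 1e-9)
  # and across a different protocol
  proto2 <- titration_protocol(cell_volume_ul = 1400, cell_conc_uM = 5,
                               syringe_conc_uM = 60,
                               injection_volumes_ul = rep(10, 30))
  expect_lt(max(abs(model_heats(pa, proto2)$heat_kcal_per_mol -
                      model_heats(pb, proto2)$heat_kcal_per_mol)), 1e-9)
})

test_that("the free-ligand solution satisfies mass balance on random draws", {
  set.seed(12)
  for (i in 1:200) {
    params <- binding_params(
      n = runif(2, 0.1, 1.5), dh = runif(2, -20, 20),
      ka = 10^runif(2, 4, 9)
    )
    xt <- 10^runif(1, -7, -4)
    m <- 10^runif(1, -6, -4)
    xf <- tetrdna:::free_ligand(xt, m, params)
    resid <- xf + m * sum(params$n * params$ka * xf / (1 + params$ka * xf)) - xt
    expect_lt(abs(resid) / xt, 1e-10)
  }
})

test_that("simulation is deterministic, seed-local and validates noise", {
  p <- binding_params(n = 0.52, dh = -10.1, kd_nM = 200)
  a <- simulate_itc(p, proto, noise_sd = 0.3, seed = 7)
  b <- simulate_itc(p, proto, noise_sd = 0.3, seed = 7)
  expect_identical(a$heat_kcal_per_mol, b$heat_kcal_per_mol)
  c0 <- simulate_itc(p, proto, noise_sd = 0, seed = 7)
  expect_identical(c0$heat_kcal_per_mol, model_heats(p, proto)$heat_kcal_per_mol)
  expect_error(simulate_itc(p, proto, noise_sd = -1), "non-negative")
  # simulating must not disturb the global RNG stream
  set.seed(123); x1 <- runif(1)
  set.seed(123); invisible(simulate_itc(p, proto, 0.3, seed = 99)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("dilution blanks subtract elementwise", {
  p <- binding_params(n = 0.52, dh = -10.1, kd_nM = 200)
  iso <- simulate_itc(p, proto, 0, 1)
  blank <- iso; blank$heat_kcal_per_mol <- rep(0.25, nrow(iso))
  corr <- subtract_dilution(iso, blank)
  expect_equal(corr$heat_kcal_per_mol, iso$heat_kcal_per_mol - 0.25)
  zero <- subtract_dilution(iso, iso)
  expect_true(all(zero$heat_kcal_per_mol == 0))
  expect_error(subtract_dilution(iso, blank[-1, ]), "injection counts")
})

test_that("derived thermodynamics match closed-form evaluations", {
  p <- binding_params(n = 1, dh = -10.1, ka = 1)
  expect_equal(derive_thermo(p, 298.15)$dg_kcal, 0, tolerance = 1e-12)
  p200 <- binding_params(n = 0.52, dh = -10.1, kd_nM = 200)
  th <- derive_thermo(p200, 298.15)
  expect_equal(th$dg_kcal, -1.9872e-3 * 298.15 * log(1 / 2e-7), tolerance = 1e-9)
  expect_equal(th$dg_kcal, -9.138, tolerance = 1e-3)
  # dH - T dS with dS = -2.7e-3 kcal/mol/K
  expect_equal(-10.1 - 298.15 * (-2.7e-3), -9.295, tolerance = 1e-3)
  expect_equal(th$tds_kcal, th$dh_kcal - th$dg_kcal, tolerance = 1e-12)
})

test_that("fit standard errors and information criteria are reported sanely", {
  p <- binding_params(n = 0.52, dh = -10.1, kd_nM = 200)
  iso <- simulate_itc(p, proto, noise_sd = 0.3, seed = 11)
  f <- fit_isotherm(iso, "one-site", n_starts = 5, seed = 3)
  expect_true(f$converged)
  expect_true(all(is.finite(unlist(f$se))))
  expect_true(all(unlist(f$se) >= 0))
  td <- tidy(f)
  expect_equal(nrow(td), 1)
  expect_true(td$kd_nM > 50 && td$kd_nM < 800)
  gl <- glance(f)
  expect_equal(gl$model, "one-site")
  expect_true(is.finite(gl$aicc))
})

test_that("noisy refits bracket the generating affinity at nominal coverage", {
  p <- binding_params(n = 0.52, dh = -10.1, kd_nM = 200)
  covered <- 0
  n_rep <- 50
  for (s in seq_len(n_rep)) {
    iso <- simulate_itc(p, proto, noise_sd = 0.3, seed = s)
    f <- fit_isotherm(iso, "one-site", n_starts = 3, seed = 7)
    lka <- log(f$params$ka)
    se_lka <- f$se["ka", 1] / f$params$ka  # delta method back to log scale
    if (abs(lka - log(5e6)) <= 1.96 * se_lka) covered <- covered + 1
  }
  expect_gte(covered / n_rep, 0.9)
})

test_that("isotherm CSV files round-trip", {
  p <- binding_params(n = 0.52, dh = -10.1, kd_nM = 200)
  iso <- simulate_itc(p, proto, 0, 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_isotherm_csv(iso, path)
  expect_identical(readLines(path)[1], "injection,volume_ul,heat_kcal_per_mol")
  back <- read_isotherm_csv(path)
  expect_equal(back$heat_kcal_per_mol, iso$heat_kcal_per_mol, tolerance = 1e-9)
  expect_error(read_isotherm_csv(withr::local_tempfile(lines = "a,b\n1,2")),
               "columns")
})
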