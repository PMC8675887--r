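test_that("cardinal points match hand values on an exactly sampled transient", {
  cp <- extract_cardinal_points(toy_transient())
  expect_equal(cp$F0, 5000)
  expect_equal(cp$F300, 6600)
  expect_equal(cp$FJ, 13000)
  expect_equal(cp$FM, 25000)
  expect_equal(cp$t_FM, 1)
  expect_equal(cp$VJ, 0.4)
  expect_equal(cp$M0, 4 * (6600 - 5000) / (25000 - 5000))  # 0.32
  expect_false(cp$degenerate)
})

test_that("landmark interpolation matches an independent two-point log-time interpolant", {
  times <- c(4e-5, 6.3e-5, 1e-3, 5e-3, 1e-1)
  fl <- c(5100, 5600, 12000, 18000, 25000)
  tr <- fluorescence_transient("x", times, fl)
  cp <- extract_cardinal_points(tr)
  expect_equal(cp$F0, bf_log_interp(4e-5, 5100, 6.3e-5, 5600, 5e-5),
               tolerance = 1e-12)
  expect_equal(cp$FJ, bf_log_interp(1e-3, 12000, 5e-3, 18000, 2e-3),
               tolerance = 1e-12)
})

test_that("flat and non-rising transients are flagged degenerate, not errors", {
  flat <- fluorescence_transient("flat", c(1e-5, 1e-4, 1e-3, 1e-2),
                                 rep(7000, 4))
  cp <- expect_no_error(extract_cardinal_points(flat))
  expect_true(cp$degenerate)
  expect_equal(cp$FM, 7000)
  expect_true(is.na(cp$VJ))
})

test_that("a transient not spanning the landmarks names the missing one", {
  short <- fluorescence_transient("short", c(1e-4, 1e-3, 1e-2, 1e-1), 1:4 * 100)
  expect_error(extract_cardinal_points(short), "t0")
})

test_that("relative variable fluorescence anchors, clamps, and rejects degenerate span", {
  expect_equal(relative_variable_fluorescence(5000, 5000, 25000), 0)
  expect_equal(relative_variable_fluorescence(25000, 5000, 25000), 1)
  expect_equal(relative_variable_fluorescence(13000, 5000, 25000), 0.4)
  expect_warning(v <- relative_variable_fluorescence(26000, 5000, 25000),
                 "clamped")
  expect_equal(v, 1)
  expect_error(relative_variable_fluorescence(1, 10, 10), "degenerate")
})

test_that("complementary area matches the analytic single-exponential integral", {
  k <- 50; F0 <- 5000; FM <- 25000
  times <- 10^seq(-5, 0, length.out = 400)
  fl <- FM - (FM - F0) * exp(-k * times)
  tr <- fluorescence_transient("exp", times, fl)
  # curve is strictly increasing so FM sits at the last point
  a_num <- compute_area(tr, FM, times[length(times)])
  a_true <- (FM - F0) / k * (exp(-k * times[1]) - exp(-k * times[length(times)]))
  expect_equal(a_num, a_true, tolerance = 5e-3)

  const <- fluorescence_transient("c", c(1e-5, 1e-4, 1e-3, 1e-2), rep(9000, 4))
  expect_equal(compute_area(const, 9000, 1e-2), 0)
})

test_that("area quadrature is converged at the default sampling density", {
  sp <- kinetic_spec()
  tr1 <- simulate_transient(sp, sampling_grid(points = 160), noise_sd = 0)
  tr3 <- simulate_transient(sp, sampling_grid(points = 480), noise_sd = 0)
  a1 <- compute_area(tr1, max(tr1$fluorescence), max(tr1$times))
  a3 <- compute_area(tr3, max(tr3$fluorescence), max(tr3$times))
  expect_lt(abs(a1 - a3) / a3, 1e-3)
})

test_that("the parameter vector reproduces the hand-derived worked example", {
  cp <- list(sample_id = "w", F0 = 5000, FM = 25000, VJ = 0.4, M0 = 1.2)
  p <- compute_jip_parameters(cp, area = 123)
  expect_equal(p$phi_po, 0.8)
  expect_equal(p$vj, 0.4)
  expect_equal(p$psi_o, 0.6)
  expect_equal(p$abs_cs, 5000)
  expect_equal(p$tr0_cs, 4000)
  expect_equal(p$et0_cs, 2400)
  expect_equal(p$di0_cs, 1000)
  expect_equal(p$rc0_cs, 5000 * 0.8 * 0.4 / 1.2)   # 1333.33
  expect_equal(p$gamma_rc_odds, 0.8 * 0.4 / 1.2)   # 0.26667
  expect_equal(p$tr0_di0, 4)
  expect_equal(p$psi_odds, 1.5)
  expect_equal(p$pi_abs, 1.6)
  expect_equal(p$area, 123)
})

test_that("the fully quenched limit gives zero photochemical fluxes", {
  p <- compute_jip_parameters(list(F0 = 7000, FM = 7000, VJ = NA, M0 = NA), 0)
  expect_equal(p$phi_po, 0)
  expect_equal(p$tr0_cs, 0)
  expect_equal(p$et0_cs, 0)
  expect_equal(p$di0_cs, p$abs_cs)
  expect_equal(p$pi_abs, 0)
})

test_that("undefined odds are NA markers while other fields persist", {
  p <- compute_jip_parameters(list(F0 = 0, FM = 100, VJ = 0.4, M0 = 1), 1)
  expect_true(is.na(p$tr0_di0))   # phi_po = 1
  expect_true(is.na(p$pi_abs))
  expect_equal(p$phi_po, 1)
  p2 <- compute_jip_parameters(list(F0 = 50, FM = 100, VJ = 0, M0 = 1), 1)
  expect_true(is.na(p2$psi_odds)) # psi_o = 1
  expect_equal(p2$et0_cs, p2$tr0_cs)
})

test_that("fluxes scale with fluorescence while ratio parameters are invariant", {
  tr <- toy_transient()
  for (c_scale in c(0.5, 3, 17)) {
    tr2 <- fluorescence_transient("s", tr$times, tr$fluorescence * c_scale)
    p1 <- compute_jip_parameters(extract_cardinal_points(tr),
                                 compute_area(tr, 25000, 1))
    cp2 <- extract_cardinal_points(tr2)
    p2 <- compute_jip_parameters(cp2, compute_area(tr2, cp2$FM, cp2$t_FM))
    for (f in c("abs_cs", "tr0_cs", "et0_cs", "di0_cs", "rc0_cs"))
      expect_equal(p2[[f]], c_scale * p1[[f]], tolerance = 1e-12)
    for (f in c("phi_po", "psi_o", "vj", "m0", "pi_abs"))
      expect_equal(p2[[f]], p1[[f]], tolerance = 1e-12)
  }
})

test_that("raising FJ raises VJ and depresses psi_o, et0_cs and pi_abs", {
  base <- list(F0 = 5000, FM = 25000, M0 = 1.2)
  fj <- seq(9000, 21000, by = 2000)
  out <- lapply(fj, function(f) {
    vj <- (f - base$F0) / (base$FM - base$F0)
    compute_jip_parameters(list(F0 = base$F0, FM = base$FM, VJ = vj,
                                M0 = base$M0), 1)
  })
  vj <- vapply(out, `[[`, numeric(1), "vj")
  psi <- vapply(out, `[[`, numeric(1), "psi_o")
  et <- vapply(out, `[[`, numeric(1), "et0_cs")
  pi <- vapply(out, `[[`, numeric(1), "pi_abs")
  expect_true(all(diff(vj) > 0))
  expect_true(all(diff(psi) < 0))
  expect_true(all(diff(et) < 0))
  expect_true(all(diff(pi) < 0))
})

test_that("batch analysis reports rejects and is order-invariant", {
  sim <- simulate_experiment(default_design(seed = 11, n_rep = 2))
  trs <- sim$transients
  trs$flat <- fluorescence_transient("flat", c(1e-5, 1e-4, 1e-3, 1e-2),
                                     rep(5000, 4))
  res <- analyze_transients(trs)
  expect_equal(nrow(res$parameters), 16)
  expect_equal(res$rejects$sample_id, "flat")
  expect_equal(res$rejects$reason, "degenerate")

  res_rev <- analyze_transients(rev(trs))
  expect_equal(res_rev$parameters, res$parameters)

  expect_error(analyze_transients(list()), "no transients")
  conv <- jip_conventions(degenerate = "error")
  expect_error(analyze_transients(trs, conv), "flat")
})
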