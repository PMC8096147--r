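test_that("derivative Tm finds the center of a symmetric sigmoid", {
  # noise-free symmetric sigmoid centered at 330 K, flat baselines
  tc <- seq(20, 90, 0.5)
  A <- 1 / (1 + exp(-(tc - (330 - 273.15)) / 3))
  cv <- melting_curve(tc, A)
  expect_equal(as.numeric(tm_first_derivative(cv)), 56.85, tolerance = 0.01)
})

test_that("derivative Tm on a two-state hairpin matches the closed form", {
  truth <- melt_truth$hairpin
  tm_true_C <- 1000 * truth$dH / truth$dS - 273.15  # 71.95
  cv <- gen_melting_curve(truth$dH, truth$dS, truth$mol, c_T = NA_real_,
                          baselines = list(folded = c(intercept = 1, slope = 0),
                                           unfolded = c(intercept = 1.2, slope = 0)))[[1]]
  expect_lt(abs(as.numeric(tm_first_derivative(cv)) - tm_true_C), 0.3)

  # sloping baselines shift the derivative peak by < 0.3 degC
  cv2 <- gen_melting_curve(truth$dH, truth$dS, truth$mol, c_T = NA_real_,
                           baselines = list(folded = c(intercept = 1, slope = -5e-4),
                                            unfolded = c(intercept = 1.2, slope = 5e-4)))[[1]]
  expect_lt(abs(as.numeric(tm_first_derivative(cv2)) -
                as.numeric(tm_first_derivative(cv))), 0.3)
})

test_that("featureless profiles raise a no-transition error", {
  tc <- seq(20, 90, 0.5)
  expect_error(tm_first_derivative(melting_curve(tc, 1 + 0.001 * tc)),
               "no melting transition")
  # transition center outside the observed range
  expect_error(
    tm_first_derivative(
      melting_curve(tc, 1 / (1 + exp(-(tc - 95) / 3)))),
    "no melting transition")
})

test_that("baseline correction recovers theta and generator baselines", {
  # a sharp hairpin whose transition is fully contained in the grid, so
  # the explicit flank windows are pure baseline
  dH <- -80; dS <- -240  # Tm = 333.3 K (60.2 degC)
  bls <- list(folded = c(intercept = 0, slope = 0),
              unfolded = c(intercept = 1, slope = 0))
  cv <- gen_melting_curve(dH, dS, "hairpin", c_T = NA_real_,
                          t_range = c(5, 95), baselines = bls)[[1]]
  bl <- fit_baselines(cv, folded_window = c(5, 25),
                      unfolded_window = c(85, 95))
  T_K <- cv$temperature_C + 273.15
  th_true <- two_state_theta(T_K, dH, dS, "hairpin")
  # A = 1 - theta here, so theta is recovered essentially exactly
  expect_lt(max(abs(bl$theta - th_true)), 1e-3)
  # theta = 0.5 at the closed-form Tm (interpolated off the 0.5 degC grid)
  expect_equal(approx(T_K, bl$theta, xout = 1000 * dH / dS)$y, 0.5,
               tolerance = 1e-3)

  # known sloping baselines recovered from the flanks
  bls2 <- list(folded = c(intercept = 0.95, slope = 3e-4),
               unfolded = c(intercept = 1.14, slope = 5e-4))
  cv2 <- gen_melting_curve(dH, dS, "hairpin", c_T = NA_real_,
                           t_range = c(5, 95), baselines = bls2)[[1]]
  bl2 <- fit_baselines(cv2, folded_window = c(5, 25),
                       unfolded_window = c(85, 95))
  expect_equal(unname(bl2$baselines$folded["slope"]), 3e-4,
               tolerance = 1e-4)
  expect_equal(unname(bl2$baselines$unfolded["slope"]), 5e-4,
               tolerance = 0.02)
  expect_equal(unname(bl2$baselines$folded["intercept"]), 0.95,
               tolerance = 1e-4)
})

test_that("degenerate baselines are rejected", {
  tc <- seq(20, 90, 0.5)
  cv <- melting_curve(tc, rep(1, length(tc)) + rnorm(length(tc), 0, 1e-9))
  expect_error(fit_baselines(cv), "degenerate")
})

test_that("van't Hoff fit inverts the forward model exactly at zero noise", {
  for (nm in names(melt_truth)) {
    truth <- melt_truth[[nm]]
    cv <- gen_melting_curve(truth$dH, truth$dS, truth$mol,
                            c_T = truth$c_T)[[1]]
    fit <- van_t_hoff_fit(cv)
    expect_equal(fit$dH, truth$dH, tolerance = 1e-5)
    expect_equal(fit$dS, truth$dS, tolerance = 1e-5)
    # internal consistency of the reported parameter set
    expect_equal(fit$dG298, fit$dH - 298.15 * fit$dS / 1000,
                 tolerance = 1e-10)
    if (truth$mol == "unimolecular_hairpin")
      expect_equal(fit$Tm_C + 273.15, 1000 * fit$dH / fit$dS,
                   tolerance = 1e-6)
  }
})

test_that("self-complementary Tm follows the 1/Tm vs ln(cT) line", {
  truth <- melt_truth$self
  # theta = 0.5 at the Tm given by the concentration closed form
  for (cc in c(1e-6, 1e-5, 1e-4)) {
    tm <- 1 / ((1.987 / (1000 * truth$dH)) * log(cc) +
                 truth$dS / (1000 * truth$dH))
    th <- two_state_theta(tm, truth$dH, truth$dS, truth$mol, cc)
    expect_equal(th, 0.5, tolerance = 1e-9)
    expect_equal(two_state_tm(truth$dH, truth$dS, truth$mol, cc), tm)
  }
})

test_that("concentration fit recovers generator parameters exactly", {
  truth <- melt_truth$nonself
  cc <- c(1, 3, 10, 30, 100) * 1e-6
  tms <- vapply(cc, function(c)
    two_state_tm(truth$dH, truth$dS, truth$mol, c), numeric(1))
  fit <- tm_concentration_fit(tms, cc, truth$mol)
  expect_equal(fit$dH, truth$dH, tolerance = 1e-8)
  expect_equal(fit$dS, truth$dS, tolerance = 1e-8)
  expect_identical(fit$method, "tm_vs_concentration")

  # self-complementary convention uses ln(cT), not ln(cT/4)
  truth2 <- melt_truth$self
  tms2 <- vapply(cc, function(c)
    two_state_tm(truth2$dH, truth2$dS, truth2$mol, c), numeric(1))
  fit2 <- tm_concentration_fit(tms2, cc, truth2$mol)
  expect_equal(fit2$dH, truth2$dH, tolerance = 1e-8)
})

test_that("concentration fit rejects invalid input", {
  expect_error(tm_concentration_fit(c(330, 331, 332), c(1e-6, 1e-5, 1e-4),
                                    "unimolecular_hairpin"),
               "concentration-independent")
  expect_error(tm_concentration_fit(c(330, 331), c(1e-6, 1e-5), "nonself"),
               "at least 3")
  expect_error(tm_concentration_fit(c(330, 331, 332), rep(1e-5, 3),
                                    "nonself"), "rank-deficient")
  # Tm falling with concentration implies dH > 0: flagged non-two-state
  expect_warning(tm_concentration_fit(c(332, 331, 330),
                                      c(1e-6, 1e-5, 1e-4), "nonself"),
                 "non-two-state")
})

test_that("delta_g reproduces measured duplex and hairpin free energies", {
  # printed dH/dS pairs for representative strands; dG at 298.15 K, 3 s.f.
  expect_equal(signif(delta_g(-79.7, -212), 3), -16.5)
  expect_equal(signif(delta_g(-51.5, -151), 3), -6.48)
  expect_equal(round(delta_g(-51.5, -151), 1), -6.5)
  expect_identical(delta_g(-50, 0), -50)          # dS = 0: dG = dH
  p <- van_t_hoff_fit(gen_melting_curve(-52.8, -153, "hairpin",
                                        c_T = NA_real_)[[1]])
  expect_equal(delta_g(p), p$dG298)
})

test_that("comparison to reference gives dTm and ddG", {
  mk <- function(dH, dS, mol = "hairpin")
    van_t_hoff_fit(gen_melting_curve(dH, dS, mol, c_T = NA_real_)[[1]])
  a <- mk(-53.5, -159); b <- mk(-52.8, -153)
  d <- compare_to_reference(a, b)
  expect_equal(unname(d["dTm_C"]), a$Tm_C - b$Tm_C)
  expect_equal(unname(d["ddG298"]), a$dG298 - b$dG298)
  expect_equal(unname(compare_to_reference(b, b)), c(0, 0))
})

test_that("replicate aggregation computes t-based 95% intervals", {
  mk <- function(dH, dS)
    van_t_hoff_fit(gen_melting_curve(dH, dS, "hairpin", c_T = NA_real_)[[1]])
  # dS chosen to keep each Tm near 345 K, inside the default grid
  fits <- list(mk(-79, -229), mk(-80, -231.9), mk(-81, -234.8))
  agg <- aggregate_replicates(fits)
  expect_equal(agg$mean$dH, -80, tolerance = 1e-6)
  # closed-form t interval on the replicate sd
  dHs <- vapply(fits, function(f) f$dH, numeric(1))
  expect_equal(unname(agg$half_width["dH"]),
               qt(0.975, df = 2) * sd(dHs) / sqrt(3), tolerance = 1e-6)
  # identical fits give a zero-width interval
  agg0 <- aggregate_replicates(list(mk(-80, -231.9), mk(-80, -231.9),
                                    mk(-80, -231.9)))
  expect_equal(unname(agg0$half_width["dH"]), 0, tolerance = 1e-8)
  expect_warning(aggregate_replicates(fits[1]), "single replicate")
  # plain sd option
  aggs <- aggregate_replicates(fits, interval = "sd")
  expect_equal(unname(aggs$half_width["dH"]), sd(dHs), tolerance = 1e-6)
})

test_that("hairpin Tm is concentration-invariant; sharper transitions need larger |dH|", {
  truth <- melt_truth$hairpin
  tms <- vapply(c(1, 10, 100) * 1e-6, function(cc) {
    cv <- gen_melting_curve(truth$dH, truth$dS, truth$mol, c_T = cc)[[1]]
    as.numeric(tm_first_derivative(cv))
  }, numeric(1))
  expect_lt(diff(range(tms)), 0.05)

  # monotonicity of cooperativity on the forward model at fixed Tm
  tm_K <- 1000 * truth$dH / truth$dS
  T_K <- seq(tm_K - 15, tm_K + 15, by = 0.1)
  slopes <- vapply(c(-40, -55, -70, -85), function(dH) {
    dS <- 1000 * dH / tm_K  # keep Tm fixed
    max(abs(diff(two_state_theta(T_K, dH, dS, truth$mol)) / 0.1))
  }, numeric(1))
  expect_true(all(diff(slopes) > 0))
})

test_that("melting_curve validates its input", {
  expect_error(melting_curve(1:30, 1:29), "equal length")
  expect_error(melting_curve(1:10, 1:10), "at least 20")
  expect_error(melting_curve(c(1:25, 25), rep(1, 26)), "increasing")
  expect_error(melting_curve(1:30, rep(1, 30), molecularity = "self"),
               "c_T > 0")
})
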