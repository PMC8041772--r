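test_that("competent fraction follows the independent two-site closed form", {
  expect_equal(competentFraction(0, 7), 0)
  expect_equal(competentFraction(5, 5), 0.25)
  expect_equal(competentFraction(50, 5), (10 / 11)^2, tolerance = 1e-12)
  # monotone increasing in S
  s <- seq(0, 100, 1)
  expect_true(all(diff(competentFraction(s, 12)) > 0))
  expect_error(competentFraction(-1, 5), "non-negative")
  expect_error(competentFraction(5, 0), "positive")
})

test_that("inhibition constant is koff/kon and undefined at kon = 0", {
  p <- KineticParameters(0.33, 10, 6.667e-3, 1e-3)
  expect_equal(inhibitionConstant(p), 1e-3 / 6.667e-3)
  expect_equal(inhibitionConstant(KineticParameters(1, 1, 0.2, 0.2 * 0.03)),
               0.03, tolerance = 1e-12)
  expect_error(inhibitionConstant(KineticParameters(1, 1, 0, 1e-3)),
               "undefined")
})

activated_params <- KineticParameters(kcat = 0.33, Kd = 10,
                                      kon = 1e-3 / 0.15, koff = 1e-3)
burst_cond <- ReactionConditions(5, 500, c(seq(0, 120, 2), seq(125, 1800, 25)))

test_that("simulation conserves mass and enzyme and is monotone", {
  crv <- simulateProgress(activated_params, burst_cond)
  p <- productSeries(crv); s <- substrateSeries(crv)
  expect_true(all(abs(s + 2 * p - 500) < 1e-6 * 500))
  expect_true(all(diff(p) >= -1e-10))
  expect_true(all(p <= 250 + 1e-9))
  expect_true(all(crv@bound >= 0 & crv@bound <= 5 + 1e-9))
})

test_that("trivial limits: no catalysis, and the uninhibited saturated slope", {
  flat <- simulateProgress(KineticParameters(0, 10, 1e-3, 1e-3),
                           ReactionConditions(5, 500, seq(0, 100, 10)))
  expect_equal(productSeries(flat), rep(0, 11), tolerance = 1e-12)
  expect_equal(substrateSeries(flat), rep(500, 11), tolerance = 1e-12)

  lin <- simulateProgress(KineticParameters(0.1, 0.001, 0, 0),
                          ReactionConditions(5, 500, seq(0, 400, 5)))
  t <- timeGrid(lin)[-1]
  expect_lt(max(abs(productSeries(lin)[-1] - 0.5 * t) / (0.5 * t)), 0.01)
})

test_that("adaptive integration matches a 10x-finer fixed-step RK4 oracle", {
  crv <- simulateProgress(activated_params, burst_cond)
  ref <- ref_rk4_progress(activated_params, 5, 500, timeGrid(crv), nsub = 10)
  rel <- abs(productSeries(crv)[-1] - ref$psyn[-1]) / pmax(ref$psyn[-1], 1e-6)
  expect_lt(max(rel), 1e-3)
})

test_that("initial rate equals the closed form and the simulated t->0 slope", {
  expect_equal(initialRate(activated_params,
                           ReactionConditions(5, 0, c(0, 1))), 0)
  expect_equal(initialRate(KineticParameters(0.2, 0.001, 0, 0),
                           ReactionConditions(5, 5000, c(0, 1))),
               1.0, tolerance = 1e-5)
  cond <- ReactionConditions(5, 500, seq(0, 1, 0.01))
  crv <- simulateProgress(activated_params, cond)
  fd <- (productSeries(crv)[2] - productSeries(crv)[1]) / 0.01
  expect_equal(initialRate(activated_params, cond), fd, tolerance = 0.01)
})

test_that("fast product-binding limit approaches the classical non-competitive rate", {
  # scale kon/koff up 1000-fold at fixed Ki: binding equilibrates, and the
  # late-time velocity must approach kcat*E0*f(S)*Ki/(Ki+P)
  fast <- KineticParameters(0.33, 10, 1000 * activated_params@kon,
                            1000 * activated_params@koff)
  cond <- ReactionConditions(5, 500, seq(0, 2000, 5))
  crv <- simulateProgress(fast, cond)
  i <- length(timeGrid(crv)) - c(10, 0)
  v_sim <- diff(productSeries(crv)[i]) / diff(timeGrid(crv)[i])
  P <- productSeries(crv)[i[2]] - crv@bound[i[2]]
  S <- substrateSeries(crv)[i[2]]
  Ki <- inhibitionConstant(fast)
  v_ss <- 0.33 * 5 * competentFraction(S, 10) * Ki / (Ki + P)
  expect_equal(v_sim, v_ss, tolerance = 0.02)
})

test_that("noiseless fits recover the generating parameters", {
  cond <- ReactionConditions(5, 500, c(seq(0, 120, 3), seq(126, 1200, 30)))
  crv <- simulateProgress(activated_params, cond)
  fit <- fitProgress(crv, KineticParameters(0.66, 20, 2 * 1e-3 / 0.15, 2e-3))
  p <- fittedParameters(fit)[[1]]
  expect_true(fit@converged)
  expect_lt(abs(kcat(p) - 0.33) / 0.33, 0.01)
  expect_lt(abs(Kd(p) - 10) / 10, 0.01)
  expect_lt(abs(inhibitionConstant(p) - 0.15) / 0.15, 0.01)
  # refitting from the optimum is a fixed point
  refit <- fitProgress(crv, p)
  expect_lt(abs(kcat(fittedParameters(refit)[[1]]) - kcat(p)) / kcat(p), 1e-4)
})

test_that("reduced-model fit with kon pinned to zero recovers kcat and Kd", {
  truth <- KineticParameters(0.2, 15, 0, 0)
  cond <- ReactionConditions(5, 500, seq(0, 900, 15))
  crv <- simulateProgress(truth, cond)
  fit <- fitProgress(crv, KineticParameters(0.4, 30, 0, 0),
                     bounds = list(kon = c(0, 0), koff = c(0, 0)))
  p <- fittedParameters(fit)[[1]]
  expect_lt(abs(kcat(p) - 0.2) / 0.2, 0.01)
  expect_lt(abs(Kd(p) - 15) / 15, 0.01)
  expect_identical(kon(p), 0)
})

test_that("global fit with shared kcat ties the estimate across curves", {
  pa <- activated_params
  pb <- KineticParameters(0.33, 10, 2e-3 / 7, 2e-3)   # Ki = 7 uM
  cond <- ReactionConditions(5, 500, c(seq(0, 120, 4), seq(128, 1200, 40)))
  ca <- simulateProgress(pa, cond); cb <- simulateProgress(pb, cond)
  fit <- fitProgress(list(ca, cb), KineticParameters(0.5, 15, 5e-3, 1.5e-3),
                     shared = c("kcat", "Kd"))
  f <- fittedParameters(fit)
  expect_identical(kcat(f[[1]]), kcat(f[[2]]))
  expect_lt(abs(kcat(f[[1]]) - 0.33) / 0.33, 0.02)
  expect_lt(abs(inhibitionConstant(f[[1]]) - 0.15) / 0.15, 0.05)
  expect_lt(abs(inhibitionConstant(f[[2]]) - 7) / 7, 0.05)
})

test_that("pooled fit of noisy replicates recovers parameters within 10%", {
  cond <- ReactionConditions(5, 500, c(seq(0, 120, 4), seq(128, 1200, 40)))
  clean_max <- max(productSeries(simulateProgress(activated_params, cond)))
  gen <- genProgressCurves(activated_params, cond,
                           noise_sd = 0.02 * clean_max, n_replicates = 20,
                           seed = 11)
  fit <- fitProgress(gen$curves, KineticParameters(0.5, 15, 4e-3, 1.5e-3),
                     shared = c("kcat", "Kd", "kon", "koff"))
  p <- fittedParameters(fit)[[1]]
  expect_lt(abs(kcat(p) - 0.33) / 0.33, 0.10)
  expect_lt(abs(inhibitionConstant(p) - 0.15) / 0.15, 0.10)
})

test_that("progress-curve CSV round-trips", {
  crv <- simulateProgress(activated_params,
                          ReactionConditions(5, 500, seq(0, 100, 10)),
                          label = "wt")
  path <- withr::local_tempfile(fileext = ".csv")
  writeProgressCurve(crv, path)
  back <- readProgressCurve(path, e0 = 5, label = "wt")
  expect_equal(productSeries(back), productSeries(crv), tolerance = 1e-6)
  expect_equal(substrateSeries(back), substrateSeries(crv), tolerance = 1e-6)
  expect_equal(timeGrid(back), timeGrid(crv))
})

test_that("invalid kinetic inputs are rejected", {
  expect_error(KineticParameters(0.3, 0, 1e-3, 1e-3), "Kd")
  expect_error(ReactionConditions(0, 500, c(0, 1)), "e0")
  expect_error(ReactionConditions(5, 500, c(1, 2)), "start at 0")
  expect_error(ReactionConditions(5, 500, c(0, 2, 2)), "increasing")
  expect_error(ProgressCurve(ReactionConditions(5, 500, c(0, 1)),
                             product = c(0, 1, 2)), "length")
})
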