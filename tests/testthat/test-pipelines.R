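test_that("kinetics pipeline writes a consistent fit report", {
  p <- KineticParameters(0.33, 10, 6.667e-3, 1e-3)
  cc <- ReactionConditions(5, 500, c(seq(0, 120, 4), seq(128, 900, 40)))
  crv <- simulateProgress(p, cc, label = "activated")
  out <- withr::local_tempdir()
  fit <- runKineticsAnalysis(crv, KineticParameters(0.5, 15, 4e-3, 1.5e-3),
                             out_dir = out)
  expect_true(file.exists(file.path(out, "fit_report.json")))
  expect_true(file.exists(file.path(out, "residuals.csv")))
  expect_true(file.exists(file.path(out, "overlay.png")))
  expect_true(file.exists(file.path(out, "config.json")))

  rep <- jsonlite::read_json(file.path(out, "fit_report.json"),
                             simplifyVector = TRUE)
  pars <- rep$curves
  expect_equal(rep$n_curves, 1)
  # the reported Ki equals koff/kon of the same report
  expect_equal(pars$Ki_uM, pars$koff_per_s / pars$kon_per_uM_s,
               tolerance = 1e-9)
  expect_true(all(c("kcat_per_s", "Kd_uM", "kon_per_uM_s",
                    "koff_per_s") %in% names(pars)))
  # rerun is deterministic
  out2 <- withr::local_tempdir()
  runKineticsAnalysis(crv, KineticParameters(0.5, 15, 4e-3, 1.5e-3),
                      out_dir = out2)
  expect_identical(readLines(file.path(out, "fit_report.json")),
                   readLines(file.path(out2, "fit_report.json")))
})

test_that("activation-geometry pipeline reports planted truths and zero self-differences", {
  gh <- genHingedConformers(n_res = 80, hinge_residue = 40, delta_psi = 169,
                            seed = 3)
  out <- withr::local_tempdir()
  rep <- runActivationGeometry(
    native = list(gh$confA, gh$confB),
    activated = list(gh$confA, gh$confB),
    rigid = list(fixed = 5:38, moving = 45:78),
    out_dir = out)
  expect_true(file.exists(file.path(out, "geometry_report.json")))
  expect_equal(rep$hinge$hinges$resno, 40)
  expect_equal(rep$hinge$hinges$delta, 169, tolerance = 1e-6)
  # native and "activated" are the same models: zero rotation
  expect_lt(rep$rigid_body$angle_deg, 1e-6)

  # synthetic register pair through the same entry point
  gcc <- genCoiledCoil(axial_offset = 9)
  rep2 <- runActivationGeometry(
    native = list(gcc$state1$helix1, gcc$state1$helix2),
    activated = list(gcc$state2$helix1, gcc$state2$helix2),
    helix = list(range = 1:21, cutoff = 4.5))
  expect_equal(rep2$register$lateral_shift_A, 9, tolerance = 0.2)
  expect_lt(rep2$register$azimuth_change_deg, 5)
})

test_that("census pipeline reports stage counts matching the generator truth", {
  gl <- genLinkerDataset(n_per_group = 25, n_groups = 3, base_length = 16,
                         mutation_rate = 0.1, seed = 5)
  out <- withr::local_tempdir()
  res <- suppressMessages(
    runCensus(gl$sequences, out, identity = NULL, peak_min_count = 5))
  expect_equal(res$counts$input, 75)
  expect_equal(res$counts$after_size_filter, 75)
  expect_equal(res$counts$accepted, 75)
  expect_equal(res$counts$rejected, 0)
  expect_equal(length(lengthPeaks(res$groups)), 3)
  expect_equal(modalSpacing(res$groups), 7L)
  for (f in c("records.tsv", "groups.tsv", "summary.json", "config.json"))
    expect_true(file.exists(file.path(out, f)))
  # every produced logo has columns summing to 1
  for (g in names(res$logos))
    expect_true(all(abs(colSums(res$logos[[g]]) - 1) < 1e-9))

  # single valid sequence: census of one
  out2 <- withr::local_tempdir()
  one <- suppressMessages(
    runCensus(c(s = "AAKPAAALAAADALTGG"), out2, identity = NULL,
              peak_min_count = 1))
  expect_equal(one$counts$accepted, 1)
  expect_error(suppressMessages(runCensus(character(0), out2)), "empty")

  # rejected sequences carry reason codes
  out3 <- withr::local_tempdir()
  mix <- suppressMessages(
    runCensus(c(ok = "AAKPAAALAAADALTGG", bad = "AAAADALTGG"), out3,
              identity = NULL, peak_min_count = 1))
  rej <- read.delim(file.path(out3, "rejections.tsv"))
  expect_equal(rej$id, "bad")
  expect_equal(rej$reason, "no_anchor_pair")
})
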