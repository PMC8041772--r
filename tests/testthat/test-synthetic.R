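test_that("generators are byte-deterministic for a fixed seed", {
  p <- KineticParameters(0.33, 10, 6.667e-3, 1e-3)
  cc <- ReactionConditions(5, 500, seq(0, 200, 10))
  g1 <- genProgressCurves(p, cc, noise_sd = 1, n_replicates = 3, seed = 7)
  g2 <- genProgressCurves(p, cc, noise_sd = 1, n_replicates = 3, seed = 7)
  expect_identical(serialize(g1, NULL), serialize(g2, NULL))

  h1 <- genHingedConformers(40, 20, 100, seed = 5)
  h2 <- genHingedConformers(40, 20, 100, seed = 5)
  expect_identical(serialize(h1, NULL), serialize(h2, NULL))

  l1 <- genLinkerDataset(n_per_group = 5, n_groups = 2, seed = 3)
  l2 <- genLinkerDataset(n_per_group = 5, n_groups = 2, seed = 3)
  expect_identical(l1$sequences, l2$sequences)
})

test_that("extending the replicate or group count preserves earlier draws", {
  p <- KineticParameters(0.33, 10, 6.667e-3, 1e-3)
  cc <- ReactionConditions(5, 500, seq(0, 200, 10))
  small <- genProgressCurves(p, cc, noise_sd = 1, n_replicates = 2, seed = 7)
  big <- genProgressCurves(p, cc, noise_sd = 1, n_replicates = 5, seed = 7)
  expect_identical(productSeries(big$curves[[2]]),
                   productSeries(small$curves[[2]]))

  lil <- genLinkerDataset(n_per_group = 4, n_groups = 2, seed = 3)
  grande <- genLinkerDataset(n_per_group = 9, n_groups = 2, seed = 3)
  expect_identical(grande$sequences[names(lil$sequences)], lil$sequences)
})

test_that("zero noise reproduces the simulator output exactly", {
  p <- KineticParameters(0.33, 10, 6.667e-3, 1e-3)
  cc <- ReactionConditions(5, 500, seq(0, 300, 10))
  g <- genProgressCurves(p, cc, noise_sd = 0, n_replicates = 1, seed = 1)
  clean <- simulateProgress(p, cc)
  expect_equal(productSeries(g$curves[[1]]), productSeries(clean))
  expect_equal(substrateSeries(g$curves[[1]]), substrateSeries(clean))
})

test_that("replicate noise is unbiased: the mean tracks the noiseless curve", {
  p <- KineticParameters(0.33, 10, 6.667e-3, 1e-3)
  cc <- ReactionConditions(5, 500, seq(10, 210, 20) - 10)
  sd_noise <- 2
  g <- genProgressCurves(p, cc, noise_sd = sd_noise, n_replicates = 200,
                         seed = 23)
  clean <- productSeries(simulateProgress(p, cc))
  mat <- do.call(rbind, lapply(g$curves, productSeries))
  se <- sd_noise / sqrt(200)
  # skip t = 0 where clipping at zero biases the mean upward
  dev <- abs(colMeans(mat)[-1] - clean[-1])
  expect_true(all(dev < 3 * se + 0.02))
})

test_that("hinged conformer pairs close the loop with hinge detection", {
  gh <- genHingedConformers(n_res = 50, hinge_residue = 25, delta_psi = -140,
                            seed = 13)
  d <- torsionDifference(backboneTorsions(gh$confA),
                         backboneTorsions(gh$confB))
  hr <- hinges(detectHinges(d))
  expect_equal(nrow(hr), 1)
  expect_equal(hr$resno, gh$truth$hinge_residue)
  expect_equal(hr$delta, gh$truth$delta_psi, tolerance = 1e-8)

  same <- genHingedConformers(n_res = 50, hinge_residue = 25, delta_psi = 0,
                              seed = 13)
  expect_identical(atoms(same$confA), atoms(same$confB))
  expect_error(genHingedConformers(10, 10, 90), "hinge")
})

test_that("coiled-coil generator plants recoverable offsets and knobs", {
  gcc <- genCoiledCoil(axial_offset = 0)
  expect_lt(lateralShift(gcc$state1, gcc$state2)$shift, 1e-8)
  gcc9 <- genCoiledCoil(axial_offset = 9)
  expect_equal(lateralShift(gcc9$state1, gcc9$state2)$shift, 9,
               tolerance = 0.2)
  ct <- symmetricPairContacts(gcc9$state1$helix1, gcc9$state1$helix2, 4.5)
  expect_identical(ct, as.integer(gcc9$truth$knob_positions))
  expect_error(genCoiledCoil(n_res = 10), "14")
})

test_that("linker dataset honours planted lengths, anchors and leucine phase", {
  gl <- genLinkerDataset(n_per_group = 12, n_groups = 3, base_length = 16,
                         mutation_rate = 0, seed = 2, length_jitter = FALSE)
  recs <- extractLinkers(gl$sequences)
  expect_true(all(is.na(recs$reason)))
  expect_equal(sort(unique(recs$length)), c(16L, 23L, 30L))
  expect_identical(recs$length, gl$truth$length)
  # leucines every 7th position counted from the DxLT anchor
  for (i in seq_len(nrow(recs))) {
    lk <- strsplit(recs$linker[i], "")[[1]]
    L <- length(lk)
    a_pos <- (L + 1) - 7 * seq_len(L %/% 7)
    a_pos <- a_pos[a_pos >= 3]
    expect_true(all(lk[a_pos] == "L"))
  }
  # full pipeline recovers the planted grouping from the generator truth
  cl <- clusterLengths(recs)
  expect_equal(length(lengthPeaks(cl)), 3)
  expect_equal(modalSpacing(cl), 7L)
})
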