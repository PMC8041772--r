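ideal_helix_ca <- function(n = 18, rise = 1.5, rpt = 3.6, r = 2.3) {
  th <- 2 * pi * (seq_len(n) - 1) / rpt
  cbind(r * cos(th), r * sin(th), rise * (seq_len(n) - 1))
}

test_that("helix axis fitting recovers planted directions", {
  ca <- ideal_helix_ca()
  ax <- fitHelixAxis(ca)
  expect_equal(abs(sum(ax@direction * c(0, 0, 1))), 1, tolerance = 1e-3)
  # direction points N -> C
  expect_gt(sum(ax@direction * c(0, 0, 1)), 0)

  R <- dgcswitch:::.rotationMatrix(c(1, 1, 0) / sqrt(2), 65)
  ax2 <- fitHelixAxis(ca %*% t(R))
  expect_equal(abs(sum(ax2@direction * as.numeric(R %*% c(0, 0, 1)))), 1,
               tolerance = 1e-3)

  set.seed(44)
  noisy <- ca + matrix(rnorm(length(ca), 0, 0.3), ncol = 3)
  axn <- fitHelixAxis(noisy)
  ang <- acos(abs(sum(axn@direction * c(0, 0, 1)))) * 180 / pi
  expect_lt(ang, 3)
  expect_error(fitHelixAxis(ca[1:6, ]), "at least 7")
})

test_that("symmetric pair contacts find exactly the planted knobs", {
  gcc <- genCoiledCoil(n_res = 21, axis_separation = 10,
                       knob_positions = c(4, 11, 18))
  ct <- symmetricPairContacts(gcc$state1$helix1, gcc$state1$helix2,
                              cutoff = 4.5)
  expect_identical(ct, c(4L, 11L, 18L))
  # helices far apart: no contacts at all
  far <- genCoiledCoil(n_res = 21, axis_separation = 40)
  expect_length(symmetricPairContacts(far$state1$helix1, far$state1$helix2,
                                      cutoff = 4.5), 0)
})

test_that("heptad assignment resolves the two registers and stays cyclic", {
  ad <- assignHeptad(c(0, 3, 7, 10))
  expect_equal(ad@pattern, "a-d-a-d")
  ae <- assignHeptad(c(0, 4, 7, 11))
  expect_equal(ae@pattern, "a-e-a-e")

  native <- assignHeptad(c(125, 128, 132, 135), segment_range = 121:136)
  expect_equal(native@pattern, "a-d-a-d")
  expect_equal(native@resno[native@letter == "a"], c(125L, 132L))
  expect_equal(native@resno[native@letter == "d"], c(121L, 128L, 135L))

  activated <- assignHeptad(c(125, 129, 132, 136), segment_range = 121:136)
  expect_equal(activated@pattern, "a-e-a-e")
  expect_equal(activated@resno[activated@letter == "a"], c(125L, 132L))
  expect_equal(activated@resno[activated@letter == "e"],
               c(122L, 129L, 136L))

  # cyclic advance: letter(i+7) == letter(i)
  l <- activated@letter
  r <- activated@resno
  for (i in seq_along(r)) {
    j <- which(r == r[i] + 7)
    if (length(j)) expect_identical(l[j], l[i])
  }
  # inconsistent contacts flagged, not raised
  odd <- assignHeptad(c(0, 1, 2, 3, 4, 5))
  expect_equal(odd@pattern, "non-canonical")
  expect_gt(odd@violations, 0)
  expect_error(assignHeptad(5), "at least 2")
})

test_that("register comparison classifies persistent and conditional contacts", {
  a <- assignHeptad(c(125, 128, 132, 135), 121:136)
  b <- assignHeptad(c(125, 129, 132, 136), 121:136)
  rc <- compareRegisters(a, b)
  expect_equal(rc@persistent, c(125L, 132L))
  expect_equal(rc@conditionalA, c(128L, 135L))
  expect_equal(rc@conditionalB, c(129L, 136L))

  same <- compareRegisters(a, a)
  expect_equal(same@persistent, a@contacts)
  expect_length(same@conditionalA, 0)

  disjoint <- compareRegisters(assignHeptad(c(0, 3)), assignHeptad(c(1, 4)))
  expect_length(disjoint@persistent, 0)
})

test_that("lateral shift recovers planted axial offsets without rolling", {
  for (off in c(0, 1.5, 4.5, 9.0)) {
    gcc <- genCoiledCoil(axial_offset = off)
    res <- lateralShift(gcc$state1, gcc$state2)
    expect_equal(res$shift, off, tolerance = 0.2)
    expect_equal(res$axial, off, tolerance = 0.2)
    if (off > 0) expect_lt(res$azimuth_change, 5)
  }
})

test_that("lateral shift is symmetric under swapping the superposed helix", {
  gcc <- genCoiledCoil(axial_offset = 6)
  a <- lateralShift(gcc$state1, gcc$state2)
  swapped1 <- list(helix1 = gcc$state1$helix2, helix2 = gcc$state1$helix1)
  swapped2 <- list(helix1 = gcc$state2$helix2, helix2 = gcc$state2$helix1)
  b <- lateralShift(swapped1, swapped2)
  expect_equal(a$shift, b$shift, tolerance = 0.5)
})

test_that("helical net is an exact heptad lattice", {
  ha <- assignHeptad(c(4, 11, 18), segment_range = 1:21)
  net <- helicalNet(ha)
  i7 <- match(ha@resno + 7, net$resno)
  ok <- !is.na(i7)
  expect_equal(net$y[i7[ok]] - net$y[ok], rep(7 * 1.5, sum(ok)))
  expect_equal(net$x[i7[ok]], net$x[ok], tolerance = 1e-10)
  expect_true(all(net$contact[net$resno %in% c(4, 11, 18)]))
  # closed-form lattice of the ideal coiled-coil helix
  i <- net$resno - net$resno[1]
  expect_equal(net$x, ((i * 2 / 7) %% 1) * 2 * pi * 2.3, tolerance = 1e-12)
  expect_equal(net$y, i * 1.5)
  # deterministic regression: identical input gives identical table
  expect_identical(net, helicalNet(ha))
})
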