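test_that("anchor location follows the KP..DxLT convention", {
  r <- locateAnchors("AAKPAAAAAAADALTGG")
  expect_equal(r$kp, 3); expect_equal(r$dxlt, 12)
  expect_equal(r$length, 9); expect_false(r$group0)
  expect_equal(r$linker, "KPAAAAAAA")

  g0 <- locateAnchors("AAKPAAAAAAASPLTGG")
  expect_true(g0$group0)
  expect_equal(g0$length, 9)
  g0n <- locateAnchors("AAKPAAAAAAANPLTGG")
  expect_true(g0n$group0)

  rej <- locateAnchors("AAAADALTGG")
  expect_equal(rej$reason, "no_anchor_pair")
  # last KP before the first DxLT that follows a KP
  multi <- locateAnchors("KPAAKPAAAAADALTAAADSLT")
  expect_equal(multi$kp, 5)
  expect_equal(multi$dxlt, 12)
})

test_that("anchor positions are stable under prepending residues", {
  s <- "AAKPAAAAAAADALTGG"
  base <- locateAnchors(s)
  for (npre in c(1, 5, 12)) {
    shifted <- locateAnchors(paste0(strrep("G", npre), s))
    expect_equal(shifted$kp, base$kp + npre)
    expect_equal(shifted$dxlt, base$dxlt + npre)
    expect_equal(shifted$length, base$length)
  }
})

test_that("size filter uses a strict < cutoff", {
  seqs <- c(keep = strrep("A", 359), drop = strrep("A", 360),
            keep2 = strrep("A", 10))
  expect_message(out <- sizeFilter(seqs, 360), "removed 1")
  expect_setequal(names(out), c("keep", "keep2"))
})

test_that("redundancy filter is greedy, order-deterministic and idempotent", {
  set.seed(51)
  a <- paste(sample(c("A", "D", "E", "F", "G"), 100, TRUE), collapse = "")
  # b: a with 15% substitutions -> identity 0.85, removed at 0.80
  bv <- strsplit(a, "")[[1]]
  idx <- sample(100, 15)
  bv[idx] <- ifelse(bv[idx] == "W", "Y", "W")
  b <- paste(bv, collapse = "")
  expect_equal(ref_hamming_identity(a, b), 0.85)
  unrelated <- strrep("KHKHMRMR", 12)

  suppressMessages({
    out <- redundancyFilter(c(s1 = a, s2 = b, s3 = unrelated, s4 = a), 0.80)
  })
  expect_setequal(names(out), c("s1", "s3"))
  # idempotent
  expect_identical(suppressMessages(redundancyFilter(out, 0.80)), out)
  # at a high threshold the 85%-identical pair survives
  out2 <- suppressMessages(redundancyFilter(c(s1 = a, s2 = b), 0.90))
  expect_length(out2, 2)
})

test_that("length clustering recovers planted heptad groups", {
  L <- 20
  lengths <- rep(c(L, L + 7, L + 14), each = 12)
  rec <- data.frame(id = paste0("s", seq_along(lengths)), length = lengths)
  cl <- clusterLengths(rec)
  expect_equal(lengthPeaks(cl), c(L, L + 7, L + 14))
  expect_equal(modalSpacing(cl), 7L)
  expect_equal(lengths(cl@groups), c(12L, 12L, 12L),
               ignore_attr = TRUE)

  single <- clusterLengths(data.frame(id = paste0("s", 1:10), length = 25))
  expect_equal(lengthPeaks(single), 25L)
  expect_true(is.na(modalSpacing(single)))

  expect_message(
    empty <- clusterLengths(data.frame(id = "x", length = 9),
                            peak_min_count = 5), "no peak")
  expect_length(lengthPeaks(empty), 0)
})

test_that("aligned logos anchor all groups at the DxLT end", {
  # the 17-residue group is the 10-residue group with one extra heptad
  # inserted after KP; the C-terminal 8 residues are identical
  recs <- data.frame(
    id = c("a1", "a2", "b1", "b2"),
    length = c(10, 10, 17, 17),
    linker = c("KPWWLAAAGL", "KPWWLAAAGL",
               "KPYYYYYYYWWLAAAGL", "KPYYYYYYYWWLAAAGL"))
  gr <- new("LengthGroups",
            histogram = data.frame(length = integer(0), count = integer(0)),
            peaks = c(10L, 17L),
            groups = list("10" = c("a1", "a2"), "17" = c("b1", "b2")),
            spacing = 7L, unassigned = character(0))
  logos <- alignedGroupLogos(recs, gr)
  # one group of identical sequences: all frequencies are 0/1
  expect_true(all(logos[["10"]] %in% c(0, 1)))
  expect_true(all(abs(colSums(logos[["10"]]) - 1) < 1e-12))
  expect_true(all(abs(colSums(logos[["17"]]) - 1) < 1e-12))
  # conserved C-terminal columns align exactly between the groups
  shared_cols <- as.character(-(8:1))
  expect_equal(logos[["10"]][, shared_cols], logos[["17"]][, shared_cols])
})

test_that("slippery scoring flags windows viable in both registers", {
  poly_g <- strrep("G", 14)
  sc <- slipperyScore(poly_g)
  expect_equal(sc$score_ad, 0)
  expect_equal(sc$score_ae, 0)
  expect_false(sc$ambiguous)

  # ideal axxdexx repeat: L at a, A at d, S at e
  ideal <- strrep("LAAASAA", 2)
  sc2 <- slipperyScore(ideal)
  expect_gt(sc2$score_ad, 3); expect_gt(sc2$score_ae, 3)
  expect_true(sc2$ambiguous)

  # proline at the conditional positions kills one register only
  native_only <- paste0("LAAAPAA", "LAAAPAA")  # P at e offsets -10/-3
  sc3 <- slipperyScore(native_only)
  expect_gt(sc3$score_ad, 3)
  expect_lt(sc3$score_ae, 0)
  expect_false(sc3$ambiguous)
  expect_error(slipperyScore("LAAASAA"), "14")
})

test_that("FASTA round-trips through the census readers", {
  seqs <- c(one = "AAKPAAAAAAADALTGG", two = "MKLVWWEE")
  path <- withr::local_tempfile(fileext = ".fasta")
  writeFastaSequences(seqs, path)
  back <- readFastaSequences(path)
  expect_identical(back, seqs)
})
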