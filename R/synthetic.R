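# run expr with a fixed RNG state, restoring the caller's stream afterwards
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate noisy replicate progress curves with known truth
#'
#' Simulates the kinetic model and adds additive Gaussian noise (clipped at
#' zero) to the product and substrate series. Each replicate uses its own
#' deterministic sub-stream (\code{seed + replicate}), so extending
#' \code{n_replicates} leaves earlier replicates unchanged.
#'
#' @param params a \linkS4class{KineticParameters} (the planted truth).
#' @param cond a \linkS4class{ReactionConditions}.
#' @param noise_sd additive Gaussian noise standard deviation, uM (>= 0).
#' @param n_replicates number of replicate curves.
#' @param seed integer seed fixing all outputs.
#' @return list with \code{curves} (list of \linkS4class{ProgressCurve}) and
#'   \code{truth} (params, conditions, noise_sd, seed).
#' @export
genProgressCurves <- function(params, cond, noise_sd = 0, n_replicates = 1,
                              seed = 1) {
  .assertScalarNonNegative(noise_sd, "noise_sd")
  clean <- simulateProgress(params, cond)
  curves <- lapply(seq_len(n_replicates), function(r) {
    .withSeed(seed + r, {
      n <- length(timeGrid(cond))
      p <- pmax(clean@product + stats::rnorm(n, 0, noise_sd), 0)
      s <- pmax(clean@substrate + stats::rnorm(n, 0, noise_sd), 0)
      ProgressCurve(cond, product = p, substrate = s,
                    label = sprintf("replicate_%d", r))
    })
  })
  list(curves = curves,
       truth = list(params = params, conditions = cond,
                    noise_sd = noise_sd, seed = seed))
}

#' Generate a hinged backbone conformer pair with a planted psi rotation
#'
#' Builds an ideal-geometry helical backbone (with a small seeded torsion
#' wobble for realism) and derives conformer B from conformer A by rotating
#' psi of the hinge residue by \code{delta_psi} via forward kinematics. All
#' other torsions are bitwise identical between the conformers, so the
#' planted hinge is the only torsion difference.
#'
#' @param n_res number of residues.
#' @param hinge_residue hinge position (1 < hinge < n_res).
#' @param delta_psi planted psi change, degrees.
#' @param seed integer seed for the torsion wobble.
#' @param wobble_sd standard deviation of the per-residue torsion wobble,
#'   degrees.
#' @return list with \code{confA}, \code{confB}
#'   (\linkS4class{BackboneModel}) and \code{truth} (hinge residue, torsion
#'   name, delta).
#' @export
genHingedConformers <- function(n_res = 150, hinge_residue = 136,
                                delta_psi = 169, seed = 1, wobble_sd = 3) {
  if (hinge_residue <= 1 || hinge_residue >= n_res)
    stop("hinge_residue must satisfy 1 < hinge < n_res")
  confA <- .withSeed(seed, {
    buildBackbone(n_res,
                  phi = -57 + stats::rnorm(n_res, 0, wobble_sd),
                  psi = -47 + stats::rnorm(n_res, 0, wobble_sd))
  })
  confB <- if (delta_psi == 0) confA else
    applyTorsionChanges(confA, data.frame(resno = hinge_residue,
                                          dphi = 0, dpsi = delta_psi))
  list(confA = confA, confB = confB,
       truth = list(hinge_residue = hinge_residue, torsion = "psi",
                    delta_psi = wrapAngle(delta_psi)))
}

# one parametric helix: Calpha trace plus pseudo side-chain CB atoms at the
# knob positions, pointing radially outward
.parametricHelix <- function(n_res, phase, rise, res_per_turn, ca_radius,
                             knob_positions, cb_extension, resnames) {
  th <- 2 * pi * (seq_len(n_res) - 1) / res_per_turn + phase
  rows <- list()
  for (i in seq_len(n_res)) {
    ca <- c(ca_radius * cos(th[i]), ca_radius * sin(th[i]), rise * (i - 1))
    rows[[length(rows) + 1]] <- data.frame(
      resno = i, resname = resnames[i], atom = "CA",
      x = ca[1], y = ca[2], z = ca[3])
    if (i %in% knob_positions) {
      cb <- ca + cb_extension * c(cos(th[i]), sin(th[i]), 0)
      rows[[length(rows) + 1]] <- data.frame(
        resno = i, resname = resnames[i], atom = "CB",
        x = cb[1], y = cb[2], z = cb[3])
    }
  }
  do.call(rbind, rows)
}

#' Generate a two-state parallel coiled-coil dimer with a planted axial shift
#'
#' Builds two parallel helices (rise 1.5 A/residue, 3.6 residues/turn,
#' Calpha radius 2.3 A) related by a twofold axis midway between them, with
#' pseudo side-chain atoms placed radially at the knob positions. The phase
#' is chosen so the central knob of each helix faces its partner. State 2
#' equals state 1 with helix 2 translated by \code{axial_offset} along its
#' axis, emulating a register shift by pure translation.
#'
#' @param n_res residues per helix (>= 14).
#' @param axis_separation inter-axis distance, Angstrom.
#' @param axial_offset planted translation of helix 2 in state 2, Angstrom.
#' @param knob_positions residues carrying a pseudo side-chain knob.
#' @param cb_extension radial knob extension beyond the Calpha, Angstrom.
#' @param seed accepted for interface uniformity; the construction is
#'   deterministic.
#' @return list with \code{state1}, \code{state2} (each a list of
#'   \code{helix1}, \code{helix2} \linkS4class{BackboneModel}s) and
#'   \code{truth}.
#' @export
genCoiledCoil <- function(n_res = 21, axis_separation = 10, axial_offset = 9,
                          knob_positions = c(4, 11, 18), cb_extension = 1.5,
                          seed = 1) {
  if (n_res < 14) stop("n_res must be at least 14 (two heptads)")
  rise <- 1.5; rpt <- 3.6; r_ca <- 2.3
  mid <- knob_positions[ceiling(length(knob_positions) / 2)]
  phase <- -2 * pi * (mid - 1) / rpt       # central knob faces +x
  resnames <- rep("ALA", n_res); resnames[knob_positions] <- "LEU"
  a1 <- .parametricHelix(n_res, phase, rise, rpt, r_ca, knob_positions,
                         cb_extension, resnames)
  # helix 2: twofold image about the axis parallel to z through the midpoint
  a2 <- a1
  a2$x <- axis_separation - a1$x
  a2$y <- -a1$y
  h1 <- BackboneModel(a1, chain = "A")
  h2 <- BackboneModel(a2, chain = "B")
  a2s <- a2; a2s$z <- a2$z + axial_offset
  h2s <- BackboneModel(a2s, chain = "B")
  list(state1 = list(helix1 = h1, helix2 = h2),
       state2 = list(helix1 = h1, helix2 = h2s),
       truth = list(axial_offset = axial_offset,
                    knob_positions = knob_positions,
                    axis_separation = axis_separation))
}

# amino-acid alphabet for randomised linker/stub positions: P and T are
# excluded so no spurious KP, D-x-L-T or (S/N)PLT anchor can arise by chance
.SAFE_AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "Q", "R", "S", "V", "W", "Y")

#' Generate a Rec-GGDEF-like sequence set with heptad-quantised linkers
#'
#' Each sequence is a receiver-like stub ending in KP, a linker of length
#' \code{base_length + 7 * (group - 1)} (plus a small seeded length jitter)
#' with leucines planted at the a-phase positions (anchored so the last a
#' sits one heptad before the DxLT motif), a DxLT motif and a GGDEF-like
#' stub. Point mutations hit non-anchor linker positions at
#' \code{mutation_rate}. Randomised positions avoid letters that could form
#' spurious anchors. Per-sequence sub-streams make the output independent of
#' \code{n_per_group} for earlier indices.
#'
#' @param n_per_group sequences per length group.
#' @param n_groups number of length groups (spaced by one heptad).
#' @param base_length linker length of group 1 (K of KP to D of DxLT,
#'   exclusive).
#' @param mutation_rate per-position substitution probability in [0, 1).
#' @param seed integer seed.
#' @param length_jitter logical; add -1/0/+1 length jitter with
#'   probabilities 0.15/0.70/0.15.
#' @param stub_length length of the receiver-like stub before KP.
#' @return list with \code{sequences} (named character vector) and
#'   \code{truth} (data.frame id, group, length).
#' @export
genLinkerDataset <- function(n_per_group = 100, n_groups = 6,
                             base_length = 16, mutation_rate = 0.1,
                             seed = 1, length_jitter = TRUE,
                             stub_length = 30) {
  stopifnot(mutation_rate >= 0, mutation_rate < 1, base_length >= 9)
  seqs <- character(0); truth <- list()
  for (g in seq_len(n_groups)) {
    for (i in seq_len(n_per_group)) {
      rec <- .withSeed(seed + 1009L * g + i, {
        L <- as.integer(base_length) + 7L * (g - 1L) +
          if (length_jitter)
            sample(c(-1L, 0L, 1L), 1, prob = c(0.15, 0.7, 0.15)) else 0L
        linker <- c("K", "P", sample(.SAFE_AA, L - 2, replace = TRUE))
        a_pos <- (L + 1) - 7L * seq_len(ceiling(L / 7))
        a_pos <- a_pos[a_pos >= 3]
        linker[a_pos] <- "L"
        mut <- which(stats::runif(L) < mutation_rate)
        mut <- mut[mut >= 3]
        if (length(mut))
          linker[mut] <- sample(.SAFE_AA, length(mut), replace = TRUE)
        stub <- sample(.SAFE_AA, stub_length, replace = TRUE)
        dxlt <- c("D", sample(.SAFE_AA, 1), "L", "T")
        tail <- sample(.SAFE_AA, 20, replace = TRUE)
        list(seq = paste(c(stub, linker, dxlt, tail), collapse = ""),
             length = L)
      })
      id <- sprintf("g%d_s%03d", g, i)
      seqs[id] <- rec$seq
      truth[[id]] <- data.frame(id = id, group = g, length = rec$length)
    }
  }
  list(sequences = seqs, truth = do.call(rbind, c(truth, make.row.names = FALSE)))
}
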