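#' Subset a backbone model by residue numbers
#'
#' @param model a \linkS4class{BackboneModel}.
#' @param resnos residue numbers to keep.
#' @return a \linkS4class{BackboneModel}.
#' @export
subsetModel <- function(model, resnos) {
  stopifnot(is(model, "BackboneModel"))
  a <- model@atoms[model@atoms$resno %in% resnos, , drop = FALSE]
  if (!nrow(a)) stop("selection resolves to no atoms")
  BackboneModel(a, chain = model@chain)
}

.writeConfig <- function(config, out_dir, name) {
  jsonlite::write_json(config, file.path(out_dir, name), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
}

#' Fit progress curves end-to-end and write a report
#'
#' Reads (or accepts) progress curves, performs the global fit, and writes a
#' JSON fit report (per-curve parameters with the derived inhibitory constant
#' Ki = koff/kon and standard errors), a CSV of residuals, an overlay plot of
#' data and fits, and the resolved configuration. All numeric fields carry
#' units in their names.
#'
#' @param curves list of \linkS4class{ProgressCurve}, or character paths to
#'   CSV/TSV curve files (columns time_s, product_uM, optional
#'   substrate_uM).
#' @param guess starting \linkS4class{KineticParameters}.
#' @param out_dir output directory (created if needed).
#' @param e0 enzyme dimer concentration, uM (needed when reading files).
#' @param shared parameter names shared across curves.
#' @param bounds per-parameter bounds, see \code{\link{fitProgress}}.
#' @param plot write \code{overlay.png}.
#' @return the \linkS4class{KineticFit}, invisibly.
#' @export
runKineticsAnalysis <- function(curves, guess, out_dir, e0 = NULL,
                                shared = character(0), bounds = list(),
                                plot = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(curves)) {
    if (is.null(e0)) stop("e0 is required when curves are given as files")
    curves <- lapply(curves, function(p) readProgressCurve(p, e0 = e0))
  }
  if (is(curves, "ProgressCurve")) curves <- list(curves)
  fit <- fitProgress(curves, guess, shared = shared, bounds = bounds)

  report <- list(
    n_curves = length(curves),
    shared = as.list(fit@shared),
    rss_uM2 = fit@rss,
    converged = fit@converged,
    n_evaluations = fit@neval,
    curves = lapply(seq_along(curves), function(i) {
      p <- fit@parameters[[i]]
      list(label = curves[[i]]@label,
           kcat_per_s = p@kcat, Kd_uM = p@Kd,
           kon_per_uM_s = p@kon, koff_per_s = p@koff,
           Ki_uM = if (p@kon > 0) p@koff / p@kon else NA,
           stderr = as.list(fit@stderr[[i]]))
    }))
  jsonlite::write_json(report, file.path(out_dir, "fit_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")

  resid <- do.call(rbind, lapply(seq_along(curves), function(i) {
    cv <- curves[[i]]
    sim <- simulateProgress(fit@parameters[[i]], cv@conditions)
    data.frame(curve = i, label = cv@label, time_s = timeGrid(cv),
               product_uM = cv@product, fitted_product_uM = sim@product,
               residual_uM = cv@product - sim@product)
  }))
  utils::write.csv(resid, file.path(out_dir, "residuals.csv"),
                   row.names = FALSE, quote = FALSE)

  if (plot) {
    grDevices::png(file.path(out_dir, "overlay.png"), width = 900,
                   height = 600)
    on.exit(grDevices::dev.off(), add = TRUE)
    cols <- grDevices::hcl.colors(max(2, length(curves)), "Dark 2")
    ylim <- range(unlist(lapply(curves, productSeries)))
    plot(NA, xlim = range(timeGrid(curves[[1]])), ylim = ylim,
         xlab = "time [s]", ylab = "product [uM]",
         main = "progress curves and kinetic-model fits")
    for (i in seq_along(curves)) {
      graphics::points(timeGrid(curves[[i]]), curves[[i]]@product,
                       col = cols[i], pch = 1, cex = 0.6)
      sim <- simulateProgress(fit@parameters[[i]], curves[[i]]@conditions)
      graphics::lines(timeGrid(sim), sim@product, col = cols[i], lwd = 2)
    }
  }
  .writeConfig(list(analysis = "kinetics", e0_uM = e0, shared = shared,
                    bounds = bounds), out_dir, "config.json")
  invisible(fit)
}

#' Activation-geometry analysis of a native/activated structure pair
#'
#' Runs the structural pipeline on two conformational states: (1) hinge
#' detection between the two protomers of the native state, (2) rigid-body
#' rotation of a moving segment between the states, (3) coiled-coil register
#' comparison (contacts, heptad patterns, persistent/conditional
#' classification), and (4) the lateral register shift. Writes one JSON
#' report with all four quantities and input provenance.
#'
#' @param native,activated each a list of two \linkS4class{BackboneModel}
#'   protomers (or two-element character paths read with
#'   \code{\link{readBackbone}} and \code{chains}).
#' @param chains chain ids used when reading from files.
#' @param hinge list of \code{\link{detectHinges}} settings (threshold,
#'   flank_window, flank_max).
#' @param rigid list with integer vectors \code{fixed} and \code{moving}
#'   (residue numbers); NULL skips the rotation.
#' @param helix list with \code{range} (coiled-coil residue numbers) and
#'   \code{cutoff} (A); NULL skips the register analysis.
#' @param out_dir output directory; NULL returns the report only.
#' @return the report as a list, invisibly when written.
#' @export
runActivationGeometry <- function(native, activated, chains = c("A", "B"),
                                  hinge = list(threshold = 90,
                                               flank_window = 4,
                                               flank_max = 30),
                                  rigid = NULL, helix = NULL,
                                  out_dir = NULL) {
  load_pair <- function(x) {
    if (is.character(x))
      lapply(chains, function(ch) readBackbone(x, chain = ch))
    else x
  }
  nat <- load_pair(native); act <- load_pair(activated)
  if (length(nat) < 2 || length(act) < 2)
    stop("each state needs two protomers")

  report <- list(chains = chains)

  tp_a <- backboneTorsions(nat[[1]]); tp_b <- backboneTorsions(nat[[2]])
  hr <- detectHinges(torsionDifference(tp_a, tp_b),
                     threshold = hinge$threshold,
                     flank_window = hinge$flank_window,
                     flank_max = hinge$flank_max)
  report$hinge <- list(threshold_deg = hr@threshold,
                       hinges = hr@hinges)

  if (!is.null(rigid)) {
    rb <- rigidBodyRotation(nat[[1]], act[[1]], rigid$fixed, rigid$moving)
    report$rigid_body <- list(angle_deg = rb@angle, axis = rb@axis,
                              fixed_rmsd_A = rb@fixedRmsd,
                              moving_rmsd_A = rb@movingRmsd)
  }

  if (!is.null(helix)) {
    cutoff <- if (is.null(helix$cutoff)) 4.5 else helix$cutoff
    seg <- function(m) subsetModel(m, helix$range)
    contacts_nat <- symmetricPairContacts(seg(nat[[1]]), seg(nat[[2]]),
                                          cutoff = cutoff)
    contacts_act <- symmetricPairContacts(seg(act[[1]]), seg(act[[2]]),
                                          cutoff = cutoff)
    sh <- lateralShift(list(helix1 = seg(nat[[1]]), helix2 = seg(nat[[2]])),
                       list(helix1 = seg(act[[1]]), helix2 = seg(act[[2]])))
    report$register <- list(
      contacts_native = contacts_nat, contacts_activated = contacts_act,
      lateral_shift_A = sh$shift, axial_shift_A = sh$axial,
      azimuth_change_deg = sh$azimuth_change)
    if (length(contacts_nat) >= 2 && length(contacts_act) >= 2) {
      rc <- compareRegisters(assignHeptad(contacts_nat, helix$range),
                             assignHeptad(contacts_act, helix$range),
                             shift = sh)
      report$register <- c(report$register, list(
        pattern_native = rc@patternA, pattern_activated = rc@patternB,
        persistent = rc@persistent, conditional_native = rc@conditionalA,
        conditional_activated = rc@conditionalB))
    } else {
      report$register$pattern_native <- NA
      report$register$pattern_activated <- NA
    }
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "geometry_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null", dataframe = "rows")
    .writeConfig(list(analysis = "activation_geometry", chains = chains,
                      hinge = hinge, rigid = rigid,
                      helix = helix), out_dir, "config.json")
  }
  invisible(report)
}

#' Run the Rec-GGDEF linker census end-to-end
#'
#' Size filter, optional redundancy filter, anchor location and linker
#' extraction, length clustering, aligned group logos and slippery-repeat
#' scoring. Writes the record and rejection tables, group memberships, one
#' logo matrix per group, and a summary JSON with the counts at every filter
#' stage.
#'
#' @param seqs FASTA path or named character vector of protein sequences.
#' @param out_dir output directory.
#' @param max_len size-filter cutoff (exclusive), residues.
#' @param identity redundancy threshold in (0, 1]; NULL skips the filter.
#' @param peak_min_count,merge_tolerance see \code{\link{clusterLengths}}.
#' @param slippery_floor register-viability floor for
#'   \code{\link{slipperyScore}}.
#' @return list with records, groups (\linkS4class{LengthGroups}), logos,
#'   slippery table and the stage counts, invisibly.
#' @export
runCensus <- function(seqs, out_dir, max_len = 360, identity = 0.80,
                      peak_min_count = 5, merge_tolerance = 1,
                      slippery_floor = 3) {
  if (is.character(seqs) && length(seqs) == 1L && file.exists(seqs))
    seqs <- readFastaSequences(seqs)
  seqs <- .asSequenceVector(seqs)
  if (!length(seqs)) stop("empty sequence set")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  counts <- list(input = length(seqs))
  seqs <- sizeFilter(seqs, max_len = max_len)
  counts$after_size_filter <- length(seqs)
  if (!is.null(identity)) {
    seqs <- redundancyFilter(seqs, identity_threshold = identity)
  }
  counts$after_redundancy_filter <- length(seqs)

  records <- extractLinkers(seqs)
  accepted <- records[is.na(records$reason), , drop = FALSE]
  rejected <- records[!is.na(records$reason), , drop = FALSE]
  counts$accepted <- nrow(accepted)
  counts$rejected <- nrow(rejected)
  counts$group0 <- sum(accepted$group0)

  canonical <- accepted[!accepted$group0, , drop = FALSE]
  groups <- clusterLengths(canonical, peak_min_count = peak_min_count,
                           merge_tolerance = merge_tolerance)
  logos <- alignedGroupLogos(canonical, groups)

  slippery <- do.call(rbind, lapply(seq_len(nrow(canonical)), function(i) {
    lk <- canonical$linker[i]
    if (nchar(lk) < 14) return(NULL)
    sc <- slipperyScore(lk, floor = slippery_floor)
    data.frame(id = canonical$id[i], score_ad = sc$score_ad,
               score_ae = sc$score_ae, ambiguous = sc$ambiguous)
  }))

  utils::write.table(records, file.path(out_dir, "records.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(rejected[, c("id", "reason")],
                     file.path(out_dir, "rejections.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  member_df <- do.call(rbind, lapply(names(groups@groups), function(g)
    if (length(groups@groups[[g]]))
      data.frame(group_mode_length = g, id = groups@groups[[g]])))
  if (!is.null(member_df))
    utils::write.table(member_df, file.path(out_dir, "groups.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  for (g in names(logos))
    utils::write.table(round(logos[[g]], 6),
                       file.path(out_dir, sprintf("logo_group_%s.tsv", g)),
                       sep = "\t", quote = FALSE)
  if (!is.null(slippery))
    utils::write.table(slippery, file.path(out_dir, "slippery.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)

  summary <- c(counts,
               list(peaks = groups@peaks,
                    modal_spacing = groups@spacing,
                    linker_length_convention =
                      "KP start (inclusive) to DxLT start (exclusive)"))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  .writeConfig(list(analysis = "census", max_len = max_len,
                    identity = identity, peak_min_count = peak_min_count,
                    merge_tolerance = merge_tolerance,
                    slippery_floor = slippery_floor), out_dir, "config.json")

  invisible(list(records = records, groups = groups, logos = logos,
                 slippery = slippery, counts = counts))
}

#' Plot a helical net
#'
#' Simple lattice plot of a \code{\link{helicalNet}} table: residues at their
#' unrolled surface coordinates, contacts highlighted.
#'
#' @param net data.frame from \code{\link{helicalNet}}.
#' @param file optional PNG path; NULL plots to the active device.
#' @return invisibly, the net.
#' @export
plotHelicalNet <- function(net, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 500, height = 700)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  plot(net$x, net$y, type = "n", xlab = "circumference [A]",
       ylab = "axial rise [A]", main = "helical net")
  graphics::text(net$x, net$y, labels = paste0(net$letter, net$resno),
                 col = ifelse(net$contact, "red", "grey30"), cex = 0.8)
  invisible(net)
}
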