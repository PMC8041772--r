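#' Signed dihedral angle of four points
#'
#' IUPAC convention: cis = 0 degrees, trans = 180; sign from the standard
#' atan2 formulation, result on (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinates, Angstrom.
#' @return angle in degrees.
#' @export
dihedralAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n2 <- .vnorm(b2)
  if (.vnorm(b1) < 1e-8 || n2 < 1e-8 || .vnorm(b3) < 1e-8)
    stop("degenerate geometry: coincident consecutive points")
  c12 <- c(b1[2] * b2[3] - b1[3] * b2[2],
           b1[3] * b2[1] - b1[1] * b2[3],
           b1[1] * b2[2] - b1[2] * b2[1])
  c23 <- c(b2[2] * b3[3] - b2[3] * b3[2],
           b2[3] * b3[1] - b2[1] * b3[3],
           b2[1] * b3[2] - b2[2] * b3[1])
  if (.vnorm(c12) < 1e-8 || .vnorm(c23) < 1e-8)
    stop("degenerate geometry: three consecutive points collinear")
  ang <- atan2(sum(b1 * c23) * n2, sum(c12 * c23)) * 180 / pi
  wrapAngle(ang)
}

#' Backbone torsions of a chain
#'
#' Computes per-residue phi, psi and omega. phi is undefined at the first
#' residue, psi and omega at the last; all three are undefined across chain
#' breaks (consecutive C-N distance >= \code{break_cutoff}) and wherever a
#' required backbone atom is missing (logged as a message, not fatal).
#'
#' @param model a \linkS4class{BackboneModel} with at least two bonded
#'   residues.
#' @param break_cutoff C(i)-N(i+1) distance above which the chain is broken,
#'   Angstrom.
#' @return a \linkS4class{TorsionProfile}.
#' @export
backboneTorsions <- function(model, break_cutoff = 2.0) {
  stopifnot(is(model, "BackboneModel"))
  a <- model@atoms
  res <- unique(a$resno)
  if (length(res) < 2) stop("need at least two residues")
  N <- lapply(res, function(r) .atomXYZ(a, r, "N"))
  CA <- lapply(res, function(r) .atomXYZ(a, r, "CA"))
  C <- lapply(res, function(r) .atomXYZ(a, r, "C"))
  n <- length(res)

  # bonded[i]: residue i's C is peptide-bonded to residue i+1's N
  bonded <- vapply(seq_len(n - 1), function(i) {
    !is.null(C[[i]]) && !is.null(N[[i + 1]]) &&
      .vnorm(N[[i + 1]] - C[[i]]) < break_cutoff
  }, logical(1))

  phi <- psi <- omega <- rep(NA_real_, n)
  missing_ct <- 0L
  for (i in seq_len(n)) {
    ok <- function(...) all(!vapply(list(...), is.null, logical(1)))
    if (i > 1 && bonded[i - 1] && ok(C[[i - 1]], N[[i]], CA[[i]], C[[i]]))
      phi[i] <- tryCatch(
        dihedralAngle(C[[i - 1]], N[[i]], CA[[i]], C[[i]]),
        error = function(e) NA_real_)
    if (i < n && bonded[i] && ok(N[[i]], CA[[i]], C[[i]], N[[i + 1]]))
      psi[i] <- tryCatch(
        dihedralAngle(N[[i]], CA[[i]], C[[i]], N[[i + 1]]),
        error = function(e) NA_real_)
    if (i < n && bonded[i] && ok(CA[[i]], C[[i]], N[[i + 1]], CA[[i + 1]]))
      omega[i] <- tryCatch(
        dihedralAngle(CA[[i]], C[[i]], N[[i + 1]], CA[[i + 1]]),
        error = function(e) NA_real_)
    if (is.null(N[[i]]) || is.null(CA[[i]]) || is.null(C[[i]]))
      missing_ct <- missing_ct + 1L
  }
  if (missing_ct)
    message(sprintf("backboneTorsions: %d residue(s) with missing backbone atoms",
                    missing_ct))
  new("TorsionProfile", chain = model@chain,
      data = data.frame(resno = res, phi = phi, psi = psi, omega = omega))
}

#' Wrapped torsion differences between two profiles
#'
#' Pairs residues by number (or an explicit two-column pairing) and reports
#' b - a for phi, psi and omega, each wrapped to (-180, 180]. Differences are
#' \code{NA} wherever either side is undefined.
#'
#' @param a,b \linkS4class{TorsionProfile} objects.
#' @param alignment optional data.frame/matrix with columns (resno_a, resno_b);
#'   default pairs equal residue numbers.
#' @return data.frame with columns resno_a, resno_b, dphi, dpsi, domega.
#' @export
torsionDifference <- function(a, b, alignment = NULL) {
  stopifnot(is(a, "TorsionProfile"), is(b, "TorsionProfile"))
  da <- a@data; db <- b@data
  if (is.null(alignment)) {
    common <- intersect(da$resno, db$resno)
    alignment <- cbind(common, common)
  }
  alignment <- as.matrix(alignment)
  if (!nrow(alignment)) stop("empty residue pairing")
  ia <- match(alignment[, 1], da$resno)
  ib <- match(alignment[, 2], db$resno)
  if (anyNA(ia) || anyNA(ib))
    stop("pairing refers to residues absent from a profile")
  data.frame(resno_a = da$resno[ia], resno_b = db$resno[ib],
             dphi = wrapAngle(db$phi[ib] - da$phi[ia]),
             dpsi = wrapAngle(db$psi[ib] - da$psi[ia]),
             domega = wrapAngle(db$omega[ib] - da$omega[ia]))
}

#' Detect localised torsion hinges
#'
#' A hinge is a residue whose |delta-phi| or |delta-psi| reaches
#' \code{threshold} while the surrounding backbone is quiet: the mean absolute
#' difference over the flanking window (\code{flank_window} residues on each
#' side, the candidate excluded) must stay below \code{flank_max}. Defaults
#' isolate a single large outlier against a quiet baseline.
#'
#' @param diffs data.frame from \code{\link{torsionDifference}}.
#' @param threshold detection threshold, degrees (> flank_max).
#' @param flank_window flank half-width in residues.
#' @param flank_max maximum mean |delta| allowed in the flank, degrees.
#' @return a \linkS4class{HingeReport}.
#' @export
detectHinges <- function(diffs, threshold = 90, flank_window = 4,
                         flank_max = 30) {
  stopifnot(is.data.frame(diffs), threshold > flank_max)
  n <- nrow(diffs)
  if (2 * flank_window + 1 > n)
    stop("flank window larger than the aligned chain")
  out <- data.frame(resno = integer(0), torsion = character(0),
                    delta = numeric(0))
  for (i in seq_len(n)) {
    for (tor in c("phi", "psi")) {
      d <- diffs[[paste0("d", tor)]][i]
      if (is.na(d) || abs(d) < threshold) next
      win <- setdiff(max(1, i - flank_window):min(n, i + flank_window), i)
      flank <- abs(c(diffs$dphi[win], diffs$dpsi[win]))
      flank <- flank[!is.na(flank)]
      if (!length(flank) || mean(flank) <= flank_max)
        out <- rbind(out, data.frame(resno = diffs$resno_a[i], torsion = tor,
                                     delta = d))
    }
  }
  new("HingeReport", hinges = out, threshold = threshold)
}
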