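#' Fitted axis of an alpha-helix
#'
#' @slot anchor a point on the axis (the centroid used in the fit), Angstrom.
#' @slot direction unit vector along the axis, pointing N- to C-terminal.
#' @slot resno residue numbers used.
#' @export
setClass("HelixAxis",
  representation(anchor = "numeric", direction = "numeric",
                 resno = "integer"))

setValidity("HelixAxis", function(object) {
  if (abs(.vnorm(object@direction) - 1) > 1e-6)
    return("direction must be unit length")
  if (length(object@resno) < 7) return("at least 7 residues required")
  TRUE
})

setMethod("show", "HelixAxis", function(object) {
  cat(sprintf("HelixAxis over residues %d-%d, direction (%.3f, %.3f, %.3f)\n",
              min(object@resno), max(object@resno), object@direction[1],
              object@direction[2], object@direction[3]))
})

#' Fit the axis of a helix from Calpha positions
#'
#' Smooths the helical path with sliding 4-residue centroids (one full turn
#' cancels most of the helical wobble) and fits a least-squares line through
#' the centroids by principal components. The direction points from the N- to
#' the C-terminal end.
#'
#' @param ca_coords n x 3 matrix of consecutive Calpha coordinates (n >= 7);
#'   rownames, if present, are taken as residue numbers.
#' @return a \linkS4class{HelixAxis}.
#' @export
fitHelixAxis <- function(ca_coords) {
  ca <- as.matrix(ca_coords)
  n <- nrow(ca)
  if (n < 7) stop("need at least 7 consecutive Calpha positions")
  cents <- t(vapply(seq_len(n - 3), function(i)
    colMeans(ca[i:(i + 3), , drop = FALSE]), numeric(3)))
  ctr <- colMeans(cents)
  s <- svd(sweep(cents, 2, ctr))
  dir <- s$v[, 1]
  if (sum(dir * (cents[nrow(cents), ] - cents[1, ])) < 0) dir <- -dir
  rn <- rownames(ca)
  resno <- if (is.null(rn)) seq_len(n) else as.integer(rn)
  new("HelixAxis", anchor = ctr, direction = dir, resno = as.integer(resno))
}

#' Heptad-register assignment of a helix segment
#'
#' @slot resno residue numbers of the segment.
#' @slot letter heptad letters a-g per residue (cyclic with residue number).
#' @slot phase integer phase offset 0-6 (residue r has letter
#'   \code{letters[(r - phase) mod 7 + 1]}).
#' @slot pattern which contact pattern fits: "a-d-a-d", "a-e-a-e", or
#'   "non-canonical".
#' @slot contacts residue numbers of the interface contacts used.
#' @slot violations number of contacts off the fitted pattern.
#' @export
setClass("HeptadAssignment",
  representation(resno = "integer", letter = "character", phase = "integer",
                 pattern = "character", contacts = "integer",
                 violations = "integer"))

setValidity("HeptadAssignment", function(object) {
  if (length(object@resno) != length(object@letter))
    return("resno and letter lengths differ")
  keep <- object@letter != ""
  if (any(keep)) {
    h <- (object@resno[keep] - object@phase) %% 7
    if (!all(object@letter[keep] == letters[h + 1]))
      return("letters must advance cyclically with residue number")
  }
  TRUE
})

setMethod("show", "HeptadAssignment", function(object) {
  cat(sprintf("HeptadAssignment: pattern %s (phase %d, %d violation(s))\n",
              object@pattern, object@phase, object@violations))
  a_res <- object@resno[object@letter == "a"]
  if (length(a_res))
    cat("  a positions:", paste(a_res, collapse = ", "), "\n")
})

#' Assign a heptad register from interface contacts
#'
#' Chooses the phase (0-6) and pattern so that the contact residues fall on
#' heptad positions {a, d} or {a, e} with the fewest violations. Knobs spaced
#' 3-4-3 define a-d-a-d; spacing 4-3-4 defines a-e-a-e (which can formally
#' also be read as d'-a'-d'-a' in the shifted frame). If no phase places all
#' contacts on a pattern, the best assignment is returned flagged
#' "non-canonical".
#'
#' @param contacts integer residue numbers of interface contacts (>= 2).
#' @param segment_range integer residue numbers of the full segment to label
#'   (defaults to the contact span).
#' @return a \linkS4class{HeptadAssignment}.
#' @examples
#' assignHeptad(c(125, 128, 132, 135))  # a-d-a-d, a = 125, 132
#' assignHeptad(c(125, 129, 132, 136))  # a-e-a-e, a = 125, 132
#' @export
assignHeptad <- function(contacts, segment_range = NULL) {
  contacts <- sort(unique(as.integer(contacts)))
  if (length(contacts) < 2) stop("need at least 2 contact residues")
  if (is.null(segment_range))
    segment_range <- seq(min(contacts), max(contacts))
  segment_range <- as.integer(segment_range)

  # A 4-3-4 spacing fits {a,d} in a shifted frame just as well as {a,e}
  # (the formal d'-a'-d'-a' reading); the convention here is that the first
  # contact residue sits at position a, which makes the two patterns
  # distinguishable. Candidates are ranked by violations, then by honouring
  # that convention, then a-d before a-e, then lowest phase.
  patterns <- list("a-d-a-d" = c(0, 3), "a-e-a-e" = c(0, 4))
  best <- NULL
  for (pat in names(patterns)) {
    for (phase in 0:6) {
      off <- (contacts - phase) %% 7
      viol <- sum(!off %in% patterns[[pat]])
      first_a <- off[1] == 0
      better <- is.null(best) || viol < best$viol ||
        (viol == best$viol && first_a && !best$first_a)
      if (better) best <- list(pat = pat, phase = phase, viol = viol,
                               first_a = first_a)
    }
  }
  letter <- letters[(segment_range - best$phase) %% 7 + 1]
  new("HeptadAssignment", resno = segment_range, letter = letter,
      phase = as.integer(best$phase),
      pattern = if (best$viol == 0) best$pat else "non-canonical",
      contacts = contacts, violations = as.integer(best$viol))
}

# side-chain atoms of a residue (Calpha fallback, used for glycine and for
# backbone-only models)
.sideChainAtoms <- function(atoms, resno) {
  sc <- atoms[atoms$resno == resno &
                !atoms$atom %in% c("N", "CA", "C", "O", "OXT"), , drop = FALSE]
  if (!nrow(sc))
    sc <- atoms[atoms$resno == resno & atoms$atom == "CA", , drop = FALSE]
  sc
}

#' Contacts between symmetry-equivalent residues of a parallel two-helix pair
#'
#' For each residue of helix A, measures the minimum heavy-atom side-chain
#' distance (Calpha for glycine) to the side chains of its symmetry-equivalent
#' residue in helix B and that residue's hole neighbourhood (up to 3 residues
#' either side), and reports residues within \code{cutoff}.
#'
#' @param helixA,helixB \linkS4class{BackboneModel} segments of equal residue
#'   count.
#' @param cutoff contact cutoff, Angstrom; default 4.5 for knobs-into-holes
#'   side-chain packing.
#' @param hole_window how far (in residues) around the symmetry mate to
#'   search for the hole.
#' @return integer residue numbers of helix A in contact, ascending.
#' @export
symmetricPairContacts <- function(helixA, helixB, cutoff = 4.5,
                                  hole_window = 3L) {
  stopifnot(is(helixA, "BackboneModel"), is(helixB, "BackboneModel"))
  .assertScalarPositive(cutoff, "cutoff")
  resA <- unique(helixA@atoms$resno); resB <- unique(helixB@atoms$resno)
  if (length(resA) != length(resB))
    stop("helix segments must have equal residue counts")
  aa <- helixA@atoms[!.isHydrogen(helixA@atoms$atom), , drop = FALSE]
  ab <- helixB@atoms[!.isHydrogen(helixB@atoms$atom), , drop = FALSE]
  hits <- integer(0)
  for (k in seq_along(resA)) {
    sc_a <- .sideChainAtoms(aa, resA[k])
    jj <- seq(max(1, k - hole_window), min(length(resB), k + hole_window))
    sc_b <- do.call(rbind, lapply(resB[jj], function(r)
      .sideChainAtoms(ab, r)))
    if (!nrow(sc_a) || is.null(sc_b) || !nrow(sc_b)) next
    d <- .residuePairMinDist(sc_a, sc_b)
    if (min(d$dist) <= cutoff) hits <- c(hits, resA[k])
  }
  sort(unique(hits))
}

#' Comparison of two coiled-coil registers
#'
#' @slot persistent residues contacting in both states.
#' @slot conditionalA,conditionalB residues contacting only in state A / B.
#' @slot patternA,patternB fitted heptad patterns of the two states.
#' @slot shift lateral shift between the states, Angstrom (NA if not
#'   measured).
#' @slot axial axial component of the shift, Angstrom.
#' @slot azimuthChange mean change in azimuthal (rolling) angle, degrees.
#' @export
setClass("RegisterComparison",
  representation(persistent = "integer", conditionalA = "integer",
                 conditionalB = "integer", patternA = "character",
                 patternB = "character", shift = "numeric", axial = "numeric",
                 azimuthChange = "numeric"))

setValidity("RegisterComparison", function(object) {
  if (length(intersect(object@persistent,
                       c(object@conditionalA, object@conditionalB))))
    return("persistent and conditional sets must be disjoint")
  if (!is.na(object@shift) && object@shift < 0)
    return("shift must be non-negative")
  TRUE
})

setMethod("show", "RegisterComparison", function(object) {
  cat("RegisterComparison\n")
  cat(sprintf("  patterns: %s vs %s\n", object@patternA, object@patternB))
  cat("  persistent:", paste(object@persistent, collapse = ", "), "\n")
  cat("  conditional A:", paste(object@conditionalA, collapse = ", "), "\n")
  cat("  conditional B:", paste(object@conditionalB, collapse = ", "), "\n")
  if (!is.na(object@shift))
    cat(sprintf("  lateral shift %.2f A (axial %.2f A, azimuth change %.1f deg)\n",
                object@shift, object@axial, object@azimuthChange))
})

#' Classify persistent vs conditional coiled-coil contacts
#'
#' Persistent contacts are residues at the interface in both states;
#' conditional contacts belong to only one state (the symmetric difference,
#' labelled by state).
#'
#' @param stateA,stateB \linkS4class{HeptadAssignment} objects carrying the
#'   per-state contact sets (same residue range).
#' @param shift optional result of \code{\link{lateralShift}} to attach.
#' @return a \linkS4class{RegisterComparison}.
#' @export
compareRegisters <- function(stateA, stateB, shift = NULL) {
  stopifnot(is(stateA, "HeptadAssignment"), is(stateB, "HeptadAssignment"))
  new("RegisterComparison",
      persistent = intersect(stateA@contacts, stateB@contacts),
      conditionalA = setdiff(stateA@contacts, stateB@contacts),
      conditionalB = setdiff(stateB@contacts, stateA@contacts),
      patternA = stateA@pattern, patternB = stateB@pattern,
      shift = if (is.null(shift)) NA_real_ else shift$shift,
      axial = if (is.null(shift)) NA_real_ else shift$axial,
      azimuthChange = if (is.null(shift)) NA_real_ else shift$azimuth_change)
}

# signed mean azimuth of helix-2 residues about its axis, measured from the
# inter-axis direction (circular mean, degrees)
.meanAzimuth <- function(ca2, axis2, ref_point) {
  u <- axis2@direction
  w <- ref_point - axis2@anchor
  w <- w - sum(w * u) * u
  if (.vnorm(w) < 1e-6) return(NA_real_)
  w <- w / .vnorm(w)
  v2 <- .cross3(u, w)
  ang <- vapply(seq_len(nrow(ca2)), function(i) {
    r <- ca2[i, ] - axis2@anchor
    r <- r - sum(r * u) * u
    atan2(sum(r * v2), sum(r * w))
  }, numeric(1))
  atan2(mean(sin(ang)), mean(cos(ang))) * 180 / pi
}

#' Lateral shift of a two-helix coiled coil between two states
#'
#' Superposes helix 1 of state 2 onto helix 1 of state 1 (Calpha), carries
#' helix 2 of state 2 along, and measures the mean displacement of the helix-2
#' Calpha equivalents. The axial component is the projection of that mean
#' displacement on the helix-2 axis; the azimuth change reports how much the
#' helices roll over each other (a pure register translation keeps it near 0).
#'
#' @param pairState1,pairState2 lists with elements \code{helix1} and
#'   \code{helix2}, each an n x 3 Calpha matrix or a
#'   \linkS4class{BackboneModel}; the same residue pairing in both states.
#' @return list with elements \code{shift} (A), \code{axial} (A) and
#'   \code{azimuth_change} (degrees).
#' @export
lateralShift <- function(pairState1, pairState2) {
  getCA <- function(h) if (is(h, "BackboneModel")) .caCoords(h) else as.matrix(h)
  h1a <- getCA(pairState1$helix1); h2a <- getCA(pairState1$helix2)
  h1b <- getCA(pairState2$helix1); h2b <- getCA(pairState2$helix2)
  if (nrow(h2a) != nrow(h2b) || nrow(h1a) != nrow(h1b))
    stop("states must contain the same residue pairing")
  sp <- superpose(h1a, h1b)
  h2b_s <- applyTransform(sp, h2b)
  disp <- colMeans(h2b_s - h2a)
  shift <- .vnorm(disp)
  axis2 <- fitHelixAxis(h2a)
  axial <- abs(sum(disp * axis2@direction))
  axis2b <- fitHelixAxis(h2b_s)
  ref1 <- fitHelixAxis(h1a)@anchor
  az_a <- .meanAzimuth(h2a, axis2, ref1)
  az_b <- .meanAzimuth(h2b_s, axis2b, ref1)
  list(shift = shift, axial = axial,
       azimuth_change = abs(wrapAngle(az_b - az_a)))
}

#' Unrolled helical-net lattice for coiled-coil plots
#'
#' Maps each residue to 2-D lattice coordinates on the unrolled helix
#' surface: axial rise along y, circumferential position along x. The lattice
#' uses the coiled-coil periodicity of 3.5 residues per turn, so residue i+7
#' sits exactly one heptad higher at the same circumferential position.
#'
#' @param assignment a \linkS4class{HeptadAssignment}.
#' @param contacts optional residue numbers to flag in the output.
#' @param rise axial rise per residue, Angstrom.
#' @param radius helix surface radius used to scale the circumference,
#'   Angstrom.
#' @return data.frame with columns resno, letter, x, y, contact.
#' @export
helicalNet <- function(assignment, contacts = NULL, rise = 1.5,
                       radius = 2.3) {
  stopifnot(is(assignment, "HeptadAssignment"))
  res <- assignment@resno
  i <- res - res[1]
  circumference <- 2 * pi * radius
  azim <- (i * 2 / 7) %% 1          # turns, 3.5 residues per turn
  data.frame(resno = res, letter = assignment@letter,
             x = azim * circumference, y = i * rise,
             contact = res %in% (if (is.null(contacts))
               assignment@contacts else contacts))
}
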