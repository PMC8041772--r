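#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares proper rotation and translation carrying \code{mobile} onto
#' \code{fixed}; reflections are excluded. The transform maps a mobile point
#' p to \code{R p + t}.
#'
#' @param fixed,mobile n x 3 coordinate matrices, equal row counts >= 3.
#' @return a \linkS4class{SuperpositionResult}.
#' @export
superpose <- function(fixed, mobile) {
  fixed <- as.matrix(fixed); mobile <- as.matrix(mobile)
  if (ncol(fixed) != 3 || ncol(mobile) != 3 || nrow(fixed) != nrow(mobile))
    stop("fixed and mobile must be n x 3 with equal n")
  n <- nrow(fixed)
  if (n < 3) stop("need at least 3 point pairs")
  cf <- colMeans(fixed); cm <- colMeans(mobile)
  X <- sweep(mobile, 2, cm); Y <- sweep(fixed, 2, cf)
  H <- t(X) %*% Y
  s <- svd(H)
  if (s$d[2] < 1e-10)
    stop("rank-deficient point sets (collinear or coincident)")
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- cf - as.numeric(R %*% cm)
  moved <- sweep(mobile %*% t(R), 2, tr, "+")
  rmsd <- sqrt(mean(rowSums((moved - fixed)^2)))
  new("SuperpositionResult", rotation = R, translation = tr,
      rmsd = rmsd, n = as.integer(n))
}

#' Apply a superposition transform to coordinates
#'
#' @param sp a \linkS4class{SuperpositionResult}.
#' @param coords n x 3 matrix.
#' @return transformed n x 3 matrix.
#' @export
applyTransform <- function(sp, coords) {
  stopifnot(is(sp, "SuperpositionResult"))
  sweep(as.matrix(coords) %*% t(sp@rotation), 2, sp@translation, "+")
}

# angle (deg, [0,180]) and unit axis of a rotation matrix; axis sign chosen
# so the positive rotation about it equals R
.rotationAngleAxis <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  angle <- acos(min(1, max(-1, ct))) * 180 / pi
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  if (.vnorm(v) > 1e-8) {
    axis <- v / .vnorm(v)
  } else if (angle < 90) {           # identity: axis arbitrary
    axis <- c(0, 0, 1)
  } else {                           # near 180 deg: eigenvector of (R + I)
    e <- eigen(R + diag(3), symmetric = FALSE)
    i <- which.max(abs(Re(e$values)))
    axis <- Re(e$vectors[, i]); axis <- axis / .vnorm(axis)
  }
  list(angle = angle, axis = axis)
}

#' Rigid-body rotation of a moving segment between two conformers
#'
#' Superposes conformer B onto conformer A using the Calpha atoms of
#' \code{fixed_set}, then computes the residual rotation carrying the
#' \code{moving_set} Calphas of A onto those of (superposed) B. The angle is
#' taken from the rotation-matrix trace (\code{tr R = 1 + 2 cos theta}), the
#' axis from its antisymmetric part, with the sign chosen so the rotation is
#' at most 180 degrees. Residues missing from either conformer are dropped
#' pairwise.
#'
#' @param confA,confB \linkS4class{BackboneModel} conformers.
#' @param fixed_set,moving_set integer vectors of residue numbers (>= 3 in
#'   common between the conformers each).
#' @return a \linkS4class{RigidBodyRotation}.
#' @export
rigidBodyRotation <- function(confA, confB, fixed_set, moving_set) {
  stopifnot(is(confA, "BackboneModel"), is(confB, "BackboneModel"))
  pick <- function(set) {
    ca_a <- .caCoords(confA, set); ca_b <- .caCoords(confB, set)
    common <- intersect(rownames(ca_a), rownames(ca_b))
    if (length(common) < 3)
      stop("fewer than 3 common Calpha atoms in a segment")
    dropped <- length(set) - length(common)
    if (dropped) message(sprintf("rigidBodyRotation: %d residue(s) dropped pairwise", dropped))
    list(a = ca_a[common, , drop = FALSE], b = ca_b[common, , drop = FALSE])
  }
  fx <- pick(fixed_set); mv <- pick(moving_set)
  sp_fixed <- superpose(fx$a, fx$b)
  b_moving <- applyTransform(sp_fixed, mv$b)
  sp_moving <- superpose(b_moving, mv$a)   # residual rotation A -> B frame
  aa <- .rotationAngleAxis(sp_moving@rotation)
  new("RigidBodyRotation", angle = aa$angle, axis = aa$axis,
      fixedRmsd = sp_fixed@rmsd, movingRmsd = sp_moving@rmsd)
}
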