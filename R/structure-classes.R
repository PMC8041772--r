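#' Backbone model of a single protein chain
#'
#' Holds the atoms of one chain as a table with columns \code{resno}
#' (author residue number, strictly increasing), \code{resname} (3-letter
#' code), \code{atom} (atom name: N, CA, C, O, CB, ...), and Cartesian
#' \code{x}, \code{y}, \code{z} in Angstrom. Consecutive residues whose C-N
#' distance exceeds 2.0 A are treated as a chain break; torsions are undefined
#' across breaks.
#'
#' @slot chain chain identifier.
#' @slot atoms data.frame as described above.
#' @export
setClass("BackboneModel",
  representation(chain = "character", atoms = "data.frame"))

setValidity("BackboneModel", function(object) {
  a <- object@atoms
  need <- c("resno", "resname", "atom", "x", "y", "z")
  if (!all(need %in% names(a)))
    return(paste("atoms needs columns:", paste(need, collapse = ", ")))
  if (nrow(a) && is.unsorted(a$resno))
    return("residue numbers must be non-decreasing in atom order")
  if (nrow(a) && any(!is.finite(c(a$x, a$y, a$z))))
    return("coordinates must be finite")
  TRUE
})

#' Construct a backbone model
#'
#' @param atoms data.frame with columns resno, resname, atom, x, y, z.
#' @param chain chain id.
#' @return a \linkS4class{BackboneModel}.
#' @export
BackboneModel <- function(atoms, chain = "A") {
  atoms$resno <- as.integer(atoms$resno)
  new("BackboneModel", chain = as.character(chain)[1],
      atoms = as.data.frame(atoms))
}

#' @rdname BackboneModel
#' @param object a BackboneModel.
#' @export
setGeneric("atoms", function(object) standardGeneric("atoms"))
#' @rdname BackboneModel
#' @export
setMethod("atoms", "BackboneModel", function(object) object@atoms)

#' @rdname BackboneModel
#' @export
setGeneric("chainId", function(object) standardGeneric("chainId"))
#' @rdname BackboneModel
#' @export
setMethod("chainId", "BackboneModel", function(object) object@chain)

setMethod("show", "BackboneModel", function(object) {
  cat(sprintf("BackboneModel chain %s: %d residues (%d-%d), %d atoms\n",
              object@chain, length(unique(object@atoms$resno)),
              min(object@atoms$resno), max(object@atoms$resno),
              nrow(object@atoms)))
})

# Cα coordinate matrix (rownames = resno) for a residue selection
.caCoords <- function(model, resnos = NULL) {
  a <- model@atoms[model@atoms$atom == "CA", , drop = FALSE]
  if (!is.null(resnos)) a <- a[a$resno %in% resnos, , drop = FALSE]
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- a$resno
  m
}

# one backbone atom's coordinates, or NULL if absent
.atomXYZ <- function(atoms, resno, name) {
  i <- which(atoms$resno == resno & atoms$atom == name)
  if (!length(i)) return(NULL)
  as.numeric(atoms[i[1], c("x", "y", "z")])
}

#' Backbone torsion profile of a chain
#'
#' Per-residue phi/psi/omega in degrees on (-180, 180], with \code{NA} marking
#' undefined angles (chain termini, breaks, missing backbone atoms). omega of
#' residue i is the torsion about the C(i)-N(i+1) peptide bond.
#'
#' @slot chain chain identifier.
#' @slot data data.frame with columns resno, phi, psi, omega.
#' @export
setClass("TorsionProfile",
  representation(chain = "character", data = "data.frame"))

setValidity("TorsionProfile", function(object) {
  d <- object@data
  if (!all(c("resno", "phi", "psi", "omega") %in% names(d)))
    return("data needs columns resno, phi, psi, omega")
  ang <- c(d$phi, d$psi, d$omega)
  ang <- ang[!is.na(ang)]
  if (length(ang) && (any(ang <= -180) || any(ang > 180)))
    return("angles must lie in (-180, 180]")
  TRUE
})

#' @rdname TorsionProfile-class
#' @param object a TorsionProfile.
#' @export
setGeneric("torsions", function(object) standardGeneric("torsions"))
#' @rdname TorsionProfile-class
#' @export
setMethod("torsions", "TorsionProfile", function(object) object@data)

setMethod("show", "TorsionProfile", function(object) {
  d <- object@data
  cat(sprintf("TorsionProfile chain %s: %d residues, %d/%d/%d defined phi/psi/omega\n",
              object@chain, nrow(d), sum(!is.na(d$phi)), sum(!is.na(d$psi)),
              sum(!is.na(d$omega))))
})

#' Least-squares rigid superposition result
#'
#' @slot rotation 3x3 proper rotation matrix (det = +1).
#' @slot translation length-3 translation, Angstrom.
#' @slot rmsd root-mean-square deviation after superposition, Angstrom.
#' @slot n number of atom pairs used.
#' @export
setClass("SuperpositionResult",
  representation(rotation = "matrix", translation = "numeric",
                 rmsd = "numeric", n = "integer"))

setValidity("SuperpositionResult", function(object) {
  if (!all(dim(object@rotation) == c(3, 3))) return("rotation must be 3x3")
  if (abs(det(object@rotation) - 1) > 1e-8)
    return("rotation must be proper (det = +1)")
  if (object@rmsd < 0) return("rmsd must be non-negative")
  TRUE
})

setMethod("show", "SuperpositionResult", function(object) {
  cat(sprintf("SuperpositionResult: rmsd %.4f A over %d atoms\n",
              object@rmsd, object@n))
})

#' Rigid-body rotation between two conformers
#'
#' @slot angle rotation angle in degrees, [0, 180].
#' @slot axis unit vector of the rotation axis.
#' @slot fixedRmsd rmsd of the fixed-set superposition, Angstrom.
#' @slot movingRmsd rmsd of the moving set after its own superposition,
#'   Angstrom.
#' @export
setClass("RigidBodyRotation",
  representation(angle = "numeric", axis = "numeric",
                 fixedRmsd = "numeric", movingRmsd = "numeric"))

setValidity("RigidBodyRotation", function(object) {
  if (object@angle < 0 || object@angle > 180)
    return("angle must be in [0, 180] degrees")
  if (abs(.vnorm(object@axis) - 1) > 1e-6) return("axis must be unit length")
  TRUE
})

#' @rdname RigidBodyRotation-class
#' @param object a RigidBodyRotation.
#' @export
setGeneric("rotationAngle", function(object) standardGeneric("rotationAngle"))
#' @rdname RigidBodyRotation-class
#' @export
setMethod("rotationAngle", "RigidBodyRotation", function(object) object@angle)

#' @rdname RigidBodyRotation-class
#' @export
setGeneric("rotationAxis", function(object) standardGeneric("rotationAxis"))
#' @rdname RigidBodyRotation-class
#' @export
setMethod("rotationAxis", "RigidBodyRotation", function(object) object@axis)

setMethod("show", "RigidBodyRotation", function(object) {
  cat(sprintf("RigidBodyRotation: %.2f deg about (%.3f, %.3f, %.3f); fixed rmsd %.3f A, moving rmsd %.3f A\n",
              object@angle, object@axis[1], object@axis[2], object@axis[3],
              object@fixedRmsd, object@movingRmsd))
})

#' Report of localised torsion-angle hinges
#'
#' @slot hinges data.frame with columns resno, torsion ("phi"/"psi"), delta
#'   (wrapped difference, degrees).
#' @slot threshold detection threshold used, degrees.
#' @export
setClass("HingeReport",
  representation(hinges = "data.frame", threshold = "numeric"))

setValidity("HingeReport", function(object) {
  h <- object@hinges
  if (!all(c("resno", "torsion", "delta") %in% names(h)))
    return("hinges needs columns resno, torsion, delta")
  if (nrow(h) && any(abs(h$delta) < object@threshold))
    return("every listed |delta| must be >= threshold")
  TRUE
})

#' @rdname HingeReport-class
#' @param object a HingeReport.
#' @export
setGeneric("hinges", function(object) standardGeneric("hinges"))
#' @rdname HingeReport-class
#' @export
setMethod("hinges", "HingeReport", function(object) object@hinges)

setMethod("show", "HingeReport", function(object) {
  cat(sprintf("HingeReport (threshold %.0f deg): %d hinge(s)\n",
              object@threshold, nrow(object@hinges)))
  if (nrow(object@hinges)) {
    h <- object@hinges
    for (i in seq_len(nrow(h)))
      cat(sprintf("  residue %d %s: %+.1f deg\n",
                  h$resno[i], h$torsion[i], h$delta[i]))
  }
})
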