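# Ideal backbone geometry used by the torsion-space builder (Angstrom/degrees)
.BOND <- c(N_CA = 1.458, CA_C = 1.525, C_N = 1.329)
.ANGLE <- c(N_CA_C = 111.2, CA_C_N = 116.2, C_N_CA = 121.7)

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Natural-extension reference frame: position of atom D given the three
# preceding atoms, bond length C-D, bond angle B-C-D and torsion A-B-C-D.
.placeAtom <- function(A, B, C, bond, angle_deg, torsion_deg) {
  th <- angle_deg * pi / 180; chi <- torsion_deg * pi / 180
  bc <- .unit(C - B)
  n <- .unit(.cross3(B - A, bc))
  m <- .cross3(n, bc)
  d <- c(-bond * cos(th), bond * sin(th) * cos(chi), bond * sin(th) * sin(chi))
  C + d[1] * bc + d[2] * m + d[3] * n
}

#' Build an ideal-geometry backbone from torsion angles
#'
#' Constructs N/CA/C coordinates for a chain with ideal bond lengths
#' (N-CA 1.458, CA-C 1.525, C-N 1.329 A) and bond angles, from supplied
#' phi/psi/omega. Round-trips with \code{\link{backboneTorsions}} to numerical
#' precision.
#'
#' @param n_res number of residues (>= 2).
#' @param phi,psi,omega torsions in degrees; scalars are recycled. phi[1],
#'   psi[n] and omega[n] are not used.
#' @param chain chain id.
#' @param resname residue name given to all residues.
#' @param start_resno first residue number.
#' @return a \linkS4class{BackboneModel}.
#' @export
buildBackbone <- function(n_res, phi = -57, psi = -47, omega = 180,
                          chain = "A", resname = "ALA", start_resno = 1L) {
  stopifnot(n_res >= 2)
  phi <- rep_len(phi, n_res); psi <- rep_len(psi, n_res)
  omega <- rep_len(omega, n_res)
  N <- CA <- C <- vector("list", n_res)
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(.BOND["N_CA"], 0, 0)
  a0 <- (180 - .ANGLE["N_CA_C"]) * pi / 180
  C[[1]] <- CA[[1]] + .BOND["CA_C"] * c(cos(a0), sin(a0), 0)
  for (i in seq_len(n_res - 1)) {
    N[[i + 1]] <- .placeAtom(N[[i]], CA[[i]], C[[i]],
                             .BOND["C_N"], .ANGLE["CA_C_N"], psi[i])
    CA[[i + 1]] <- .placeAtom(CA[[i]], C[[i]], N[[i + 1]],
                              .BOND["N_CA"], .ANGLE["C_N_CA"], omega[i])
    C[[i + 1]] <- .placeAtom(C[[i]], N[[i + 1]], CA[[i + 1]],
                             .BOND["CA_C"], .ANGLE["N_CA_C"], phi[i + 1])
  }
  resno <- rep(start_resno + seq_len(n_res) - 1L, each = 3)
  xyz <- do.call(rbind, unlist(lapply(seq_len(n_res), function(i)
    list(N[[i]], CA[[i]], C[[i]])), recursive = FALSE))
  BackboneModel(data.frame(resno = resno, resname = resname,
                           atom = rep(c("N", "CA", "C"), n_res),
                           x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
                chain = chain)
}

#' Apply torsion-angle edits by forward kinematics
#'
#' Rotates all atoms C-terminal to each edited bond rigidly about that bond:
#' a phi edit at residue i turns everything kinematically downstream of CA(i)
#' (side chain, C and O of residue i, and all later residues) about the
#' N(i)-CA(i) axis; a psi edit turns O(i) and all later residues about the
#' CA(i)-C(i) axis. Bond lengths and angles are untouched, atoms N-terminal
#' to the first edited bond do not move, and re-measured torsions equal the
#' originals plus the edits (wrapped).
#'
#' @param model a \linkS4class{BackboneModel}.
#' @param edits data.frame with columns \code{resno}, \code{dphi},
#'   \code{dpsi} (degrees; NA or 0 = no change), applied in row order.
#' @return the edited \linkS4class{BackboneModel}.
#' @export
applyTorsionChanges <- function(model, edits) {
  stopifnot(is(model, "BackboneModel"), is.data.frame(edits),
            all(c("resno", "dphi", "dpsi") %in% names(edits)))
  a <- model@atoms
  res <- unique(a$resno)
  prof <- backboneTorsions(model)

  rotate_about <- function(a, base, axis, delta, rows) {
    R <- .rotationMatrix(axis, delta)
    xyz <- as.matrix(a[rows, c("x", "y", "z")])
    xyz <- sweep(sweep(xyz, 2, base) %*% t(R), 2, base, "+")
    a[rows, c("x", "y", "z")] <- xyz
    a
  }

  for (k in seq_len(nrow(edits))) {
    r <- edits$resno[k]
    if (!r %in% res) stop(sprintf("residue %d not in model", r))
    ti <- prof@data[prof@data$resno == r, ]
    for (tor in c("dphi", "dpsi")) {
      delta <- edits[[tor]][k]
      if (is.na(delta) || delta == 0) next
      if (tor == "dphi" && is.na(ti$phi))
        stop(sprintf("phi undefined at residue %d (terminus or break)", r))
      if (tor == "dpsi" && is.na(ti$psi))
        stop(sprintf("psi undefined at residue %d (terminus or break)", r))
      ca <- .atomXYZ(a, r, "CA"); nn <- .atomXYZ(a, r, "N")
      cc <- .atomXYZ(a, r, "C")
      if (tor == "dphi") {
        axis <- .unit(ca - nn); base <- nn
        rows <- which(a$resno > r |
                        (a$resno == r & !a$atom %in% c("N", "CA")))
      } else {
        axis <- .unit(cc - ca); base <- ca
        rows <- which(a$resno > r | (a$resno == r & a$atom %in% c("O", "OXT")))
      }
      a <- rotate_about(a, base, axis, delta, rows)
    }
  }
  BackboneModel(a, chain = model@chain)
}
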