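# residue-blocked minimum-distance table between two atom sets
.residuePairMinDist <- function(atomsA, atomsB) {
  xa <- as.matrix(atomsA[, c("x", "y", "z")])
  xb <- as.matrix(atomsB[, c("x", "y", "z")])
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  # min over atoms within each residue pair
  ra <- factor(atomsA$resno); rb <- factor(atomsB$resno)
  mins <- vapply(levels(ra), function(i)
    vapply(levels(rb), function(j)
      min(d[ra == i, rb == j]), numeric(1)), numeric(nlevels(rb)))
  if (is.null(dim(mins))) mins <- matrix(mins, nrow = nlevels(rb))
  list(dist = t(mins), resA = as.integer(levels(ra)),
       resB = as.integer(levels(rb)))
}

.isHydrogen <- function(atom_names) grepl("^[0-9]*H", atom_names)

#' Inter-chain residue contacts
#'
#' Lists all residue pairs between two chains whose minimum heavy-atom
#' distance is at most \code{cutoff}. Hydrogens are ignored. Symmetric in
#' chain order (swapping the arguments swaps the columns).
#'
#' @param chainA,chainB \linkS4class{BackboneModel} objects (side chains
#'   included when available).
#' @param cutoff contact cutoff, Angstrom (> 0); the value used for the
#'   receiver-domain dimer interface in this system is 3.2 A.
#' @return data.frame with columns resnoA, resnoB, dist (A), sorted by
#'   (resnoA, resnoB).
#' @export
interchainContacts <- function(chainA, chainB, cutoff = 3.2) {
  stopifnot(is(chainA, "BackboneModel"), is(chainB, "BackboneModel"))
  .assertScalarPositive(cutoff, "cutoff")
  aa <- chainA@atoms[!.isHydrogen(chainA@atoms$atom), , drop = FALSE]
  ab <- chainB@atoms[!.isHydrogen(chainB@atoms$atom), , drop = FALSE]
  if (!nrow(aa) || !nrow(ab))
    return(data.frame(resnoA = integer(0), resnoB = integer(0),
                      dist = numeric(0)))
  pm <- .residuePairMinDist(aa, ab)
  hits <- which(pm$dist <= cutoff, arr.ind = TRUE)
  out <- data.frame(resnoA = pm$resA[hits[, 1]], resnoB = pm$resB[hits[, 2]],
                    dist = pm$dist[hits])
  out[order(out$resnoA, out$resnoB), , drop = FALSE]
}
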