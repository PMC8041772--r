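#' Read a chain from a PDB or mmCIF coordinate file
#'
#' PDB files are parsed with \pkg{bio3d}; mmCIF files with a minimal
#' \code{atom_site} reader. Model 1 is used for multi-model files. Altloc
#' handling keeps the highest-occupancy conformer (ties broken by label
#' order); hydrogens are dropped. Insertion-coded residues are kept in file
#' order after their base number.
#'
#' @param path coordinate file (.pdb/.ent or .cif/.mmcif).
#' @param chain chain identifier to extract (required when the file has more
#'   than one chain).
#' @return a \linkS4class{BackboneModel}.
#' @export
readBackbone <- function(path, chain = NULL) {
  if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) {
    at <- .readCifAtoms(path)
  } else {
    pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
    at <- pdb$atom[pdb$atom$type == "ATOM",
                   c("chain", "resno", "resid", "elety", "x", "y", "z",
                     "o", "alt", "elesy")]
    names(at) <- c("chain", "resno", "resname", "atom", "x", "y", "z",
                   "occ", "alt", "element")
  }
  chains <- unique(at$chain)
  if (is.null(chain)) {
    if (length(chains) > 1)
      stop("file has chains ", paste(chains, collapse = ", "),
           "; specify one")
    chain <- chains
  }
  at <- at[at$chain == chain, , drop = FALSE]
  if (!nrow(at)) stop(sprintf("chain '%s' not found in %s", chain, path))
  at <- at[!(.isHydrogen(at$atom) | at$element %in% "H"), , drop = FALSE]
  # altloc: keep highest occupancy per (resno, atom), ties by label order
  if (any(!is.na(at$alt) & at$alt != "")) {
    key <- paste(at$resno, at$atom)
    ord <- order(key, -replace(at$occ, is.na(at$occ), 1),
                 replace(at$alt, is.na(at$alt), ""))
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$resno, at$atom)), , drop = FALSE]
    at <- at[order(as.integer(rownames(at))), , drop = FALSE]
  }
  at <- at[order(at$resno), , drop = FALSE]
  BackboneModel(at[, c("resno", "resname", "atom", "x", "y", "z")],
                chain = chain)
}

# Minimal mmCIF atom_site loop reader (whitespace-tokenised; quoted values
# without embedded blanks are unquoted). First model only, ATOM records.
.readCifAtoms <- function(path) {
  lines <- readLines(path)
  hdr_idx <- grep("^_atom_site\\.", lines)
  if (!length(hdr_idx)) stop("no _atom_site loop found in ", path)
  fields <- sub("^_atom_site\\.", "", trimws(lines[hdr_idx]))
  body_start <- max(hdr_idx) + 1
  rows <- character(0)
  for (i in body_start:length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#") || startsWith(ln, "loop_") ||
        startsWith(ln, "_")) break
    rows <- c(rows, ln)
  }
  tok <- strsplit(rows, "[[:space:]]+")
  nf <- length(fields)
  tok <- tok[lengths(tok) == nf]
  m <- do.call(rbind, tok)
  colnames(m) <- fields
  g <- function(nm, alt = NULL) {
    if (nm %in% fields) m[, nm]
    else if (!is.null(alt) && alt %in% fields) m[, alt]
    else rep(NA_character_, nrow(m))
  }
  unq <- function(x) gsub('^"|"$|^\'|\'$', "", x)
  d <- data.frame(
    group = g("group_PDB"),
    chain = g("auth_asym_id", "label_asym_id"),
    resno = as.integer(g("auth_seq_id", "label_seq_id")),
    resname = g("auth_comp_id", "label_comp_id"),
    atom = unq(g("auth_atom_id", "label_atom_id")),
    x = as.numeric(g("Cartn_x")), y = as.numeric(g("Cartn_y")),
    z = as.numeric(g("Cartn_z")),
    occ = suppressWarnings(as.numeric(g("occupancy"))),
    alt = g("label_alt_id"),
    element = g("type_symbol"),
    model = g("pdbx_PDB_model_num"))
  d$alt[d$alt %in% c(".", "?")] <- ""
  if (!all(is.na(d$model))) d <- d[d$model == d$model[1], , drop = FALSE]
  d[d$group == "ATOM", setdiff(names(d), c("group", "model")), drop = FALSE]
}

#' Write a backbone model as a PDB file
#'
#' @param model a \linkS4class{BackboneModel}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeBackbonePDB <- function(model, path) {
  stopifnot(is(model, "BackboneModel"))
  a <- model@atoms
  lines <- vapply(seq_len(nrow(a)), function(i) {
    nm <- a$atom[i]
    nm_fmt <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else sprintf("%-4s", nm)
    sprintf("ATOM  %5d %s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            i, nm_fmt, substr(a$resname[i], 1, 3), model@chain, a$resno[i],
            a$x[i], a$y[i], a$z[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
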