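#' Locate the KP and DxLT linker anchors in a Rec-GGDEF sequence
#'
#' The inter-domain linker runs from the KP motif in the receiver-domain
#' beta5-alpha5 loop to the DxLT motif at the start of the GGDEF domain. DxLT
#' is matched as D-x-L-T (x = any residue), KP as the literal dipeptide. The
#' anchor pair is the first DxLT that has a KP before it, together with the
#' last such KP. Sequences carrying an (S/N)PLT motif instead of DxLT are the
#' divergent group 0 and are anchored on that motif with \code{group0 = TRUE}.
#'
#' The linker length convention is fixed package-wide: residues from the K of
#' KP (inclusive) to the D of DxLT (exclusive), i.e.
#' \code{length = dxlt - kp}.
#'
#' @param seq a single amino-acid sequence (character string).
#' @return list with elements \code{kp}, \code{dxlt} (1-based motif start
#'   positions), \code{length}, \code{linker} (the linker sequence),
#'   \code{group0}, and \code{reason} (\code{NA} on success, else a rejection
#'   code: \code{"no_anchor_pair"}).
#' @examples
#' locateAnchors("AAKPAAAAAAADALTGG")  # kp = 3, dxlt = 12, length 9
#' locateAnchors("AAKPAAAAAAASPLTGG")$group0  # TRUE
#' @export
locateAnchors <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  kp_pos <- gregexpr("KP", seq, fixed = TRUE)[[1]]
  kp_pos <- kp_pos[kp_pos > 0]
  find_pair <- function(pattern) {
    d_pos <- gregexpr(pattern, seq)[[1]]
    d_pos <- d_pos[d_pos > 0]
    for (d in d_pos) {
      before <- kp_pos[kp_pos < d]
      if (length(before)) return(c(kp = max(before), dxlt = d))
    }
    NULL
  }
  hit <- find_pair("D[A-Z]LT"); group0 <- FALSE
  if (is.null(hit)) {
    hit <- find_pair("[SN]PLT"); group0 <- TRUE
  }
  if (is.null(hit))
    return(list(kp = NA_integer_, dxlt = NA_integer_, length = NA_integer_,
                linker = NA_character_, group0 = NA,
                reason = "no_anchor_pair"))
  list(kp = unname(hit["kp"]), dxlt = unname(hit["dxlt"]),
       length = unname(hit["dxlt"] - hit["kp"]),
       linker = substr(seq, hit["kp"], hit["dxlt"] - 1),
       group0 = group0, reason = NA_character_)
}

#' Extract linker records from a sequence set
#'
#' Applies \code{\link{locateAnchors}} to every sequence and tabulates the
#' results, including rejected sequences with their reason codes.
#'
#' @param seqs named character vector or \code{Biostrings::AAStringSet}.
#' @return data.frame with columns id, kp, dxlt, length, linker, group0,
#'   reason.
#' @export
extractLinkers <- function(seqs) {
  seqs <- .asSequenceVector(seqs)
  recs <- lapply(seqs, locateAnchors)
  data.frame(id = names(seqs),
             kp = vapply(recs, `[[`, integer(1), "kp"),
             dxlt = vapply(recs, `[[`, integer(1), "dxlt"),
             length = vapply(recs, `[[`, integer(1), "length"),
             linker = vapply(recs, `[[`, character(1), "linker"),
             group0 = vapply(recs, `[[`, logical(1), "group0"),
             reason = vapply(recs, `[[`, character(1), "reason"),
             row.names = NULL)
}

.asSequenceVector <- function(seqs) {
  if (is(seqs, "AAStringSet") || is(seqs, "XStringSet")) {
    v <- as.character(seqs)
  } else {
    v <- as.character(seqs)
    names(v) <- names(seqs)
  }
  if (is.null(names(v)) && length(v)) names(v) <- paste0("seq", seq_along(v))
  v
}

#' Filter sequences by size
#'
#' Retains sequences shorter than \code{max_len} residues (the census uses
#' this to exclude Rec-GGDEF proteins with additional domains).
#'
#' @param seqs named character vector or AAStringSet.
#' @param max_len exclusive length cutoff; a sequence of exactly
#'   \code{max_len} residues is removed.
#' @return the retained subset (named character vector).
#' @export
sizeFilter <- function(seqs, max_len = 360) {
  v <- .asSequenceVector(seqs)
  keep <- nchar(v) < max_len
  if (any(!keep))
    message(sprintf("sizeFilter: removed %d of %d sequences (>= %d residues)",
                    sum(!keep), length(v), max_len))
  v[keep]
}

# pairwise global identity: matches / alignment columns, columns inside any
# leading or trailing gap run of either sequence excluded
.globalIdentity <- function(a, b) {
  sm <- outer(Biostrings::AA_ALPHABET, Biostrings::AA_ALPHABET, "==") * 1
  dimnames(sm) <- list(Biostrings::AA_ALPHABET, Biostrings::AA_ALPHABET)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = sm,
                                       gapOpening = 10, gapExtension = 0.5)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  start <- max(which(pa != "-")[1], which(pb != "-")[1])
  end <- min(max(which(pa != "-")), max(which(pb != "-")))
  if (end < start) return(0)
  cols <- start:end
  sum(pa[cols] == pb[cols] & pa[cols] != "-") / length(cols)
}

#' Greedy redundancy filter on pairwise identity
#'
#' Iterates the sequences in input order and keeps a sequence only if its
#' global-alignment identity to every previously kept sequence is below
#' \code{identity_threshold}. Deterministic for a fixed input order and
#' idempotent. Identity is matches over alignment columns, terminal gap runs
#' excluded (alignment: match +1, mismatch 0, gap open -10, extend -0.5).
#'
#' @param seqs named character vector or AAStringSet.
#' @param identity_threshold maximum allowed identity in (0, 1].
#' @return the retained subset (named character vector), in input order.
#' @export
redundancyFilter <- function(seqs, identity_threshold = 0.80) {
  v <- .asSequenceVector(seqs)
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  kept <- character(0); kept_names <- character(0)
  for (i in seq_along(v)) {
    ok <- TRUE
    for (k in kept) {
      if (.globalIdentity(v[i], k) >= identity_threshold) { ok <- FALSE; break }
    }
    if (ok) { kept <- c(kept, v[i]); kept_names <- c(kept_names, names(v)[i]) }
  }
  names(kept) <- kept_names
  if (length(kept) < length(v))
    message(sprintf("redundancyFilter: removed %d of %d sequences (identity >= %.0f%%)",
                    length(v) - length(kept), length(v),
                    100 * identity_threshold))
  kept
}

#' Heptad-quantised linker length groups
#'
#' @slot histogram data.frame with columns length, count (raw).
#' @slot peaks integer peak lengths (modes).
#' @slot groups named list (one entry per peak, name = modal length) of
#'   member identifiers.
#' @slot spacing modal difference between adjacent peak positions
#'   (\code{NA} with fewer than 2 peaks).
#' @slot unassigned identifiers not within tolerance of any peak.
#' @export
setClass("LengthGroups",
  representation(histogram = "data.frame", peaks = "integer",
                 groups = "list", spacing = "integer",
                 unassigned = "character"))

setMethod("show", "LengthGroups", function(object) {
  cat(sprintf("LengthGroups: %d peak(s) at %s; modal spacing %s; %d unassigned\n",
              length(object@peaks), paste(object@peaks, collapse = ", "),
              ifelse(is.na(object@spacing), "undefined", object@spacing),
              length(object@unassigned)))
})

#' @rdname LengthGroups-class
#' @param object a LengthGroups.
#' @export
setGeneric("modalSpacing", function(object) standardGeneric("modalSpacing"))
#' @rdname LengthGroups-class
#' @export
setMethod("modalSpacing", "LengthGroups", function(object) object@spacing)

#' @rdname LengthGroups-class
#' @export
setGeneric("lengthPeaks", function(object) standardGeneric("lengthPeaks"))
#' @rdname LengthGroups-class
#' @export
setMethod("lengthPeaks", "LengthGroups", function(object) object@peaks)

#' Cluster linker lengths into discrete groups
#'
#' Builds the linker length histogram, smooths it with a +/-1 triangular
#' kernel (weights 1-2-1), and takes local maxima with raw count at least
#' \code{peak_min_count} as group modes. Records are assigned to the nearest
#' peak within \code{merge_tolerance}; the modal spacing is the most common
#' difference between adjacent peaks.
#'
#' @param records data.frame from \code{\link{extractLinkers}} (columns id,
#'   length; rejected rows are ignored).
#' @param peak_min_count minimum raw count for a peak.
#' @param merge_tolerance maximum |length - mode| for group membership.
#' @return a \linkS4class{LengthGroups}.
#' @export
clusterLengths <- function(records, peak_min_count = 5, merge_tolerance = 1) {
  stopifnot(is.data.frame(records), all(c("id", "length") %in% names(records)))
  rec <- records[!is.na(records$length), , drop = FALSE]
  if (!nrow(rec)) stop("no records with a measured linker length")
  rng <- min(rec$length):max(rec$length)
  count <- as.integer(table(factor(rec$length, levels = rng)))
  pad <- c(0, count, 0)
  smooth <- (pad[seq_along(count)] + 2 * pad[seq_along(count) + 1] +
               pad[seq_along(count) + 2]) / 4
  is_peak <- vapply(seq_along(count), function(i) {
    l <- if (i == 1) 0 else smooth[i - 1]
    r <- if (i == length(count)) 0 else smooth[i + 1]
    smooth[i] > l && smooth[i] >= r && count[i] >= peak_min_count
  }, logical(1))
  peaks <- rng[is_peak]
  if (!length(peaks)) {
    message("clusterLengths: no peak reaches the minimum count")
    return(new("LengthGroups",
               histogram = data.frame(length = rng, count = count),
               peaks = integer(0), groups = list(), spacing = NA_integer_,
               unassigned = as.character(rec$id)))
  }
  nearest <- vapply(rec$length, function(l) {
    d <- abs(peaks - l)
    if (min(d) <= merge_tolerance) peaks[which.min(d)] else NA_integer_
  }, integer(1))
  groups <- lapply(peaks, function(p) as.character(rec$id[!is.na(nearest) & nearest == p]))
  names(groups) <- as.character(peaks)
  spacing <- if (length(peaks) >= 2) {
    ds <- diff(sort(peaks))
    as.integer(names(sort(table(ds), decreasing = TRUE))[1])
  } else NA_integer_
  new("LengthGroups", histogram = data.frame(length = rng, count = count),
      peaks = as.integer(peaks), groups = groups,
      spacing = spacing, unassigned = as.character(rec$id[is.na(nearest)]))
}

#' Mutually aligned position-frequency matrices per length group
#'
#' All groups are anchored at the DxLT motif (the C-terminal end of every
#' linker), so column \code{-j} of any group is the same distance from the
#' anchor; N-terminal starts are offset by the inter-group length differences
#' (multiples of one heptad for canonical groups). Shorter members of a group
#' are left-padded with gaps; gaps are excluded from the frequencies, which
#' sum to 1 in every non-empty column.
#'
#' @param records data.frame from \code{\link{extractLinkers}}.
#' @param groups a \linkS4class{LengthGroups} from
#'   \code{\link{clusterLengths}}.
#' @return named list (by modal length) of frequency matrices; rows are the
#'   20 amino acids plus X, columns are offsets from the DxLT anchor
#'   (\code{"-1"} = the residue immediately before the D).
#' @export
alignedGroupLogos <- function(records, groups) {
  stopifnot(is(groups, "LengthGroups"))
  alpha <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
             "M", "N", "P", "Q", "R", "S", "T", "V", "W", "X", "Y")
  out <- list()
  for (g in names(groups@groups)) {
    ids <- groups@groups[[g]]
    lk <- records$linker[match(ids, records$id)]
    lk <- lk[!is.na(lk)]
    if (!length(lk)) next
    w <- max(nchar(lk))
    padded <- vapply(lk, function(s)
      paste0(strrep("-", w - nchar(s)), s), character(1))
    chars <- do.call(rbind, strsplit(padded, ""))
    pfm <- vapply(seq_len(w), function(j) {
      col <- chars[, j]; col <- col[col != "-"]
      if (!length(col)) return(rep(0, length(alpha)))
      as.numeric(table(factor(col, levels = alpha))) / length(col)
    }, numeric(length(alpha)))
    rownames(pfm) <- alpha
    colnames(pfm) <- as.character(-(w:1))
    out[[g]] <- pfm
  }
  out
}

#' Load the coiled-coil residue propensity table
#'
#' Versioned table of per-residue propensities for heptad positions a, d and
#' e: hydrophobic residues score high at a; small polar residues (Ala, Ser,
#' Asn, Thr) that tolerate coiled-coil packing score moderately at d/e;
#' proline is strongly penalised everywhere.
#'
#' @param version table version string.
#' @return data.frame with columns aa, a, d, e.
#' @export
coilPropensityTable <- function(version = "v1") {
  path <- system.file("extdata",
                      sprintf("coil_propensity_%s.tsv", version),
                      package = "dgcswitch", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Score a linker C-terminal window for a slippery heptad repeat
#'
#' Scores the two alternative registers of the axxdexx repeat over the last
#' two heptads of the window. The phase is anchored so the e position of the
#' last repeat sits at offset -3 from the DxLT motif (the window's last
#' residue is offset -1), which puts a at offsets -14 and -7, d at -11 and
#' -4, and e at -10 and -3. Each register score sums the propensity-table
#' values of its positions (a+d for the native-like register, a+e for the
#' activated-like one). When both registers reach \code{floor}, the repeat is
#' flagged ambiguous ("slippery"): both packings are viable.
#'
#' @param window amino-acid string, length >= 14, ending at offset -1 from
#'   DxLT (i.e. the linker's C-terminal residues).
#' @param floor minimum register score for viability.
#' @param propensity table from \code{\link{coilPropensityTable}}.
#' @return list with \code{score_ad}, \code{score_ae}, \code{ambiguous}, and
#'   \code{positions} (the offsets scored per register).
#' @export
slipperyScore <- function(window, floor = 3,
                          propensity = coilPropensityTable()) {
  stopifnot(is.character(window), length(window) == 1L)
  n <- nchar(window)
  if (n < 14) stop("window must cover at least two heptads (14 residues)")
  res <- strsplit(window, "")[[1]]
  at_offset <- function(off) res[n + off + 1]  # off = -1 is the last residue
  prop <- function(aa, pos) {
    i <- match(aa, propensity$aa)
    if (is.na(i)) 0 else propensity[[pos]][i]
  }
  a_off <- c(-14, -7); d_off <- c(-11, -4); e_off <- c(-10, -3)
  score_ad <- sum(vapply(a_off, function(o) prop(at_offset(o), "a"), 1)) +
    sum(vapply(d_off, function(o) prop(at_offset(o), "d"), 1))
  score_ae <- sum(vapply(a_off, function(o) prop(at_offset(o), "a"), 1)) +
    sum(vapply(e_off, function(o) prop(at_offset(o), "e"), 1))
  list(score_ad = score_ad, score_ae = score_ae,
       ambiguous = score_ad >= floor && score_ae >= floor,
       positions = list(a = a_off, d = d_off, e = e_off))
}

#' Read / write FASTA sequence sets
#'
#' Thin wrappers over \pkg{Biostrings} returning the named character vectors
#' the census functions consume.
#'
#' @param path FASTA file path.
#' @return \code{readFastaSequences}: named character vector.
#' @export
readFastaSequences <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  v <- as.character(x)
  names(v) <- sub("\\s.*$", "", names(x))
  v
}

#' @rdname readFastaSequences
#' @param seqs named character vector.
#' @return \code{writeFastaSequences}: the path, invisibly.
#' @export
writeFastaSequences <- function(seqs, path) {
  v <- .asSequenceVector(seqs)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(v), path)
  invisible(path)
}
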