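# Alignment container and MSA-level statistics.
#
# Sequences are stored as an integer matrix (rows = sequences, columns =
# sites). Codes 1..20 index the amino acids in alphabetical one-letter order
# (ACDEFGHIKLMNPQRSTVWY); 21 is the gap. All downstream statistics
# (frequencies, Potts models) live on the 20 amino-acid states only; the gap
# is a storage/distance state.

AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
GAP_CODE <- 21L
ALPHABET <- c(AA_LETTERS, "-")

#' Encode residue letters as integer codes
#'
#' @param x character vector of single letters, or a character matrix.
#' @return integer codes 1..21 (21 = gap; unknown characters map to gap).
#' @keywords internal
encode_residues <- function(x) {
  m <- match(toupper(x), AA_LETTERS)
  m[is.na(m)] <- GAP_CODE
  if (is.matrix(x)) m <- matrix(m, nrow = nrow(x))
  storage.mode(m) <- "integer"
  m
}

decode_residues <- function(codes) ALPHABET[codes]

new_alignment <- function(seqs, ids, wt, wt_id = NA_character_,
                          weights = NULL, reweighted = FALSE,
                          col_map = seq_len(ncol(seqs))) {
  stopifnot(is.matrix(seqs), is.integer(seqs))
  if (any(seqs < 1L | seqs > GAP_CODE)) abort("residue codes out of range")
  if (length(wt) != ncol(seqs)) abort("wild-type length differs from alignment width")
  if (is.null(weights)) weights <- rep(1, nrow(seqs))
  if (any(weights <= 0 | weights > 1)) abort("weights must lie in (0, 1]")
  structure(
    list(seqs = seqs, ids = ids, wt = as.integer(wt), wt_id = wt_id,
         weights = as.numeric(weights), reweighted = reweighted,
         col_map = as.integer(col_map)),
    class = "msa_alignment"
  )
}

#' @export
print.msa_alignment <- function(x, ...) {
  d <- msa_descriptors(x)
  cat(sprintf(
    "<msa_alignment> %d sequences x %d sites (wt: %s)\n  B = %.2f, D = %.2f sites (%.3f normalized), reweighted = %s\n",
    nrow(x$seqs), ncol(x$seqs),
    if (is.na(x$wt_id)) "unnamed" else x$wt_id,
    d$B, d$D, d$D_norm, x$reweighted))
  invisible(x)
}

#' Number of sequences / sites in an alignment
#' @param aln an `msa_alignment`.
#' @return integer count.
#' @export
n_sequences <- function(aln) nrow(aln$seqs)

#' @rdname n_sequences
#' @export
n_sites <- function(aln) ncol(aln$seqs)

#' Read an aligned FASTA file
#'
#' Reads a gapped, fixed-width FASTA alignment, removes duplicate sequences,
#' drops columns with more than 50% gaps (the same columns are removed from
#' the wild type), upper-cases residues and maps unknown characters to the
#' gap state. The original 1-based column indices of the retained sites are
#' kept so that mutation tables in original coordinates can be remapped (see
#' [read_scan()]).
#'
#' @param path path to an aligned FASTA file.
#' @param wt either the identifier of a record in the file or a wild-type
#'   sequence string of the same width as the alignment.
#' @param max_gap_frac columns with a gap fraction strictly greater than this
#'   are removed (default 0.5).
#' @param reweight if `TRUE` (default) compute similarity-based sequence
#'   weights with [compute_weights()] after reading.
#' @return an `msa_alignment`.
#' @export
read_alignment <- function(path, wt, max_gap_frac = 0.5, reweight = TRUE) {
  aa <- Biostrings::readBStringSet(path)
  if (length(aa) == 0) abort("empty FASTA file", class = "pf_data_error")
  widths <- Biostrings::width(aa)
  if (length(unique(widths)) != 1)
    abort("ragged alignment: sequences have unequal lengths",
          class = "pf_format_error")
  chars <- do.call(rbind, strsplit(toupper(as.character(aa)), ""))
  seqs <- encode_residues(chars)
  ids <- sub("\\s.*$", "", names(aa))

  # resolve wild type before any filtering
  if (length(wt) == 1 && wt %in% ids) {
    wt_codes <- seqs[match(wt, ids), ]
    wt_id <- wt
  } else if (length(wt) == 1 && nchar(wt) == ncol(seqs)) {
    wt_codes <- encode_residues(strsplit(toupper(wt), "")[[1]])
    wt_id <- NA_character_
  } else {
    abort("wild type not found: give a record id or a full-width sequence",
          class = "pf_lookup_error")
  }

  dedup <- function(m, id) {
    key <- apply(m, 1, paste, collapse = ",")
    keep <- !duplicated(key)
    list(seqs = m[keep, , drop = FALSE], ids = id[keep])
  }
  d1 <- dedup(seqs, ids)

  gap_frac <- colMeans(d1$seqs == GAP_CODE)
  keep_cols <- which(gap_frac <= max_gap_frac)
  if (length(keep_cols) == 0)
    abort("no columns left after gap filtering", class = "pf_data_error")
  d2 <- dedup(d1$seqs[, keep_cols, drop = FALSE], d1$ids)
  if (nrow(d2$seqs) == 0)
    abort("empty alignment after filtering", class = "pf_data_error")

  aln <- new_alignment(d2$seqs, d2$ids, wt_codes[keep_cols], wt_id,
                       col_map = keep_cols)
  if (reweight) aln <- compute_weights(aln) else aln$reweighted <- FALSE
  aln
}

#' Write an alignment back to FASTA
#'
#' Inverse of [read_alignment()] on the retained columns: the code matrix
#' round-trips bit-exactly.
#'
#' @param aln an `msa_alignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  lines <- character(2L * nrow(aln$seqs))
  lines[c(TRUE, FALSE)] <- paste0(">", aln$ids)
  lines[c(FALSE, TRUE)] <- apply(aln$seqs, 1, function(r)
    paste(decode_residues(r), collapse = ""))
  writeLines(lines, path)
  invisible(path)
}

#' Hamming distance between two sequences
#'
#' Counts differing positions; gap-vs-residue and gap-vs-gap comparisons are
#' counted literally as differ/match.
#'
#' @param seq1,seq2 integer code vectors (or character strings) of equal length.
#' @param normalized divide by the length?
#' @return a real number.
#' @export
hamming <- function(seq1, seq2, normalized = FALSE) {
  if (is.character(seq1)) seq1 <- encode_residues(strsplit(seq1, "")[[1]])
  if (is.character(seq2)) seq2 <- encode_residues(strsplit(seq2, "")[[1]])
  if (length(seq1) != length(seq2)) abort("sequence length mismatch")
  d <- sum(seq1 != seq2)
  if (normalized) d / length(seq1) else d
}

# Raw Hamming distances of every row to the wild type.
wt_distances <- function(aln) {
  as.integer(hamming_to_ref_cpp(aln$seqs, aln$wt))
}

#' Similarity-based sequence reweighting
#'
#' Each sequence gets weight `z(s) = 1 / #\{s' : d_norm(s, s') < threshold\}`
#' (the sequence itself is always counted, so weights are in (0, 1]). The
#' default 0.2 corresponds to the usual 80% identity threshold.
#'
#' @param aln an `msa_alignment`.
#' @param similarity_threshold strict upper bound on the normalized distance.
#' @return the alignment with updated weights.
#' @export
compute_weights <- function(aln, similarity_threshold = 0.2) {
  if (nrow(aln$seqs) == 0) abort("empty alignment")
  aln$weights <- as.numeric(msa_weights_cpp(aln$seqs, similarity_threshold))
  aln$reweighted <- TRUE
  aln
}

# Subset rows and refresh weights according to the alignment's policy.
msa_subset <- function(aln, idx) {
  out <- aln
  out$seqs <- aln$seqs[idx, , drop = FALSE]
  out$ids <- aln$ids[idx]
  out$weights <- rep(1, length(idx))
  if (aln$reweighted) out <- compute_weights(out)
  out
}

#' Quantity and relevance descriptors of an alignment
#'
#' `B` is the effective number of sequences (sum of weights) and `D` the
#' weighted mean raw Hamming distance to the wild type; `D_norm = D / N`.
#'
#' @param aln an `msa_alignment`.
#' @return a one-row tibble with `n_seq`, `n_site`, `B`, `D`, `D_norm`.
#' @export
msa_descriptors <- function(aln) {
  if (nrow(aln$seqs) == 0) abort("empty alignment")
  z <- aln$weights
  B <- sum(z)
  d <- wt_distances(aln)
  D <- sum(z * d) / B
  tibble(n_seq = nrow(aln$seqs), n_site = ncol(aln$seqs),
         B = B, D = D, D_norm = D / ncol(aln$seqs))
}

#' Weighted amino-acid frequency tables
#'
#' Site marginals over the 20 amino-acid states (gap occurrences are excluded
#' from the counts but their weight stays in the denominator, so rows sum to
#' at most 1), regularized by uniform pseudocount mixing
#' `p~ = (1 - lambda) p + lambda / 20` (and `lambda / 400` for pairs). Pair
#' tables are computed lazily per requested pair via [pair_frequencies()].
#'
#' @param aln an `msa_alignment`.
#' @param lambda pseudocount in `[0, 1)`; the default 0.01 keeps log
#'   frequencies finite for unseen residues.
#' @return a `freq_tables` object.
#' @export
frequencies <- function(aln, lambda = 0.01) {
  if (lambda < 0 || lambda >= 1)
    abort("lambda must lie in [0, 1)", class = "pf_parameter_error")
  Q <- 20L
  N <- ncol(aln$seqs)
  z <- aln$weights
  B <- sum(z)
  p <- matrix(0, N, Q)
  for (a in seq_len(Q)) p[, a] <- colSums(z * (aln$seqs == a)) / B
  structure(
    list(p = (1 - lambda) * p + lambda / Q, p_raw = p, lambda = lambda,
         B = B, Q = Q, N = N, wt = aln$wt,
         seqs = aln$seqs, weights = z,
         pair_cache = new.env(parent = emptyenv())),
    class = "freq_tables"
  )
}

#' @export
print.freq_tables <- function(x, ...) {
  cat(sprintf("<freq_tables> %d sites x %d states, lambda = %g, B = %.2f\n",
              x$N, x$Q, x$lambda, x$B))
  invisible(x)
}

#' Joint frequencies of a site pair
#'
#' @param ft a `freq_tables` object.
#' @param i,j site indices (1-based).
#' @param regularized apply the pseudocount mixing (default `TRUE`)?
#' @return a 20 x 20 matrix.
#' @export
pair_frequencies <- function(ft, i, j, regularized = TRUE) {
  if (i > j) { tmp <- i; i <- j; j <- tmp; transpose <- TRUE } else transpose <- FALSE
  key <- paste0(i, "_", j)
  pij <- ft$pair_cache[[key]]
  if (is.null(pij)) {
    Q <- ft$Q
    si <- ft$seqs[, i]
    sj <- ft$seqs[, j]
    ok <- si <= Q & sj <= Q
    pij <- matrix(0, Q, Q)
    if (any(ok)) {
      tw <- rowsum(ft$weights[ok], group = (si[ok] - 1L) * Q + sj[ok])
      idx <- as.integer(rownames(tw))
      pij[cbind((idx - 1L) %/% Q + 1L, (idx - 1L) %% Q + 1L)] <- tw[, 1]
    }
    pij <- pij / ft$B
    ft$pair_cache[[key]] <- pij
  }
  if (regularized) pij <- (1 - ft$lambda) * pij + ft$lambda / ft$Q^2
  if (transpose) t(pij) else pij
}

#' Read a single-mutant mutational scan
#'
#' Accepts a delimited table (comma/tab/semicolon sniffed) with either a
#' mutation-code column (`mutant` like "G24A", 1-based positions in original
#' alignment coordinates) plus a `score` column, or explicit
#' `pos`, `wt`, `mut`, `score` columns. Positions are remapped to the
#' alignment's retained columns; records at removed columns or whose stated
#' wild-type residue disagrees with the alignment's wild type are dropped
#' with a message.
#'
#' @param path path to the table.
#' @param aln the `msa_alignment` the scan refers to.
#' @return a tibble of class `mutational_scan` with columns
#'   `site` (1-based, filtered coordinates), `wt_aa`, `mut_aa`, `mut_code`,
#'   `score`; attribute `n_rejected` counts dropped records.
#' @export
read_scan <- function(path, aln) {
  header <- readLines(path, n = 1)
  delim <- if (grepl("\t", header)) "\t" else if (grepl(";", header)) ";" else ","
  tb <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          trim_ws = TRUE)
  names(tb) <- tolower(names(tb))
  if (all(c("pos", "wt", "mut", "score") %in% names(tb))) {
    pos <- as.integer(tb$pos); wt_aa <- toupper(tb$wt); mut_aa <- toupper(tb$mut)
    score <- as.numeric(tb$score)
  } else if (all(c("mutant", "score") %in% names(tb))) {
    m <- stringr::str_match(toupper(tb$mutant), "^([A-Z])(\\d+)([A-Z])$")
    if (anyNA(m[, 1]))
      abort(sprintf("unparsable mutation code(s): e.g. '%s'",
                    tb$mutant[which(is.na(m[, 1]))[1]]),
            class = "pf_format_error")
    pos <- as.integer(m[, 3]); wt_aa <- m[, 2]; mut_aa <- m[, 4]
    score <- as.numeric(tb$score)
  } else {
    abort("expected columns 'mutant,score' or 'pos,wt,mut,score'",
          class = "pf_format_error")
  }
  build_scan(pos, wt_aa, mut_aa, score, aln)
}

# Shared scan assembly/validation (positions in original coordinates).
build_scan <- function(pos, wt_aa, mut_aa, score, aln) {
  site <- match(pos, aln$col_map)
  wt_code <- encode_residues(wt_aa)
  mut_code <- encode_residues(mut_aa)
  keep_col <- !is.na(site)
  agree <- keep_col & aln$wt[ifelse(is.na(site), 1L, site)] == wt_code
  n_dropped_col <- sum(!keep_col)
  n_mismatch <- sum(keep_col & !agree)
  if (n_dropped_col > 0)
    inform(sprintf("read_scan: %d record(s) at columns removed by the gap filter",
                   n_dropped_col))
  if (n_mismatch > 0)
    warn(sprintf("read_scan: %d record(s) rejected (stated wt residue disagrees with alignment wt)",
                 n_mismatch))
  keep <- agree & mut_code <= 20L & mut_code != aln$wt[ifelse(is.na(site), 1L, site)]
  if (!any(keep)) abort("all scan records rejected", class = "pf_data_error")
  out <- tibble(site = site[keep], wt_aa = wt_aa[keep], mut_aa = mut_aa[keep],
                mut_code = as.integer(mut_code[keep]), score = score[keep])
  if (anyDuplicated(out[, c("site", "mut_code")]))
    abort("duplicate (site, mutation) records in scan", class = "pf_data_error")
  attr(out, "n_rejected") <- n_dropped_col + n_mismatch
  class(out) <- c("mutational_scan", class(out))
  out
}

#' Write a mutational scan table
#'
#' Emits `mutant,score` rows in original (pre-filter) 1-based coordinates so
#' the file round-trips through [read_scan()].
#'
#' @param scan a `mutational_scan` tibble.
#' @param aln the alignment used to map coordinates.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, aln, path) {
  readr::write_csv(
    tibble(mutant = paste0(scan$wt_aa, aln$col_map[scan$site], scan$mut_aa),
           score = scan$score),
    path)
  invisible(path)
}
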