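# LAST -fTAB ingestion and a slow exact local aligner for test-scale data.
#
# TAB columns: score, ref name/start/alnlen/strand/seqlen,
#              query name/start/alnlen/strand/seqlen, [blocks, ...].
# Coordinates are 0-based starts plus lengths (half-open), preserved
# internally; minus-strand query starts are converted to forward-strand
# coordinates on parse and converted back on write.

ALN_COLS <- c("score", "ref_name", "ref_start", "ref_aln_len", "ref_strand",
              "ref_total_len", "read_name", "read_start", "read_aln_len",
              "read_strand", "read_total_len", "blocks")

#' Parse local alignments in the LAST tabular (-fTAB) dialect
#'
#' Lines beginning with `#` are comments. Each alignment line carries at least
#' 11 whitespace-delimited fields in the LAST TAB column order; a 12th
#' (the gapless block list) is retained verbatim when present. Minus-strand
#' query start coordinates are converted to forward-strand coordinates
#' (`start_fwd = seqlen - start - alnlen`).
#'
#' @param path Path to a TAB file (plain or gzip), or a character vector of
#'   lines via `text`.
#' @param text Optional character vector of lines (overrides `path`).
#' @return A data.frame of class `alignment_tab` with columns
#'   `score, ref_name, ref_start, ref_aln_len, ref_strand, ref_total_len,
#'   read_name, read_start, read_aln_len, read_strand, read_total_len, blocks`.
#' @export
parse_alignment_table <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(empty_alignment_tab())
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  bad <- which(nf < 11L)
  if (length(bad))
    stop("malformed alignment line ", lineno[bad[1]], ": expected >= 11 fields, got ",
         nf[bad[1]])
  m <- t(vapply(fields, function(f) f[1:11], character(11)))
  num_idx <- c(1, 3, 4, 6, 8, 9, 11)
  num <- suppressWarnings(apply(m[, num_idx, drop = FALSE], 2, as.numeric))
  num <- matrix(num, ncol = length(num_idx))
  if (anyNA(num)) {
    bad <- which(apply(num, 1, anyNA))[1]
    stop("malformed alignment line ", lineno[bad],
         ": non-numeric coordinate or score")
  }
  out <- data.frame(
    score = num[, 1], ref_name = m[, 2], ref_start = num[, 2],
    ref_aln_len = num[, 3], ref_strand = m[, 5], ref_total_len = num[, 4],
    read_name = m[, 7], read_start = num[, 5], read_aln_len = num[, 6],
    read_strand = m[, 10], read_total_len = num[, 7],
    blocks = ifelse(nf >= 12L, vapply(fields, function(f)
      if (length(f) >= 12) f[12] else NA_character_, ""), NA_character_),
    stringsAsFactors = FALSE
  )
  if (!all(out$read_strand %in% c("+", "-")))
    stop("malformed alignment line ",
         lineno[which(!out$read_strand %in% c("+", "-"))[1]],
         ": query strand must be '+' or '-'")
  minus <- out$read_strand == "-"
  out$read_start[minus] <-
    out$read_total_len[minus] - out$read_start[minus] - out$read_aln_len[minus]
  validate_alignment_tab(out)
  class(out) <- c("alignment_tab", "data.frame")
  out
}

empty_alignment_tab <- function() {
  out <- data.frame(score = numeric(), ref_name = character(),
                    ref_start = numeric(), ref_aln_len = numeric(),
                    ref_strand = character(), ref_total_len = numeric(),
                    read_name = character(), read_start = numeric(),
                    read_aln_len = numeric(), read_strand = character(),
                    read_total_len = numeric(), blocks = character(),
                    stringsAsFactors = FALSE)
  class(out) <- c("alignment_tab", "data.frame")
  out
}

validate_alignment_tab <- function(x) {
  stopifnot(all(ALN_COLS %in% names(x)))
  if (nrow(x) == 0) return(invisible(x))
  ok <- x$ref_start >= 0 & x$read_start >= 0 &
    x$ref_aln_len > 0 & x$read_aln_len > 0 &
    x$ref_start + x$ref_aln_len <= x$ref_total_len &
    x$read_start + x$read_aln_len <= x$read_total_len
  if (!all(ok))
    stop("invalid alignment record(s) at row(s): ",
         paste(head(which(!ok), 5), collapse = ", "))
  invisible(x)
}

#' Serialize alignments back to the LAST tabular dialect
#'
#' Inverse of [parse_alignment_table()]: minus-strand query starts are
#' converted back to reverse-strand coordinates.
#'
#' @param x An `alignment_tab` data.frame.
#' @param path Output path, or `NULL` to return the lines.
#' @return The lines invisibly (or visibly when `path` is `NULL`).
#' @export
write_alignment_table <- function(x, path = NULL) {
  validate_alignment_tab(x)
  read_start <- x$read_start
  minus <- x$read_strand == "-"
  read_start[minus] <-
    x$read_total_len[minus] - x$read_start[minus] - x$read_aln_len[minus]
  lines <- sprintf("%d\t%s\t%d\t%d\t%s\t%d\t%s\t%d\t%d\t%s\t%d%s",
                   as.integer(x$score), x$ref_name, as.integer(x$ref_start),
                   as.integer(x$ref_aln_len), x$ref_strand,
                   as.integer(x$ref_total_len), x$read_name,
                   as.integer(read_start), as.integer(x$read_aln_len),
                   x$read_strand, as.integer(x$read_total_len),
                   ifelse(is.na(x$blocks), "", paste0("\t", x$blocks)))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

.kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character())
  unique(substring(seq, 1:(n - k + 1), k:n))
}

#' Exact local alignment of one read against a reference database
#'
#' A slow, exact affine-gap local aligner (Smith-Waterman / Gotoh) used as the
#' in-package stand-in for an external aligner on test-scale data. Scoring
#' mirrors a unit-score scheme with gap existence cost 1 and extension cost 1
#' (a length-k gap costs `1 + k`): match +1, mismatch -1, first gap base -2,
#' each further gap base -1. Both query strands are searched; the single best
#' alignment per region and strand is reported when it reaches `min_score`.
#'
#' @param read Read sequence (character scalar).
#' @param db A `reference_db` from [build_reference_db()].
#' @param min_score Minimum reported score (default 50).
#' @param read_name Query name used in the output records.
#' @param match,mismatch,gap_open,gap_ext Scoring parameters; `gap_open` is
#'   the cost of the first base of a gap (existence + extension).
#' @param seed_k If > 0, only align region/strand pairs sharing at least
#'   `seed_min_hits` exact k-mers of this length with the read. Off by
#'   default; the classification pipeline enables it for speed. With errors at
#'   the few-percent level a truly present region shares hundreds of exact
#'   13-mers, so the filter only skips hopeless region/strand pairs.
#' @param seed_min_hits Minimum shared k-mers when `seed_k > 0`.
#' @param max_hits Maximum alignments reported per region and strand: after
#'   each hit the aligned read interval is masked and the search repeats, so
#'   a region occurring several times in one read (the same promoter at two
#'   slots) is reported at each occurrence.
#' @param ref_kmers Precomputed k-mer sets per region ([align_reads()] caches
#'   these across reads); computed on the fly when `NULL`.
#' @return An `alignment_tab` data.frame, sorted by read coordinate.
#' @export
naive_align <- function(read, db, min_score = 50, read_name = "read",
                        match = 1, mismatch = -1, gap_open = 2, gap_ext = 1,
                        seed_k = 0, seed_min_hits = 1, max_hits = 4,
                        ref_kmers = NULL) {
  stopifnot(inherits(db, "reference_db"), nzchar(read))
  read <- toupper(read)
  read_rc <- revcomp(read)
  n <- nchar(read)
  if (seed_k > 0) {
    fwd_kmers <- .kmer_set(read, seed_k)
    rc_kmers <- .kmer_set(read_rc, seed_k)
    if (is.null(ref_kmers))
      ref_kmers <- lapply(db$seq, .kmer_set, k = seed_k)
  }
  recs <- list()
  for (i in seq_along(db$seq)) {
    ref <- db$seq[[i]]
    rname <- names(db$seq)[i]
    for (strand in c("+", "-")) {
      qseq <- if (strand == "+") read else read_rc
      if (seed_k > 0) {
        hits <- sum(ref_kmers[[i]] %in%
                      (if (strand == "+") fwd_kmers else rc_kmers))
        if (hits < seed_min_hits) next
      }
      for (h in seq_len(max_hits)) {
        a <- sw_align_cpp(qseq, ref, as.integer(match), as.integer(mismatch),
                          as.integer(gap_open), as.integer(gap_ext),
                          as.integer(min_score))
        if (a[["score"]] < min_score) break
        qs <- a[["read_start"]]; qe <- a[["read_end"]]
        # mask the hit so a further occurrence of the region can surface
        substr(qseq, qs + 1, qe) <- strrep("#", qe - qs)
        # cheap retry gate: another occurrence needs shared k-mers too
        retry <- seed_k <= 0 ||
          sum(ref_kmers[[i]] %in% .kmer_set(qseq, seed_k)) >= seed_min_hits
        if (strand == "-") {        # back to forward-strand read coordinates
          tmp <- n - qe
          qe <- n - qs
          qs <- tmp
        }
        recs[[length(recs) + 1L]] <- data.frame(
          score = a[["score"]], ref_name = rname, ref_start = a[["ref_start"]],
          ref_aln_len = a[["ref_end"]] - a[["ref_start"]], ref_strand = "+",
          ref_total_len = nchar(ref), read_name = read_name, read_start = qs,
          read_aln_len = qe - qs, read_strand = strand, read_total_len = n,
          blocks = NA_character_, stringsAsFactors = FALSE)
        if (!retry) break
      }
    }
  }
  if (!length(recs)) return(empty_alignment_tab())
  out <- do.call(rbind, recs)
  out <- out[order(out$read_name, out$read_start, -out$score), ]
  rownames(out) <- NULL
  class(out) <- c("alignment_tab", "data.frame")
  out
}

#' Align a set of reads against a reference database
#'
#' Convenience wrapper running [naive_align()] per read (with the k-mer
#' prefilter on by default, which this pipeline path needs for speed) and
#' concatenating the records.
#'
#' @param reads Named character vector of read sequences.
#' @param db A `reference_db`.
#' @param min_score Minimum reported score.
#' @param seed_k,seed_min_hits See [naive_align()].
#' @param ... Further arguments to [naive_align()].
#' @return An `alignment_tab` data.frame.
#' @export
align_reads <- function(reads, db, min_score = 50, seed_k = 13,
                        seed_min_hits = 2, ...) {
  stopifnot(!is.null(names(reads)))
  ref_kmers <- if (seed_k > 0) lapply(db$seq, .kmer_set, k = seed_k)
  tabs <- lapply(names(reads), function(rn)
    naive_align(reads[[rn]], db, min_score = min_score, read_name = rn,
                seed_k = seed_k, seed_min_hits = seed_min_hits,
                ref_kmers = ref_kmers, ...))
  out <- do.call(rbind, tabs)
  if (is.null(out) || !nrow(out)) return(empty_alignment_tab())
  class(out) <- c("alignment_tab", "data.frame")
  rownames(out) <- NULL
  out
}
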