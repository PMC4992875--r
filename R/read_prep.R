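#' Quality-control parameters for read preparation
#'
#' @param three_prime_trim bases dropped from each mate's 3' end before
#'   merging (default 50 for 300-nt reads).
#' @param min_overlap minimum overlap accepted when merging mates.
#' @param max_overlap_mismatch_ratio maximum fraction of mismatching
#'   positions tolerated in the chosen overlap.
#' @param mean_quality_threshold minimum mean Phred quality of a merged
#'   sequence (default 35, inclusive).
#' @return a list of class `qc_params`.
#' @export
qc_params <- function(three_prime_trim = 50L, min_overlap = 10L,
                      max_overlap_mismatch_ratio = 0.25,
                      mean_quality_threshold = 35) {
  if (mean_quality_threshold < 0 || mean_quality_threshold > 41)
    stop("mean_quality_threshold must be in [0, 41]")
  if (min_overlap < 4) stop("min_overlap must be >= 4")
  structure(list(three_prime_trim = as.integer(three_prime_trim),
                 min_overlap = as.integer(min_overlap),
                 max_overlap_mismatch_ratio = max_overlap_mismatch_ratio,
                 mean_quality_threshold = mean_quality_threshold),
            class = "qc_params")
}

#' Trim the 3' end of reads
#'
#' Drops the last `n` bases (and qualities) of every read.  Reads that would
#' fall below 30 remaining bases are dropped entirely rather than truncated
#' into uselessness.
#'
#' @param reads a [read_table()].
#' @param n bases to remove from each 3' end.
#' @return the trimmed read table (possibly with fewer rows).
#' @export
trim_three_prime <- function(reads, n) {
  stopifnot(n >= 0)
  keep <- nchar(reads$bases) - n >= 30L
  reads <- reads[keep, , drop = FALSE]
  if (n > 0 && nrow(reads)) {
    L <- nchar(reads$bases) - n
    reads$bases <- substr(reads$bases, 1L, L)
    reads$quals <- substr(reads$quals, 1L, L)
  }
  reads
}

# merge one mate pair; b/q inputs are integer (utf8) vectors,
# r2 already reverse-complemented.  Returns list(bases, quals) or NULL.
merge_one <- function(b1, q1, b2, q2, min_overlap, max_ratio) {
  n1 <- length(b1); n2 <- length(b2)
  omax <- min(n1, n2)
  if (omax < min_overlap) return(NULL)
  best_o <- NA_integer_; best_ratio <- Inf
  for (o in min_overlap:omax) {
    mism <- sum(b1[(n1 - o + 1L):n1] != b2[1:o])
    ratio <- mism / o
    if (ratio < best_ratio || (ratio == best_ratio && !is.na(best_o) && o > best_o)) {
      best_ratio <- ratio; best_o <- o
    }
  }
  if (best_ratio > max_ratio) return(NULL)
  o <- best_o
  i1 <- (n1 - o + 1L):n1; i2 <- 1:o
  ov_b <- ifelse(q1[i1] >= q2[i2], b1[i1], b2[i2])
  agree <- b1[i1] == b2[i2]
  ov_q <- ifelse(agree, pmax(q1[i1], q2[i2]), abs(q1[i1] - q2[i2]))
  list(bases = c(b1[seq_len(n1 - o)], ov_b, b2[seq_len(n2 - o) + o]),
       quals = c(q1[seq_len(n1 - o)], ov_q, q2[seq_len(n2 - o) + o]))
}

#' Merge forward and reverse mates by overlap
#'
#' Read 2 is reverse-complemented, then every 3'-of-read-1 / 5'-of-read-2
#' overlap of at least `min_overlap` bases is scored; the overlap with the
#' smallest mismatch ratio wins (ties go to the longest overlap).  In the
#' overlap the higher-quality base is taken; the consensus quality is the
#' maximum of the two qualities where the mates agree and their absolute
#' difference where they disagree.  Pairs whose best overlap still exceeds
#' `max_overlap_mismatch_ratio` are rejected.
#'
#' @param r1,r2 row-aligned [read_table()]s of mates.
#' @param params a [qc_params()] object.
#' @return list with `merged` (read table of merged sequences) and
#'   `rejected` (integer row indices of unmergeable pairs).
#' @export
merge_pairs <- function(r1, r2, params = qc_params()) {
  n <- nrow(r1)
  stopifnot(nrow(r2) == n)
  out_b <- character(n); out_q <- character(n); ok <- logical(n)
  for (i in seq_len(n)) {
    b1 <- utf8ToInt(r1$bases[i]); q1 <- utf8ToInt(r1$quals[i]) - 33L
    rc2 <- revcomp(r2$bases[i])
    b2 <- utf8ToInt(rc2); q2 <- rev(utf8ToInt(r2$quals[i]) - 33L)
    m <- merge_one(b1, q1, b2, q2, params$min_overlap,
                   params$max_overlap_mismatch_ratio)
    if (!is.null(m)) {
      ok[i] <- TRUE
      out_b[i] <- intToUtf8(m$bases)
      out_q[i] <- int_to_phred(pmin(m$quals, 41L))
    }
  }
  merged <- read_table(r1$read_id[ok], out_b[ok], out_q[ok], mate = "merged",
                       sample_id = r1$sample_id[ok], run_id = r1$run_id[ok])
  list(merged = merged, rejected = which(!ok))
}

#' Filter merged reads on mean Phred quality
#'
#' @param merged a [read_table()] of merged sequences.
#' @param threshold minimum arithmetic mean Phred value (kept when mean is
#'   greater than or equal to the threshold).
#' @return list with `kept` (read table) and `dropped` (row indices).
#' @export
mean_quality_filter <- function(merged, threshold = 35) {
  mq <- vapply(merged$quals, function(q) mean(phred_to_int(q)), numeric(1),
               USE.NAMES = FALSE)
  keep <- mq >= threshold
  list(kept = merged[keep, , drop = FALSE], dropped = which(!keep))
}

#' Trim primers from merged reads, enforcing global trimming
#'
#' A merged sequence is kept only when the forward primer is present at the
#' 5' end (behind at most `spacer_max` spacer bases) and the reverse
#' complement of the reverse primer at the 3' end (before at most
#' `spacer_max` trailing spacer bases), each within the marker's mismatch
#' tolerance.  Both primer copies and any spacers are removed; sequences
#' whose trimmed core is shorter than the marker's `min_merged_length` are
#' rejected.
#'
#' @param merged a [read_table()] of merged sequences.
#' @param spec the [marker_spec()] of the stream.
#' @return list with `kept` (trimmed read table), `rejected_primer` and
#'   `rejected_length` (row indices).
#' @export
global_primer_trim <- function(merged, spec) {
  n <- nrow(merged)
  f <- match_primer(merged$bases, spec$fwd_primer, spec$spacer_max,
                    spec$max_primer_mismatches)
  r <- match_primer(revcomp(merged$bases), spec$rev_primer, spec$spacer_max,
                    spec$max_primer_mismatches)
  both <- f$matched & r$matched
  from <- f$spacer_len + nchar(spec$fwd_primer) + 1L
  to <- nchar(merged$bases) - r$spacer_len - nchar(spec$rev_primer)
  longenough <- both & !is.na(from) & (to - from + 1L) >= spec$min_merged_length
  kept <- merged[which(longenough), , drop = FALSE]
  idx <- which(longenough)
  kept$bases <- substr(merged$bases[idx], from[idx], to[idx])
  kept$quals <- substr(merged$quals[idx], from[idx], to[idx])
  list(kept = kept,
       rejected_primer = which(!both),
       rejected_length = which(both & !longenough))
}

#' Format a provenance header
#'
#' Renders the identifier `<sample>.<run>_<serial>` used in the per-marker
#' FASTA files; the delimiters `.` and `_` are therefore forbidden in sample
#' and run names.
#'
#' @param sample_id,run_id provenance labels.
#' @param serial 1-based read number within the sample (unique).
#' @return character vector of identifiers.
#' @export
format_header <- function(sample_id, run_id, serial) {
  if (any(grepl("[._]", c(sample_id, run_id))))
    stop("sample and run names must not contain '.' or '_'")
  if (any(serial < 1)) stop("serial must be >= 1")
  if (anyDuplicated(paste(sample_id, serial)))
    stop("duplicate read serials within a sample")
  sprintf("%s.%s_%d", sample_id, run_id, as.integer(serial))
}

#' Run the full read-preparation chain for one marker stream
#'
#' Applies 3' trimming, overlap merging, the mean-quality filter and global
#' primer trimming, then formats provenance headers.  Returns the surviving
#' reads together with a conservation ledger.
#'
#' @param r1,r2 row-aligned mate [read_table()]s of one sample/marker.
#' @param spec the stream's [marker_spec()].
#' @param params a [qc_params()] object.
#' @return list with `reads` (trimmed merged read table, headers formatted)
#'   and `counts` (named vector: input, merged, quality_pass, primer_pass).
#' @export
prep_reads <- function(r1, r2, spec, params = qc_params()) {
  n_in <- nrow(r1)
  r1 <- trim_three_prime(r1, params$three_prime_trim)
  r2 <- trim_three_prime(r2, params$three_prime_trim)
  common <- intersect(r1$read_id, r2$read_id)
  r1 <- r1[match(common, r1$read_id), , drop = FALSE]
  r2 <- r2[match(common, r2$read_id), , drop = FALSE]
  mg <- merge_pairs(r1, r2, params)
  qf <- mean_quality_filter(mg$merged, params$mean_quality_threshold)
  pt <- global_primer_trim(qf$kept, spec)
  reads <- pt$kept
  if (nrow(reads)) {
    reads$read_id <- format_header(reads$sample_id, reads$run_id,
                                   seq_len(nrow(reads)))
  }
  list(reads = reads,
       counts = c(input = n_in, merged = nrow(mg$merged),
                  quality_pass = nrow(qf$kept), primer_pass = nrow(reads)))
}
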