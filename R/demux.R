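#' Construct a table of sequence reads
#'
#' Reads are carried through the pipeline as plain data frames: one row per
#' read, with the quality string kept in Phred+33 encoding exactly as in
#' FASTQ.
#'
#' @param read_id character vector of identifiers (unique within a sample).
#' @param bases nucleotide strings.
#' @param quals Phred+33 quality strings, same lengths as `bases`.
#' @param mate `"forward"` or `"reverse"`.
#' @param sample_id,run_id provenance labels.
#' @return a `data.frame` with class `read_table`.
#' @export
read_table <- function(read_id, bases, quals, mate = "forward",
                       sample_id = NA_character_, run_id = NA_character_) {
  if (any(nchar(bases) != nchar(quals)))
    stop("bases and quals must have identical lengths")
  if (anyDuplicated(read_id)) stop("read_id values must be unique")
  if (length(read_id) == 0) {
    df <- data.frame(read_id = character(0), bases = character(0),
                     quals = character(0), mate = character(0),
                     sample_id = character(0), run_id = character(0),
                     stringsAsFactors = FALSE)
    class(df) <- c("read_table", "data.frame")
    return(df)
  }
  df <- data.frame(read_id = as.character(read_id), bases = toupper(bases),
                   quals = quals, mate = mate,
                   sample_id = sample_id, run_id = run_id,
                   stringsAsFactors = FALSE)
  class(df) <- c("read_table", "data.frame")
  df
}

# IUPAC-aware mismatch counts of equal-length windows against a primer.
# wins entries shorter than the primer yield NA.
iupac_mismatches <- function(wins, primer) {
  L <- nchar(primer)
  pc <- strsplit(primer, "", fixed = TRUE)[[1]]
  n <- length(wins)
  out <- rep(NA_integer_, n)
  full <- !is.na(wins) & nchar(wins) == L
  if (!any(full)) return(out)
  mat <- matrix(unlist(strsplit(wins[full], "", fixed = TRUE)), nrow = L)
  mism <- integer(sum(full))
  for (p in seq_len(L))
    mism <- mism + !(mat[p, ] %in% IUPAC[[pc[p]]])
  out[full] <- mism
  out
}

#' Locate a primer behind a heterogeneity spacer
#'
#' Scans offsets 0..`spacer_max` from the 5' end and reports, per read, the
#' best primer placement: fewest IUPAC-aware mismatches, ties broken by the
#' smallest offset.  A read matches when its best placement has at most
#' `max_mismatches` mismatches.
#'
#' @param bases character vector of read sequences.
#' @param primer primer string (IUPAC codes allowed).
#' @param spacer_max maximum spacer length to scan.
#' @param max_mismatches mismatch tolerance.
#' @return data.frame with columns `matched`, `spacer_len`, `mismatches`
#'   (`spacer_len`/`mismatches` are `NA` where unmatched).
#' @export
match_primer <- function(bases, primer, spacer_max = 3L, max_mismatches = 2L) {
  offs <- 0:spacer_max
  L <- nchar(primer)
  mm <- sapply(offs, function(s) {
    wins <- substr(bases, s + 1L, s + L)
    wins[nchar(bases) < s + L] <- NA
    iupac_mismatches(wins, primer)
  })
  mm <- matrix(mm, ncol = length(offs))
  best <- apply(mm, 1, function(v) {
    if (all(is.na(v))) return(c(NA_integer_, NA_integer_))
    i <- which.min(v)                       # earliest offset wins ties
    c(offs[i], v[i])
  })
  spacer <- best[1, ]; mism <- best[2, ]
  matched <- !is.na(mism) & mism <= max_mismatches
  spacer[!matched] <- NA_integer_; mism[!matched] <- NA_integer_
  data.frame(matched = matched, spacer_len = spacer, mismatches = mism)
}

#' Strip read-through adapter tails from short amplicons
#'
#' When the sequenced fragment is shorter than the read, the read runs past
#' the amplicon into the reverse complement of the opposite-mate primer and
#' its overhang tail.  This step finds the reverse complement of
#' (tail + opposite primer) -- possibly truncated at the 3' read end -- at or
#' after position 30 and cuts the read there.  Reads without a tail signal
#' are returned unchanged.
#'
#' @param reads a [read_table()].
#' @param specs list of [marker_spec()] objects (all markers are tried; the
#'   marker is unknown at this stage).
#' @param min_overlap minimum number of read bases a truncated tail match
#'   must cover (default 12).
#' @return the read table with matched reads truncated.
#' @export
strip_readthrough <- function(reads, specs, min_overlap = 12L) {
  guard <- 30L   # 0-based guard: spacer(<=3) + primer(>=15) can't end earlier
  subj <- Biostrings::DNAStringSet(paste0(reads$bases,
                                          strrep("N", 60L)))
  lens <- nchar(reads$bases)
  cut <- rep(NA_integer_, nrow(reads))
  for (spec in specs) {
    pats <- unique(vapply(c("forward", "reverse"), function(m) {
      p <- if (m == "forward") spec$rev_primer else spec$fwd_primer
      revcomp(paste0(spec$tail, p))
    }, character(1)))
    for (pat in pats) {
      hits <- Biostrings::vmatchPattern(
        pat, subj, max.mismatch = spec$max_primer_mismatches, fixed = FALSE)
      st <- Biostrings::startIndex(hits)
      for (i in seq_along(st)) {
        s <- st[[i]]
        if (is.null(s)) next
        s <- s[s >= guard + 1L & s <= lens[i] - min_overlap + 1L]
        if (length(s) == 0) next
        s0 <- min(s)
        if (is.na(cut[i]) || s0 < cut[i]) cut[i] <- s0
      }
    }
  }
  hit <- !is.na(cut)
  if (any(hit)) {
    reads$bases[hit] <- substr(reads$bases[hit], 1L, cut[hit] - 1L)
    reads$quals[hit] <- substr(reads$quals[hit], 1L, cut[hit] - 1L)
  }
  reads
}

#' Split a sample's mixed reads into per-marker streams
#'
#' A read pair is assigned to a marker when the marker's forward primer is
#' found at the 5' end of read 1 and its reverse primer at the 5' end of
#' read 2 (both behind at most `spacer_max` spacer bases, within the
#' per-marker mismatch tolerance).  Pairs matching no marker, or more than
#' one, are left unassigned.
#'
#' @param r1,r2 [read_table()]s of forward and reverse mates, row-aligned.
#' @param specs list of [marker_spec()]s; primer pairs must be mutually
#'   distinguishable (validated).
#' @return a `demux_result` list: `assigned` (marker -> list(r1, r2)),
#'   `unassigned` (list(r1, r2)), and a `counts` table.
#' @export
demultiplex_sample <- function(r1, r2, specs) {
  specs <- validate_specs(specs)
  if (nrow(r1) != nrow(r2)) stop("r1 and r2 must be row-aligned")
  nmk <- names(specs)
  hit <- sapply(specs, function(sp) {
    f <- match_primer(r1$bases, sp$fwd_primer, sp$spacer_max,
                      sp$max_primer_mismatches)$matched
    r <- match_primer(r2$bases, sp$rev_primer, sp$spacer_max,
                      sp$max_primer_mismatches)$matched
    f & r
  })
  hit <- matrix(hit, ncol = length(specs), dimnames = list(NULL, nmk))
  nhits <- rowSums(hit)
  assigned <- lapply(nmk, function(m) {
    idx <- which(hit[, m] & nhits == 1L)
    list(r1 = r1[idx, , drop = FALSE], r2 = r2[idx, , drop = FALSE])
  })
  names(assigned) <- nmk
  uidx <- which(nhits != 1L)
  counts <- c(vapply(assigned, function(x) nrow(x$r1), integer(1)),
              unassigned = length(uidx))
  structure(list(assigned = assigned,
                 unassigned = list(r1 = r1[uidx, , drop = FALSE],
                                   r2 = r2[uidx, , drop = FALSE]),
                 counts = counts, n_input = nrow(r1)),
            class = "demux_result")
}

#' @export
print.demux_result <- function(x, ...) {
  cat("<demux result>", x$n_input, "pairs\n")
  print(x$counts)
  invisible(x)
}
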