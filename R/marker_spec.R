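#' Define an amplicon marker
#'
#' A marker specification carries everything the pipeline needs to recognise
#' and process one amplicon: the primer pair used in the first PCR, the 33-nt
#' overhang tail that shows up by read-through on short amplicons, the
#' heterogeneity-spacer range (0-3 random 5' bases), the primer-mismatch
#' tolerance, the clustering identity threshold, and the minimum merged
#' length.
#'
#' @param name marker name, e.g. `"16S"`, `"18S"`, `"23S"`, `"tufA"`.
#' @param fwd_primer,rev_primer primer sequences, 5'->3', IUPAC codes allowed;
#'   must be at least 15 nt.
#' @param tail overhang tail sequence ligated 5' of each primer during library
#'   preparation (33 nt in the reference design).
#' @param spacer_max maximum heterogeneity-spacer length (default 3).
#' @param max_primer_mismatches mismatches tolerated when recognising a primer
#'   (default 2).
#' @param identity_threshold OTU clustering / read-mapping identity threshold;
#'   0.98 is conservative species level for tufA, 0.97 the default elsewhere.
#' @param min_merged_length minimum length of a merged, primer-trimmed
#'   sequence.
#' @return an object of class `marker_spec`.
#' @export
marker_spec <- function(name, fwd_primer, rev_primer,
                        tail = "ACACTCTTTCCCTACACGACGCTCTTCCGATCT",
                        spacer_max = 3L, max_primer_mismatches = 2L,
                        identity_threshold = if (identical(name, "tufA")) 0.98 else 0.97,
                        min_merged_length = 100L) {
  fwd_primer <- toupper(fwd_primer); rev_primer <- toupper(rev_primer)
  ok <- function(p) nchar(p) >= 15 &&
    all(strsplit(p, "", fixed = TRUE)[[1]] %in% names(IUPAC))
  if (!ok(fwd_primer) || !ok(rev_primer))
    stop("primers must be IUPAC nucleotide strings of length >= 15")
  if (identity_threshold <= 0.5 || identity_threshold > 1)
    stop("identity_threshold must be in (0.5, 1]")
  if (spacer_max < 0) stop("spacer_max must be >= 0")
  structure(list(
    name = name, fwd_primer = fwd_primer, rev_primer = rev_primer,
    tail = toupper(tail), spacer_max = as.integer(spacer_max),
    max_primer_mismatches = as.integer(max_primer_mismatches),
    identity_threshold = identity_threshold,
    min_merged_length = as.integer(min_merged_length)
  ), class = "marker_spec")
}

#' @export
print.marker_spec <- function(x, ...) {
  cat(sprintf("<marker %s>  fwd %s  rev %s  id>=%.2f  minlen %d\n",
              x$name, x$fwd_primer, x$rev_primer, x$identity_threshold,
              x$min_merged_length))
  invisible(x)
}

#' Default four-marker specification set
#'
#' The pooled-library design of the pipeline: 16S rDNA (prokaryotes and
#' plastids), 18S rDNA (eukaryotes), an algal-plastid 23S rDNA fragment, and
#' the green-algal barcode tufA.  Amplicon core lengths differ between
#' markers; the 16S fragment used here is short enough that 300-nt reads run
#' through into the opposite adapter tail.
#'
#' @param core_length named integer vector giving, per marker, the length of
#'   the inter-primer region the synthetic generator simulates.
#' @return named list of [marker_spec()] objects.
#' @export
default_marker_specs <- function(core_length = c(`16S` = 180L, `18S` = 340L,
                                                 `23S` = 330L, tufA = 350L)) {
  specs <- list(
    `16S` = marker_spec("16S", "GTGYCAGCMGCCGCGGTAA", "GGACTACNVGGGTWTCTAAT"),
    `18S` = marker_spec("18S", "GTACACACCGCCCGTCGC", "TGATCCTTCTGCAGGTTCACCTAC"),
    `23S` = marker_spec("23S", "ACAGWAAGACCCTATGAAGCTT", "CCTGTTATCCCTAGAGTAACTT"),
    tufA  = marker_spec("tufA", "TGAAACAGAAMAWCGTCATTATGC", "CCTTCNCGAATMGCRAAWCGC")
  )
  for (m in names(specs)) {
    if (m %in% names(core_length))
      attr(specs[[m]], "core_length") <- as.integer(core_length[[m]])
  }
  specs
}

# validate that a list of specs has mutually distinguishable primers:
# pairwise Hamming distance over the common prefix must exceed
# 2 * max_primer_mismatches for both fwd and rev primers.
validate_specs <- function(specs) {
  if (is.null(names(specs)) || any(names(specs) == ""))
    names(specs) <- vapply(specs, `[[`, character(1), "name")
  nm <- names(specs)
  prim_dist <- function(p, q) {
    L <- min(nchar(p), nchar(q))
    a <- strsplit(substr(p, 1, L), "", fixed = TRUE)[[1]]
    b <- strsplit(substr(q, 1, L), "", fixed = TRUE)[[1]]
    sum(vapply(seq_len(L), function(i)
      length(intersect(IUPAC[[a[i]]], IUPAC[[b[i]]])) == 0, logical(1)))
  }
  for (i in seq_along(specs)) for (j in seq_along(specs)) {
    if (i >= j) next
    lim <- 2 * max(specs[[i]]$max_primer_mismatches,
                   specs[[j]]$max_primer_mismatches)
    if (prim_dist(specs[[i]]$fwd_primer, specs[[j]]$fwd_primer) <= lim &&
        prim_dist(specs[[i]]$rev_primer, specs[[j]]$rev_primer) <= lim)
      stop(sprintf("markers %s and %s have indistinguishable primers", nm[i], nm[j]))
  }
  specs
}
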