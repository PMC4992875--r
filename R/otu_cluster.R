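#' Collapse identical sequences into unique records
#'
#' @param bases character vector of uppercase, ungapped sequences.
#' @param labels optional read labels carried along as members.
#' @return data.frame of class `unique_seqs` with columns `bases`,
#'   `abundance` and list-column `members`, sorted by decreasing abundance
#'   (ties by lexicographic sequence).
#' @export
dereplicate <- function(bases, labels = NULL) {
  if (is.null(labels)) labels <- as.character(seq_along(bases))
  grp <- split(labels, bases)
  df <- data.frame(bases = names(grp),
                   abundance = lengths(grp), stringsAsFactors = FALSE)
  df$members <- unname(grp)
  o <- order(-df$abundance, df$bases, method = "radix")
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("unique_seqs", "data.frame")
  df
}

#' Global-alignment identity of two sequences
#'
#' Needleman-Wunsch/Gotoh global alignment with match +1, mismatch -1, gap
#' open -2, gap extension -1.  Identity is the fraction of matched columns
#' among alignment columns, excluding terminal-gap columns; internal gap
#' columns count against identity.  Alignment ties are resolved
#' deterministically (substitution preferred over a gap in the second
#' sequence, preferred over a gap in the first).
#'
#' @param a,b nucleotide strings.
#' @return identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  if (nchar(a) == 0 || nchar(b) == 0) stop("sequences must be non-empty")
  .align_pair(a, b)$identity
}

# per-query-position match profile (1 = aligned to an identical base)
alignment_profile <- function(query, ref) {
  .align_pair(query, ref, profile = TRUE)$profile
}

#' De novo two-parent chimera screen
#'
#' A query is called chimeric when some breakpoint splits it into a left
#' segment nearly identical (>= `seg_identity`) to one sufficiently more
#' abundant centroid and a right segment nearly identical to a different
#' one, while no single centroid explains the whole query (best whole-query
#' identity <= `max_parent_identity`).  Only centroids with at least
#' `skew` times the query's abundance are considered possible parents;
#' breakpoints are scanned at least `margin` bases from either end.
#'
#' @param query_bases,query_abundance the candidate sequence and its read
#'   count.
#' @param centroids data.frame with columns `otu_id`, `bases`, `size`.
#' @param seg_identity per-segment identity needed to call a parent.
#' @param max_parent_identity whole-query identity above which the query is
#'   considered a genuine variant of one centroid.
#' @param skew abundance ratio a parent must have over the query.
#' @param margin minimum distance of the breakpoint from the query ends.
#' @return list: `chimeric` (logical) and, when chimeric, `parent_a`,
#'   `parent_b`, `breakpoint` (0-based query coordinate of the junction).
#' @export
chimera_check <- function(query_bases, query_abundance, centroids,
                          seg_identity = 0.99, max_parent_identity = 0.97,
                          skew = 2, margin = 50L) {
  clean <- list(chimeric = FALSE)
  if (is.null(centroids) || nrow(centroids) == 0) return(clean)
  cand <- centroids[centroids$size >= skew * query_abundance, , drop = FALSE]
  if (nrow(cand) < 2) return(clean)
  ids <- .identity_many(query_bases, cand$bases)
  if (max(ids) > max_parent_identity) return(clean)
  L <- nchar(query_bases)
  if (L < 2L * margin + 2L) return(clean)
  # keep the most promising parents to bound the pair scan
  keep <- head(order(-ids), 6L)
  cand <- cand[keep, , drop = FALSE]
  profs <- lapply(cand$bases, function(cb) alignment_profile(query_bases, cb))
  cums <- lapply(profs, cumsum)
  bps <- margin:(L - margin)  # breakpoint b: left = 1..b, right = b+1..L
  best <- NULL
  for (i in seq_len(nrow(cand))) for (j in seq_len(nrow(cand))) {
    if (i == j) next
    left_id <- cums[[i]][bps] / bps
    right_id <- (cums[[j]][L] - cums[[j]][bps]) / (L - bps)
    sc <- pmin(left_id, right_id)
    # the breakpoint is ambiguous where the parents agree; report the
    # midpoint of the plateau of maximal score
    plateau <- which(sc == max(sc))
    k <- plateau[ceiling(length(plateau) / 2)]
    if (left_id[k] >= seg_identity && right_id[k] >= seg_identity &&
        (is.null(best) || sc[k] > best$score)) {
      best <- list(score = sc[k], parent_a = cand$otu_id[i],
                   parent_b = cand$otu_id[j], breakpoint = bps[k])
    }
  }
  if (is.null(best)) return(clean)
  list(chimeric = TRUE, parent_a = best$parent_a, parent_b = best$parent_b,
       breakpoint = best$breakpoint)
}

#' Abundance-ordered greedy centroid clustering
#'
#' Unique sequences are scanned in dereplication order (abundance
#' descending).  Each is assigned to the existing centroid of maximal
#' identity when that identity reaches the marker threshold (ties prefer the
#' larger centroid, then the earlier one); otherwise it is screened for
#' chimeras against the current centroids, and discarded if chimeric or
#' promoted to a new centroid if clean.  Centroid sequences are never
#' updated after promotion.
#'
#' @param uniques a [dereplicate()] result.
#' @param threshold clustering identity threshold in (0.5, 1].
#' @param chimera_args list of overrides passed to [chimera_check()].
#' @return list: `centroids` (data.frame `otu_id`, `bases`, `size`),
#'   `assignment` (per-unique otu_id, `NA` for discarded chimeras), and
#'   `chimeras` (data.frame of discarded records).
#' @export
greedy_cluster <- function(uniques, threshold, chimera_args = list()) {
  if (threshold <= 0.5 || threshold > 1)
    stop("threshold must be in (0.5, 1]")
  n <- nrow(uniques)
  cent_bases <- character(0); cent_size <- numeric(0); cent_id <- character(0)
  assignment <- rep(NA_character_, n)
  chim <- list()
  for (i in seq_len(n)) {
    b <- uniques$bases[i]; ab <- uniques$abundance[i]
    if (length(cent_bases)) {
      ids <- .identity_many(b, cent_bases)
      o <- order(-ids, -cent_size, seq_along(ids))[1]
      if (ids[o] >= threshold) {
        assignment[i] <- cent_id[o]
        cent_size[o] <- cent_size[o] + ab
        next
      }
      cc <- do.call(chimera_check, c(
        list(query_bases = b, query_abundance = ab,
             centroids = data.frame(otu_id = cent_id, bases = cent_bases,
                                    size = cent_size,
                                    stringsAsFactors = FALSE)),
        chimera_args))
      if (cc$chimeric) {
        chim[[length(chim) + 1L]] <- data.frame(
          bases = b, abundance = ab, parent_a = cc$parent_a,
          parent_b = cc$parent_b, breakpoint = cc$breakpoint,
          stringsAsFactors = FALSE)
        next
      }
    }
    id <- sprintf("OTU_%04d", length(cent_id) + 1L)
    cent_id <- c(cent_id, id)
    cent_bases <- c(cent_bases, b)
    cent_size <- c(cent_size, ab)
    assignment[i] <- id
  }
  list(centroids = data.frame(otu_id = cent_id, bases = cent_bases,
                              size = cent_size, stringsAsFactors = FALSE),
       assignment = assignment,
       chimeras = if (length(chim)) do.call(rbind, chim) else
         data.frame(bases = character(0), abundance = numeric(0),
                    parent_a = character(0), parent_b = character(0),
                    breakpoint = integer(0)))
}

#' Build an OTU x sample count table by mapping reads to centroids
#'
#' Each read is mapped to the centroid of maximal identity when that
#' identity reaches the mapping threshold (same tie rules as clustering);
#' reads below the threshold are counted as unmapped.
#'
#' @param reads a [read_table()] of prepared reads with `sample_id` set.
#' @param centroids centroid data.frame from [greedy_cluster()].
#' @param threshold mapping identity threshold (the marker's clustering
#'   threshold by default in the pipeline).
#' @param marker marker name recorded on the table.
#' @param samples optional character vector fixing the column order (and
#'   including samples with zero mapped reads).
#' @return an object of class `marker_otu_table`: list with integer `counts`
#'   (OTU x sample), `marker`, `unmapped` count and `filter_log`.
#' @export
build_otu_table <- function(reads, centroids, threshold, marker = "marker",
                            samples = NULL) {
  if (is.null(centroids) || nrow(centroids) == 0)
    stop("empty centroid list")
  if (is.null(samples)) samples <- sort(unique(reads$sample_id))
  if (!all(reads$sample_id %in% samples)) stop("unknown sample label")
  uq <- dereplicate(reads$bases, labels = seq_len(nrow(reads)))
  counts <- matrix(0L, nrow(centroids), length(samples),
                   dimnames = list(centroids$otu_id, samples))
  unmapped <- 0L
  for (i in seq_len(nrow(uq))) {
    ids <- .identity_many(uq$bases[i], centroids$bases)
    o <- order(-ids, -centroids$size, seq_along(ids))[1]
    ridx <- as.integer(uq$members[[i]])
    if (ids[o] >= threshold) {
      tab <- table(reads$sample_id[ridx])
      counts[o, names(tab)] <- counts[o, names(tab)] + as.integer(tab)
    } else {
      unmapped <- unmapped + length(ridx)
    }
  }
  structure(list(counts = counts, marker = marker, unmapped = unmapped,
                 filter_log = list()),
            class = "marker_otu_table")
}

#' @export
print.marker_otu_table <- function(x, ...) {
  cat(sprintf("<OTU table> marker %s: %d OTUs x %d samples, %d reads (%d unmapped)\n",
              x$marker, nrow(x$counts), ncol(x$counts), sum(x$counts),
              x$unmapped))
  if (length(x$filter_log))
    cat("filters applied:", paste(vapply(x$filter_log, `[[`, character(1),
                                         "step"), collapse = " -> "), "\n")
  invisible(x)
}
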