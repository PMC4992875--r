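#' Parameters of the three-tier OTU filter
#'
#' @param per_sample_min reads an OTU must exceed in a sample to be kept in
#'   that sample (default 2; with `strict = TRUE` a count of exactly 2 is
#'   zeroed).
#' @param dataset_min reads an OTU must exceed across the whole dataset
#'   (default 5).
#' @param strict interpret both minima as strict "exceed" (`> n`, the
#'   default); `FALSE` switches to inclusive `>= n` semantics.
#' @return a `filter_params` list.
#' @export
filter_params <- function(per_sample_min = 2L, dataset_min = 5L,
                          strict = TRUE) {
  if (per_sample_min < 0 || dataset_min < 0) stop("minima must be >= 0")
  structure(list(per_sample_min = as.integer(per_sample_min),
                 dataset_min = as.integer(dataset_min), strict = strict),
            class = "filter_params")
}

log_filter <- function(tab, step, removed_otus) {
  tab$filter_log <- c(tab$filter_log,
                      list(list(step = step, removed = removed_otus,
                                otus = nrow(tab$counts),
                                reads = sum(tab$counts))))
  tab
}

#' Remove OTUs detected in negative controls
#'
#' Any OTU with at least one read in any negative-control sample is removed
#' from the whole table (global exclusion, not count subtraction); the
#' control columns themselves are then dropped.
#'
#' @param tab a `marker_otu_table`.
#' @param controls character vector of control sample ids (must be columns
#'   of the table).  An empty set is a logged no-op.
#' @return the filtered table.
#' @export
drop_negative_control_otus <- function(tab, controls) {
  if (length(controls) == 0) {
    warning("no negative controls supplied; table unchanged")
    return(log_filter(tab, "negative_controls", character(0)))
  }
  if (!all(controls %in% colnames(tab$counts)))
    stop("unknown control label: ",
         paste(setdiff(controls, colnames(tab$counts)), collapse = ", "))
  inctrl <- rowSums(tab$counts[, controls, drop = FALSE] >= 1L) > 0
  removed <- rownames(tab$counts)[inctrl]
  keepcols <- setdiff(colnames(tab$counts), controls)
  tab$counts <- tab$counts[!inctrl, keepcols, drop = FALSE]
  log_filter(tab, "negative_controls", removed)
}

#' Per-sample minimum count filter
#'
#' Cells at or below the minimum (strict semantics) are zeroed; OTU rows
#' that become all-zero are removed.
#'
#' @param tab a `marker_otu_table`.
#' @param per_sample_min threshold (default 2).
#' @param strict `TRUE`: zero cells with `count <= min`; `FALSE`: zero cells
#'   with `count < min`.
#' @return the filtered table.
#' @export
per_sample_min_filter <- function(tab, per_sample_min = 2L, strict = TRUE) {
  zero <- if (strict) tab$counts <= per_sample_min else
    tab$counts < per_sample_min
  tab$counts[zero] <- 0L
  gone <- rowSums(tab$counts) == 0
  removed <- rownames(tab$counts)[gone]
  tab$counts <- tab$counts[!gone, , drop = FALSE]
  log_filter(tab, "per_sample_min", removed)
}

#' Dataset-wide rare-OTU filter
#'
#' OTUs whose total count across all samples does not exceed the minimum are
#' removed.
#'
#' @param tab a `marker_otu_table`.
#' @param dataset_min threshold (default 5).
#' @param strict `TRUE`: remove rows with `sum <= min`; `FALSE`: `sum < min`.
#' @return the filtered table.
#' @export
dataset_min_filter <- function(tab, dataset_min = 5L, strict = TRUE) {
  s <- rowSums(tab$counts)
  gone <- if (strict) s <= dataset_min else s < dataset_min
  removed <- rownames(tab$counts)[gone]
  tab$counts <- tab$counts[!gone, , drop = FALSE]
  log_filter(tab, "dataset_min", removed)
}

#' Apply the full filter chain in pipeline order
#'
#' Order is fixed: negative-control exclusion, then the per-sample minimum,
#' then the dataset-wide minimum.  Swapping the last two steps can change
#' the result, so the order is part of the contract.
#'
#' @param tab a `marker_otu_table`.
#' @param controls negative-control sample ids.
#' @param params a [filter_params()] object.
#' @return the filtered table with a populated filter log.
#' @export
filter_otu_table <- function(tab, controls, params = filter_params()) {
  tab <- drop_negative_control_otus(tab, controls)
  tab <- per_sample_min_filter(tab, params$per_sample_min, params$strict)
  dataset_min_filter(tab, params$dataset_min, params$strict)
}

#' Summarise a filter chain into a report
#'
#' @param initial the table before filtering.
#' @param final the table after filtering (same marker; carries the filter
#'   log).
#' @return a `filter_report` list: per-step OTU/read counts and removed OTU
#'   ids, per-sample retained depth, and totals.
#' @export
summarize_filters <- function(initial, final) {
  if (!identical(initial$marker, final$marker))
    stop("tables come from different markers")
  steps <- lapply(final$filter_log, function(st)
    data.frame(step = st$step, otus = st$otus, reads = st$reads,
               n_removed = length(st$removed), stringsAsFactors = FALSE))
  structure(list(
    marker = initial$marker,
    initial = c(otus = nrow(initial$counts), reads = sum(initial$counts)),
    steps = do.call(rbind, steps),
    removed = lapply(final$filter_log, `[[`, "removed"),
    sample_depth = colSums(final$counts)
  ), class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter report> marker %s: %d OTUs / %d reads in\n",
              x$marker, x$initial["otus"], x$initial["reads"]))
  print(x$steps)
  invisible(x)
}
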