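RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

# integer codes (1-based, in 1..4^k) of the distinct k-words of a sequence;
# windows containing non-ACGT characters are skipped.
kmer_words <- function(seq, k) {
  lut <- rep(NA_integer_, 128)
  lut[utf8ToInt("A")] <- 0L; lut[utf8ToInt("C")] <- 1L
  lut[utf8ToInt("G")] <- 2L; lut[utf8ToInt("T")] <- 3L
  v <- lut[utf8ToInt(seq)]
  n <- length(v)
  if (n < k) return(integer(0))
  acc <- numeric(n - k + 1)
  bad <- logical(n - k + 1)
  for (j in 0:(k - 1)) {
    vj <- v[(1 + j):(n - k + 1 + j)]
    bad <- bad | is.na(vj)
    acc <- acc * 4 + ifelse(is.na(vj), 0, vj)
  }
  unique(as.integer(acc[!bad]) + 1L)
}

#' Train the naive Bayes k-mer taxonomic classifier
#'
#' Words (k-mers) are counted presence/absence per training sequence.  With
#' `n(w)` the number of corpus sequences containing word `w` out of `N`, the
#' corpus prior is `Pr(w) = (n(w) + 0.5) / (N + 1)`; with `m(w)` the number
#' of sequences of a genus containing `w` out of that genus' `M` sequences,
#' the genus-conditional word probability is `(m(w) + Pr(w)) / (M + 1)`.
#'
#' @param refs list of reference taxa as produced by
#'   [build_reference_set()]: each has `taxon_id`, a 6-rank `lineage`
#'   (domain..genus) and named `marker_seqs`.
#' @param marker which marker sequence to train on.
#' @param k word size (default 8).
#' @return an object of class `nb_classifier`.
#' @export
train_classifier <- function(refs, marker, k = 8L) {
  seqs <- lapply(refs, function(r) r$marker_seqs[[marker]])
  if (any(vapply(seqs, is.null, logical(1))))
    stop("some reference taxa lack sequences for marker ", marker)
  short <- vapply(seqs, nchar, integer(1)) < k
  if (any(short))
    stop("training sequence shorter than k: ",
         refs[[which(short)[1]]]$taxon_id)
  genera <- vapply(refs, function(r) r$lineage[[6]], character(1))
  lineages <- lapply(refs, `[[`, "lineage")
  gset <- sort(unique(genera))
  # order-invariant: genera sorted, word sets independent of input order
  words <- lapply(seqs, kmer_words, k = k)
  W <- 4L^k
  nw <- tabulate(unlist(words), nbins = W)           # corpus n(w)
  N <- length(seqs)
  prior <- (nw + 0.5) / (N + 1)
  logp <- matrix(NA_real_, W, length(gset), dimnames = list(NULL, gset))
  glin <- list()
  for (g in gset) {
    idx <- which(genera == g)
    mw <- tabulate(unlist(words[idx]), nbins = W)
    logp[, g] <- log((mw + prior) / (length(idx) + 1))
    glin[[g]] <- lineages[[idx[1]]]
  }
  structure(list(k = as.integer(k), marker = marker, log_prob = logp,
                 genera = gset, lineages = glin, n_train = N),
            class = "nb_classifier")
}

#' @export
print.nb_classifier <- function(x, ...) {
  cat(sprintf("<naive Bayes classifier> marker %s, k=%d, %d genera, %d sequences\n",
              x$marker, x$k, length(x$genera), x$n_train))
  invisible(x)
}

#' Classify a sequence with bootstrap confidence
#'
#' The full word set of the query scores each genus by the sum of log
#' word-in-genus probabilities; the winning genus supplies the reported
#' lineage.  Each of `n_bootstrap` trials rescores a random subsample of
#' one-eighth of the query's words and votes for its top genus; the
#' confidence of a rank label is the fraction of trials whose voted genus
#' carries that label.  Ranks whose confidence falls below `threshold` are
#' reported as `unclassified_<deepest confident label>`.
#'
#' @param query nucleotide string (length >= k).
#' @param clf a trained [train_classifier()] model.
#' @param n_bootstrap bootstrap trials (default 100).
#' @param threshold reporting threshold on confidence (default 0.7).
#' @param seed integer seed for the bootstrap subsampling.
#' @return a `taxonomic_assignment`: data.frame with columns `rank`,
#'   `label`, `confidence`, `reported`.
#' @export
classify_sequence <- function(query, clf, n_bootstrap = 100L,
                              threshold = 0.7, seed = 1L) {
  if (!inherits(clf, "nb_classifier")) stop("untrained classifier")
  words <- kmer_words(toupper(query), clf$k)
  if (length(words) == 0) stop("query shorter than k or without valid words")
  lp <- clf$log_prob[words, , drop = FALSE]
  full <- colSums(lp)
  win <- which.max(full)                 # ties: first (alphabetical) genus
  win_lin <- clf$lineages[[clf$genera[win]]]
  nsub <- ceiling(length(words) / 8)
  set.seed(seed)
  votes <- integer(n_bootstrap)
  for (b in seq_len(n_bootstrap)) {
    sub <- sample.int(length(words), nsub, replace = TRUE)
    sc <- colSums(lp[sub, , drop = FALSE])
    votes[b] <- which.max(sc)
  }
  vote_lin <- lapply(clf$genera[votes], function(g) clf$lineages[[g]])
  conf <- vapply(seq_along(RANKS), function(r) {
    mean(vapply(vote_lin, function(l) identical(l[[r]], win_lin[[r]]),
                logical(1)))
  }, numeric(1))
  # enforce nesting: agreement at a deeper rank implies the shallower ones
  conf <- rev(cummax(rev(conf)))
  label <- unlist(win_lin)
  reported <- label
  deepest <- "root"
  for (r in seq_along(RANKS)) {
    if (conf[r] >= threshold) deepest <- label[r]
    else reported[r] <- paste0("unclassified_", deepest)
  }
  structure(data.frame(rank = RANKS, label = label, confidence = conf,
                       reported = reported, stringsAsFactors = FALSE),
            class = c("taxonomic_assignment", "data.frame"))
}

#' Classify OTU centroids
#'
#' @param centroids centroid data.frame from [greedy_cluster()].
#' @param clf a trained [train_classifier()] model.
#' @param seed integer seed; each OTU gets a distinct derived seed.
#' @inheritParams classify_sequence
#' @return data.frame in long form: `otu_id`, `rank`, `label`, `confidence`,
#'   `reported`.
#' @export
classify_otus <- function(centroids, clf, n_bootstrap = 100L,
                          threshold = 0.7, seed = 1L) {
  out <- lapply(seq_len(nrow(centroids)), function(i) {
    a <- classify_sequence(centroids$bases[i], clf, n_bootstrap, threshold,
                           seed = derive_seed(seed, centroids$otu_id[i]))
    cbind(otu_id = centroids$otu_id[i], as.data.frame(a))
  })
  do.call(rbind, out)
}
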