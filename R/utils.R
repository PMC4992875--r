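#' @useDynLib endolith, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim optimise quantile rbinom rexp runif dpois
#'   median setNames simulate logLik coef
#' @importFrom utils write.table read.table head
NULL

# IUPAC nucleotide expansion sets
IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Reverse complement of a nucleotide string
#'
#' Handles IUPAC ambiguity codes.  Vectorised over `x`.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# Phred+33 encoded quality string <-> integer vector
phred_to_int <- function(q) utf8ToInt(q) - 33L
int_to_phred <- function(q) intToUtf8(q + 33L)

# Stable per-stage seed derived from a global seed; always < 2^31 - 1.
derive_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483647
  s <- (seed %% 2147483647) * 48271 %% 2147483647
  as.integer((h + s) %% 2147483629 + 1)
}

# random ACGT string(s)
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# substitute bases at given positions with a different random base
mutate_bases <- function(seq, pos) {
  if (length(pos) == 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
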