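#' Write reads to FASTQ (Phred+33)
#'
#' @param reads a [read_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  dna <- Biostrings::DNAStringSet(reads$bases)
  names(dna) <- reads$read_id
  Biostrings::writeXStringSet(dna, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quals))
  invisible(path)
}

#' Read a FASTQ file into a read table
#'
#' @param path FASTQ file (Phred+33).
#' @param mate,sample_id,run_id provenance recorded on the table.
#' @return a [read_table()].
#' @export
read_fastq <- function(path, mate = "forward", sample_id = NA_character_,
                       run_id = NA_character_) {
  dna <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
  read_table(names(dna), as.character(dna),
             as.character(S4Vectors::mcols(dna)$qualities),
             mate = mate, sample_id = sample_id, run_id = run_id)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  dna <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  setNames(as.character(dna), names(dna))
}

#' Write a reference set as annotated FASTA
#'
#' Headers carry the lineage in the `d__;p__;c__;o__;f__;g__` dialect.
#'
#' @param refs reference set from [build_reference_set()].
#' @param marker which marker sequence to write.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(refs, marker, path) {
  pre <- c("d__", "p__", "c__", "o__", "f__", "g__")
  seqs <- vapply(refs, function(r) r$marker_seqs[[marker]], character(1))
  names(seqs) <- vapply(refs, function(r)
    paste0(r$taxon_id, " ",
           paste0(pre, unlist(r$lineage), collapse = ";")), character(1))
  write_fasta(seqs, path)
}

#' Read an annotated reference FASTA
#'
#' @param path FASTA whose headers are `<id> d__X;p__X;c__X;o__X;f__X;g__X`.
#' @param marker marker name to attach the sequences under.
#' @return reference list in the [build_reference_set()] layout.
#' @export
read_reference_fasta <- function(path, marker) {
  seqs <- read_fasta(path)
  lapply(seq_along(seqs), function(i) {
    hdr <- strsplit(names(seqs)[i], " ", fixed = TRUE)[[1]]
    ranks <- sub("^[dpcofg]__", "", strsplit(hdr[2], ";", fixed = TRUE)[[1]])
    if (length(ranks) != 6) stop("header must carry 6 ranks: ", names(seqs)[i])
    list(taxon_id = hdr[1], lineage = setNames(ranks, RANKS),
         marker_seqs = setNames(list(unname(seqs[i])), marker))
  })
}

#' Write / read a sample manifest
#'
#' Plain TSV with columns `sample_id`, `run_id`, `is_negative_control`,
#' `r1`, `r2`.
#'
#' @param manifest data.frame with those columns.
#' @param path TSV file.
#' @return the manifest (invisibly for the writer).
#' @export
write_manifest <- function(manifest, path) {
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("sample_id", "run_id", "is_negative_control", "r1", "r2")
  if (!all(need %in% names(m)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  m$is_negative_control <- as.logical(m$is_negative_control)
  m
}

#' Write an OTU table as TSV (rows OTUs, columns samples)
#'
#' @param tab a `marker_otu_table`.
#' @param path TSV file.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(tab, path) {
  df <- data.frame(otu_id = rownames(tab$counts), tab$counts,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV OTU table
#'
#' @param path TSV written by [write_otu_table()].
#' @param marker marker name recorded on the table.
#' @return a `marker_otu_table`.
#' @export
read_otu_table <- function(path, marker = "marker") {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- df$otu_id
  structure(list(counts = counts, marker = marker, unmapped = 0L,
                 filter_log = list()), class = "marker_otu_table")
}

#' Read a binary trait table
#'
#' TSV with columns `tip` and `state` (0/1).
#'
#' @param path TSV file.
#' @return named 0/1 vector.
#' @export
read_trait_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  setNames(as.integer(df$state), df$tip)
}
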