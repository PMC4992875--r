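#' Indexing-oligo arithmetic for pooled multi-marker libraries
#'
#' Dual indexing addresses `a x b` samples with `a + b` oligos; markers ride
#' along for free because they are separated bioinformatically by primer.
#' The classic one-index-per-library alternative needs one forward oligo per
#' sample-marker combination plus one reverse primer per marker.
#'
#' @param n_samples number of samples (>= 1).
#' @param n_markers number of pooled markers (>= 1).
#' @param scheme `"dual_index"` or `"single_index_per_marker"`.
#' @return an `index_design` list with `forward_oligos`, `reverse_oligos`
#'   and `total_oligos`.
#' @examples
#' design_index_oligos(96, 4, "dual_index")$total_oligos          # 20
#' design_index_oligos(96, 4, "single_index_per_marker")$forward_oligos # 384
#' @export
design_index_oligos <- function(n_samples, n_markers,
                                scheme = c("dual_index",
                                           "single_index_per_marker")) {
  scheme <- match.arg(scheme)
  if (n_samples < 1 || n_markers < 1) stop("counts must be >= 1")
  if (scheme == "dual_index") {
    # minimise a + b subject to a * b >= n_samples; ties -> most square
    best <- NULL
    for (a in seq_len(n_samples)) {
      b <- ceiling(n_samples / a)
      if (is.null(best) || a + b < best$a + best$b ||
          (a + b == best$a + best$b && abs(a - b) < abs(best$a - best$b)))
        best <- list(a = a, b = b)
    }
    out <- list(scheme = scheme, n_samples = n_samples, n_markers = n_markers,
                forward_oligos = best$a, reverse_oligos = best$b,
                total_oligos = best$a + best$b)
  } else {
    out <- list(scheme = scheme, n_samples = n_samples, n_markers = n_markers,
                forward_oligos = n_samples * n_markers,
                reverse_oligos = n_markers,
                total_oligos = n_samples * n_markers + n_markers)
  }
  structure(out, class = "index_design")
}

#' @export
print.index_design <- function(x, ...) {
  cat(sprintf("<index design %s> %d samples x %d markers: %d fwd + %d rev = %d oligos\n",
              x$scheme, x$n_samples, x$n_markers, x$forward_oligos,
              x$reverse_oligos, x$total_oligos))
  invisible(x)
}

#' Assemble a pipeline configuration
#'
#' A single declarative object driving [run_pipeline()].  Round-trips
#' through YAML via [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param manifest path to the sample manifest TSV (see [write_manifest()]).
#' @param output_dir directory for all artifacts.
#' @param seed global seed; per-stage seeds are derived from it by stable
#'   hashing of the stage name.
#' @param specs list of [marker_spec()]s.
#' @param qc a [qc_params()].
#' @param filters a [filter_params()].
#' @param classify list: `reference_fasta` (named per marker, may be empty),
#'   `k`, `n_bootstrap`, `threshold`.
#' @param evolution optional list: `tree` (newick path), `traits` (TSV
#'   path), `variant`, `root_prior`, `n_maps`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(manifest, output_dir, seed = 1L,
                            specs = default_marker_specs(),
                            qc = qc_params(), filters = filter_params(),
                            classify = list(reference_fasta = list(), k = 8L,
                                            n_bootstrap = 100L,
                                            threshold = 0.7),
                            evolution = NULL) {
  structure(list(manifest = manifest, output_dir = output_dir,
                 seed = as.integer(seed), specs = validate_specs(specs),
                 qc = qc, filters = filters, classify = classify,
                 evolution = evolution),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a [pipeline_config()].
#' @param path YAML file.
#' @return for the reader, the reconstructed `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$specs <- lapply(config$specs, function(sp)
    c(unclass(sp), list(core_length = attr(sp, "core_length"))))
  x$qc <- unclass(x$qc); x$filters <- unclass(x$filters)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  specs <- lapply(x$specs, function(sp) {
    s <- marker_spec(sp$name, sp$fwd_primer, sp$rev_primer, tail = sp$tail,
                     spacer_max = sp$spacer_max,
                     max_primer_mismatches = sp$max_primer_mismatches,
                     identity_threshold = sp$identity_threshold,
                     min_merged_length = sp$min_merged_length)
    if (!is.null(sp$core_length))
      attr(s, "core_length") <- as.integer(sp$core_length)
    s
  })
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  pipeline_config(x$manifest, x$output_dir, x$seed, specs,
                  do.call(qc_params, x$qc), do.call(filter_params, x$filters),
                  x$classify, x$evolution)
}

#' Simulate a complete multi-marker dataset on disk
#'
#' Generates a reference set and community profiles, simulates per-sample
#' paired FASTQ files with ground truth, and writes the manifest, truth
#' tables and per-marker reference FASTA files under `dir`.
#'
#' @param dir output directory.
#' @param specs list of [marker_spec()]s.
#' @param cfg a [sim_config()]; its `seed` drives everything.
#' @param n_genera,seqs_per_genus reference-set dimensions.
#' @param n_samples,n_controls real samples and PCR negative controls.
#' @param taxa_per_sample number of taxa present in each sample (geometric
#'   abundance profile).
#' @return list: `manifest` (data.frame), `refs`, `profiles`, `truth`
#'   (per-sample list), and file `paths`.
#' @export
simulate_dataset <- function(dir, specs = default_marker_specs(),
                             cfg = sim_config(), n_genera = 6L,
                             seqs_per_genus = 1L, n_samples = 5L,
                             n_controls = 1L, taxa_per_sample = 4L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  refs <- build_reference_set(n_genera, seqs_per_genus, specs, cfg$seed)
  taxa <- vapply(refs, `[[`, character(1), "taxon_id")
  set.seed(derive_seed(cfg$seed, "profiles"))
  profiles <- list()
  for (i in seq_len(n_samples)) {
    chosen <- sample(taxa, min(taxa_per_sample, length(taxa)))
    ab <- 0.5^seq_along(chosen)
    profiles[[i]] <- community_profile(sprintf("S%d", i),
                                       setNames(ab / sum(ab), chosen))
  }
  for (j in seq_len(n_controls)) {
    profiles[[n_samples + j]] <-
      community_profile(sprintf("NEG%d", j), is_negative_control = TRUE)
  }
  rows <- list(); truth <- list()
  for (p in profiles) {
    sim <- simulate_sample_reads(p, refs, specs, cfg)
    r1p <- file.path(dir, paste0(p$sample_id, "_R1.fastq"))
    r2p <- file.path(dir, paste0(p$sample_id, "_R2.fastq"))
    write_fastq(sim$r1, r1p); write_fastq(sim$r2, r2p)
    rows[[p$sample_id]] <- data.frame(
      sample_id = p$sample_id, run_id = "RUN1",
      is_negative_control = p$is_negative_control, r1 = r1p, r2 = r2p,
      stringsAsFactors = FALSE)
    truth[[p$sample_id]] <- sim$truth
    if (!is.null(sim$truth$read_truth))
      write.table(sim$truth$read_truth,
                  file.path(dir, paste0(p$sample_id, "_truth.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  write_manifest(manifest, file.path(dir, "manifest.tsv"))
  refpaths <- list()
  for (m in names(specs)) {
    refpaths[[m]] <- file.path(dir, paste0("refs_", m, ".fasta"))
    write_reference_fasta(refs, m, refpaths[[m]])
  }
  list(manifest = manifest, refs = refs, profiles = profiles, truth = truth,
       paths = list(dir = dir, manifest = file.path(dir, "manifest.tsv"),
                    reference_fasta = refpaths))
}

#' Run the full metabarcoding workflow
#'
#' Executes, per sample: read-through stripping and marker demultiplexing;
#' per marker: read preparation (trim, merge, quality filter, global primer
#' trim), pooled dereplication, greedy clustering with chimera screening,
#' read mapping into an OTU table, optional taxonomy assignment, and the
#' three-tier filter chain.  When the configuration carries a dated tree and
#' trait table, the evolution stage fits the Mk model, draws stochastic maps
#' and summarises origins of the endolithic state.  Fully deterministic
#' under the configuration seed.
#'
#' @param config a [pipeline_config()].
#' @return a run manifest: per-marker ledgers, file paths of artifacts, OTU
#'   tables before/after filtering, taxonomy, and the evolution summary (if
#'   run).
#' @export
run_pipeline <- function(config) {
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- if (is.character(config$manifest))
    read_manifest(config$manifest) else config$manifest
  missing <- manifest$r1[!file.exists(manifest$r1)]
  missing <- c(missing, manifest$r2[!file.exists(manifest$r2)])
  if (length(missing))
    stop("manifest FASTQ missing: ", paste(missing, collapse = ", "))
  specs <- config$specs
  controls <- manifest$sample_id[manifest$is_negative_control]
  per_marker <- setNames(vector("list", length(specs)), names(specs))
  demux_report <- list()

  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$sample_id[i]
    r1 <- read_fastq(manifest$r1[i], "forward", sid, manifest$run_id[i])
    r2 <- read_fastq(manifest$r2[i], "reverse", sid, manifest$run_id[i])
    r1 <- strip_readthrough(r1, specs)
    r2 <- strip_readthrough(r2, specs)
    dm <- demultiplex_sample(r1, r2, specs)
    demux_report[[sid]] <- data.frame(
      sample_id = sid, category = names(dm$counts),
      n_pairs = as.integer(dm$counts),
      fraction = as.numeric(dm$counts) / max(1L, dm$n_input),
      stringsAsFactors = FALSE)
    for (m in names(specs)) {
      pr <- prep_reads(dm$assigned[[m]]$r1, dm$assigned[[m]]$r2,
                       specs[[m]], config$qc)
      per_marker[[m]]$reads <- rbind(per_marker[[m]]$reads, pr$reads)
      per_marker[[m]]$ledger[[sid]] <- pr$counts
    }
  }
  dmr <- do.call(rbind, demux_report)
  rownames(dmr) <- NULL
  write.table(dmr, file.path(out, "demux_report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  results <- list(demux = dmr, markers = list(), output_dir = out,
                  seed = config$seed)
  for (m in names(specs)) {
    reads <- per_marker[[m]]$reads
    mk <- list(ledger = per_marker[[m]]$ledger)
    if (is.null(reads) || nrow(reads) == 0) {
      results$markers[[m]] <- c(mk, list(error = "no reads survived"))
      next
    }
    write_fasta(setNames(reads$bases, reads$read_id),
                file.path(out, paste0(m, "_prepared.fasta")))
    uq <- dereplicate(reads$bases, reads$read_id)
    cl <- greedy_cluster(uq, specs[[m]]$identity_threshold)
    write_fasta(setNames(cl$centroids$bases,
                         sprintf("%s;size=%d", cl$centroids$otu_id,
                                 cl$centroids$size)),
                file.path(out, paste0(m, "_centroids.fasta")))
    tab <- build_otu_table(reads, cl$centroids,
                           specs[[m]]$identity_threshold, marker = m,
                           samples = manifest$sample_id)
    write_otu_table(tab, file.path(out, paste0(m, "_otu_table_raw.tsv")))
    taxonomy <- NULL
    reffa <- config$classify$reference_fasta[[m]]
    if (!is.null(reffa)) {
      refs <- read_reference_fasta(reffa, m)
      clf <- train_classifier(refs, m, k = config$classify$k %||% 8L)
      taxonomy <- classify_otus(cl$centroids, clf,
                                n_bootstrap = config$classify$n_bootstrap %||% 100L,
                                threshold = config$classify$threshold %||% 0.7,
                                seed = derive_seed(config$seed,
                                                   paste0("classify_", m)))
      write.table(taxonomy, file.path(out, paste0(m, "_taxonomy.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    filtered <- filter_otu_table(tab, controls, config$filters)
    write_otu_table(filtered, file.path(out, paste0(m, "_otu_table_filtered.tsv")))
    report <- summarize_filters(tab, filtered)
    results$markers[[m]] <- c(mk, list(
      n_uniques = nrow(uq), n_chimeras = nrow(cl$chimeras),
      table_raw = tab, table_filtered = filtered, taxonomy = taxonomy,
      filter_report = report, centroids = cl$centroids))
  }

  if (!is.null(config$evolution)) {
    ev <- config$evolution
    tree <- ape::read.tree(ev$tree)
    states <- read_trait_table(ev$traits)
    fit <- fit_mk(tree, states, variant = ev$variant %||% "equal_rates",
                  root_prior = ev$root_prior %||% "stationary")
    maps <- sample_maps(fit, n_maps = ev$n_maps %||% 1000L,
                        seed = derive_seed(config$seed, "stochastic_maps"))
    origins <- count_origins(maps)
    write.table(data.frame(map = seq_along(origins$per_map),
                           origins = origins$per_map),
                file.path(out, "origin_counts.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    n <- ape::Ntip(maps$tree)
    write.table(data.frame(node = seq_along(origins$node_prob),
                           p_endolithic = origins$node_prob),
                file.path(out, "node_state_probability.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    antree <- maps$tree
    antree$node.label <- sprintf("%.3f", origins$node_prob[(n + 1):length(origins$node_prob)])
    ape::write.tree(antree, file.path(out, "tree_node_probability.nwk"))
    results$evolution <- list(fit = fit, origins = origins)
  }
  class(results) <- "pipeline_run"
  results
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline run>", length(x$markers), "markers ->", x$output_dir, "\n")
  for (m in names(x$markers)) {
    mk <- x$markers[[m]]
    if (!is.null(mk$error)) { cat(sprintf("  %s: %s\n", m, mk$error)); next }
    cat(sprintf("  %s: %d OTUs raw, %d after filters, %d chimeras discarded\n",
                m, nrow(mk$table_raw$counts), nrow(mk$table_filtered$counts),
                mk$n_chimeras))
  }
  if (!is.null(x$evolution))
    cat(sprintf("  origins of endolithic state: mean %.2f\n",
                x$evolution$origins$mean))
  invisible(x)
}
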