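#' Simulation configuration
#'
#' Defaults emulate a 2 x 300 nt paired-end run over pooled amplicons with
#' heterogeneity spacers of 0-3 random 5' bases, position-dependent quality
#' decay, occasional PCR chimeras, and a trickle of cross-contamination into
#' negative controls.
#'
#' @param seed integer master seed; all generator randomness derives from it.
#' @param read_length read length in bases (>= 50).
#' @param spacer_max maximum heterogeneity-spacer length (uniform 0..max).
#' @param substitution_rate mean per-base substitution probability; errors
#'   fall preferentially on low-quality (3') positions, with the quality
#'   profile shaping where they land.  Zero disables errors entirely.
#' @param quality_start Phred value at the first cycle (default 38).
#' @param quality_slope linear per-base Phred decay toward the 3' end.
#' @param quality_floor lowest Phred value emitted (default 2).
#' @param chimera_fraction fraction of templates replaced by two-parent
#'   recombinants.
#' @param negcontrol_contamination_reads contaminant read pairs injected per
#'   marker into each negative control.
#' @param reads_per_sample template count per sample per marker.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, read_length = 300L, spacer_max = 3L,
                       substitution_rate = 0.001, quality_start = 38,
                       quality_slope = 0.02, quality_floor = 2,
                       chimera_fraction = 0.01,
                       negcontrol_contamination_reads = 5L,
                       reads_per_sample = 500L) {
  if (read_length < 50) stop("read_length must be >= 50")
  for (r in c(substitution_rate, chimera_fraction))
    if (r < 0 || r > 1) stop("rates must be in [0, 1]")
  structure(list(seed = as.integer(seed), read_length = as.integer(read_length),
                 spacer_max = as.integer(spacer_max),
                 substitution_rate = substitution_rate,
                 quality_start = quality_start, quality_slope = quality_slope,
                 quality_floor = quality_floor,
                 chimera_fraction = chimera_fraction,
                 negcontrol_contamination_reads =
                   as.integer(negcontrol_contamination_reads),
                 reads_per_sample = as.integer(reads_per_sample)),
            class = "sim_config")
}

# concrete (unambiguous) instantiation of an IUPAC primer
concretize <- function(primer) {
  ch <- strsplit(primer, "", fixed = TRUE)[[1]]
  paste(vapply(ch, function(c) IUPAC[[c]][1], character(1)), collapse = "")
}

#' Generate a synthetic reference taxon set
#'
#' Genera receive independent random amplicon cores per marker (pairwise
#' identity well below 90%); sequences within a genus are 1% point mutants
#' of the genus core (pairwise identity >= 97%).  Every marker sequence is a
#' full amplicon: concrete forward primer + core + reverse complement of the
#' concrete reverse primer.  Lineages are hierarchical six-rank labels with
#' genera nested pairwise into families.
#'
#' @param n_genera number of genera (>= 1).
#' @param seqs_per_genus sequences (taxa) per genus.
#' @param specs list of [marker_spec()]s; the simulated inter-primer core
#'   length is read from each spec's `core_length` attribute (default 300).
#' @param seed integer seed; output is byte-identical under the same seed.
#' @return list of reference taxa: each a list with `taxon_id`, `lineage`
#'   (named 6-rank character vector) and `marker_seqs`.
#' @export
build_reference_set <- function(n_genera, seqs_per_genus = 1L, specs, seed = 1L) {
  if (n_genera < 1) stop("n_genera must be >= 1")
  specs <- validate_specs(specs)
  core_len <- vapply(specs, function(sp)
    as.integer(attr(sp, "core_length") %||% 300L), integer(1))
  if (any(core_len < 50))
    stop("core length below 50 cannot meet the divergence targets")
  set.seed(derive_seed(seed, "reference_set"))
  fwd <- vapply(specs, function(sp) concretize(sp$fwd_primer), character(1))
  rev <- vapply(specs, function(sp) revcomp(concretize(sp$rev_primer)),
                character(1))
  gcore <- lapply(names(specs), function(m) random_dna(n_genera, core_len[m]))
  names(gcore) <- names(specs)
  refs <- list()
  for (g in seq_len(n_genera)) {
    lineage <- c(domain = "Eukaryota", phylum = "Chlorophyta",
                 class = sprintf("Class%02d", ceiling(g / 8)),
                 order = sprintf("Order%02d", ceiling(g / 4)),
                 family = sprintf("Family%02d", ceiling(g / 2)),
                 genus = sprintf("Genus%02d", g))
    for (s in seq_len(seqs_per_genus)) {
      mseqs <- lapply(names(specs), function(m) {
        core <- gcore[[m]][g]
        if (s > 1L || seqs_per_genus > 1L) {
          nmut <- max(1L, round(0.01 * core_len[m]))
          core <- mutate_bases(core, sample.int(core_len[m], nmut))
        }
        paste0(fwd[m], core, rev[m])
      })
      names(mseqs) <- names(specs)
      refs[[length(refs) + 1L]] <- list(
        taxon_id = sprintf("Genus%02d_t%d", g, s),
        lineage = lineage, marker_seqs = mseqs)
    }
  }
  refs
}

#' Describe a (mock) community
#'
#' @param sample_id sample label (no `.` or `_`).
#' @param abundances named numeric vector (taxon_id -> relative abundance);
#'   must sum to 1 for real samples; empty for negative controls.
#' @param is_negative_control logical.
#' @return a `community_profile` list.
#' @export
community_profile <- function(sample_id, abundances = numeric(0),
                              is_negative_control = FALSE) {
  if (!is_negative_control) {
    if (length(abundances) == 0) stop("non-control profile must not be empty")
    if (abs(sum(abundances) - 1) > 1e-9)
      stop("abundances must sum to 1")
  }
  structure(list(sample_id = sample_id, abundances = abundances,
                 is_negative_control = is_negative_control),
            class = "community_profile")
}

# position-dependent Phred profile for a read of length L
quality_profile <- function(cfg, L) {
  q <- cfg$quality_start - cfg$quality_slope * (seq_len(L) - 1)
  as.integer(round(pmax(q, cfg$quality_floor)))
}

# apply substitution errors shaped by the quality profile
apply_errors <- function(bases, qprof, rate) {
  if (rate == 0) return(bases)
  perr <- 10^(-qprof / 10)
  perr <- pmin(1, rate * perr / mean(perr))
  n <- length(bases)
  out <- bases
  for (i in seq_len(n)) {
    hit <- which(runif(nchar(bases[i])) < perr[seq_len(nchar(bases[i]))])
    if (length(hit)) out[i] <- mutate_bases(bases[i], hit)
  }
  out
}

PAD_ADAPTER <- "ATCTCGTATGCCGTCTTCTGCTTGAAAAAAAAAACGGTCTCGGCATTCCTGCTGAACCGCTCTTCCGATCTATCTCGTATGCCGTCTTCTGCTTG"

#' Simulate one sample's paired-end multi-marker reads
#'
#' For every marker, `reads_per_sample` templates are drawn from the
#' community profile (multinomially); a `chimera_fraction` of them are
#' replaced by two-parent recombinants with a uniform breakpoint at least
#' 50 nt from either end.  Read 1 is spacer + forward primer + template
#' prefix; short amplicons read through into the reverse complement of the
#' opposite primer and overhang tail, then adapter.  Qualities follow the
#' linear decay model and substitution errors are drawn per base.  Negative
#' controls receive `negcontrol_contamination_reads` contaminant pairs per
#' marker, drawn uniformly from all reference taxa.
#'
#' @param profile a [community_profile()].
#' @param refs reference set from [build_reference_set()].
#' @param specs list of [marker_spec()]s.
#' @param cfg a [sim_config()].
#' @return list with `r1`, `r2` ([read_table()]s, row-aligned) and `truth`
#'   (list: `template_counts`, `read_truth`, `chimeras`,
#'   `contaminant_read_ids`).
#' @export
simulate_sample_reads <- function(profile, refs, specs, cfg) {
  specs <- validate_specs(specs)
  set.seed(derive_seed(cfg$seed, paste0("reads_", profile$sample_id)))
  taxa <- vapply(refs, `[[`, character(1), "taxon_id")
  names(refs) <- taxa
  RL <- cfg$read_length
  r1b <- character(0); r2b <- character(0); ids <- character(0)
  truth_rows <- list(); chim_rows <- list(); tc_rows <- list()
  contaminants <- character(0)
  for (m in names(specs)) {
    sp <- specs[[m]]
    fwd <- concretize(sp$fwd_primer); rev <- concretize(sp$rev_primer)
    if (profile$is_negative_control) {
      ntpl <- cfg$negcontrol_contamination_reads
      tpl_taxa <- if (ntpl > 0) sample(taxa, ntpl, replace = TRUE) else character(0)
      contam <- rep(TRUE, ntpl)
    } else {
      if (length(profile$abundances) == 0) stop("empty non-control profile")
      ntpl <- cfg$reads_per_sample
      tpl_taxa <- sample(names(profile$abundances), ntpl, replace = TRUE,
                         prob = profile$abundances)
      contam <- rep(FALSE, ntpl)
    }
    if (ntpl == 0) next
    amps <- vapply(refs[tpl_taxa], function(r) r$marker_seqs[[m]], character(1))
    is_chim <- runif(ntpl) < cfg$chimera_fraction
    parent_b <- rep(NA_character_, ntpl); bp <- rep(NA_integer_, ntpl)
    for (i in which(is_chim)) {
      L <- nchar(amps[i])
      if (L < 102 || ntpl < 2) { is_chim[i] <- FALSE; next }
      j <- sample(setdiff(seq_len(ntpl), i), 1)
      parent_b[i] <- tpl_taxa[j]
      bp[i] <- sample(50:(L - 50), 1)
      amps[i] <- paste0(substr(amps[i], 1, bp[i]),
                        substr(refs[[tpl_taxa[j]]]$marker_seqs[[m]],
                               bp[i] + 1, L))
    }
    s1 <- sample(0:cfg$spacer_max, ntpl, replace = TRUE)
    s2 <- sample(0:cfg$spacer_max, ntpl, replace = TRUE)
    spac1 <- vapply(s1, function(k) paste(sample(c("A","C","G","T"), k,
                                                 replace = TRUE),
                                          collapse = ""), character(1))
    spac2 <- vapply(s2, function(k) paste(sample(c("A","C","G","T"), k,
                                                 replace = TRUE),
                                          collapse = ""), character(1))
    tail_rc <- revcomp(sp$tail)
    full1 <- paste0(spac1, amps, revcomp(rev), tail_rc, PAD_ADAPTER)
    full2 <- paste0(spac2, revcomp(amps), revcomp(fwd), tail_rc, PAD_ADAPTER)
    b1 <- substr(full1, 1, RL); b2 <- substr(full2, 1, RL)
    qprof <- quality_profile(cfg, RL)
    b1 <- apply_errors(b1, qprof, cfg$substitution_rate)
    b2 <- apply_errors(b2, qprof, cfg$substitution_rate)
    rid <- sprintf("%s-%s-%05d", profile$sample_id, m, seq_len(ntpl))
    r1b <- c(r1b, b1); r2b <- c(r2b, b2); ids <- c(ids, rid)
    truth_rows[[m]] <- data.frame(
      read_id = rid, marker = m, taxon_id = tpl_taxa,
      is_chimera = is_chim, parent_b = parent_b, breakpoint = bp,
      is_contaminant = contam, stringsAsFactors = FALSE)
    if (any(is_chim))
      chim_rows[[m]] <- truth_rows[[m]][is_chim,
        c("read_id", "marker", "taxon_id", "parent_b", "breakpoint")]
    tc <- table(tpl_taxa)
    tc_rows[[m]] <- data.frame(marker = m, taxon_id = names(tc),
                               templates = as.integer(tc),
                               stringsAsFactors = FALSE)
    if (profile$is_negative_control) contaminants <- c(contaminants, rid)
  }
  qstr <- int_to_phred(quality_profile(cfg, RL))
  n <- length(ids)
  truth <- list(
    template_counts = if (length(tc_rows)) do.call(rbind, tc_rows) else NULL,
    read_truth = if (length(truth_rows)) do.call(rbind, truth_rows) else NULL,
    chimeras = if (length(chim_rows)) do.call(rbind, chim_rows) else NULL,
    contaminant_read_ids = contaminants)
  if (!is.null(truth$read_truth)) rownames(truth$read_truth) <- NULL
  list(r1 = read_table(ids, r1b, rep(qstr, n), mate = "forward",
                       sample_id = profile$sample_id, run_id = "RUN1"),
       r2 = read_table(ids, r2b, rep(qstr, n), mate = "reverse",
                       sample_id = profile$sample_id, run_id = "RUN1"),
       truth = truth)
}

# simulate a binary character down a tree by exact CTMC sampling;
# returns tip states, node states and the full event history
sim_character_history <- function(tree, q01, q10, root_state = 0L) {
  tr <- ape::reorder.phylo(tree, "postorder")
  n <- ape::Ntip(tr); nn <- n + tr$Nnode
  node_state <- rep(NA_integer_, nn)
  node_state[n + 1L] <- as.integer(root_state)
  events <- list()
  rates <- c(q01, q10)  # exit rate of state 0, state 1
  for (e in rev(seq_len(nrow(tr$edge)))) {   # preorder
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    s <- node_state[p]; t_left <- tr$edge.length[e]; at <- 0
    repeat {
      rate <- rates[s + 1L]
      if (rate == 0) break
      w <- rexp(1, rate)
      if (w >= t_left) break
      at <- at + w; t_left <- t_left - w
      events[[length(events) + 1L]] <-
        data.frame(edge = e, time = at, from = s, to = 1L - s)
      s <- 1L - s
    }
    node_state[ch] <- s
  }
  history <- if (length(events)) do.call(rbind, events) else
    data.frame(edge = integer(0), time = numeric(0), from = integer(0),
               to = integer(0))
  list(tree = tr, tip_states = setNames(node_state[seq_len(n)], tr$tip.label),
       node_states = node_state, history = history)
}

#' Simulate a dated phylogeny with a binary character
#'
#' Draws an ultrametric birth-death tree conditioned on the number of tips,
#' then evolves a two-state character along it by exact continuous-time
#' Markov sampling, recording every transition event.
#'
#' @param n_tips number of extant tips (>= 2).
#' @param birth_rate,death_rate birth-death rates (death < birth).
#' @param q01,q10 character gain/loss rates per unit branch length.
#' @param root_state state at the root (0 or 1).
#' @param seed integer seed; byte-identical output under the same seed.
#' @return list: `tree` (postorder `phylo`), `tip_states` (named 0/1),
#'   `node_states`, and `history` (data.frame `edge`, `time`, `from`, `to`;
#'   `time` from the parent end of the branch).
#' @export
simulate_phylogeny_with_character <- function(n_tips, birth_rate = 1,
                                              death_rate = 0, q01 = 0.1,
                                              q10 = 0.1, root_state = 0L,
                                              seed = 1L) {
  if (n_tips < 2) stop("n_tips must be >= 2")
  if (any(c(birth_rate, death_rate, q01, q10) < 0)) stop("rates must be >= 0")
  if (death_rate >= birth_rate)
    stop("death_rate must be below birth_rate (non-viable process)")
  set.seed(derive_seed(seed, "phylogeny"))
  tree <- ape::rphylo(n_tips, birth = birth_rate, death = death_rate)
  h <- sim_character_history(tree, q01, q10, root_state)
  c(list(tree = h$tree), h[c("tip_states", "node_states", "history")])
}
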