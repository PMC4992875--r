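test_that("dereplication groups exactly and orders deterministically", {
  uq <- dereplicate(c("AAA", "AAA", "AAT"))
  expect_equal(uq$bases, c("AAA", "AAT"))
  expect_equal(uq$abundance, c(2L, 1L))
  expect_equal(sum(uq$abundance), 3L)

  set.seed(1)
  distinct <- replicate(12, rand_seq(20))
  expect_equal(nrow(dereplicate(distinct)), 12)

  tied <- dereplicate(c("TTT", "AAA"))           # equal abundance
  expect_equal(tied$bases, c("AAA", "TTT"))       # lexicographic tie rule
})

test_that("pairwise identity matches hand counts and the DP oracle", {
  expect_equal(pairwise_identity("AAAA", "AAAA"), 1.0)
  expect_equal(pairwise_identity("AAAA", "AAAT"), 0.75)
  expect_equal(pairwise_identity("ACGT", "ACGT"), 1.0)
  # symmetry and random agreement with the independent DP implementation
  set.seed(99)
  for (i in 1:30) {
    a <- rand_seq(sample(20:60, 1))
    b <- if (runif(1) < 0.5) rand_seq(sample(20:60, 1)) else {
      ch <- strsplit(a, "")[[1]]
      k <- sample(seq_along(ch), sample(1:5, 1))
      for (p in k) ch[p] <- sample(c("A","C","G","T"), 1)
      paste(c(ch, strsplit(rand_seq(sample(0:6, 1)), "")[[1]]), collapse = "")
    }
    expect_equal(pairwise_identity(a, b), oracle_identity(a, b),
                 label = sprintf("identity case %d", i))
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  }
})

test_that("chimera screening detects planted recombinants and obeys the skew rule", {
  set.seed(3)
  A <- rand_seq(300)
  B <- local({ ch <- strsplit(A, "")[[1]]
    for (p in sample(300, 45)) ch[p] <- sample(setdiff(c("A","C","G","T"),
                                                       ch[p]), 1)
    paste(ch, collapse = "") })
  expect_lte(pairwise_identity(A, B), 0.90)
  Q <- paste0(substr(A, 1, 150), substr(B, 151, 300))
  cent <- data.frame(otu_id = c("OTU_0001", "OTU_0002"), bases = c(A, B),
                     size = c(100, 100), stringsAsFactors = FALSE)
  v <- chimera_check(Q, 5, cent)
  expect_true(v$chimeric)
  expect_setequal(c(v$parent_a, v$parent_b), cent$otu_id)
  expect_lte(abs(v$breakpoint - 150), 5)

  # a genuine member of centroid A is clean
  expect_false(chimera_check(A, 5, cent)$chimeric)
  # abundance skew: a query more abundant than half the parents is clean
  expect_false(chimera_check(Q, 300, cent)$chimeric)
})

test_that("greedy clustering respects the identity threshold", {
  set.seed(8)
  S1 <- rand_seq(200)
  S2 <- local({ ch <- strsplit(S1, "")[[1]]
    for (p in sample(200, 8)) ch[p] <- sample(setdiff(c("A","C","G","T"),
                                                      ch[p]), 1)
    paste(ch, collapse = "") })
  id <- oracle_identity(S1, S2)
  expect_equal(id, 0.96)
  uq <- dereplicate(c(rep(S1, 10), rep(S2, 3)))
  expect_equal(nrow(greedy_cluster(uq, 0.97)$centroids), 2)
  cl <- greedy_cluster(uq, 0.95)
  expect_equal(nrow(cl$centroids), 1)
  expect_equal(cl$centroids$size, 13)
  expect_equal(cl$centroids$bases, S1)    # most abundant member is centroid

  single <- dereplicate("ACGTACGTACGTACGT")
  expect_equal(greedy_cluster(single, 0.97)$centroids$bases,
               "ACGTACGTACGTACGT")
  expect_error(greedy_cluster(single, 0.4), "threshold")
})

test_that("lowering the threshold never increases the OTU count", {
  set.seed(21)
  base <- replicate(5, rand_seq(150))
  seqs <- unlist(lapply(base, function(b) {
    c(b, replicate(3, { ch <- strsplit(b, "")[[1]]
      for (p in sample(150, sample(1:8, 1)))
        ch[p] <- sample(c("A","C","G","T"), 1)
      paste(ch, collapse = "") }))
  }))
  uq <- dereplicate(rep(seqs, times = rev(seq_along(seqs))))
  counts <- sapply(c(0.99, 0.97, 0.95, 0.90, 0.80),
                   function(th) nrow(greedy_cluster(uq, th)$centroids))
  expect_true(all(diff(counts) <= 0))
})

test_that("small-instance clustering equals a brute-force reimplementation", {
  brute_cluster <- function(uq, th) {
    cents <- list()
    assign <- character(nrow(uq))
    for (i in seq_len(nrow(uq))) {
      ids <- vapply(cents, function(cb) oracle_identity(uq$bases[i], cb$b),
                    numeric(1))
      if (length(ids) && max(ids) >= th) {
        sizes <- vapply(cents, `[[`, numeric(1), "size")
        o <- order(-ids, -sizes, seq_along(ids))[1]
        assign[i] <- names(cents)[o]
        cents[[o]]$size <- cents[[o]]$size + uq$abundance[i]
      } else {
        id <- sprintf("OTU_%04d", length(cents) + 1L)
        cents[[id]] <- list(b = uq$bases[i], size = uq$abundance[i])
        assign[i] <- id
      }
    }
    assign
  }
  set.seed(5)
  pool <- replicate(4, rand_seq(80))
  seqs <- unlist(lapply(pool, function(b) replicate(5, {
    ch <- strsplit(b, "")[[1]]
    for (p in sample(80, sample(0:4, 1))) ch[p] <- sample(c("A","C","G","T"), 1)
    paste(ch, collapse = "") })))
  uq <- dereplicate(rep(seqs, times = rep(c(5, 2, 1, 1), 5)))
  got <- greedy_cluster(uq, 0.95,
                        chimera_args = list(skew = Inf))  # disable screening
  expect_equal(got$assignment, brute_cluster(uq, 0.95))
})

test_that("OTU tables reproduce ground-truth counts and flag weak mappings", {
  specs <- default_marker_specs()
  refs <- build_reference_set(2, 1, specs, seed = 12)
  taxa <- vapply(refs, `[[`, character(1), "taxon_id")
  cfg <- sim_config(seed = 3, substitution_rate = 0, chimera_fraction = 0,
                    reads_per_sample = 40)
  pools <- list()
  for (s in c("S1", "S2")) {
    p <- community_profile(s, setNames(c(.7, .3), taxa))
    sim <- simulate_sample_reads(p, refs, specs["tufA"], cfg)
    dm <- demultiplex_sample(strip_readthrough(sim$r1, specs["tufA"]),
                             strip_readthrough(sim$r2, specs["tufA"]),
                             specs["tufA"])
    pr <- prep_reads(dm$assigned$tufA$r1, dm$assigned$tufA$r2, specs$tufA)
    pools[[s]] <- list(reads = pr$reads, truth = sim$truth$template_counts)
  }
  reads <- rbind(pools$S1$reads, pools$S2$reads)
  uq <- dereplicate(reads$bases, reads$read_id)
  cl <- greedy_cluster(uq, specs$tufA$identity_threshold)
  tab <- build_otu_table(reads, cl$centroids, specs$tufA$identity_threshold,
                         marker = "tufA")
  expect_equal(sum(tab$counts) + tab$unmapped, nrow(reads))
  expect_equal(tab$unmapped, 0L)
  # per-sample counts equal the planted template counts
  core_of <- function(tx) {
    amp <- refs[[which(taxa == tx)]]$marker_seqs$tufA
    substr(amp, nchar(specs$tufA$fwd_primer) + 1,
           nchar(amp) - nchar(specs$tufA$rev_primer))
  }
  for (s in c("S1", "S2")) for (tx in taxa) {
    want <- pools[[s]]$truth$templates[pools[[s]]$truth$taxon_id == tx]
    otu <- cl$centroids$otu_id[cl$centroids$bases == core_of(tx)]
    expect_equal(unname(tab$counts[otu, s]), want)
  }

  expect_error(build_otu_table(reads, cl$centroids[0, ], 0.97), "empty")
  # a read below the mapping threshold is counted unmapped
  far <- reads[1, ]; far$bases <- rand_seq(nchar(far$bases))
  tab2 <- build_otu_table(far, cl$centroids, 0.97, marker = "tufA")
  expect_equal(tab2$unmapped, 1L)
  expect_equal(sum(tab2$counts), 0L)
})
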