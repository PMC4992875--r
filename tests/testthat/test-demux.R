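specs <- default_marker_specs()
sp16 <- specs[["16S"]]

test_that("match_primer finds planted primers behind spacers", {
  pay <- strrep("ACGT", 30)
  r <- match_primer(paste0("GG", concretize_test(sp16$fwd_primer), pay),
                    sp16$fwd_primer, 3, 0)
  expect_true(r$matched)
  expect_equal(r$spacer_len, 2)
  expect_equal(r$mismatches, 0)

  # IUPAC expansion: R matches A or G
  r <- match_primer("ACGTGACCCCCCCCCCCCCC", "ACGTRACCCCCCCCCCC", 3, 0)
  expect_true(r$matched)
  expect_equal(r$spacer_len, 0)

  # too-short read never matches
  expect_false(match_primer("ACG", sp16$fwd_primer, 3, 2)$matched)
})

test_that("match_primer agrees with exhaustive offset/mismatch enumeration", {
  set.seed(42)
  primer <- sp16$fwd_primer
  for (i in 1:60) {
    s <- sample(0:3, 1)
    nmut <- sample(0:3, 1)
    base <- paste0(rand_seq(s), concretize_test(primer), rand_seq(60))
    if (nmut > 0) {
      pos <- s + sample.int(nchar(primer), nmut)
      ch <- strsplit(base, "")[[1]]
      for (p in pos) ch[p] <- setdiff(c("A","C","G","T"), ch[p])[1]
      base <- paste(ch, collapse = "")
    }
    for (mm in 0:2) {
      got <- match_primer(base, primer, 3, mm)
      want <- oracle_match_primer(base, primer, 3, mm)
      expect_equal(got$matched, want$matched,
                   label = sprintf("case %d mm=%d matched", i, mm))
      if (want$matched) {
        expect_equal(got$spacer_len, unname(want$spacer_len))
        expect_equal(got$mismatches, unname(want$mismatches))
      }
    }
  }
})

test_that("read-through tails are stripped at the planted position", {
  set.seed(7)
  pat <- revcomp(paste0(sp16$tail, sp16$rev_primer))
  # full-pattern occurrence at 0-based position 120
  b <- paste0(rand_seq(120), concretize_test_iupac(pat), rand_seq(50))
  reads <- read_table("r1", b, strrep("I", nchar(b)))
  out <- strip_readthrough(reads, list(sp16))
  expect_equal(nchar(out$bases), 120)
  expect_equal(nchar(out$quals), 120)

  # no tail signal: identity
  clean <- read_table("r2", rand_seq(200), strrep("I", 200))
  expect_identical(strip_readthrough(clean, list(sp16))$bases, clean$bases)

  # match before the guard position is ignored
  early <- read_table("r3", paste0(rand_seq(10), concretize_test_iupac(pat),
                                   rand_seq(140)),
                      strrep("I", 10 + nchar(pat) + 140))
  expect_equal(nchar(strip_readthrough(early, list(sp16))$bases),
               10 + nchar(pat) + 140)
})

test_that("demultiplexing partitions pairs and routes conflicts to unassigned", {
  refs <- build_reference_set(2, 1, specs, seed = 3)
  cfg <- sim_config(seed = 5, substitution_rate = 0, chimera_fraction = 0,
                    reads_per_sample = 25)
  p <- community_profile("S1", setNames(1, refs[[1]]$taxon_id))
  sim <- simulate_sample_reads(p, refs, specs, cfg)
  r1 <- strip_readthrough(sim$r1, specs)
  r2 <- strip_readthrough(sim$r2, specs)
  dm <- demultiplex_sample(r1, r2, specs)
  expect_equal(unname(dm$counts[names(specs)]), rep(25L, 4))
  expect_equal(unname(dm$counts["unassigned"]), 0L)
  # conservation
  expect_equal(sum(dm$counts), nrow(sim$r1))
  # ground-truth marker labels recovered exactly
  for (m in names(specs)) {
    want <- sim$truth$read_truth$read_id[sim$truth$read_truth$marker == m]
    expect_setequal(dm$assigned[[m]]$r1$read_id, want)
  }
})

test_that("conflicting mate evidence is unassigned", {
  f16 <- concretize_test(specs[["16S"]]$fwd_primer)
  r18 <- concretize_test(specs[["18S"]]$rev_primer)
  r1 <- read_table("x", paste0(f16, rand_seq(80)), strrep("I", nchar(f16) + 80))
  r2 <- read_table("x", paste0(r18, rand_seq(80)), strrep("I", nchar(r18) + 80))
  dm <- demultiplex_sample(r1, r2, specs)
  expect_equal(unname(dm$counts["unassigned"]), 1L)
})

test_that("primer-mutated pairs fail demultiplexing at the mismatch cap", {
  set.seed(11)
  refs <- build_reference_set(2, 1, specs, seed = 3)
  cfg <- sim_config(seed = 6, substitution_rate = 0, chimera_fraction = 0,
                    reads_per_sample = 30)
  p <- community_profile("S1", setNames(1, refs[[1]]$taxon_id))
  sim <- simulate_sample_reads(p, refs, specs, cfg)
  # mutate 3 bases of the forward primer region of three 16S pairs
  idx <- which(sim$truth$read_truth$marker == "16S")[1:3]
  pchars <- strsplit(specs[["16S"]]$fwd_primer, "")[[1]]
  rigid <- which(pchars %in% c("A", "C", "G", "T"))  # non-degenerate positions
  for (i in idx) {
    b <- strsplit(sim$r1$bases[i], "")[[1]]
    f <- match_primer(sim$r1$bases[i], specs[["16S"]]$fwd_primer, 3, 2)
    pos <- sample(rigid, 3)
    for (p2 in pos)
      b[f$spacer_len + p2] <- setdiff(c("A","C","G","T"), pchars[p2])[1]
    sim$r1$bases[i] <- paste(b, collapse = "")
  }
  dm <- demultiplex_sample(strip_readthrough(sim$r1, specs),
                           strip_readthrough(sim$r2, specs), specs)
  expect_equal(unname(dm$counts["unassigned"]), 3L)
  expect_setequal(dm$unassigned$r1$read_id, sim$r1$read_id[idx])
})

test_that("raising the mismatch tolerance never loses assignments", {
  refs <- build_reference_set(2, 1, specs, seed = 9)
  cfg <- sim_config(seed = 8, substitution_rate = 0.01, reads_per_sample = 40)
  p <- community_profile("S1", setNames(1, refs[[1]]$taxon_id))
  sim <- simulate_sample_reads(p, refs, specs, cfg)
  n_assigned <- sapply(0:3, function(mm) {
    sp <- lapply(specs, function(s) { s$max_primer_mismatches <- mm; s })
    dm <- demultiplex_sample(sim$r1, sim$r2, sp)
    sum(dm$counts[names(specs)])
  })
  expect_true(all(diff(n_assigned) >= 0))
})

test_that("indistinguishable primer sets are rejected at load time", {
  a <- marker_spec("A", "ACGTACGTACGTACGTAC", "TGCATGCATGCATGCATG")
  b <- marker_spec("B", "ACGTACGTACGTACGTAG", "TGCATGCATGCATGCAAG")
  expect_error(demultiplex_sample(
    read_table("x", "ACGT", "IIII"), read_table("x", "ACGT", "IIII"),
    list(A = a, B = b)), "indistinguishable")
})
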