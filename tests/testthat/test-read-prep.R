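specs <- default_marker_specs()

test_that("three-prime trimming obeys the length floor", {
  r <- read_table(c("a", "b"), c(strrep("A", 300), strrep("C", 70)),
                  c(strrep("I", 300), strrep("I", 70)))
  expect_identical(trim_three_prime(r, 0), r)
  out <- trim_three_prime(r, 50)
  expect_equal(nrow(out), 1)         # the 70-base read would drop to 20 < 30
  expect_equal(nchar(out$bases), 250)
  expect_equal(nchar(out$quals), 250)
})

test_that("pair merging matches the brute-force overlap oracle", {
  # spec-style planted case
  r1 <- read_table("p", "AAAATTTTGGGG", strrep("I", 12))
  r2 <- read_table("p", revcomp("TTTTGGGGCCCC"), strrep("I", 12),
                   mate = "reverse")
  m <- merge_pairs(r1, r2, qc_params(three_prime_trim = 0, min_overlap = 8))
  expect_equal(m$merged$bases, "AAAATTTTGGGGCCCC")

  # identical mates fully overlapping collapse to the single sequence
  s <- rand_seq(40)
  m2 <- merge_pairs(read_table("q", s, strrep("I", 40)),
                    read_table("q", revcomp(s), strrep("I", 40),
                               mate = "reverse"),
                    qc_params(min_overlap = 10))
  expect_equal(m2$merged$bases, s)

  # randomised agreement with the oracle
  set.seed(5)
  for (i in 1:25) {
    tmpl <- rand_seq(120)
    o <- sample(15:60, 1)
    b1 <- substr(tmpl, 1, 60)
    b2rc <- substr(tmpl, 61 - o, 120)
    got <- merge_pairs(read_table("x", b1, strrep("I", nchar(b1))),
                       read_table("x", revcomp(b2rc),
                                  strrep("I", nchar(b2rc)), mate = "reverse"),
                       qc_params(min_overlap = 10))
    want <- oracle_merge(b1, b2rc, 10, 0.25)
    expect_equal(got$merged$bases, want, label = paste("merge case", i))
  }
})

test_that("mismatch-heavy overlaps are rejected at the ratio threshold", {
  b1 <- paste0(rand_seq(20), "AAAAAAAA")
  b2rc <- paste0("ATATATAA", rand_seq(20))  # 3 mismatches in 8 = 0.375
  got <- merge_pairs(read_table("x", b1, strrep("I", 28)),
                     read_table("x", revcomp(b2rc), strrep("I", 28),
                                mate = "reverse"),
                     qc_params(min_overlap = 8,
                               max_overlap_mismatch_ratio = 0.25))
  want <- oracle_merge(b1, b2rc, 8, 0.25)
  expect_equal(nrow(got$merged) == 0, is.null(want))
})

test_that("consensus takes the higher-quality base and reports max/diff quality", {
  # same sequence except one disagreement in the overlap
  b1 <- "ACGTACGTAC"
  b2 <- "ACGTACGTAC"
  substr(b2, 5, 5) <- "G"
  q1 <- int_to_phred_test(rep(30, 10))
  q2 <- int_to_phred_test(rep(20, 10))
  m <- merge_pairs(read_table("x", b1, q1),
                   read_table("x", revcomp(b2), paste(rev(strsplit(q2, "")[[1]]),
                                                      collapse = ""),
                              mate = "reverse"),
                   qc_params(min_overlap = 10))
  expect_equal(m$merged$bases, b1)  # read 1 wins at higher quality
  qv <- utf8ToInt(m$merged$quals) - 33
  expect_equal(qv[5], 10)           # |30 - 20| at the disagreement
  expect_equal(qv[1], 30)           # max(Q) at agreements
})

test_that("mean-quality filter applies an inclusive threshold", {
  m35 <- read_table("a", strrep("A", 50), int_to_phred_test(rep(35, 50)))
  m34 <- read_table("b", strrep("A", 50), int_to_phred_test(rep(34, 50)))
  mixed <- read_table("c", strrep("A", 110),
                      int_to_phred_test(c(rep(40, 100), rep(20, 10))))
  expect_equal(nrow(mean_quality_filter(m35, 35)$kept), 1)
  expect_equal(nrow(mean_quality_filter(m34, 35)$kept), 0)
  expect_equal(nrow(mean_quality_filter(mixed, 35)$kept), 1)  # mean 38.18
  # lowering the threshold never loses reads
  all3 <- rbind(m35, m34, mixed)
  kept <- sapply(c(41, 38, 35, 30, 0),
                 function(th) nrow(mean_quality_filter(all3, th)$kept))
  expect_true(all(diff(kept) >= 0))
})

test_that("global primer trimming requires both primers and the length floor", {
  sp <- specs[["16S"]]
  fwd <- concretize_test(sp$fwd_primer)
  rev <- concretize_test(sp$rev_primer)
  core <- rand_seq(180)
  full <- paste0("GA", fwd, core, revcomp(rev), "T")
  m <- read_table("a", full, strrep("I", nchar(full)))
  out <- global_primer_trim(m, sp)
  expect_equal(out$kept$bases, core)

  # missing 3' primer
  no3 <- read_table("b", paste0(fwd, core), strrep("I", nchar(fwd) + 180))
  expect_equal(nrow(global_primer_trim(no3, sp)$kept), 0)
  expect_equal(global_primer_trim(no3, sp)$rejected_primer, 1)

  # core below the marker minimum length
  short <- paste0(fwd, rand_seq(80), revcomp(rev))
  m2 <- read_table("c", short, strrep("I", nchar(short)))
  expect_equal(nrow(global_primer_trim(m2, sp)$kept), 0)
  expect_equal(global_primer_trim(m2, sp)$rejected_length, 1)
})

test_that("provenance headers are formatted and guarded", {
  expect_equal(format_header("S01", "RUN1", 7), "S01.RUN1_7")
  expect_error(format_header("S.01", "RUN1", 1), "must not contain")
  expect_error(format_header("S01", "RUN_1", 1), "must not contain")
  expect_error(format_header(c("S01", "S01"), "RUN1", c(3, 3)), "duplicate")
})

test_that("noise-free pairs survive the whole preparation chain unchanged", {
  refs <- build_reference_set(2, 1, specs, seed = 17)
  cfg <- sim_config(seed = 23, substitution_rate = 0, chimera_fraction = 0,
                    reads_per_sample = 30)
  p <- community_profile("S1", setNames(c(.5, .5),
                                        vapply(refs, `[[`, character(1),
                                               "taxon_id")))
  sim <- simulate_sample_reads(p, refs, specs, cfg)
  r1 <- strip_readthrough(sim$r1, specs)
  r2 <- strip_readthrough(sim$r2, specs)
  dm <- demultiplex_sample(r1, r2, specs)
  for (m in names(specs)) {
    pr <- prep_reads(dm$assigned[[m]]$r1, dm$assigned[[m]]$r2, specs[[m]])
    expect_equal(unname(pr$counts["primer_pass"]), unname(pr$counts["input"]))
    # every surviving sequence equals a reference core exactly
    plen_f <- nchar(specs[[m]]$fwd_primer)
    plen_r <- nchar(specs[[m]]$rev_primer)
    cores <- vapply(refs, function(r) {
      amp <- r$marker_seqs[[m]]
      substr(amp, plen_f + 1, nchar(amp) - plen_r)
    }, character(1))
    expect_true(all(pr$reads$bases %in% cores))
  }
})
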