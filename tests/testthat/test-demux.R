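test_that("exact barcode plus cut-site matching assigns and strips correctly", {
  bc <- c(s1 = "AAACCCTTT", s2 = "GGGTTTAAA")
  rd <- data.frame(
    id = c("r1", "r2", "r3", "r4"),
    seq = c(paste0("AAACCCTTT", "TGCAG", "ACGTACGT"),   # s1
            paste0("GGGTTTAAA", "TGCAG", "TTTTAAAA"),   # s2
            paste0("CCCCCCCCC", "TGCAG", "ACGTACGT"),   # unknown barcode
            paste0("AAACCCTTT", "TTCAG", "ACGTACGT")),  # bad remnant
    qual = strrep("I", 22), stringsAsFactors = FALSE)
  out <- demultiplex(rd, bc)
  expect_equal(out$samples$s1$seq, "TGCAGACGTACGT")
  expect_equal(out$samples$s2$seq, "TGCAGTTTTAAAA")
  expect_equal(out$stats$total_reads, 4L)
  expect_equal(out$stats$assigned_reads, 2L)
  expect_equal(sum(out$stats$per_sample_counts), out$stats$assigned_reads)
  ## quality trimmed in lockstep
  expect_equal(nchar(out$samples$s1$qual), nchar(out$samples$s1$seq))
  expect_error(demultiplex(rd, character(0)), "empty")
})

test_that("zero-error simulated reads all return to their truth sample", {
  cfg <- tiny_config()
  sim <- simulate_reference(cfg)
  pop <- simulate_ril_population(sim$reference, sim$variants, cfg)
  amp <- select_amplifiable(digest_genome(sim$reference, cfg), cfg)
  bcs <- make_barcodes(4L, seed = 3L)
  names(bcs) <- pop$individuals[1:4]
  rs <- generate_reads(sim$reference, sim$variants, pop, amp, bcs, cfg)
  out <- demultiplex(rs, bcs)
  expect_equal(out$stats$assigned_reads, out$stats$total_reads)
  for (s in names(bcs)) {
    truth_ids <- rs$truth$id[rs$truth$sample == s]
    expect_setequal(out$samples[[s]]$id, truth_ids)
  }
})

test_that("assignment decreases monotonically with barcode mutation rate", {
  cfg <- tiny_config()
  sim <- simulate_reference(cfg)
  pop <- simulate_ril_population(sim$reference, sim$variants, cfg)
  amp <- select_amplifiable(digest_genome(sim$reference, cfg), cfg)
  bcs <- make_barcodes(4L, seed = 3L)
  names(bcs) <- pop$individuals[1:4]
  rs <- generate_reads(sim$reference, sim$variants, pop, amp, bcs, cfg)
  assigned <- vapply(c(0, 0.02, 0.08), function(mu) {
    set.seed(17)
    rd <- rs$reads
    rd$seq <- gbsim:::mutate_substitutions(rd$seq, mu)
    demultiplex(rd, bcs)$stats$assigned_reads
  }, numeric(1))
  expect_true(all(diff(assigned) < 0))
})

test_that("adapter trimming matches the exhaustive offset-scan oracle", {
  adapter <- "AGATCGGAAGAGC"
  set.seed(42)
  mk <- function(seq) data.frame(id = "r", seq = seq, qual = strrep("I", nchar(seq)),
                                 stringsAsFactors = FALSE)
  ## read with no adapter: unchanged
  clean <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  clean <- gsub("AGA", "ATA", clean, fixed = TRUE)  # scrub chance 3-mer matches
  out <- trim_reverse_adapter(mk(clean), adapter, min_overlap = 5)
  if (is.na(oracle_trim_pos(clean, adapter, 5, 0.1))) {
    expect_equal(out$reads$seq, clean)
  }

  ## 20 bp insert + full adapter: trimmed then discarded (< 30 bp)
  short <- paste0(strrep("ACGT", 5), adapter)
  out2 <- trim_reverse_adapter(mk(short), adapter)
  expect_equal(nrow(out2$reads), 0L)
  expect_equal(out2$n_discarded, 1L)

  ## 50 bp insert + 10 bp adapter prefix with one mismatch, error rate 0.1
  insert <- paste(rep("ACGTG", 10), collapse = "")
  pre <- substr(adapter, 1, 10)
  substr(pre, 4, 4) <- "T"
  read3 <- paste0(insert, pre)
  out3 <- trim_reverse_adapter(mk(read3), adapter, min_overlap = 3,
                               max_error_rate = 0.1)
  expect_equal(oracle_trim_pos(read3, adapter, 3, 0.1), 51L)
  expect_equal(out3$reads$seq, insert)

  ## randomised agreement with the oracle
  for (i in 1:60) {
    ins_len <- sample(25:70, 1)
    ad_len <- sample(0:12, 1)
    r <- paste(sample(c("A", "C", "G", "T"), ins_len, TRUE), collapse = "")
    if (ad_len > 0) r <- paste0(r, substr(adapter, 1, ad_len))
    o <- oracle_trim_pos(r, adapter, 3, 0.1)
    res <- trim_reverse_adapter(mk(r), adapter, min_overlap = 3,
                                max_error_rate = 0.1, min_length = 1)
    expected_len <- if (is.na(o)) nchar(r) else o - 1L
    expect_equal(nchar(res$reads$seq), expected_len)
  }
})

test_that("trimming the trimmed reads changes nothing on simulated data", {
  cfg <- tiny_config()
  sim <- simulate_reference(cfg)
  pop <- simulate_ril_population(sim$reference, sim$variants, cfg)
  amp <- select_amplifiable(digest_genome(sim$reference, cfg), cfg)
  bcs <- make_barcodes(3L, seed = 5L)
  names(bcs) <- pop$individuals[1:3]
  rs <- generate_reads(sim$reference, sim$variants, pop, amp, bcs, cfg)
  dm <- demultiplex(rs, bcs)
  for (s in names(bcs)) {
    t1 <- trim_reverse_adapter(dm$samples[[s]], cfg$reverse_adapter,
                               min_overlap = 5)
    t2 <- trim_reverse_adapter(t1$reads, cfg$reverse_adapter, min_overlap = 5)
    expect_identical(t2$reads, t1$reads)
    expect_equal(t2$n_discarded, 0L)
  }
})
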