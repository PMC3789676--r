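sim_readset <- function(cfg, n_samples = 3L) {
  sim <- simulate_reference(cfg)
  pop <- simulate_ril_population(sim$reference, sim$variants, cfg)
  amp <- select_amplifiable(digest_genome(sim$reference, cfg), cfg)
  bcs <- make_barcodes(n_samples, width = cfg$barcode_length, seed = 55L)
  names(bcs) <- pop$individuals[seq_len(n_samples)]
  list(sim = sim, pop = pop, amp = amp, bcs = bcs,
       rs = generate_reads(sim$reference, sim$variants, pop, amp, bcs, cfg))
}

test_that("error-free reads are layout-exact and substring-exact to their haplotype", {
  cfg <- tiny_config()
  x <- sim_readset(cfg)
  rs <- x$rs
  expect_true(all(nchar(rs$reads$seq) == cfg$read_length_bp))
  expect_true(all(nchar(rs$reads$seq) == nchar(rs$reads$qual)))

  ## parent-B chromosome for haplotype checks
  chromB <- x$sim$reference$chromosomes
  v <- x$sim$variants
  for (i in seq_len(nrow(v)))
    substr(chromB[[v$chrom[i]]], v$pos[i] + 1L, v$pos[i] + 1L) <- v$allele_b[i]

  bcs <- x$bcs
  for (k in sample(nrow(rs$reads), 200L)) {
    tr <- rs$truth[k, ]
    read <- rs$reads$seq[k]
    ## barcode + remnant layout
    expect_identical(substr(read, 1L, 9L), unname(bcs[[tr$sample]]))
    expect_identical(substr(read, 10L, 14L), "TGCAG")
    ## genomic portion matches one of the two parental chromosomes
    ## (per-locus haplotype may mix parents, so check per-base)
    genomic <- substring(read, 10L)
    span_a <- x$sim$reference$chromosomes[[tr$chrom]]
    span_b <- chromB[[tr$chrom]]
    if (tr$strand == "+") {
      template_a <- substring(span_a, tr$frag_start - 3L, tr$frag_end)
      template_b <- substring(span_b, tr$frag_start - 3L, tr$frag_end)
    } else {
      template_a <- revcomp(substring(span_a, tr$frag_start + 1L, tr$frag_end))
      template_b <- revcomp(substring(span_b, tr$frag_start + 1L, tr$frag_end))
    }
    gl <- min(nchar(genomic), nchar(template_a))
    ga <- substr(genomic, 1L, gl)
    ok <- vapply(seq_len(gl), function(p)
      substr(ga, p, p) == substr(template_a, p, p) ||
      substr(ga, p, p) == substr(template_b, p, p), logical(1))
    expect_true(all(ok))
  }
})

test_that("read generation is byte-deterministic under a fixed seed", {
  cfg <- tiny_config()
  a <- sim_readset(cfg)$rs
  b <- sim_readset(cfg)$rs
  expect_identical(a$reads, b$reads)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq(a, f1); write_fastq(b, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("ion model puts indels in homopolymer runs and varies read length", {
  cfg <- tiny_config(platform = "ion", hp_indel_rate = 0.02)
  x <- sim_readset(cfg)
  expect_gt(length(unique(nchar(x$rs$reads$seq))), 1L)

  ## homopolymer corruption preserves the run structure: a substitution-free
  ## corrupted sequence collapses to the same base order as its template
  set.seed(9)
  template <- "GGAAAACCTTTTTG"
  for (i in 1:50) {
    out <- gbsim:::homopolymer_indels(template, rate = 0.2)
    collapse <- function(s) paste(rle(strsplit(s, "")[[1]])$values, collapse = "")
    ## runs may vanish entirely, so the collapsed corrupted string must be a
    ## subsequence of the collapsed template
    expect_true(grepl(paste(strsplit(collapse(out), "")[[1]], collapse = ".*"),
                      collapse(template)))
  }
})

test_that("lognormal pooling produces the observed uneven per-sample yields", {
  cfg <- tiny_config(depth_meanlog = log(300), depth_sdlog = 1.3)
  sim <- simulate_reference(cfg)
  pop <- simulate_ril_population(sim$reference, sim$variants, cfg)
  amp <- select_amplifiable(digest_genome(sim$reference, cfg), cfg)
  bcs <- make_barcodes(8L, seed = 77L)
  names(bcs) <- pop$individuals
  rs <- generate_reads(sim$reference, sim$variants, pop, amp, bcs, cfg)
  counts <- table(rs$truth$sample)
  expect_gt(max(counts) / min(counts), 10)
})

test_that("duplicate barcodes are rejected", {
  cfg <- tiny_config()
  sim <- simulate_reference(cfg)
  pop <- simulate_ril_population(sim$reference, sim$variants, cfg)
  amp <- select_amplifiable(digest_genome(sim$reference, cfg), cfg)
  bcs <- c(RIL001 = "AAAAAAAAA", RIL002 = "AAAAAAAAA")
  expect_error(generate_reads(sim$reference, sim$variants, pop, amp, bcs, cfg),
               "duplicate")
})
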