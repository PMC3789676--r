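test_that("binomial caller equals the enumeration oracle for all depths <= 10", {
  e <- 0.01
  for (depth in 0:10) {
    for (n_r in 0:depth) {
      n_a <- depth - n_r
      got <- call_genotype_counts(n_r, n_a, e = e)
      want <- oracle_posterior(n_r, n_a, e = e)
      if (depth == 0) {
        expect_true(is.na(got$geno))
        next
      }
      expect_equal(as.numeric(got$post), as.numeric(want), tolerance = 1e-12)
      expect_equal(got$geno, unname(which.max(want)) - 1L)
      expect_equal(got$gq,
                   min(99L, as.integer(round(-10 * log10(max(1 - max(want), 1e-10))))))
    }
  }
  ## spot values: clean homozygote and balanced het
  expect_equal(call_genotype_counts(5, 0, e = 0.01)$geno, 0L)
  expect_equal(call_genotype_counts(3, 3, e = 0.01)$geno, 1L)
  expect_equal(call_genotype_counts(0, 7, e = 0.01)$geno, 2L)
  ## RIL-informed prior suppresses marginal het calls
  expect_equal(call_genotype_counts(2, 1, e = 0.1)$geno, 1L)
  expect_equal(call_genotype_counts(2, 1, e = 0.1,
                                    prior = c(0.49, 0.02, 0.49))$geno, 0L)
})

test_that("pileup calling recovers constructed genotypes with depth and gq", {
  ## reference: one contig; reads planted to give known allele counts
  set.seed(8)
  s <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  ref <- structure(list(chromosomes = c(chr1 = s),
                        contigs = data.frame(contig_id = "c1", chrom = "chr1",
                                             start = 0L, end = 400L, cM = 0)),
                   class = "gbs_reference")
  pos <- 100L  # 0-based site position
  refbase <- substr(s, pos + 1L, pos + 1L)
  altbase <- setdiff(c("A", "C", "G", "T"), refbase)[1]
  window <- function(allele) {
    x <- substr(s, pos - 29L, pos + 30L)  # 60 bp read covering the site
    substr(x, 31L, 31L) <- allele
    x
  }
  mk <- function(n_ref, n_alt, sample) {
    n <- n_ref + n_alt
    if (n == 0) return(NULL)
    data.frame(id = sprintf("%s_%d", sample, seq_len(n)),
               contig = "c1", offset = pos - 30L, strand = "+",
               n_mismatch = 0L,
               seq_fwd = c(rep(window(refbase), n_ref), rep(window(altbase), n_alt)),
               sample = sample, stringsAsFactors = FALSE)
  }
  pl <- rbind(mk(5, 0, "s1"), mk(3, 3, "s2"), mk(0, 6, "s3"), mk(0, 0, "s4"))
  tab <- pileup_and_call(pl, ref, e = 0.01)
  i <- which(tab$sites$pos == pos)
  expect_length(i, 1L)
  expect_equal(tab$sites$ref[i], refbase)
  expect_equal(tab$sites$alt[i], altbase)
  expect_equal(unname(tab$geno[i, c("s1", "s2", "s3")]), c(0L, 1L, 2L))
  expect_equal(unname(tab$depth[i, c("s1", "s2", "s3")]), c(5, 6, 6))
  ## a sample with no coverage at the site is missing
  expect_true(!"s4" %in% colnames(tab$geno) || is.na(tab$geno[i, "s4"]))
  ## gq from the exact posterior for s1
  want <- oracle_posterior(5, 0, 0.01)
  expect_equal(unname(tab$gq[i, "s1"]),
               min(99L, as.integer(round(-10 * log10(1 - max(want))))))
})

test_that("tag path finds the SNP between two one-mismatch tags", {
  set.seed(11)
  s <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  ref <- structure(list(chromosomes = c(chr1 = s),
                        contigs = data.frame(contig_id = "c1", chrom = "chr1",
                                             start = 0L, end = 300L, cM = 0)),
                   class = "gbs_reference")
  idx <- build_index(c(c1 = s), k = 21L)
  tag_ref <- substr(s, 51L, 114L)          # 64 bp, matches the reference
  tag_alt <- tag_ref
  refb <- substr(tag_alt, 40L, 40L)
  altb <- setdiff(c("A", "C", "G", "T"), refb)[1]
  substr(tag_alt, 40L, 40L) <- altb
  reads <- list(
    s1 = data.frame(id = paste0("a", 1:6), seq = rep(tag_ref, 6),
                    qual = strrep("I", 64), stringsAsFactors = FALSE),
    s2 = data.frame(id = paste0("b", 1:6), seq = rep(tag_alt, 6),
                    qual = strrep("I", 64), stringsAsFactors = FALSE),
    s3 = data.frame(id = paste0("c", 1:6),
                    seq = c(rep(tag_ref, 3), rep(tag_alt, 3)),
                    qual = strrep("I", 64), stringsAsFactors = FALSE))
  tab <- tag_based_call(reads, idx, ref, tag_length = 64L, e = 0.01)
  expect_equal(nrow(tab$sites), 1L)
  expect_equal(tab$sites$pos, 50L + 39L)   # 0-based converted coordinate
  expect_equal(tab$sites$ref, refb)
  expect_equal(tab$sites$alt, altb)
  expect_equal(unname(tab$geno[1L, ]), c(0L, 2L, 1L))
})

test_that("tag and full-read paths agree on jointly discovered sites", {
  cfg <- tiny_config(snp_density = 0.004, depth_meanlog = log(900))
  sim <- simulate_reference(cfg)
  pop <- simulate_ril_population(sim$reference, sim$variants, cfg)
  amp <- select_amplifiable(digest_genome(sim$reference, cfg), cfg)
  bcs <- make_barcodes(6L, seed = 13L)
  names(bcs) <- pop$individuals[1:6]
  rs <- generate_reads(sim$reference, sim$variants, pop, amp, bcs, cfg)
  dm <- demultiplex(rs, bcs)
  for (s in names(bcs))
    dm$samples[[s]] <- trim_reverse_adapter(dm$samples[[s]],
                                            cfg$reverse_adapter)$reads
  idx <- build_index(sim$reference, k = 21L)
  placements <- do.call(rbind, lapply(names(bcs), function(s) {
    p <- place_reads(dm$samples[[s]], idx)
    if (nrow(p)) cbind(p, sample = s, stringsAsFactors = FALSE) else NULL
  }))
  full <- pileup_and_call(placements, sim$reference, e = 0.01)
  tags <- tag_based_call(dm$samples, idx, sim$reference,
                         tag_length = 64L, e = 0.01)
  kf <- paste(full$sites$contig, full$sites$pos)
  kt <- paste(tags$sites$contig, tags$sites$pos)
  joint <- intersect(kf, kt)
  expect_gt(length(joint), 0L)
  for (key in joint) {
    gi <- full$geno[match(key, kf), ]
    gj <- tags$geno[match(key, kt), ]
    both <- !is.na(gi) & !is.na(gj)
    expect_equal(gi[both], gj[both])
  }
})
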