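test_that("marker preprocessing matches a brute-force predicate scan", {
  set.seed(12)
  n_ind <- 40L
  mk_row <- function(miss, het) {
    x <- sample(c("A", "B"), n_ind, TRUE)
    x[sample(n_ind, round(het * n_ind))] <- "H"
    x[sample(n_ind, round(miss * n_ind))] <- NA
    x
  }
  mat <- rbind(m1 = mk_row(0.25, 0),    # > 20% missing: dropped
               m2 = mk_row(0.05, 0),    # kept
               m3 = mk_row(0.05, 0.10), # missing+het > 10%: dropped
               m4 = mk_row(0, 0.05),    # kept, H set missing
               m5 = mk_row(0, 0))
  out <- preprocess_markers(mat, params = map_build_params())
  expect_setequal(rownames(out), c("m2", "m4", "m5"))
  expect_false(any(out == "H", na.rm = TRUE))

  ## one marker per contig: least missing wins, ties to lowest position
  contigs <- data.frame(marker = c("m2", "m4", "m5"),
                        contig = c("c1", "c1", "c2"),
                        pos = c(10L, 5L, 1L))
  out2 <- preprocess_markers(mat, contigs, map_build_params())
  expect_setequal(rownames(out2), c("m4", "m5"))  # m4 has less missing than m2

  ## brute-force scan over a random matrix (no contig step)
  set.seed(13)
  big <- matrix(sample(c("A", "B", "H", NA), 50 * 30, TRUE,
                       prob = c(0.44, 0.44, 0.04, 0.08)), 50, 30)
  rownames(big) <- sprintf("x%02d", 1:50)
  got <- rownames(preprocess_markers(big, params = map_build_params()))
  want <- rownames(big)[vapply(seq_len(50), function(i) {
    r <- big[i, ]
    mean(is.na(r)) <= 0.20 &&
      (mean(is.na(r)) + mean(r == "H", na.rm = TRUE) * mean(!is.na(r))) <= 0.10
  }, logical(1))]
  expect_equal(got, want)
  expect_error(preprocess_markers(big[0, , drop = FALSE]))
})

test_that("two-point estimates behave at the linkage extremes", {
  x <- rep(c("A", "B"), each = 47)
  ## identical markers: r 0, overwhelming linkage
  r0 <- recombination_fraction(x, x)
  expect_equal(r0$r_hat, 0)
  expect_lt(r0$p_value, 1e-20)
  ## 47 of 94 recombinant: r 0.5, chi-square p ~ 1
  y <- x
  y[seq(1, 94, by = 2)] <- ifelse(x[seq(1, 94, by = 2)] == "A", "B", "A")
  r5 <- recombination_fraction(x, y)
  expect_equal(r5$r_hat, round(47 / 94, 4), tolerance = 1e-3)
  expect_gt(r5$p_value, 0.5)
  expect_equal(r5$n_informative, 94L)
  ## no informative individuals
  rn <- recombination_fraction(c("A", NA), c(NA, "B"))
  expect_true(is.na(rn$r_hat))
  expect_equal(rn$n_informative, 0L)
})

test_that("simulated 10 cM marker pairs show the RIL-expanded recombination rate", {
  ## single-meiosis oracle: Haldane inverse of 10 cM
  r_meiosis <- (1 - exp(-2 * 10 / 100)) / 2
  expect_equal(r_meiosis, 0.0906, tolerance = 1e-3)
  ## on fixed SSD RILs two-point disagreement is map-expanded: R = 2r/(1+2r)
  R_expected <- 2 * r_meiosis / (1 + 2 * r_meiosis)

  cfg <- sim_config(n_chromosomes = 1, chrom_length_bp = 20000L,
                    snp_density = 0, n_rils = 400L, map_length_cM = 10,
                    selfing_generations = 25L, rng_seed = 14L)
  sim <- simulate_reference(cfg)
  variants <- data.frame(chrom = "chr1H", pos = c(0L, 19999L),
                         allele_a = "A", allele_b = "C")
  pop <- simulate_ril_population(sim$reference, variants, cfg)
  est <- recombination_fraction(pop$calls[1, ], pop$calls[2, ])
  se <- sqrt(R_expected * (1 - R_expected) / est$n_informative)
  expect_lt(abs(est$r_hat - R_expected), 3 * se)
})

test_that("kosambi matches its closed form and dominates the linear map", {
  expect_equal(kosambi(0), 0)
  expect_equal(kosambi(0.25), 25 * log(3))
  ## first-order limit d ~ 100 r
  expect_equal(kosambi(1e-4), 100 * 1e-4, tolerance = 1e-4)
  r <- seq(0.01, 0.49, by = 0.01)
  d <- kosambi(r)
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= 100 * r))
  expect_error(kosambi(0.5), "0.5")
})

test_that("linkage grouping recovers chromosomes and isolates unlinked markers", {
  cfg <- sim_config(n_chromosomes = 7, chrom_length_bp = 100000L,
                    snp_density = 6e-4, n_rils = 94L, map_length_cM = 150,
                    rng_seed = 18L)
  sim <- simulate_reference(cfg)
  pop <- simulate_ril_population(sim$reference, sim$variants, cfg)
  mat <- pop$calls
  rownames(mat) <- paste0(pop$loci$chrom, ":", pop$loci$pos)
  pre <- preprocess_markers(mat, params = map_build_params())
  groups <- group_markers(pre, map_build_params())
  expect_equal(length(groups), 7L)
  ## groups correspond to chromosomes exactly
  for (g in groups) {
    chroms <- unique(sub(":.*", "", g))
    expect_length(chroms, 1L)
  }

  ## grouping equals brute-force connected components on the p-value graph
  sub <- pre[1:40, ]
  pl <- gbsim:::pairwise_linkage(sub)
  adj <- pl$p <= 1e-5; diag(adj) <- FALSE
  reach <- function(a) {
    seen <- a
    repeat {
      nxt <- unique(c(seen, which(rowSums(adj[, seen, drop = FALSE]) > 0)))
      if (length(nxt) == length(seen)) return(sort(seen))
      seen <- nxt
    }
  }
  got <- group_markers(sub, map_build_params())
  for (g in got) {
    idx <- match(g, rownames(sub))
    expect_setequal(idx, reach(idx[1]))
  }

  ## independent markers stay singletons
  set.seed(20)
  unl <- matrix(sample(c("A", "B"), 6 * 94, TRUE), 6, 94,
                dimnames = list(paste0("u", 1:6), NULL))
  expect_equal(lengths(group_markers(unl, map_build_params())),
               setNames(rep(1L, 6), NULL), ignore_attr = TRUE)
})

test_that("error-free ordering recovers the true marker order up to reversal", {
  ## a population large enough to resolve every adjacent bin exactly
  cfg <- sim_config(n_chromosomes = 1, chrom_length_bp = 300000L,
                    snp_density = 2e-4, n_rils = 250L, map_length_cM = 120,
                    rng_seed = 25L)
  sim <- simulate_reference(cfg)
  pop <- simulate_ril_population(sim$reference, sim$variants, cfg)
  mat <- pop$calls
  rownames(mat) <- sprintf("m%04d", seq_len(nrow(mat)))  # id order = true order
  pre <- preprocess_markers(mat, params = map_build_params())
  om <- order_markers(pre)
  truth_rank <- as.integer(sub("m", "", om$marker))
  ## collapse cosegregating bins: mean true position per bin must be monotone
  bin_means <- tapply(truth_rank, om$cM, mean)
  bin_means <- bin_means[order(as.numeric(names(bin_means)))]
  expect_true(all(diff(bin_means) > 0) || all(diff(bin_means) < 0))

  ## cM positions are non-decreasing and 2-marker groups are exact
  expect_true(all(diff(om$cM) >= 0))
  two <- order_markers(pre[c(1, 10), ])
  rf <- recombination_fraction(pre[1, ], pre[10, ])
  expect_equal(max(two$cM), kosambi(rf$r_hat))

  ## at 94 lines local bin swaps are possible but the order stays near-true
  cfg94 <- sim_config(n_chromosomes = 1, chrom_length_bp = 300000L,
                      snp_density = 2e-4, n_rils = 94L, map_length_cM = 120,
                      rng_seed = 25L)
  sim94 <- simulate_reference(cfg94)
  pop94 <- simulate_ril_population(sim94$reference, sim94$variants, cfg94)
  m94 <- pop94$calls
  rownames(m94) <- sprintf("m%04d", seq_len(nrow(m94)))
  om94 <- order_markers(preprocess_markers(m94, params = map_build_params()))
  tr94 <- as.integer(sub("m", "", om94$marker))
  expect_gt(abs(cor(seq_along(tr94), tr94, method = "spearman")), 0.999)
})

test_that("2-opt refinement never increases the adjacent recombination sum", {
  set.seed(30)
  R <- matrix(runif(15 * 15, 0.05, 0.45), 15, 15)
  R <- (R + t(R)) / 2; diag(R) <- 0
  o0 <- sample(15)
  o1 <- gbsim:::two_opt(o0, R)
  s <- function(o) sum(R[cbind(o[-length(o)], o[-1])])
  expect_lte(s(o1), s(o0))
})
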