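test_that("position merging, presence flags and venn regions follow set algebra", {
  t1 <- toy_table(matrix(0L, 3, 2))                 # sites 0,1,2
  t2 <- toy_table(matrix(0L, 3, 2)); t2$sites$pos <- c(1L, 2L, 3L)
  m <- merge_by_position(list(A = t1, B = t2))
  expect_equal(nrow(m$sites), 4L)
  v <- venn_counts(m)
  expect_equal(unname(v[c("A", "B", "A&B")]), c(1L, 1L, 2L))
  expect_equal(sum(v), 4L)

  ## identical tables: everything shared
  m2 <- merge_by_position(list(A = t1, B = t1))
  expect_equal(unname(venn_counts(m2)[c("A", "B", "A&B")]), c(0L, 0L, 3L))

  ## disjoint site sets
  t3 <- toy_table(matrix(0L, 2, 2)); t3$sites$pos <- c(10L, 11L)
  m3 <- merge_by_position(list(A = t1, B = t3))
  expect_equal(unname(venn_counts(m3)["A&B"]), 0L)

  ## three-way counts equal a brute-force bit-pattern tally
  set.seed(5)
  keys <- lapply(1:3, function(i) sort(sample(0:30, 15)))
  tabs <- lapply(keys, function(k) {
    t <- toy_table(matrix(0L, length(k), 2)); t$sites$pos <- k; t
  })
  names(tabs) <- c("X", "Y", "Z")
  vc <- venn_counts(merge_by_position(tabs))
  all_pos <- sort(unique(unlist(keys)))
  pat <- sapply(all_pos, function(p) paste(c("X", "Y", "Z")[
    c(p %in% keys[[1]], p %in% keys[[2]], p %in% keys[[3]])], collapse = "&"))
  brute <- table(pat)
  expect_equal(unname(vc[names(brute)]), unname(as.integer(brute)))
  expect_error(venn_counts(merge_by_position(c(tabs, list(W = tabs$X)))),
               "2 or 3")
})

test_that("discordance counts hand-checkable call pairs and is symmetric", {
  gx <- matrix(c(0L, 0L, 2L, 2L), 2, 2)
  gy <- matrix(c(0L, 0L, 2L, 0L), 2, 2)   # exactly one of four pairs differs
  tx <- toy_table(gx); ty <- toy_table(gy)
  m <- merge_by_position(list(A = tx, B = ty))
  r <- percent_discordant(m, "A", "B")
  expect_equal(r$compared_calls, 4L)
  expect_equal(r$discordant_calls, 1L)
  expect_equal(r$percent_discordant, 25)
  r2 <- percent_discordant(m, "B", "A")
  expect_equal(r2$percent_discordant, r$percent_discordant)

  ## identical tables: zero discordance
  m0 <- merge_by_position(list(A = tx, B = tx))
  expect_equal(percent_discordant(m0)$percent_discordant, 0)

  ## missing calls are never compared; het vs hom is discordant
  gz <- matrix(c(NA, 1L, 2L, 2L), 2, 2)
  mz <- merge_by_position(list(A = tx, B = toy_table(gz)))
  rz <- percent_discordant(mz)
  expect_equal(rz$compared_calls, 3L)
  expect_equal(rz$discordant_calls, 1L)

  ## allele-conflict sites are excluded from comparison
  tc <- toy_table(gy); tc$sites$alt[1] <- "G"
  mc <- merge_by_position(list(A = tx, B = tc))
  expect_equal(sum(mc$conflict), 1L)
  expect_equal(percent_discordant(mc)$shared_snps, 1L)
})

test_that("independent 0.5% errors on two platforms sum to ~1% discordance", {
  set.seed(33)
  truth <- matrix(sample(c(0L, 2L), 1000 * 50, TRUE), 1000, 50)
  corrupt <- function(g, seed) {
    set.seed(seed)
    flip <- matrix(runif(length(g)) < 0.005, nrow(g), ncol(g))
    g[flip] <- 2L - g[flip]
    g
  }
  m <- merge_by_position(list(A = toy_table(corrupt(truth, 1)),
                              B = toy_table(corrupt(truth, 2))))
  r <- percent_discordant(m)
  p <- 2 * 0.005 * 0.995
  se <- sqrt(p * (1 - p) / r$compared_calls)
  expect_lt(abs(r$percent_discordant / 100 - p), 3 * se)
})

test_that("parental encoding reproduces the simulation truth matrix", {
  cfg <- tiny_config()
  sim <- simulate_reference(cfg)
  pop <- add_parents(simulate_ril_population(sim$reference, sim$variants, cfg))
  tab <- truth_genotype_table(pop, sim$variants)
  enc <- encode_parental(tab, "P1", "P2")
  expect_equal(enc$samples, pop$individuals[1:8])
  expect_equal(nrow(enc$sites), nrow(pop$loci))  # parents are fixed: all encodable
  expect_identical(unname(enc$calls), unname(pop$calls[, enc$samples]))

  ## uninformative sites are dropped: make parents identical at site 1
  tab2 <- tab
  tab2$geno[1L, c("P1", "P2")] <- 0L
  enc2 <- encode_parental(tab2, "P1", "P2")
  expect_equal(nrow(enc2$sites), nrow(pop$loci) - 1L)
  expect_error(encode_parental(tab, "P1", "nope"), "absent")
})
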