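# Shared fixtures and independent oracles, all built in code.

tiny_config <- function(...) {
  defaults <- list(n_chromosomes = 2, chrom_length_bp = 60000L,
                   contig_length_bp = 2000L, snp_density = 0.003,
                   n_rils = 8L, depth_meanlog = log(600), depth_sdlog = 0.3,
                   sub_error_rate = 0, hp_indel_rate = 0, rng_seed = 101L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# Build a genotype_table directly from an integer 0/1/2/NA matrix.
toy_table <- function(geno, depth = NULL, gq = NULL, provenance = "toy",
                      contig = "c1") {
  n <- nrow(geno)
  sites <- data.frame(contig = rep(contig, n), pos = seq_len(n) - 1L,
                      ref = rep("A", n), alt = rep("C", n),
                      stringsAsFactors = FALSE)
  samples <- paste0("s", seq_len(ncol(geno)))
  big <- matrix(99, n, ncol(geno))
  genotype_table(sites, samples, geno,
                 depth = depth %||% big, gq = gq %||% big,
                 provenance = provenance)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent caller oracle: enumerate every ordered read-outcome string of
# the given depth, accumulate P(outcome | genotype) read by read, and sum
# over outcomes matching the observed counts.  No closed-form shortcut.
oracle_posterior <- function(n_r, n_a, e, prior = c(1, 1, 1) / 3) {
  depth <- n_r + n_a
  p_read <- list(hom_ref = c(r = 1 - e, a = e),
                 het     = c(r = 0.5, a = 0.5),
                 hom_alt = c(r = e, a = 1 - e))
  like <- vapply(p_read, function(p) {
    if (depth == 0) return(1)
    tot <- 0
    for (mask in 0:(2^depth - 1)) {
      bits <- as.integer(intToBits(mask))[seq_len(depth)]
      if (sum(bits == 0) != n_r) next
      pr <- 1
      for (b in bits) pr <- pr * if (b == 0) p["r"] else p["a"]
      tot <- tot + pr
    }
    tot
  }, numeric(1))
  post <- like * prior
  post / sum(post)
}

# Direct per-site filter predicates, written independently of the package.
oracle_site_keep <- function(g_row, max_missing, min_maf, max_het) {
  n <- length(g_row)
  miss <- sum(is.na(g_row))
  called <- g_row[!is.na(g_row)]
  if (length(called) == 0) return(FALSE)
  if (miss / n > max_missing) return(FALSE)
  a <- 2 * sum(called == 0) + sum(called == 1)
  b <- 2 * sum(called == 2) + sum(called == 1)
  if (min(a, b) / (a + b) < min_maf) return(FALSE)
  sum(called == 1) / length(called) < max_het
}

# Exhaustive semi-global adapter scan: leftmost start whose overlap with the
# adapter prefix has at least min_overlap bases and mismatch fraction at
# most max_err.
oracle_trim_pos <- function(read, adapter, min_overlap, max_err) {
  rl <- nchar(read); al <- nchar(adapter)
  for (j in seq_len(rl)) {
    ov <- min(al, rl - j + 1)
    if (ov < min_overlap) next
    mism <- sum(strsplit(substr(read, j, j + ov - 1), "")[[1]] !=
                strsplit(substr(adapter, 1, ov), "")[[1]])
    if (mism <= max_err * ov) return(j)
  }
  NA_integer_
}

# Single-locus selfing Markov chain: P(het) after g generations of selfing
# starting from a het F1, iterated numerically (not the closed form).
oracle_het_after_selfing <- function(g) {
  p <- c(AA = 0, AB = 1, BB = 0)
  for (i in seq_len(g)) {
    p <- c(AA = p["AA"] + p["AB"] / 4,
           AB = p["AB"] / 2,
           BB = p["BB"] + p["AB"] / 4)
    names(p) <- c("AA", "AB", "BB")
  }
  p[["AB"]]
}
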