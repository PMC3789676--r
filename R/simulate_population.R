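#' Simulate an F8-derived RIL population by single seed descent
#'
#' Each line descends from an independent F2 (two gametes of the F1 between
#' the two inbred parents), followed by `selfing_generations` rounds of
#' single seed descent.  Meioses place a Poisson(`map_length_cM`/100) number
#' of crossovers per chromosome uniformly in genetic (cM) position with no
#' interference; physical position maps linearly to cM.
#'
#' With `g` generations of selfing after the F1 the expected residual
#' heterozygosity per locus is `0.5^g` (0.78\% for F8-derived lines),
#' matching the 1--2\% heterozygosity expected of advanced RILs, and the
#' expected frequency of either parental allele at every locus is 50\%.
#'
#' @param ref a `gbs_reference` from [simulate_reference()].
#' @param variants parental variant table from [simulate_reference()].
#' @param config a [sim_config()].
#' @param seed integer seed; defaults to `config$rng_seed + 1`.
#' @return an object of class `ril_population`:
#'   \describe{
#'     \item{individuals}{sample ids (`RIL001`, ...).}
#'     \item{loci}{data.frame `chrom, pos, cM` (0-based positions).}
#'     \item{calls}{loci x individuals character matrix over `"A","B","H"`.}
#'     \item{hap1, hap2}{loci x individuals 0/1 matrices (0 = parent-A
#'       allele, 1 = parent-B allele).}
#'     \item{crossovers}{per individual, per chromosome, the cM positions of
#'       all crossovers drawn in that line's pedigree.}
#'   }
#' @examples
#' cfg <- sim_config(n_chromosomes = 1, chrom_length_bp = 30000,
#'                   n_rils = 10, rng_seed = 3)
#' sim <- simulate_reference(cfg)
#' pop <- simulate_ril_population(sim$reference, sim$variants, cfg)
#' mean(pop$calls == "H")
#' @export
simulate_ril_population <- function(ref, variants, config,
                                    seed = config$rng_seed + 1L) {
  if (nrow(variants) == 0L) stop("no parental variants to genotype")
  set.seed(seed)
  chroms <- names(ref$chromosomes)
  L <- nchar(ref$chromosomes[[1]])
  ord <- order(match(variants$chrom, chroms), variants$pos)
  variants <- variants[ord, , drop = FALSE]
  loci <- data.frame(chrom = variants$chrom, pos = variants$pos,
                     cM = config$map_length_cM * variants$pos / L,
                     stringsAsFactors = FALSE)
  by_chrom <- split(seq_len(nrow(loci)), factor(loci$chrom, levels = chroms))

  n <- config$n_rils
  ids <- sprintf("RIL%03d", seq_len(n))
  m <- nrow(loci)
  hap1 <- matrix(0L, m, n, dimnames = list(NULL, ids))
  hap2 <- hap1
  xovers <- vector("list", n)
  names(xovers) <- ids

  for (j in seq_len(n)) {
    ind_x <- setNames(vector("list", length(chroms)), chroms)
    h1 <- integer(m); h2 <- integer(m)
    for (ch in chroms) {
      idx <- by_chrom[[ch]]
      cm <- loci$cM[idx]
      ## F1 haplotypes: one from each parent
      a <- rep(0L, length(idx)); b <- rep(1L, length(idx))
      xo_all <- numeric(0)
      g1 <- make_gamete(a, b, cm, config$map_length_cM)
      g2 <- make_gamete(a, b, cm, config$map_length_cM)
      xo_all <- c(xo_all, attr(g1, "xo"), attr(g2, "xo"))
      x <- g1; y <- g2
      for (gen in seq_len(config$selfing_generations - 1L)) {
        n1 <- make_gamete(x, y, cm, config$map_length_cM)
        n2 <- make_gamete(x, y, cm, config$map_length_cM)
        xo_all <- c(xo_all, attr(n1, "xo"), attr(n2, "xo"))
        x <- as.integer(n1); y <- as.integer(n2)
      }
      h1[idx] <- x; h2[idx] <- y
      ind_x[[ch]] <- sort(xo_all)
    }
    hap1[, j] <- h1; hap2[, j] <- h2
    xovers[[j]] <- ind_x
  }

  s <- hap1 + hap2
  calls <- matrix(c("A", "H", "B")[s + 1L], m, n, dimnames = list(NULL, ids))
  structure(list(individuals = ids, loci = loci, calls = calls,
                 hap1 = hap1, hap2 = hap2, crossovers = xovers),
            class = "ril_population")
}

## One meiotic product of a diploid (h1, h2) at loci with cM positions `cm`.
## Crossover count ~ Poisson(map_len/100); uniform placement in cM.
make_gamete <- function(h1, h2, cm, map_len) {
  n_xo <- rpois(1L, map_len / 100)
  xo <- if (n_xo > 0L) sort(runif(n_xo, 0, map_len)) else numeric(0)
  seg <- findInterval(cm, xo)
  pick <- (seg + sample.int(2L, 1L)) %% 2L
  out <- ifelse(pick == 0L, h1, h2)
  attr(out, "xo") <- xo
  out
}

#' @export
print.ril_population <- function(x, ...) {
  cat(sprintf("RIL population: %d lines x %d loci; %.2f%% heterozygous calls\n",
              length(x$individuals), nrow(x$loci),
              100 * mean(x$calls == "H")))
  invisible(x)
}

#' Parental genotype matrices for the simulated cross
#'
#' Appends the two inbred parents (`P1` fixed for the A allele, `P2` for the
#' B allele) to a simulated population so they can be sequenced and used for
#' parent-of-origin encoding downstream.
#'
#' @param pop a `ril_population`.
#' @return a `ril_population` with two extra individuals `P1` and `P2`.
#' @export
add_parents <- function(pop) {
  m <- nrow(pop$loci)
  if (all(c("P1", "P2") %in% pop$individuals)) return(pop)
  pop$hap1 <- cbind(pop$hap1, P1 = rep(0L, m), P2 = rep(1L, m))
  pop$hap2 <- cbind(pop$hap2, P1 = rep(0L, m), P2 = rep(1L, m))
  pop$calls <- cbind(pop$calls, P1 = rep("A", m), P2 = rep("B", m))
  pop$individuals <- c(pop$individuals, "P1", "P2")
  pop
}

#' Minor allele frequency per locus of an A/B/H call matrix
#'
#' Heterozygous calls contribute half a count to each allele; missing calls
#' (NA) are excluded.
#'
#' @param calls character matrix over `"A","B","H"` and NA (loci x samples).
#' @return numeric vector of per-locus minor allele frequencies (NA where a
#'   locus has no non-missing calls).
#' @export
locus_maf <- function(calls) {
  nA <- rowSums(calls == "A", na.rm = TRUE) + 0.5 * rowSums(calls == "H", na.rm = TRUE)
  nB <- rowSums(calls == "B", na.rm = TRUE) + 0.5 * rowSums(calls == "H", na.rm = TRUE)
  tot <- nA + nB
  maf <- pmin(nA, nB) / tot
  maf[tot == 0] <- NA_real_
  maf
}
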