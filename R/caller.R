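#' Binomial-likelihood genotype call from allele counts
#'
#' For per-sample counts `n_r` (reference allele) and `n_a` (alternate
#' allele) and a symmetric per-base error rate `e`, the three genotype
#' likelihoods are
#' `L(hom_ref) = (1-e)^n_r * e^n_a`,
#' `L(hom_alt) = e^n_r * (1-e)^n_a`,
#' `L(het) = 0.5^(n_r+n_a)`.
#' The call is the maximum-posterior genotype under `prior`, with genotype
#' quality `GQ = round(-10*log10(1 - posterior_max))` capped at 99.
#' Zero-depth samples are missing.
#'
#' @param n_r,n_a integer vectors of reference/alternate allele counts.
#' @param e per-base error rate in (0, 0.5).
#' @param prior length-3 prior over (hom_ref, het, hom_alt); default
#'   uniform.  A RIL-informed prior would down-weight the het class, e.g.
#'   `c(0.49, 0.02, 0.49)`.
#' @return list of vectors `geno` (0/1/2/NA), `gq`, and the posterior
#'   matrix `post`.
#' @examples
#' call_genotype_counts(5, 0, e = 0.01)$geno
#' @export
call_genotype_counts <- function(n_r, n_a, e = 0.01,
                                 prior = c(1, 1, 1) / 3) {
  stopifnot(e > 0, e < 0.5, length(prior) == 3L, all(prior > 0))
  n_r <- as.numeric(n_r); n_a <- as.numeric(n_a)
  ll <- cbind(
    hom_ref = n_r * log1p(-e) + n_a * log(e),
    het     = (n_r + n_a) * log(0.5),
    hom_alt = n_r * log(e) + n_a * log1p(-e)
  )
  ll <- ll + rep(log(prior), each = length(n_r))
  mx <- apply(ll, 1L, max)
  post <- exp(ll - mx)
  post <- post / rowSums(post)
  geno <- max.col(post, ties.method = "first") - 1L
  pmax_ <- post[cbind(seq_along(geno), geno + 1L)]
  gq <- pmin(99L, as.integer(round(-10 * log10(pmax(1 - pmax_, 1e-10)))))
  zero <- (n_r + n_a) == 0
  geno[zero] <- NA_integer_
  gq[zero] <- NA_integer_
  list(geno = geno, gq = gq, post = post)
}

#' Pileup placed reads and call genotypes at variant sites
#'
#' Builds a per-sample pileup over contig positions from ungapped read
#' placements, nominates every position where a non-reference base is
#' observed, and calls genotypes with the binomial caller.  At each site the
#' reference allele is the reference base and the alternate allele the most
#' frequent non-reference base pooled over samples; sites where more than
#' two alleles segregate (pooled count >= 2 each) are dropped.  Reads
#' carrying neither site allele at a site are excluded from its depth.
#'
#' @param placements data.frame from [place_reads()] with an additional
#'   `sample` column (or a named list of per-sample placement frames).
#' @param ref a `gbs_reference` (for contig reference bases).
#' @param e per-base error rate for the caller.
#' @param prior genotype prior, see [call_genotype_counts()].
#' @param min_alt_obs minimum pooled count of the alternate allele for a
#'   site to be nominated (default 1).
#' @param provenance dataset label stored in the result.
#' @return a [genotype_table()].
#' @export
pileup_and_call <- function(placements, ref, e = 0.01,
                            prior = c(1, 1, 1) / 3, min_alt_obs = 1L,
                            provenance = "full-read") {
  if (is.list(placements) && !is.data.frame(placements)) {
    placements <- do.call(rbind, lapply(names(placements), function(s) {
      p <- placements[[s]]
      if (nrow(p)) cbind(p, sample = s, stringsAsFactors = FALSE) else NULL
    }))
  }
  stopifnot(is.data.frame(placements), "sample" %in% names(placements))
  samples <- sort(unique(placements$sample))
  cseqs <- contig_sequences(ref)

  pile <- expand_pileup(placements)
  ## reference base at every piled position
  pile[, ref_base := substring(cseqs[contig], pos + 1L, pos + 1L)]

  ## candidate sites: any non-reference observation
  pooled <- pile[, .(n = .N), by = .(contig, pos, base, ref_base)]
  nonref <- pooled[base != ref_base]
  cand <- nonref[, .(alt_n = sum(n)), by = .(contig, pos, ref_base)]
  cand <- cand[alt_n >= min_alt_obs]
  if (nrow(cand) == 0L) {
    empty <- data.frame(contig = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        stringsAsFactors = FALSE)
    return(genotype_table(empty, samples,
                          matrix(NA_integer_, 0L, length(samples)),
                          provenance = provenance))
  }

  ## alternate allele = most frequent non-reference base; drop >2-allelic
  site_alleles <- nonref[cand, on = c("contig", "pos")]
  setorder(site_alleles, contig, pos, -n, base)
  alt_tab <- site_alleles[, .(alt = base[1L],
                              n_seg = 1L + sum(n >= 2L)), by = .(contig, pos)]
  alt_tab <- alt_tab[n_seg <= 2L]
  sites <- merge(cand, alt_tab, by = c("contig", "pos"))
  setorder(sites, contig, pos)

  ## per-sample counts of the two site alleles
  per <- pile[, .(n = .N), by = .(contig, pos, base, sample)]
  per <- per[sites[, .(contig, pos, ref_base, alt)], on = c("contig", "pos")]
  nr <- dcast_counts(per[base == ref_base], sites, samples)
  na_ <- dcast_counts(per[base == alt], sites, samples)

  cl <- call_genotype_counts(as.vector(nr), as.vector(na_), e, prior)
  geno <- matrix(cl$geno, nrow(sites), length(samples))
  gq <- matrix(cl$gq, nrow(sites), length(samples))
  site_df <- data.frame(contig = sites$contig, pos = sites$pos,
                        ref = sites$ref_base, alt = sites$alt,
                        stringsAsFactors = FALSE)
  genotype_table(site_df, samples, geno, depth = nr + na_, gq = gq,
                 n_ref = nr, n_alt = na_, provenance = provenance)
}

## Expand placements into one row per covered base.
expand_pileup <- function(placements) {
  lens <- nchar(placements$seq_fwd)
  chars <- strsplit(placements$seq_fwd, "", fixed = TRUE)
  data.table::data.table(
    sample = rep(placements$sample, lens),
    contig = rep(placements$contig, lens),
    pos = unlist(lapply(seq_len(nrow(placements)), function(i) {
      placements$offset[i] + 0:(lens[i] - 1L)
    })),
    base = unlist(chars)
  )
}

## counts matrix (sites x samples) from a long count table
dcast_counts <- function(long, sites, samples) {
  m <- matrix(0, nrow(sites), length(samples),
              dimnames = list(NULL, samples))
  if (nrow(long)) {
    i <- match(paste(long$contig, long$pos), paste(sites$contig, sites$pos))
    j <- match(long$sample, samples)
    m[cbind(i, j)] <- long$n
  }
  m
}

#' Tag-based genotype calling from collapsed read prefixes
#'
#' Emulates a tag-counting pipeline: reads are truncated to `tag_length`
#' bases from the cut-site remnant (shorter reads dropped) and collapsed to
#' unique tags with per-sample counts.  Tags are placed uniquely on the
#' reference; tags sharing a placement and differing at exactly one base
#' define a SNP, whose tag-relative offset is converted to contig
#' coordinates by adding the placement offset (the degenerate CIGAR case of
#' ungapped placement).  Per-sample genotypes come from tag counts through
#' the same binomial rule as the full-read path.
#'
#' @param sample_reads named list of per-sample read data.frames
#'   (`id, seq, qual`), as produced by [demultiplex()].
#' @param index a `kmer_index`.
#' @param ref a `gbs_reference`.
#' @param tag_length tag truncation length (default 64).
#' @param e,prior caller parameters, see [call_genotype_counts()].
#' @param max_mismatch_frac placement mismatch gate.
#' @return a [genotype_table()] with provenance `"tag"`.
#' @export
tag_based_call <- function(sample_reads, index, ref, tag_length = 64L,
                           e = 0.01, prior = c(1, 1, 1) / 3,
                           max_mismatch_frac = 0.05) {
  stopifnot(tag_length >= index$k)
  samples <- names(sample_reads)
  long <- data.table::rbindlist(lapply(samples, function(s) {
    sq <- sample_reads[[s]]$seq
    sq <- sq[nchar(sq) >= tag_length]
    if (length(sq) == 0L) return(NULL)
    data.table::data.table(sample = s, tag = substr(sq, 1L, tag_length))
  }))
  if (is.null(long) || nrow(long) == 0L) stop("no reads of tag length")
  counts <- long[, .(n = .N), by = .(tag, sample)]
  tags <- unique(counts$tag)

  placed <- place_reads(data.frame(id = tags, seq = tags,
                                   stringsAsFactors = FALSE),
                        index, max_mismatch_frac)
  if (nrow(placed) == 0L)
    stop("no tags could be placed on the reference")

  ## pair tags sharing a placement window and differing at exactly one base
  placed$grp <- paste(placed$contig, placed$offset, placed$strand)
  cseqs <- contig_sequences(ref)
  site_rows <- list()
  for (g in unique(placed$grp)) {
    gi <- which(placed$grp == g)
    if (length(gi) < 2L) next
    for (a in seq_along(gi)[-length(gi)]) for (b in (a + 1L):length(gi)) {
      s1 <- placed$seq_fwd[gi[a]]; s2 <- placed$seq_fwd[gi[b]]
      d <- which(utf8ToInt(s1) != utf8ToInt(s2))
      if (length(d) != 1L) next
      ctg <- placed$contig[gi[a]]
      pos <- placed$offset[gi[a]] + d - 1L
      refb <- substring(cseqs[[ctg]], pos + 1L, pos + 1L)
      b1 <- substring(s1, d, d); b2 <- substring(s2, d, d)
      if (refb != b1 && refb != b2) next
      altb <- if (refb == b1) b2 else b1
      site_rows[[length(site_rows) + 1L]] <-
        data.frame(contig = ctg, pos = pos, ref = refb, alt = altb,
                   tag_ref = placed$id[gi[if (refb == b1) a else b]],
                   tag_alt = placed$id[gi[if (refb == b1) b else a]],
                   stringsAsFactors = FALSE)
    }
  }
  if (length(site_rows) == 0L) stop("no SNPs discovered by the tag path")
  sd_ <- do.call(rbind, site_rows)

  ## deduplicate by site, keeping the deepest-supported tag pair
  pooled_tag <- counts[, .(tot = sum(n)), by = tag]
  sd_$support <- pooled_tag$tot[match(sd_$tag_ref, pooled_tag$tag)] +
    pooled_tag$tot[match(sd_$tag_alt, pooled_tag$tag)]
  sd_ <- sd_[order(sd_$contig, sd_$pos, -sd_$support), , drop = FALSE]
  sd_ <- sd_[!duplicated(paste(sd_$contig, sd_$pos)), , drop = FALSE]

  n_sites <- nrow(sd_)
  nr <- matrix(0, n_sites, length(samples), dimnames = list(NULL, samples))
  na_ <- nr
  cmat <- dcast_tag_counts(counts, samples)
  nr[] <- cmat[match(sd_$tag_ref, rownames(cmat)), , drop = FALSE]
  na_[] <- cmat[match(sd_$tag_alt, rownames(cmat)), , drop = FALSE]
  cl <- call_genotype_counts(as.vector(nr), as.vector(na_), e, prior)
  geno <- matrix(cl$geno, n_sites, length(samples))
  gq <- matrix(cl$gq, n_sites, length(samples))
  site_df <- sd_[, c("contig", "pos", "ref", "alt")]
  rownames(site_df) <- NULL
  genotype_table(site_df, samples, geno, depth = nr + na_, gq = gq,
                 n_ref = nr, n_alt = na_, provenance = "tag")
}

dcast_tag_counts <- function(counts, samples) {
  tags <- unique(counts$tag)
  m <- matrix(0, length(tags), length(samples),
              dimnames = list(tags, samples))
  m[cbind(match(counts$tag, tags), match(counts$sample, samples))] <- counts$n
  m
}
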