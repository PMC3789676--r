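#' Simulate a reference genome with anchored contigs and parental variants
#'
#' Generates i.i.d.-uniform chromosome sequences, tiles each chromosome with
#' contigs of `contig_length_bp` carrying genetic (cM) anchor positions
#' obtained by linear scaling of physical position to `map_length_cM`, and
#' plants biallelic SNPs distinguishing the two inbred parents at per-bp
#' density `snp_density`.
#'
#' Parent A is identical to the reference; parent B carries the alternate
#' allele at every planted locus.  SNPs are never placed inside a restriction
#' recognition site, and alternate alleles that would create a new PstI or
#' MspI site are rejected, so in-silico digestion is genotype-independent
#' and both parents share all fragment boundaries.
#'
#' @param config a [sim_config()] object.
#' @param seed integer seed; defaults to `config$rng_seed`.
#' @return a list with components
#'   \describe{
#'     \item{reference}{class `gbs_reference`: `chromosomes` (named character
#'       vector) and `contigs` (data.frame `contig_id, chrom, start, end, cM`
#'       with 0-based half-open coordinates).}
#'     \item{variants}{data.frame `chrom, pos, allele_a, allele_b` with
#'       0-based positions, unique per chromosome.}
#'   }
#' @examples
#' sim <- simulate_reference(sim_config(n_chromosomes = 1,
#'                                      chrom_length_bp = 20000,
#'                                      rng_seed = 7))
#' nrow(sim$variants)
#' @export
simulate_reference <- function(config, seed = config$rng_seed) {
  validate_sim_config(config)
  set.seed(seed)
  L <- config$chrom_length_bp
  chrom_names <- sprintf("chr%dH", seq_len(config$n_chromosomes))

  chromosomes <- vapply(chrom_names, function(nm) {
    paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")
  }, character(1))

  contigs <- do.call(rbind, lapply(chrom_names, function(nm) {
    starts <- seq(0L, L - 1L, by = config$contig_length_bp)
    ends <- pmin(starts + config$contig_length_bp, L)
    mid <- (starts + ends) / 2
    data.frame(
      contig_id = sprintf("%s_ctg%05d", nm, seq_along(starts)),
      chrom = nm,
      start = starts,
      end = ends,
      cM = config$map_length_cM * mid / L,
      stringsAsFactors = FALSE
    )
  }))
  rownames(contigs) <- NULL

  variants <- do.call(rbind, lapply(chrom_names, function(nm) {
    plant_variants(chromosomes[[nm]], nm, config)
  }))
  rownames(variants) <- NULL

  ref <- structure(list(chromosomes = chromosomes, contigs = contigs),
                   class = "gbs_reference")
  list(reference = ref, variants = variants)
}

## All 0-based positions covered by occurrences of `site` in `seq`.
site_mask_positions <- function(seq, site) {
  hits <- gregexpr(site, seq, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(integer(0))
  w <- nchar(site)
  as.integer(outer(hits - 1L, 0:(w - 1L), "+"))
}

## Choose SNP positions and alleles on one chromosome, avoiding enzyme
## recognition sites and alleles that would create new ones.
plant_variants <- function(seq, chrom_name, config) {
  L <- nchar(seq)
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      allele_a = character(0), allele_b = character(0),
                      stringsAsFactors = FALSE)
  n <- rbinom(1L, L, config$snp_density)
  if (n == 0L) return(empty)
  pos <- sort(sample.int(L, n)) - 1L   # 0-based

  masked <- unique(c(site_mask_positions(seq, config$enzyme_rare$site),
                     site_mask_positions(seq, config$enzyme_frequent$site)))
  pos <- setdiff(pos, masked)
  if (length(pos) == 0L) return(empty)

  sites <- c(config$enzyme_rare$site, config$enzyme_frequent$site)
  max_w <- max(nchar(sites))
  ref_base <- substring(seq, pos + 1L, pos + 1L)
  alt <- character(length(pos))
  keep <- logical(length(pos))
  for (i in seq_along(pos)) {
    p <- pos[i]
    lo <- max(0L, p - (max_w - 1L))
    hi <- min(L - 1L, p + (max_w - 1L))
    window <- substring(seq, lo + 1L, hi + 1L)
    centre <- p - lo + 1L
    for (cand in sample(setdiff(DNA_BASES, ref_base[i]))) {
      w2 <- window
      substr(w2, centre, centre) <- cand
      creates <- any(vapply(sites, function(s) {
        h <- gregexpr(s, w2, fixed = TRUE)[[1]]
        if (h[1] == -1L) return(FALSE)
        any(h <= centre & h + nchar(s) - 1L >= centre)
      }, logical(1)))
      if (!creates) {
        alt[i] <- cand
        keep[i] <- TRUE
        break
      }
    }
  }
  data.frame(chrom = chrom_name, pos = pos[keep],
             allele_a = ref_base[keep], allele_b = alt[keep],
             stringsAsFactors = FALSE)
}

#' @export
print.gbs_reference <- function(x, ...) {
  cat(sprintf("GBS reference: %d chromosome(s), %s bp total, %d anchored contigs\n",
              length(x$chromosomes),
              format(sum(nchar(x$chromosomes)), big.mark = ","),
              nrow(x$contigs)))
  invisible(x)
}

#' Locate the anchored contig containing chromosome positions
#'
#' @param ref a `gbs_reference`.
#' @param chrom chromosome names.
#' @param pos 0-based chromosome positions.
#' @return data.frame with `contig_id` and 0-based `offset` on the contig
#'   (NA where a position falls on no contig).
#' @export
chrom_to_contig <- function(ref, chrom, pos) {
  ct <- ref$contigs
  idx <- vapply(seq_along(chrom), function(i) {
    j <- which(ct$chrom == chrom[i] & ct$start <= pos[i] & ct$end > pos[i])
    if (length(j)) j[1] else NA_integer_
  }, integer(1))
  data.frame(contig_id = ct$contig_id[idx],
             offset = pos - ct$start[idx],
             stringsAsFactors = FALSE)
}

#' Convert contig coordinates back to chromosome coordinates
#'
#' @param ref a `gbs_reference`.
#' @param contig_id contig identifiers.
#' @param offset 0-based offsets on the contig.
#' @return data.frame with `chrom` and 0-based `pos`.
#' @export
contig_to_chrom <- function(ref, contig_id, offset) {
  ct <- ref$contigs
  idx <- match(contig_id, ct$contig_id)
  data.frame(chrom = ct$chrom[idx], pos = ct$start[idx] + offset,
             stringsAsFactors = FALSE)
}

#' Extract contig sequences from a reference
#'
#' @param ref a `gbs_reference`.
#' @return named character vector of contig sequences.
#' @export
contig_sequences <- function(ref) {
  ct <- ref$contigs
  setNames(substring(ref$chromosomes[ct$chrom], ct$start + 1L, ct$end),
           ct$contig_id)
}
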