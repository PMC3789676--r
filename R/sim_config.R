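#' Configuration for a simulated GBS experiment
#'
#' Collects every tunable of the synthetic-data generator: genome geometry,
#' SNP density, population design (biparental RILs by single seed descent),
#' restriction enzymes, library layout (barcode, spacer, cut-site remnant),
#' sequencing platform model and per-sample depth distribution.
#'
#' Defaults mirror a two-enzyme barley GBS experiment: PstI (CTGCAG, cutting
#' after base 5 on the top strand) as rare cutter, MspI (CCGG, cutting after
#' base 1) as frequent cutter, 9 bp barcodes, a TGCAG cut-site remnant at the
#' start of every genomic read, F8-derived lines (7 generations of selfing
#' after the F1) and uneven, lognormally distributed read yields per sample.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length_bp length of each chromosome in bp.
#' @param contig_length_bp tiling length of anchored contigs in bp.
#' @param snp_density per-bp probability that a site is polymorphic between
#'   the two parents.
#' @param n_rils number of recombinant inbred lines.
#' @param selfing_generations generations of selfing after the F1
#'   (7 for F8-derived lines).
#' @param map_length_cM genetic length of each chromosome in centimorgans.
#' @param enzyme_rare,enzyme_frequent lists with `site` (recognition string)
#'   and `cut` (cut offset after this many bases of the site, top strand).
#' @param amplifiable_size_range two-element bp interval; only PstI--MspI
#'   fragments inside it amplify.
#' @param barcode_length barcode length in bp (all barcodes equal length).
#' @param cutsite_remnant invariant bases at the start of each genomic read.
#' @param spacer optional fixed sequence between barcode and remnant
#'   (`""` or `"CGAT"`).
#' @param platform `"illumina"` (fixed-length reads, substitution errors) or
#'   `"ion"` (variable-length reads, homopolymer indels plus substitutions).
#' @param read_length_bp fixed read length (illumina).
#' @param ion_length_mean,ion_length_sd,ion_length_min truncated-normal read
#'   length model (ion).
#' @param sub_error_rate per-base substitution error probability.
#' @param hp_indel_rate per-homopolymer-unit indel probability per run (ion).
#' @param depth_meanlog,depth_sdlog lognormal parameters of reads per sample.
#' @param reverse_adapter common-adapter sequence appearing at the 3' end of
#'   reads whose insert is shorter than the read length.
#' @param rng_seed integer seed controlling all simulation randomness.
#' @return an object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_chromosomes = 1, chrom_length_bp = 20000, rng_seed = 1)
#' cfg$enzyme_rare$site
#' @export
sim_config <- function(n_chromosomes = 2,
                       chrom_length_bp = 100000,
                       contig_length_bp = 2000,
                       snp_density = 0.002,
                       n_rils = 24,
                       selfing_generations = 7,
                       map_length_cM = 150,
                       enzyme_rare = list(site = "CTGCAG", cut = 5L),
                       enzyme_frequent = list(site = "CCGG", cut = 1L),
                       amplifiable_size_range = c(50L, 500L),
                       barcode_length = 9L,
                       cutsite_remnant = "TGCAG",
                       spacer = "",
                       platform = c("illumina", "ion"),
                       read_length_bp = 100L,
                       ion_length_mean = 120,
                       ion_length_sd = 40,
                       ion_length_min = 30L,
                       sub_error_rate = 0.002,
                       hp_indel_rate = 0.002,
                       depth_meanlog = log(2000),
                       depth_sdlog = 0.4,
                       reverse_adapter = "AGATCGGAAGAGCGGTTCAGCAGGAATGCCGAGACCG",
                       rng_seed = 1L) {
  platform <- match.arg(platform)
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = as.integer(chrom_length_bp),
    contig_length_bp = as.integer(contig_length_bp),
    snp_density = snp_density,
    n_rils = as.integer(n_rils),
    selfing_generations = as.integer(selfing_generations),
    map_length_cM = map_length_cM,
    enzyme_rare = enzyme_rare,
    enzyme_frequent = enzyme_frequent,
    amplifiable_size_range = as.integer(amplifiable_size_range),
    barcode_length = as.integer(barcode_length),
    cutsite_remnant = cutsite_remnant,
    spacer = spacer,
    platform = platform,
    read_length_bp = as.integer(read_length_bp),
    ion_length_mean = ion_length_mean,
    ion_length_sd = ion_length_sd,
    ion_length_min = as.integer(ion_length_min),
    sub_error_rate = sub_error_rate,
    hp_indel_rate = hp_indel_rate,
    depth_meanlog = depth_meanlog,
    depth_sdlog = depth_sdlog,
    reverse_adapter = reverse_adapter,
    rng_seed = as.integer(rng_seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_chromosomes >= 1L,
    cfg$chrom_length_bp >= 1L,
    cfg$contig_length_bp >= 1L,
    cfg$n_rils >= 1L,
    cfg$selfing_generations >= 1L,
    cfg$map_length_cM > 0,
    cfg$barcode_length >= 1L,
    length(cfg$amplifiable_size_range) == 2L,
    cfg$amplifiable_size_range[1] <= cfg$amplifiable_size_range[2],
    cfg$sub_error_rate >= 0, cfg$sub_error_rate < 1,
    cfg$hp_indel_rate >= 0, cfg$hp_indel_rate < 1
  )
  if (cfg$snp_density < 0 || cfg$snp_density >= 1)
    stop("snp_density must lie in [0, 1)")
  if (cfg$contig_length_bp > cfg$chrom_length_bp)
    stop("contig_length_bp exceeds chrom_length_bp")
  for (enz in list(cfg$enzyme_rare, cfg$enzyme_frequent)) {
    if (!all(c("site", "cut") %in% names(enz)))
      stop("enzymes need 'site' and 'cut' fields")
    if (enz$cut < 1L || enz$cut >= nchar(enz$site))
      stop("enzyme cut offset must fall inside the recognition site")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("GBS simulation configuration\n")
  cat(sprintf("  genome: %d chromosome(s) x %s bp, contigs %s bp, SNP density %g\n",
              x$n_chromosomes, format(x$chrom_length_bp, big.mark = ","),
              format(x$contig_length_bp, big.mark = ","), x$snp_density))
  cat(sprintf("  population: %d RILs, %d selfing generations, %g cM/chromosome\n",
              x$n_rils, x$selfing_generations, x$map_length_cM))
  cat(sprintf("  enzymes: %s/%s, amplifiable %d-%d bp\n",
              x$enzyme_rare$site, x$enzyme_frequent$site,
              x$amplifiable_size_range[1], x$amplifiable_size_range[2]))
  cat(sprintf("  platform: %s, sub error %g, seed %d\n",
              x$platform, x$sub_error_rate, x$rng_seed))
  invisible(x)
}

#' Default barcode set for simulated samples
#'
#' Generates `n` distinct fixed-length barcodes (default 9 bp) that contain
#' no PstI or MspI recognition site and do not begin with the cut-site
#' remnant, so demultiplexing is unambiguous.
#'
#' @param n number of barcodes.
#' @param width barcode length in bp.
#' @param seed integer seed.
#' @return named character vector, names `RIL001`, ... (`P1`, `P2` are
#'   appended by callers that include parents).
#' @export
make_barcodes <- function(n, width = 9L, seed = 1L) {
  set.seed(seed)
  out <- character(0)
  bad <- function(b) {
    grepl("CTGCAG", b, fixed = TRUE) || grepl("CCGG", b, fixed = TRUE) ||
      startsWith(b, "TGCAG")
  }
  while (length(out) < n) {
    b <- paste(sample(DNA_BASES, width, replace = TRUE), collapse = "")
    if (!bad(b) && !(b %in% out)) out <- c(out, b)
  }
  names(out) <- sprintf("RIL%03d", seq_len(n))
  out
}
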