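#' Simulate barcoded GBS reads from amplifiable fragments
#'
#' Per-sample read totals are drawn from a lognormal distribution (emulating
#' uneven pooling).  Each read starts at the PstI end of a uniformly sampled
#' amplifiable fragment, on one of the two haplotypes of its individual
#' chosen with probability 1/2 (so a heterozygous locus covered by a single
#' read is observed as one allele only), and consists of
#' `barcode + spacer + cut-site remnant (TGCAG) + genomic sequence`.
#'
#' Platform models: `illumina` reads are a fixed `read_length_bp` long with
#' per-base substitution errors; inserts shorter than the read length run
#' into the reverse adapter.  `ion` reads draw their length from a truncated
#' normal and additionally receive homopolymer-run indels at
#' `hp_indel_rate` per homopolymer unit before substitution errors.
#' Quality strings are flat Phred+33 encodings of the substitution rate.
#'
#' @param ref a `gbs_reference`.
#' @param variants parental variant table.
#' @param pop a `ril_population` (use [add_parents()] to sequence parents).
#' @param fragments amplifiable fragments from [select_amplifiable()].
#' @param barcodes named character vector, one barcode per sample; names
#'   must be individuals of `pop`.
#' @param config a [sim_config()].
#' @param seed integer seed; defaults to `config$rng_seed + 2`.
#' @return an object of class `read_set`: list with `reads` (data.frame
#'   `id, seq, qual`) and `truth` (data.frame `id, sample, chrom, frag_start,
#'   frag_end, strand, hap`).
#' @export
generate_reads <- function(ref, variants, pop, fragments, barcodes, config,
                           seed = config$rng_seed + 2L) {
  if (anyDuplicated(barcodes)) stop("duplicate barcodes")
  if (anyDuplicated(names(barcodes))) stop("duplicate sample ids")
  missing_s <- setdiff(names(barcodes), pop$individuals)
  if (length(missing_s))
    stop("barcoded samples absent from population: ",
         paste(missing_s, collapse = ", "))
  if (nrow(fragments) == 0L) stop("no amplifiable fragments")
  set.seed(seed)

  frag_info <- prepare_fragments(ref, variants, pop, fragments, config)
  samples <- names(barcodes)

  seq_list <- vector("list", length(samples))
  truth_list <- vector("list", length(samples))
  for (si in seq_along(samples)) {
    s <- samples[si]
    n_reads <- max(1L, round(rlnorm(1L, config$depth_meanlog, config$depth_sdlog)))
    fi <- sample.int(nrow(fragments), n_reads, replace = TRUE)
    hap <- sample.int(2L, n_reads, replace = TRUE)
    body <- fragment_read_body(frag_info, fi, hap, s, pop)
    full <- paste0(barcodes[[s]], config$spacer, body)
    full <- finish_reads(full, config)
    seq_list[[si]] <- full
    truth_list[[si]] <- data.frame(
      sample = s,
      chrom = fragments$chrom[fi],
      frag_start = fragments$start[fi],
      frag_end = fragments$end[fi],
      strand = frag_info$strand[fi],
      hap = hap,
      stringsAsFactors = FALSE
    )
  }

  seqs <- unlist(seq_list, use.names = FALSE)
  seqs <- mutate_substitutions(seqs, config$sub_error_rate)
  truth <- do.call(rbind, truth_list)
  ids <- sprintf("read%07d", seq_along(seqs))
  truth <- cbind(data.frame(id = ids, stringsAsFactors = FALSE), truth)
  reads <- data.frame(id = ids, seq = seqs,
                      qual = qual_string_vec(nchar(seqs), config$sub_error_rate),
                      stringsAsFactors = FALSE)
  structure(list(reads = reads, truth = truth), class = "read_set")
}

qual_string_vec <- function(lens, error_rate) {
  strrep(phred_char(error_rate), lens)
}

## Precompute per-fragment reference sequence, contained variant loci and
## sequencing orientation (reads start at the PstI end).
prepare_fragments <- function(ref, variants, pop, fragments, config) {
  n <- nrow(fragments)
  seqs <- substring(ref$chromosomes[fragments$chrom],
                    fragments$start + 1L, fragments$end)
  strand <- ifelse(fragments$left_end == "PstI", "+", "-")
  ## loci of the population inside each fragment, as row indices of pop$loci
  var_idx <- vector("list", n)
  var_off <- vector("list", n)
  loci_key <- split(seq_len(nrow(pop$loci)), pop$loci$chrom)
  for (i in seq_len(n)) {
    cand <- loci_key[[fragments$chrom[i]]]
    if (is.null(cand)) { var_idx[[i]] <- integer(0); var_off[[i]] <- integer(0); next }
    p <- pop$loci$pos[cand]
    in_frag <- p >= fragments$start[i] & p < fragments$end[i]
    var_idx[[i]] <- cand[in_frag]
    var_off[[i]] <- p[in_frag] - fragments$start[i] + 1L  # 1-based in fragment
  }
  alt_allele <- variants$allele_b[match(
    paste(pop$loci$chrom, pop$loci$pos),
    paste(variants$chrom, variants$pos))]
  ## adapter-restored prefix before the genomic fragment on '+' reads
  prefix <- substr(config$enzyme_rare$site, 2L, config$enzyme_rare$cut)
  list(seqs = seqs, strand = strand, var_idx = var_idx, var_off = var_off,
       alt_allele = alt_allele, prefix = prefix)
}

## Build read bodies (remnant + genomic sequence from the PstI end) for
## fragment indices `fi` on haplotype `hap` of sample `s`.
fragment_read_body <- function(frag_info, fi, hap, s, pop) {
  h1 <- pop$hap1[, s]; h2 <- pop$hap2[, s]
  out <- vapply(seq_along(fi), function(k) {
    i <- fi[k]
    seq <- frag_info$seqs[i]
    vi <- frag_info$var_idx[[i]]
    if (length(vi)) {
      alleles <- if (hap[k] == 1L) h1[vi] else h2[vi]
      subs <- which(alleles == 1L)
      for (j in subs) {
        off <- frag_info$var_off[[i]][j]
        substr(seq, off, off) <- frag_info$alt_allele[vi[j]]
      }
    }
    seq
  }, character(1))
  minus <- frag_info$strand[fi] == "-"
  if (any(minus)) out[minus] <- revcomp(out[minus])
  out[!minus] <- paste0(frag_info$prefix, out[!minus])
  out
}

## Apply platform length model: Illumina fixed-length with adapter
## read-through; Ion truncated-normal lengths with homopolymer indels.
finish_reads <- function(full, config) {
  if (config$platform == "illumina") {
    target <- rep(config$read_length_bp, length(full))
  } else {
    full <- vapply(full, homopolymer_indels, character(1),
                   rate = config$hp_indel_rate, USE.NAMES = FALSE)
    target <- pmax(config$ion_length_min,
                   round(rnorm(length(full), config$ion_length_mean,
                               config$ion_length_sd)))
  }
  short <- nchar(full) < target
  if (any(short)) {
    pad <- paste0(config$reverse_adapter,
                  strrep("A", max(target)))
    full[short] <- paste0(full[short], pad)
  }
  substr(full, 1L, target)
}

## One insertion or deletion of a single unit per homopolymer run, with
## probability min(1, rate * run_length) per run.
homopolymer_indels <- function(seq, rate) {
  if (rate <= 0) return(seq)
  r <- rle(strsplit(seq, "", fixed = TRUE)[[1]])
  p <- pmin(1, rate * r$lengths)
  hit <- runif(length(p)) < p
  if (any(hit)) {
    delta <- ifelse(runif(sum(hit)) < 0.5, -1L, 1L)
    r$lengths[hit] <- pmax(0L, r$lengths[hit] + delta)
  }
  paste(strrep(r$values, r$lengths), collapse = "")
}

## Independent per-base substitutions to a random different base.
mutate_substitutions <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  n_err <- rbinom(length(seqs), nchar(seqs), rate)
  idx <- which(n_err > 0L)
  for (i in idx) {
    pos <- sample.int(nchar(seqs[i]), n_err[i])
    for (p in pos) {
      old <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(DNA_BASES, old), 1L)
    }
  }
  seqs
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read set: %d reads, %d sample(s), lengths %d-%d bp\n",
              nrow(x$reads), length(unique(x$truth$sample)),
              min(nchar(x$reads$seq)), max(nchar(x$reads$seq))))
  invisible(x)
}
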