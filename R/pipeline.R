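#' Inject missing data or genotype errors into an A/B/H call matrix
#'
#' `inject_missing()` sets a random fraction of calls to NA;
#' `inject_genotype_errors()` flips homozygous calls to the opposite
#' homozygote with the given per-call probability (heterozygous calls are
#' left untouched), emulating independent platform genotyping error.
#'
#' @param calls character matrix over `"A","B","H"`/NA.
#' @param frac fraction of calls set to missing.
#' @param rate per-call error probability.
#' @param seed integer seed.
#' @return the corrupted matrix.
#' @export
inject_missing <- function(calls, frac, seed = 1L) {
  set.seed(seed)
  n <- length(calls)
  idx <- sample.int(n, round(frac * n))
  calls[idx] <- NA_character_
  calls
}

#' @rdname inject_missing
#' @export
inject_genotype_errors <- function(calls, rate, seed = 1L) {
  set.seed(seed)
  flip <- !is.na(calls) & calls != "H" &
    matrix(runif(length(calls)) < rate, nrow(calls), ncol(calls))
  calls[flip] <- ifelse(calls[flip] == "A", "B", "A")
  calls
}

#' Evaluate called genotypes against simulation truth
#'
#' Matches called sites to true variant loci by coordinate and allele pair
#' and tabulates a confusion matrix of true vs called genotype classes.
#' The rate at which true heterozygotes are called homozygous (the
#' single-allele-sampling failure mode of shallow GBS coverage) is
#' reported separately.
#'
#' @param table a [genotype_table()]; sites either in chromosome
#'   coordinates or in contig coordinates (supply `ref` to convert).
#' @param pop the true `ril_population`.
#' @param variants the parental variant table.
#' @param ref a `gbs_reference`, required when `table` uses contig
#'   coordinates.
#' @return list of class `truth_evaluation`: `n_sites_called,
#'   n_sites_matched, confusion` (truth A/H/B x called A/H/B/missing),
#'   `error_rate` (over pairs called in both), `hom_error_rate` (same but
#'   restricted to homozygous truth: with error-free sequencing this is
#'   exactly 0, while `error_rate` still includes heterozygous loci whose
#'   sampled reads happened to show one allele), `het_called_hom_rate`,
#'   `n_novel_sites` (called sites matching no true locus).
#' @export
evaluate_against_truth <- function(table, pop, variants, ref = NULL) {
  sites <- table$sites
  if (!is.null(ref) && any(sites$contig %in% ref$contigs$contig_id)) {
    conv <- contig_to_chrom(ref, sites$contig, sites$pos)
    sites <- data.frame(contig = conv$chrom, pos = conv$pos,
                        ref = sites$ref, alt = sites$alt,
                        stringsAsFactors = FALSE)
  }
  truth_key <- paste(pop$loci$chrom, pop$loci$pos)
  call_key <- paste(sites$contig, sites$pos)
  ti <- match(call_key, truth_key)
  vi <- match(call_key, paste(variants$chrom, variants$pos))
  allele_ok <- !is.na(ti) & !is.na(vi) &
    sites$ref == variants$allele_a[vi] & sites$alt == variants$allele_b[vi]
  matched <- which(allele_ok)
  if (length(matched) == 0L)
    return(structure(list(n_sites_called = nrow(sites), n_sites_matched = 0L,
                          confusion = NULL, error_rate = NA_real_,
                          hom_error_rate = NA_real_,
                          het_called_hom_rate = NA_real_,
                          n_novel_sites = nrow(sites)),
                     class = "truth_evaluation"))

  samp <- intersect(table$samples, pop$individuals)
  truth <- pop$calls[ti[matched], samp, drop = FALSE]
  called_code <- table$geno[matched, match(samp, table$samples), drop = FALSE]
  called <- matrix(c("A", "H", "B")[called_code + 1L],
                   nrow(called_code), ncol(called_code))
  called[is.na(called_code)] <- "missing"

  confusion <- table(factor(truth, levels = c("A", "H", "B")),
                     factor(called, levels = c("A", "H", "B", "missing")),
                     dnn = c("truth", "called"))
  both <- called != "missing"
  err <- mean(truth[both] != called[both])
  hom <- truth != "H" & both
  hom_err <- if (any(hom)) mean(truth[hom] != called[hom]) else NA_real_
  hh <- truth == "H" & both
  het_hom <- if (any(hh)) mean(called[hh] != "H") else NA_real_
  structure(list(n_sites_called = nrow(sites),
                 n_sites_matched = length(matched),
                 confusion = confusion, error_rate = err,
                 hom_error_rate = hom_err,
                 het_called_hom_rate = het_hom,
                 n_novel_sites = nrow(sites) - length(matched)),
            class = "truth_evaluation")
}

#' @export
print.truth_evaluation <- function(x, ...) {
  cat(sprintf("truth evaluation: %d called sites, %d matched to true loci (%d novel)\n",
              x$n_sites_called, x$n_sites_matched, x$n_novel_sites))
  if (!is.null(x$confusion)) {
    cat(sprintf("  genotype error rate (both called): %.4f%%\n", 100 * x$error_rate))
    cat(sprintf("  error rate at homozygous truth: %.4f%%\n", 100 * x$hom_error_rate))
    cat(sprintf("  het called hom rate: %s\n",
                if (is.na(x$het_called_hom_rate)) "NA"
                else sprintf("%.1f%%", 100 * x$het_called_hom_rate)))
  }
  invisible(x)
}

#' Reference anchors for markers named after their sites
#'
#' Builds the `marker, chrom, ref_cM` anchor table used by the map
#' comparison module, anchoring each marker at its contig's cM position on
#' the integrated map (anchor resolution is the contig, as in
#' reference-based marker ordering).
#'
#' @param sites data.frame `contig, pos` of the markers, in contig or
#'   chromosome coordinates.
#' @param ref a `gbs_reference`.
#' @return data.frame `marker, contig, pos, chrom, ref_cM`.
#' @export
marker_anchors <- function(sites, ref) {
  marker <- paste0(sites$contig, ":", sites$pos)
  if (any(sites$contig %in% ref$contigs$contig_id)) {
    i <- match(sites$contig, ref$contigs$contig_id)
    data.frame(marker = marker, contig = sites$contig, pos = sites$pos,
               chrom = ref$contigs$chrom[i], ref_cM = ref$contigs$cM[i],
               stringsAsFactors = FALSE)
  } else {
    ## chromosome coordinates: anchor through the containing contig
    cc <- chrom_to_contig(ref, sites$contig, sites$pos)
    i <- match(cc$contig_id, ref$contigs$contig_id)
    data.frame(marker = marker, contig = cc$contig_id, pos = sites$pos,
               chrom = sites$contig, ref_cM = ref$contigs$cM[i],
               stringsAsFactors = FALSE)
  }
}

#' Run the full simulated GBS experiment end to end
#'
#' Executes simulate (reference, population, digestion, reads) ->
#' demultiplex -> adapter trim -> place -> call -> mask/filter ->
#' cross-platform comparison -> parental encoding -> de novo map ->
#' order evaluation -> truth evaluation, and optionally writes the
#' intermediate files (FASTA/FASTQ/VCF/TSV/JSON) to a directory.
#'
#' @param config a [sim_config()]; `config$platform` is overridden per
#'   entry of `platforms`.
#' @param platforms character vector of platform datasets to emulate from
#'   the one truth population (default `c("illumina", "ion")`).
#' @param out_dir optional output directory for artifact files.
#' @param k k-mer size for the placement index.
#' @param caller_error per-base error rate assumed by the caller.
#' @param build_map whether to build and evaluate the de novo map.
#' @param tag_path also run the tag-based calling path on the first
#'   platform (default FALSE).
#' @param quiet suppress per-stage messages.
#' @return list with the reference, truth, per-platform genotype tables
#'   (raw, masked, filtered), demux statistics, the merged comparison
#'   (venn counts, pairwise discordance), encoded A/B/H matrices, the
#'   genetic map with its order comparison, truth evaluations, and a
#'   per-stage count log.
#' @export
run_gbs_pipeline <- function(config = sim_config(),
                             platforms = c("illumina", "ion"),
                             out_dir = NULL, k = 21L,
                             caller_error = 0.01,
                             build_map = TRUE, tag_path = FALSE,
                             quiet = TRUE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  log <- list()

  sim <- simulate_reference(config)
  ref <- sim$reference; variants <- sim$variants
  say("reference: %d variants", nrow(variants))
  pop <- add_parents(simulate_ril_population(ref, variants, config))
  frags <- digest_genome(ref, config)
  amp <- select_amplifiable(frags, config)
  log$n_variants <- nrow(variants)
  log$n_fragments <- nrow(frags)
  log$n_amplifiable <- nrow(amp)
  say("digestion: %d fragments, %d amplifiable", nrow(frags), nrow(amp))

  barcodes <- make_barcodes(length(pop$individuals),
                            width = config$barcode_length,
                            seed = derive_seed(config$rng_seed, 9L))
  names(barcodes) <- pop$individuals
  index <- build_index(ref, k = k)

  tables <- list(); demux_stats <- list(); evals <- list()
  sample_reads_first <- NULL
  for (pi in seq_along(platforms)) {
    pf <- platforms[pi]
    cfg_p <- config
    cfg_p$platform <- pf
    reads <- generate_reads(ref, variants, pop, amp, barcodes, cfg_p,
                            seed = derive_seed(config$rng_seed, 100L + pi))
    dm <- demultiplex(reads, barcodes, spacer = config$spacer,
                      cutsite_remnant = config$cutsite_remnant)
    n_disc <- 0L
    for (s in names(dm$samples)) {
      tr <- trim_reverse_adapter(dm$samples[[s]], config$reverse_adapter)
      dm$samples[[s]] <- tr$reads
      n_disc <- n_disc + tr$n_discarded
    }
    dm$stats$discarded_short <- n_disc
    demux_stats[[pf]] <- dm$stats
    say("%s: %d/%d reads assigned, %d discarded short", pf,
        dm$stats$assigned_reads, dm$stats$total_reads, n_disc)
    if (pi == 1L) sample_reads_first <- dm$samples

    placements <- do.call(rbind, lapply(names(dm$samples), function(s) {
      p <- place_reads(dm$samples[[s]], index)
      if (nrow(p)) cbind(p, sample = s, stringsAsFactors = FALSE) else NULL
    }))
    tab <- pileup_and_call(placements, ref, e = caller_error,
                           provenance = pf)
    masked <- mask_low_confidence(tab)
    filtered <- filter_sites(masked, filter_criteria())
    say("%s: %d sites called, %d after filtering", pf,
        nrow(tab$sites), nrow(filtered$sites))
    tables[[pf]] <- list(raw = tab, masked = masked, filtered = filtered)
    evals[[pf]] <- evaluate_against_truth(filtered, pop, variants, ref)
  }

  if (tag_path) {
    tag_tab <- tag_based_call(sample_reads_first, index, ref,
                              e = caller_error)
    tables$tag <- list(raw = tag_tab,
                       masked = mask_low_confidence(tag_tab),
                       filtered = filter_sites(mask_low_confidence(tag_tab),
                                               filter_criteria()))
  }

  ## cross-dataset comparison on comparison-grade tables
  comp_tabs <- lapply(tables, function(t)
    filter_sites(t$masked, comparison_criteria()))
  comparison <- NULL
  if (length(comp_tabs) >= 2L) {
    merged <- merge_by_position(comp_tabs)
    pairs <- combn(names(comp_tabs), 2L, simplify = FALSE)
    disc <- lapply(pairs, function(p)
      percent_discordant(merged, p[1L], p[2L]))
    names(disc) <- vapply(pairs, paste, "", collapse = " vs ")
    comparison <- list(merged = merged,
                       venn = if (length(comp_tabs) <= 3L) venn_counts(merged),
                       discordance = disc)
  }

  ## parental encoding and de novo map from the first platform
  map <- NULL; order_cmp <- NULL; encoded <- NULL
  if (build_map) {
    encoded <- encode_parental(tables[[platforms[1L]]]$filtered, "P1", "P2")
    mat <- encoded$calls
    rownames(mat) <- paste0(encoded$sites$contig, ":", encoded$sites$pos)
    anchors <- marker_anchors(encoded$sites, ref)
    contig_map <- data.frame(marker = anchors$marker,
                             contig = anchors$contig, pos = anchors$pos,
                             stringsAsFactors = FALSE)
    map <- tryCatch(build_genetic_map(mat, contig_map),
                    error = function(e) NULL)
    if (!is.null(map))
      order_cmp <- compare_map_orders(map, anchors)
  }

  out <- list(config = config, reference = ref, variants = variants,
              population = pop, fragments = frags, amplifiable = amp,
              barcodes = barcodes, demux_stats = demux_stats,
              tables = tables, comparison = comparison,
              encoded = encoded, map = map, order_comparison = order_cmp,
              truth_evaluation = evals, log = log)
  if (!is.null(out_dir)) write_pipeline_artifacts(out, out_dir)
  out
}

## Persist the main pipeline artifacts as plain files.
write_pipeline_artifacts <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_reference_fasta(res$reference, file.path(out_dir, "reference.fa"))
  write_contig_anchors(res$reference, file.path(out_dir, "contig_anchors.tsv"))
  write_barcode_table(res$barcodes, file.path(out_dir, "barcodes.tsv"))
  write_genotype_vcf(truth_genotype_table(res$population, res$variants),
                     file.path(out_dir, "truth.vcf.gz"))
  for (pf in names(res$tables))
    write_genotype_vcf(res$tables[[pf]]$filtered,
                       file.path(out_dir, sprintf("calls_%s.vcf.gz", pf)))
  if (!is.null(res$map))
    write.table(res$map, file.path(out_dir, "genetic_map.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  summary <- list(
    log = res$log,
    demux = res$demux_stats,
    venn = as.list(res$comparison$venn %||% NULL),
    discordance = lapply(res$comparison$discordance %||% list(), function(d)
      d[c("shared_snps", "compared_calls", "percent_discordant")]),
    mean_spearman = res$order_comparison$mean_spearman %||% NULL,
    error_rates = lapply(res$truth_evaluation, `[[`, "error_rate")
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
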