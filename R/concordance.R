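#' Merge genotype tables from multiple datasets by reference coordinate
#'
#' Takes the union of site keys `(contig, pos)` across datasets, records a
#' presence flag per dataset, and computes the sample intersection.  Sites
#' whose ref/alt allele pair conflicts between datasets are flagged and
#' excluded from genotype comparison (but still counted as present for
#' set-overlap purposes).
#'
#' @param tables named list of [genotype_table()] objects on the same
#'   reference (apply comparison filtering upstream).
#' @return object of class `merged_table`: list with `sites` (data.frame
#'   `contig, pos`), `presence` (logical sites x datasets matrix),
#'   `conflict` (logical vector), `shared_samples`, and the input `tables`.
#' @export
merge_by_position <- function(tables) {
  stopifnot(length(tables) >= 2L)
  if (is.null(names(tables)) || any(names(tables) == ""))
    names(tables) <- paste0("dataset", seq_along(tables))
  keys <- lapply(tables, function(t) paste(t$sites$contig, t$sites$pos))
  all_keys <- unique(unlist(keys))
  presence <- vapply(keys, function(k) all_keys %in% k,
                     logical(length(all_keys)))
  if (is.null(dim(presence)))
    presence <- matrix(presence, nrow = length(all_keys),
                       dimnames = list(NULL, names(tables)))

  ## allele-pair conflicts among datasets containing the site
  allele <- vapply(tables, function(t) {
    k <- paste(t$sites$contig, t$sites$pos)
    paste(t$sites$ref, t$sites$alt)[match(all_keys, k)]
  }, character(length(all_keys)))
  if (is.null(dim(allele)))
    allele <- matrix(allele, nrow = length(all_keys))
  conflict <- apply(allele, 1L, function(a) {
    a <- a[!is.na(a)]
    length(unique(a)) > 1L
  })

  parts <- strsplit(all_keys, " ", fixed = TRUE)
  sites <- data.frame(contig = vapply(parts, `[`, "", 1L),
                      pos = as.integer(vapply(parts, `[`, "", 2L)),
                      stringsAsFactors = FALSE)
  shared_samples <- Reduce(intersect, lapply(tables, `[[`, "samples"))
  structure(list(sites = sites, presence = presence, conflict = conflict,
                 shared_samples = shared_samples, tables = tables),
            class = "merged_table")
}

#' @export
print.merged_table <- function(x, ...) {
  cat(sprintf("merged table: %d datasets, %d site keys, %d shared samples, %d allele conflicts\n",
              ncol(x$presence), nrow(x$sites), length(x$shared_samples),
              sum(x$conflict)))
  invisible(x)
}

#' Counts of every SNP presence-pattern region (Venn regions)
#'
#' @param merged a `merged_table` of 2 or 3 datasets.
#' @return named integer vector, one element per non-empty presence
#'   pattern (names like `"A"`, `"A&B"`), summing to the union size.
#' @export
venn_counts <- function(merged) {
  nd <- ncol(merged$presence)
  if (nd < 2L || nd > 3L) stop("venn_counts supports 2 or 3 datasets")
  labels <- colnames(merged$presence)
  pattern <- apply(merged$presence, 1L, function(p)
    paste(labels[p], collapse = "&"))
  tab <- table(pattern)
  ## present every possible region, zero-filled, in a stable order
  regions <- unlist(lapply(seq_len(nd), function(m)
    combn(labels, m, paste, collapse = "&", simplify = FALSE)))
  out <- setNames(integer(length(regions)), regions)
  out[names(tab)] <- as.integer(tab)
  out
}

#' Percent discordant genotype calls between two datasets
#'
#' Over shared sites (present in both datasets, no allele conflict) and
#' shared samples, counts call pairs where both calls are non-missing;
#' a pair is discordant when the genotype labels differ (heterozygous vs
#' homozygous counts as discordant).
#'
#' @param merged a `merged_table`.
#' @param x,y dataset names (or indices) within the merged table.
#' @return list of class `discordance_report`: `shared_snps,
#'   shared_samples, compared_calls, discordant_calls, percent_discordant`
#'   (NA when no calls can be compared).
#' @export
percent_discordant <- function(merged, x = 1L, y = 2L) {
  tx <- merged$tables[[x]]; ty <- merged$tables[[y]]
  nm <- colnames(merged$presence)
  ix <- if (is.character(x)) x else nm[x]
  iy <- if (is.character(y)) y else nm[y]
  shared <- merged$presence[, ix] & merged$presence[, iy] & !merged$conflict
  keys <- paste(merged$sites$contig, merged$sites$pos)[shared]
  ss <- merged$shared_samples

  report <- function(compared, discordant) {
    structure(list(shared_snps = sum(shared), shared_samples = length(ss),
                   compared_calls = compared, discordant_calls = discordant,
                   percent_discordant =
                     if (compared > 0) 100 * discordant / compared else NA_real_),
              class = "discordance_report")
  }
  if (length(keys) == 0L || length(ss) == 0L) return(report(0L, 0L))

  kx <- paste(tx$sites$contig, tx$sites$pos)
  ky <- paste(ty$sites$contig, ty$sites$pos)
  gx <- tx$geno[match(keys, kx), match(ss, tx$samples), drop = FALSE]
  gy <- ty$geno[match(keys, ky), match(ss, ty$samples), drop = FALSE]
  both <- !is.na(gx) & !is.na(gy)
  report(sum(both), sum(gx[both] != gy[both]))
}

#' @export
print.discordance_report <- function(x, ...) {
  cat(sprintf("discordance: %d shared SNPs, %d shared samples, %d/%d calls discordant (%.2f%%)\n",
              x$shared_snps, x$shared_samples, x$discordant_calls,
              x$compared_calls,
              if (is.na(x$percent_discordant)) NA else x$percent_discordant))
  invisible(x)
}

#' Re-express RIL genotype calls as parental A/B/H codes
#'
#' Uses the two parent samples to orient each site: sites where both
#' parents are non-missing, homozygous and different are encodable; RIL
#' calls matching parent A become `"A"`, matching parent B `"B"`,
#' heterozygous `"H"`, otherwise missing.  Uninformative sites (parents
#' missing, heterozygous or identical) are dropped.
#'
#' @param table a [genotype_table()] containing both parents.
#' @param parent_a,parent_b sample ids of the two parents.
#' @return list: `calls` (character matrix sites x RILs over
#'   `"A","B","H"`/NA), `sites` (the encodable site rows), `samples`.
#' @export
encode_parental <- function(table, parent_a, parent_b) {
  if (!all(c(parent_a, parent_b) %in% table$samples))
    stop("parent id absent from the genotype table")
  ga <- table$geno[, parent_a]
  gb <- table$geno[, parent_b]
  ok <- !is.na(ga) & !is.na(gb) & ga != 1L & gb != 1L & ga != gb
  rils <- setdiff(table$samples, c(parent_a, parent_b))
  g <- table$geno[ok, rils, drop = FALSE]
  ga <- ga[ok]; gb <- gb[ok]
  calls <- matrix(NA_character_, nrow(g), ncol(g),
                  dimnames = list(NULL, rils))
  calls[!is.na(g) & g == 1L] <- "H"
  calls[!is.na(g) & g == matrix(ga, nrow(g), ncol(g))] <- "A"
  calls[!is.na(g) & g == matrix(gb, nrow(g), ncol(g))] <- "B"
  list(calls = calls, sites = table$sites[ok, , drop = FALSE],
       samples = rils)
}
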