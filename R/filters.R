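#' Genotype-call and site filter criteria
#'
#' Two standard criteria sets for a RIL population:
#' \describe{
#'   \item{`filter_criteria()`}{the calling-stage set: per-call depth/GQ
#'     masking (depth >= 1 and GQ >= 3 for homozygous calls, depth >= 3 and
#'     GQ >= 5 for heterozygous calls), then per-site retention with at most
#'     90\% missing calls, minor allele frequency at least 5\% and less than
#'     10\% heterozygous calls.}
#'   \item{`comparison_criteria()`}{the stricter set used before
#'     cross-dataset comparison: at most 50\% missing data and MAF at least
#'     30\% (no additional per-call masking or het gate).}
#' }
#'
#' @param min_depth_hom,min_depth_het minimum read depth per genotype class.
#' @param min_gq_hom,min_gq_het minimum genotype quality per class.
#' @param max_missing_frac maximum fraction of missing calls per site.
#' @param min_maf minimum minor allele frequency (het calls contribute half
#'   a count to each allele).
#' @param max_het_frac heterozygous fraction must be strictly below this
#'   (set to `Inf` to disable).
#' @return a list of class `filter_criteria`.
#' @export
filter_criteria <- function(min_depth_hom = 1L, min_depth_het = 3L,
                            min_gq_hom = 3L, min_gq_het = 5L,
                            max_missing_frac = 0.90, min_maf = 0.05,
                            max_het_frac = 0.10) {
  stopifnot(max_missing_frac >= 0, max_missing_frac <= 1,
            min_maf >= 0, min_maf <= 1,
            min_depth_het >= min_depth_hom, min_gq_het >= min_gq_hom)
  structure(list(min_depth_hom = min_depth_hom, min_depth_het = min_depth_het,
                 min_gq_hom = min_gq_hom, min_gq_het = min_gq_het,
                 max_missing_frac = max_missing_frac, min_maf = min_maf,
                 max_het_frac = max_het_frac),
            class = "filter_criteria")
}

#' @rdname filter_criteria
#' @export
comparison_criteria <- function(max_missing_frac = 0.50, min_maf = 0.30) {
  filter_criteria(min_depth_hom = 0L, min_depth_het = 0L,
                  min_gq_hom = 0L, min_gq_het = 0L,
                  max_missing_frac = max_missing_frac, min_maf = min_maf,
                  max_het_frac = Inf)
}

#' Mask low-confidence genotype calls
#'
#' Sets to missing every call that fails the depth or genotype-quality
#' threshold of its genotype class (homozygous vs heterozygous).  Site and
#' sample dimensions are unchanged; the operation is idempotent.
#'
#' @param table a [genotype_table()] with depth and GQ populated.
#' @param criteria a [filter_criteria()].
#' @return the masked `genotype_table`.
#' @export
mask_low_confidence <- function(table, criteria = filter_criteria()) {
  g <- table$geno
  het <- !is.na(g) & g == 1L
  hom <- !is.na(g) & g != 1L
  fail <- (hom & (table$depth < criteria$min_depth_hom |
                  table$gq < criteria$min_gq_hom)) |
          (het & (table$depth < criteria$min_depth_het |
                  table$gq < criteria$min_gq_het))
  table$geno[fail] <- NA_integer_
  table
}

#' Retain sites passing missingness, MAF and heterozygosity criteria
#'
#' A site survives when its missing fraction is at most `max_missing_frac`,
#' its minor allele frequency (computed over non-missing calls, het calls
#' contributing half a count to each allele) is at least `min_maf`, and its
#' heterozygous fraction (over non-missing calls) is strictly below
#' `max_het_frac`.  Sites where every call is missing are removed (MAF
#' undefined).  Site order is preserved.
#'
#' @param table a [genotype_table()]; apply [mask_low_confidence()] first
#'   when using the calling-stage criteria.
#' @param criteria a [filter_criteria()] or [comparison_criteria()].
#' @return the filtered `genotype_table`.
#' @export
filter_sites <- function(table, criteria = filter_criteria()) {
  keep <- which(site_predicates(table$geno, criteria))
  subset_table(table, site_idx = keep)
}

## Vector of per-site survival decisions for an integer 0/1/2/NA matrix.
site_predicates <- function(g, criteria) {
  n <- ncol(g)
  n_miss <- rowSums(is.na(g))
  n_called <- n - n_miss
  n_het <- rowSums(g == 1L, na.rm = TRUE)
  n_ref_allele <- 2 * rowSums(g == 0L, na.rm = TRUE) + n_het
  n_alt_allele <- 2 * rowSums(g == 2L, na.rm = TRUE) + n_het
  tot <- n_ref_allele + n_alt_allele
  maf <- ifelse(tot > 0, pmin(n_ref_allele, n_alt_allele) / tot, NA_real_)
  het_frac <- ifelse(n_called > 0, n_het / n_called, NA_real_)
  n_called > 0 &
    n_miss / n <= criteria$max_missing_frac &
    !is.na(maf) & maf >= criteria$min_maf &
    het_frac < criteria$max_het_frac
}
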