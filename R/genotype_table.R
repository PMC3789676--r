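#' Construct a genotype table
#'
#' The container passed between the caller, the filters and the concordance
#' module: per-site, per-sample genotype calls with depth, genotype quality
#' and allele counts.
#'
#' @param sites data.frame `contig, pos, ref, alt` (0-based `pos`; site keys
#'   unique).
#' @param samples character vector of sample ids.
#' @param geno integer matrix (sites x samples): 0 = homozygous reference,
#'   1 = heterozygous, 2 = homozygous alternate, NA = missing.
#' @param depth,gq,n_ref,n_alt numeric matrices of matching dimension
#'   (optional; default 0/NA).
#' @param provenance free-text dataset label (platform/pipeline).
#' @return object of class `genotype_table`.
#' @export
genotype_table <- function(sites, samples, geno, depth = NULL, gq = NULL,
                           n_ref = NULL, n_alt = NULL, provenance = "") {
  stopifnot(nrow(geno) == nrow(sites), ncol(geno) == length(samples))
  key <- paste(sites$contig, sites$pos)
  if (anyDuplicated(key)) stop("duplicate site keys")
  zero <- matrix(0, nrow(sites), length(samples))
  nm <- function(m) { dimnames(m) <- list(NULL, samples); m }
  structure(list(sites = sites, samples = samples, geno = nm(geno),
                 depth = nm(depth %||% zero), gq = nm(gq %||% zero),
                 n_ref = nm(n_ref %||% zero), n_alt = nm(n_alt %||% zero),
                 provenance = provenance),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype table [%s]: %d sites x %d samples, %.1f%% missing\n",
              x$provenance, nrow(x$sites), length(x$samples),
              100 * mean(is.na(x$geno))))
  invisible(x)
}

#' @export
summary.genotype_table <- function(object, ...) {
  g <- object$geno
  out <- list(
    n_sites = nrow(object$sites),
    n_samples = length(object$samples),
    missing_frac = mean(is.na(g)),
    het_frac = mean(g == 1L, na.rm = TRUE),
    mean_depth = mean(object$depth),
    provenance = object$provenance
  )
  class(out) <- "summary.genotype_table"
  out
}

#' @export
print.summary.genotype_table <- function(x, ...) {
  cat(sprintf(paste0("genotype table [%s]\n  sites: %d  samples: %d\n",
                     "  missing: %.2f%%  het (of called): %.2f%%  mean depth: %.2f\n"),
              x$provenance, x$n_sites, x$n_samples,
              100 * x$missing_frac, 100 * x$het_frac, x$mean_depth))
  invisible(x)
}

## Subset a genotype table by site index and/or sample names.
subset_table <- function(tab, site_idx = NULL, samples = NULL) {
  si <- site_idx %||% seq_len(nrow(tab$sites))
  sj <- if (is.null(samples)) tab$samples else samples
  jj <- match(sj, tab$samples)
  genotype_table(tab$sites[si, , drop = FALSE], sj,
                 tab$geno[si, jj, drop = FALSE],
                 tab$depth[si, jj, drop = FALSE],
                 tab$gq[si, jj, drop = FALSE],
                 tab$n_ref[si, jj, drop = FALSE],
                 tab$n_alt[si, jj, drop = FALSE],
                 tab$provenance)
}
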