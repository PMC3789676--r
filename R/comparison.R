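#' Per-group rank correlation between de novo and reference marker order
#'
#' For each linkage group, takes the markers anchored to the group's
#' majority reference chromosome and computes the absolute Spearman rank
#' correlation between de novo cM and reference cM (average ranks for
#' ties; absolute value because linkage-group orientation is arbitrary).
#' Groups with fewer than 3 anchored markers are skipped.
#'
#' @param map a `genetic_map` (or data.frame `marker, group, cM`).
#' @param anchors data.frame `marker, chrom, ref_cM` giving each marker's
#'   reference chromosome and position; markers absent from it are
#'   unanchored.
#' @return data.frame `group, chrom, n_markers, spearman_abs`.
#' @export
spearman_order <- function(map, anchors) {
  joined <- join_anchors(map, anchors)
  out <- lapply(split(joined, joined$group), function(d) {
    d <- d[!is.na(d$chrom), , drop = FALSE]
    if (nrow(d) == 0L) return(NULL)
    maj <- majority_chrom(d$chrom)
    d <- d[d$chrom == maj, , drop = FALSE]
    if (nrow(d) < 3L) return(NULL)
    data.frame(group = d$group[1L], chrom = maj, n_markers = nrow(d),
               spearman_abs = abs(cor(d$cM, d$ref_cM, method = "spearman")),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

join_anchors <- function(map, anchors) {
  i <- match(map$marker, anchors$marker)
  data.frame(marker = map$marker, group = map$group, cM = map$cM,
             chrom = anchors$chrom[i], ref_cM = anchors$ref_cM[i],
             stringsAsFactors = FALSE)
}

majority_chrom <- function(chrom) {
  tab <- sort(table(chrom), decreasing = TRUE)
  names(tab)[1L]
}

#' Chromosome-assignment concordance of a de novo map
#'
#' Assigns each linkage group its majority reference chromosome; an
#' anchored marker is discordant iff its own reference chromosome differs
#' from its group's majority.  Unanchored markers are excluded from the
#' denominator.
#'
#' @inheritParams spearman_order
#' @return list `n_discordant, n_anchored, fraction, group_chrom` (named
#'   vector group -> majority chromosome).
#' @export
chromosome_concordance <- function(map, anchors) {
  joined <- join_anchors(map, anchors)
  joined <- joined[!is.na(joined$chrom), , drop = FALSE]
  gc <- vapply(split(joined$chrom, joined$group), majority_chrom, "")
  disc <- joined$chrom != gc[joined$group]
  list(n_discordant = sum(disc), n_anchored = nrow(joined),
       fraction = if (nrow(joined)) sum(disc) / nrow(joined) else NA_real_,
       group_chrom = gc)
}

#' Local-regression displacement between de novo and reference positions
#'
#' Per linkage group (majority-chromosome markers only), aligns the group
#' orientation to the reference (flipping de novo cM when the rank
#' correlation is negative), fits a tricube-weighted local linear
#' regression of reference cM on de novo cM, and reports each marker's
#' absolute residual from the fit.  Markers displaced by more than
#' `threshold_cM` are counted.  Groups too small for a local fit fall back
#' to a global linear fit.
#'
#' @inheritParams spearman_order
#' @param span loess span (default 0.75).
#' @param threshold_cM displacement threshold in cM (default 5).
#' @param min_loess_n below this many markers a linear fit is used.
#' @return list with `per_marker` (data.frame `marker, group, chrom, cM,
#'   ref_cM, displacement`) and `n_displaced`.
#' @export
displacement <- function(map, anchors, span = 0.75, threshold_cM = 5,
                         min_loess_n = 10L) {
  joined <- join_anchors(map, anchors)
  joined <- joined[!is.na(joined$chrom), , drop = FALSE]
  parts <- lapply(split(joined, joined$group), function(d) {
    maj <- majority_chrom(d$chrom)
    d <- d[d$chrom == maj, , drop = FALSE]
    if (nrow(d) < 3L) return(NULL)
    if (cor(d$cM, d$ref_cM, method = "spearman") < 0)
      d$cM <- max(d$cM) - d$cM
    fit <- NULL
    if (nrow(d) >= min_loess_n)
      fit <- tryCatch(
        loess(ref_cM ~ cM, data = d, span = span, degree = 1L,
              surface = "direct"),
        error = function(e) NULL, warning = function(w) NULL)
    pred <- if (is.null(fit)) predict(lm(ref_cM ~ cM, data = d))
            else predict(fit, d$cM)
    d$displacement <- abs(pred - d$ref_cM)
    d
  })
  per_marker <- do.call(rbind, parts)
  rownames(per_marker) <- NULL
  list(per_marker = per_marker,
       n_displaced = sum(per_marker$displacement > threshold_cM))
}

#' Full comparison of a de novo map against the reference framework
#'
#' Combines [spearman_order()], [chromosome_concordance()] and
#' [displacement()] into one report.
#'
#' @inheritParams displacement
#' @return object of class `order_comparison`.
#' @export
compare_map_orders <- function(map, anchors, span = 0.75, threshold_cM = 5) {
  sp <- spearman_order(map, anchors)
  cc <- chromosome_concordance(map, anchors)
  dp <- displacement(map, anchors, span = span, threshold_cM = threshold_cM)
  structure(list(per_group = sp,
                 mean_spearman = sum(sp$spearman_abs * sp$n_markers) /
                   sum(sp$n_markers),
                 concordance = cc,
                 displacement = dp,
                 threshold_cM = threshold_cM),
            class = "order_comparison")
}

#' @export
print.order_comparison <- function(x, ...) {
  cat("de novo vs reference marker order\n")
  cat(sprintf("  marker-weighted mean |Spearman rho|: %.4f\n", x$mean_spearman))
  cat(sprintf("  discordant chromosome assignments: %d/%d (%.2f%%)\n",
              x$concordance$n_discordant, x$concordance$n_anchored,
              100 * x$concordance$fraction))
  cat(sprintf("  markers displaced > %g cM: %d\n",
              x$threshold_cM, x$displacement$n_displaced))
  invisible(x)
}
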