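#' Parameters for de novo genetic map construction
#'
#' Mirrors a standard MSTmap-style invocation for an advanced RIL
#' population treated as doubled haploids: markers with more than 20\%
#' missing data are discarded, one marker is kept per reference contig,
#' markers with more than 10\% missing-plus-heterozygous calls are dropped
#' and remaining heterozygous calls set to missing, linkage groups are cut
#' at a two-point p-value of 1e-5, and distances use the Kosambi map
#' function.
#'
#' @param max_missing_marker pre-filter: maximum missing fraction.
#' @param missing_threshold maximum missing+heterozygous fraction.
#' @param cut_off_p two-point p-value threshold for joining markers into a
#'   linkage group.
#' @param one_marker_per_contig keep a single marker per contig (the one
#'   with least missing data; ties broken by lowest position).
#' @param no_map_dist,no_map_size post-hoc discard of isolated marker sets:
#'   groups of at most `no_map_size` markers whose nearest within-group
#'   neighbour exceeds `no_map_dist` cM are dropped (inert for connected
#'   simulated data).
#' @return list of class `map_build_params`.
#' @export
map_build_params <- function(max_missing_marker = 0.20,
                             missing_threshold = 0.10,
                             cut_off_p = 1e-5,
                             one_marker_per_contig = TRUE,
                             no_map_dist = 20,
                             no_map_size = 2L) {
  stopifnot(max_missing_marker > 0, max_missing_marker < 1,
            missing_threshold > 0, missing_threshold < 1,
            cut_off_p > 0, cut_off_p < 1)
  structure(list(max_missing_marker = max_missing_marker,
                 missing_threshold = missing_threshold,
                 cut_off_p = cut_off_p,
                 one_marker_per_contig = one_marker_per_contig,
                 no_map_dist = no_map_dist, no_map_size = no_map_size),
            class = "map_build_params")
}

#' Pre-filter an A/B/H marker matrix for map construction
#'
#' Applies, in order: the 20\% missing-data discard, the one-marker-per-
#' contig selection (least missing data, ties to the lowest position), the
#' 10\% missing+heterozygous discard, and finally sets heterozygous calls
#' to missing (doubled-haploid treatment).
#'
#' @param mat character matrix (markers x individuals) over
#'   `"A","B","H"`/NA with marker ids as rownames.
#' @param contigs optional data.frame `marker, contig, pos` assigning each
#'   marker to a reference contig.
#' @param params a [map_build_params()].
#' @return the filtered matrix with `"H"` replaced by NA.
#' @export
preprocess_markers <- function(mat, contigs = NULL,
                               params = map_build_params()) {
  stopifnot(!is.null(rownames(mat)))
  miss <- rowMeans(is.na(mat))
  mat <- mat[miss <= params$max_missing_marker, , drop = FALSE]

  if (params$one_marker_per_contig && !is.null(contigs)) {
    info <- contigs[match(rownames(mat), contigs$marker), , drop = FALSE]
    miss <- rowMeans(is.na(mat))
    ord <- order(info$contig, miss, info$pos)
    keep_first <- !duplicated(info$contig[ord])
    keep <- sort(ord[keep_first])
    mat <- mat[keep, , drop = FALSE]
  }

  bad <- rowMeans(is.na(mat)) + rowMeans(!is.na(mat) & mat == "H")
  mat <- mat[bad <= params$missing_threshold, , drop = FALSE]
  mat[!is.na(mat) & mat == "H"] <- NA_character_
  if (nrow(mat) == 0L)
    stop("no markers survived preprocessing; filters too strict for input")
  mat
}

#' Two-point recombination fraction and linkage test
#'
#' Over individuals non-missing at both markers, estimates the
#' recombination fraction as the fraction of parental-class disagreements
#' and tests linkage with a 1-df chi-square test of independence on the
#' 2x2 parental-class table.  The estimate is capped at 0.4999 so distance
#' transforms stay finite.
#'
#' @param x,y character vectors over `"A","B"`/NA for two markers.
#' @return list `r_hat, p_value, n_informative` (`r_hat` NA and `p_value`
#'   1 when no informative individuals exist).
#' @examples
#' recombination_fraction(c("A","A","B","B"), c("A","A","B","B"))
#' @export
recombination_fraction <- function(x, y) {
  ok <- !is.na(x) & !is.na(y) & x %in% c("A", "B") & y %in% c("A", "B")
  n <- sum(ok)
  if (n == 0L)
    return(list(r_hat = NA_real_, p_value = 1, n_informative = 0L))
  a <- sum(x[ok] == "A" & y[ok] == "A")
  b <- sum(x[ok] == "A" & y[ok] == "B")
  c_ <- sum(x[ok] == "B" & y[ok] == "A")
  d <- sum(x[ok] == "B" & y[ok] == "B")
  r <- (b + c_) / n
  stat <- chisq_2x2(a, b, c_, d)
  list(r_hat = min(r, 0.4999),
       p_value = pchisq(stat, df = 1L, lower.tail = FALSE),
       n_informative = n)
}

chisq_2x2 <- function(a, b, c_, d) {
  n <- a + b + c_ + d
  denom <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  ifelse(denom > 0, n * (a * d - b * c_)^2 / denom, 0)
}

## All-pairs recombination fractions, chi-square p-values and informative
## counts for a markers x individuals matrix, by matrix algebra.
pairwise_linkage <- function(mat) {
  XA <- (!is.na(mat) & mat == "A") * 1
  XB <- (!is.na(mat) & mat == "B") * 1
  nAA <- tcrossprod(XA)
  nBB <- tcrossprod(XB)
  nAB <- tcrossprod(XA, XB)
  nBA <- t(nAB)
  n <- nAA + nAB + nBA + nBB
  r <- ifelse(n > 0, (nAB + nBA) / n, NA_real_)
  stat <- chisq_2x2(nAA, nAB, nBA, nBB)
  p <- pchisq(stat, df = 1L, lower.tail = FALSE)
  p[n == 0] <- 1
  list(r = pmin(r, 0.4999), p = p, n = n)
}

#' Partition markers into linkage groups
#'
#' Single-linkage clustering: two markers join the same group iff their
#' two-point linkage p-value is at most `cut_off_p` and their estimated
#' recombination fraction lies below 0.5; linkage groups are the connected
#' components of the resulting graph.  The coupling requirement matters
#' because the chi-square test is two-sided: for parental-coded RIL data a
#' significant excess of disagreements (repulsion) cannot arise from
#' linkage and would otherwise create spurious joins.
#'
#' @param mat preprocessed character matrix over `"A","B"`/NA
#'   (markers x individuals).
#' @param params a [map_build_params()].
#' @return list of character vectors of marker ids, largest group first.
#' @export
group_markers <- function(mat, params = map_build_params()) {
  pl <- pairwise_linkage(mat)
  adj <- (pl$p <= params$cut_off_p) & !is.na(pl$r) & pl$r < 0.4999
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  groups <- split(rownames(mat), comp)
  groups[order(-lengths(groups), vapply(groups, `[`, "", 1L))]
}

#' Kosambi map function
#'
#' Converts a recombination fraction to genetic distance:
#' `d = 25 * ln((1 + 2r) / (1 - 2r))` centimorgans.
#'
#' @param r recombination fraction(s) in `[0, 0.5)`.
#' @return distance(s) in cM.
#' @examples
#' kosambi(0.25)   # 25 * log(3)
#' @export
kosambi <- function(r) {
  if (any(r < 0 | r >= 0.5, na.rm = TRUE))
    stop("recombination fraction must lie in [0, 0.5)")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Order markers within a linkage group
#'
#' Markers with identical genotype vectors are collapsed into bins.  A
#' complete graph over bins weighted by pairwise recombination fraction is
#' reduced to its minimum spanning tree; the weighted diameter path of the
#' tree seeds the order, remaining bins are inserted at the position of
#' least added adjacent recombination, and the order is refined by 2-opt
#' segment reversals minimising the sum of adjacent recombination
#' fractions.  Positions are cumulative Kosambi-transformed adjacent
#' fractions; bins share a cM position, members ordered by marker id.
#'
#' @param mat preprocessed character matrix over `"A","B"`/NA for the
#'   markers of one linkage group (>= 2 markers).
#' @return data.frame `marker, order_index, cM`.
#' @export
order_markers <- function(mat) {
  stopifnot(nrow(mat) >= 2L)
  key <- apply(mat, 1L, function(z) paste(ifelse(is.na(z), ".", z), collapse = ""))
  markers <- rownames(mat)
  bin_of <- match(key, unique(key))
  bins <- split(markers, bin_of)
  bins <- lapply(bins, sort)
  reps <- vapply(bins, `[`, "", 1L)
  m <- length(bins)
  if (m == 1L)
    return(data.frame(marker = bins[[1L]],
                      order_index = seq_along(bins[[1L]]),
                      cM = 0, stringsAsFactors = FALSE))

  R <- pairwise_linkage(mat[reps, , drop = FALSE])$r
  R[is.na(R)] <- 0.4999

  o <- mst_backbone_order(R)
  o <- two_opt(o, R)
  ## deterministic orientation: lexicographically smaller end first
  if (reps[o[1L]] > reps[o[m]]) o <- rev(o)

  adj_r <- R[cbind(o[-m], o[-1L])]
  cm <- c(0, cumsum(kosambi(pmin(adj_r, 0.4999))))
  out <- do.call(rbind, lapply(seq_along(o), function(i) {
    data.frame(marker = bins[[o[i]]], cM = cm[i], stringsAsFactors = FALSE)
  }))
  out$order_index <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("marker", "order_index", "cM")]
}

## Initial order: weighted diameter path of the MST, remaining vertices
## greedily inserted where they add least adjacent recombination.
mst_backbone_order <- function(R) {
  m <- nrow(R)
  g <- igraph::graph_from_adjacency_matrix(R + 1e-9, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  t <- igraph::mst(g)
  path <- as.integer(igraph::get_diameter(t))
  rest <- setdiff(seq_len(m), path)
  o <- path
  for (v in rest) {
    k <- length(o)
    ## insertion cost at slot 0 (before), between i,i+1, and after
    cost <- c(R[v, o[1L]],
              if (k > 1L) R[o[-k], v] + R[v, o[-1L]] - R[cbind(o[-k], o[-1L])]
              else numeric(0),
              R[o[k], v])
    slot <- which.min(cost)
    o <- append(o, v, after = slot - 1L)
  }
  o
}

## 2-opt segment reversals minimising the sum of adjacent weights.
two_opt <- function(o, R, max_moves = 4000L) {
  m <- length(o)
  if (m < 3L) return(o)
  for (it in seq_len(max_moves)) {
    A <- R[o, o]
    adj <- A[cbind(seq_len(m - 1L), 2:m)]
    L <- rbind(0, sweep(A[seq_len(m - 1L), , drop = FALSE], 1L, adj, "-"))
    Rt <- cbind(sweep(A[, 2:m, drop = FALSE], 2L, adj, "-"), 0)
    D <- L + Rt
    D[lower.tri(D, diag = TRUE)] <- Inf
    best <- which.min(D)
    if (D[best] > -1e-12) break
    i <- (best - 1L) %% m + 1L
    j <- (best - 1L) %/% m + 1L
    o[i:j] <- rev(o[i:j])
  }
  o
}

#' Build a de novo genetic map from an A/B/H marker matrix
#'
#' Runs [preprocess_markers()], [group_markers()] and [order_markers()] and
#' assembles the per-group ordered maps, discarding isolated marker sets
#' when the `no_map` parameters demand it.
#'
#' @param mat character matrix (markers x individuals) over `"A","B","H"`/NA.
#' @param contigs optional marker-to-contig table, see
#'   [preprocess_markers()].
#' @param params a [map_build_params()].
#' @return object of class `genetic_map`: data.frame
#'   `marker, group, order_index, cM` plus a `params` attribute.  Groups
#'   are named `LG1, LG2, ...` by decreasing size.
#' @export
build_genetic_map <- function(mat, contigs = NULL,
                              params = map_build_params()) {
  pre <- preprocess_markers(mat, contigs, params)
  groups <- group_markers(pre, params)
  maps <- lapply(seq_along(groups), function(gi) {
    ids <- groups[[gi]]
    if (length(ids) < 2L) {
      data.frame(marker = ids, group = sprintf("LG%d", gi),
                 order_index = 1L, cM = 0, stringsAsFactors = FALSE)
    } else {
      om <- order_markers(pre[ids, , drop = FALSE])
      cbind(om[, "marker", drop = FALSE], group = sprintf("LG%d", gi),
            om[, c("order_index", "cM")])
    }
  })
  res <- do.call(rbind, maps)
  rownames(res) <- NULL
  res <- drop_isolated(res, params)
  structure(res, class = c("genetic_map", "data.frame"), params = params)
}

## no_map post-filter: discard isolated sets of at most no_map_size markers
## (such sets sit beyond no_map_dist cM from every retained group by
## construction of the p-value clustering; inert for well-connected data).
drop_isolated <- function(map_df, params) {
  sizes <- table(map_df$group)
  small <- names(sizes)[sizes <= params$no_map_size]
  if (length(small) == length(sizes)) return(map_df)  # keep everything rather than nothing
  map_df[!(map_df$group %in% small), , drop = FALSE]
}

#' @export
print.genetic_map <- function(x, ...) {
  sizes <- table(x$group)
  lens <- tapply(x$cM, x$group, max)
  cat(sprintf("genetic map: %d markers in %d linkage group(s)\n",
              nrow(x), length(sizes)))
  for (g in names(sort(sizes, decreasing = TRUE)))
    cat(sprintf("  %s: %d markers, %.1f cM\n", g, sizes[[g]], lens[[g]]))
  invisible(x)
}
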