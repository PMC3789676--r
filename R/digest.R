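#' In-silico co-digestion of a genome with two restriction enzymes
#'
#' Cuts every occurrence of the rare-cutter (PstI, CTGCAG, cut after base 5
#' on the top strand) and frequent-cutter (MspI, CCGG, cut after base 1)
#' recognition sites.  The resulting fragments partition each chromosome
#' exactly; every internal boundary coincides with an enzyme cut, and each
#' fragment is labelled by the type of its two ends.
#'
#' Because simulated variants are never planted inside recognition sites,
#' digestion is identical for both parental haplotypes, so the reference
#' sequence is digested once for the whole experiment.
#'
#' @param ref a `gbs_reference`, or a named character vector of sequences.
#' @param config a [sim_config()] supplying the two enzymes.
#' @return data.frame of fragments with 0-based half-open `start`/`end` and
#'   end labels `left_end`/`right_end` in `{"PstI","MspI","chrom_end"}`
#'   (labels follow the configured enzyme names `rare` = PstI,
#'   `frequent` = MspI).
#' @examples
#' cfg <- sim_config()
#' digest_genome(c(chr1 = "AAACTGCAGTTTCCGGAAA"), cfg)
#' @export
digest_genome <- function(ref, config) {
  seqs <- if (inherits(ref, "gbs_reference")) ref$chromosomes else ref
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%d", seq_along(seqs))
  if (any(grepl("[^ACGT]", seqs)))
    stop("sequences must contain only A, C, G, T")
  out <- lapply(names(seqs), function(nm) {
    digest_one(seqs[[nm]], nm, config)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

digest_one <- function(seq, name, config) {
  L <- nchar(seq)
  cuts_of <- function(enz) {
    hits <- gregexpr(enz$site, seq, fixed = TRUE)[[1]]
    if (hits[1] == -1L) return(integer(0))
    as.integer(hits) - 1L + enz$cut   # 0-based cut position
  }
  rare <- cuts_of(config$enzyme_rare)
  freq <- cuts_of(config$enzyme_frequent)
  cuts <- c(rare, freq)
  labels <- c(rep("PstI", length(rare)), rep("MspI", length(freq)))
  ord <- order(cuts)
  cuts <- cuts[ord]; labels <- labels[ord]

  bounds <- c(0L, cuts, L)
  blabs <- c("chrom_end", labels, "chrom_end")
  n <- length(bounds) - 1L
  data.frame(
    chrom = rep(name, n),
    start = bounds[-length(bounds)],
    end = bounds[-1L],
    left_end = blabs[seq_len(n)],
    right_end = blabs[seq_len(n) + 1L],
    stringsAsFactors = FALSE
  )
}

#' Select fragments that amplify in a two-enzyme GBS library
#'
#' Only fragments with a PstI cut at one end and an MspI cut at the other
#' amplify: the barcoded forward adapter ligates to the PstI overhang while
#' the common Y-adapter on MspI ends suppresses amplification of MspI--MspI
#' fragments, and PstI--PstI and chromosome-end fragments lack a complete
#' adapter pair.  A size gate models PCR and sequencer preferences.
#'
#' @param fragments data.frame from [digest_genome()].
#' @param config a [sim_config()]; `amplifiable_size_range` gives the
#'   inclusive bp interval of fragment lengths retained.
#' @return the subset of `fragments` that amplifies, original order kept.
#' @export
select_amplifiable <- function(fragments, config) {
  len <- fragments$end - fragments$start
  pm <- (fragments$left_end == "PstI" & fragments$right_end == "MspI") |
        (fragments$left_end == "MspI" & fragments$right_end == "PstI")
  keep <- pm & len >= config$amplifiable_size_range[1] &
               len <= config$amplifiable_size_range[2]
  fragments[keep, , drop = FALSE]
}
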