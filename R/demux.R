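#' Demultiplex reads by exact barcode and cut-site match
#'
#' A read is assigned to a sample iff its first `L` bases exactly equal that
#' sample's barcode (all barcodes equal length `L`) and the following bases
#' exactly equal the expected prefix (spacer, if any, followed by the PstI
#' cut-site remnant `TGCAG`).  No mismatches are tolerated.  The barcode and
#' spacer are removed from assigned reads; the cut-site remnant is retained
#' because it is genomic sequence.  Unassigned reads are counted but not
#' emitted.
#'
#' @param reads a `read_set`, or a data.frame with columns `id, seq, qual`.
#' @param barcodes named character vector (sample id -> barcode), all equal
#'   length and unique.
#' @param spacer fixed sequence between barcode and remnant (default `""`).
#' @param cutsite_remnant expected remnant after the spacer.
#' @return list with
#'   \describe{
#'     \item{samples}{named list of per-sample data.frames `id, seq, qual`
#'       (barcode+spacer removed).}
#'     \item{stats}{list `total_reads, assigned_reads, per_sample_counts,
#'       discarded_short` (the latter filled in by adapter trimming).}
#'   }
#' @examples
#' bc <- c(s1 = "AAACCCTTT")
#' rd <- data.frame(id = "r1", seq = "AAACCCTTTTGCAGACGTACGT",
#'                  qual = strrep("I", 22))
#' demultiplex(rd, bc)$samples$s1$seq
#' @export
demultiplex <- function(reads, barcodes, spacer = "",
                        cutsite_remnant = "TGCAG") {
  if (length(barcodes) == 0L) stop("empty barcode set")
  if (anyDuplicated(barcodes)) stop("barcodes must be unique")
  bl <- unique(nchar(barcodes))
  if (length(bl) != 1L) stop("all barcodes must have equal length")
  rd <- if (inherits(reads, "read_set")) reads$reads else reads

  prefix <- paste0(spacer, cutsite_remnant)
  pl <- nchar(prefix)
  bc_obs <- substr(rd$seq, 1L, bl)
  pre_obs <- substr(rd$seq, bl + 1L, bl + pl)
  samp <- names(barcodes)[match(bc_obs, barcodes)]
  ok <- !is.na(samp) & pre_obs == prefix

  drop_n <- bl + nchar(spacer)
  out_seq <- substring(rd$seq, drop_n + 1L)
  out_qual <- substring(rd$qual, drop_n + 1L)

  per_sample <- setNames(vector("list", length(barcodes)), names(barcodes))
  counts <- setNames(integer(length(barcodes)), names(barcodes))
  for (s in names(barcodes)) {
    sel <- which(ok & samp == s)
    per_sample[[s]] <- data.frame(id = rd$id[sel], seq = out_seq[sel],
                                  qual = out_qual[sel],
                                  stringsAsFactors = FALSE)
    counts[[s]] <- length(sel)
  }
  stats <- list(total_reads = nrow(rd),
                assigned_reads = sum(ok),
                per_sample_counts = counts,
                discarded_short = 0L)
  list(samples = per_sample, stats = stats)
}

#' Trim the reverse adapter from the 3' end of reads
#'
#' Scans every start offset for a semi-global match of the adapter's prefix
#' against the read (overlap at least `min_overlap` bases, mismatch fraction
#' at most `max_error_rate`); the leftmost valid match wins and the read is
#' truncated at its start.  Reads shorter than `min_length` bases after
#' trimming are discarded.  Quality strings are trimmed in lockstep.
#'
#' @param reads data.frame `id, seq, qual` (one demultiplexed sample).
#' @param adapter adapter sequence to remove.
#' @param min_overlap minimum adapter overlap in bases (default 3).
#' @param max_error_rate maximum mismatch fraction in the overlap
#'   (default 0.1).
#' @param min_length reads shorter than this after trimming are discarded
#'   (default 30).
#' @return list with `reads` (the surviving trimmed data.frame) and
#'   `n_discarded` (reads dropped by the length filter).
#' @export
trim_reverse_adapter <- function(reads, adapter, min_overlap = 3L,
                                 max_error_rate = 0.1, min_length = 30L) {
  stopifnot(min_overlap >= 1L)
  if (nrow(reads) == 0L)
    return(list(reads = reads, n_discarded = 0L))
  lens <- nchar(reads$seq)
  maxlen <- max(lens)
  acode <- utf8ToInt(adapter)
  alen <- length(acode)

  ## integer code matrix, NA beyond each read's length
  M <- matrix(NA_integer_, nrow(reads), maxlen)
  codes <- lapply(reads$seq, utf8ToInt)
  for (i in seq_len(nrow(reads))) M[i, seq_len(lens[i])] <- codes[[i]]

  trim_at <- rep(NA_integer_, nrow(reads))
  for (j in seq_len(maxlen)) {
    if (!anyNA(trim_at)) break
    w <- min(alen, maxlen - j + 1L)
    slice <- M[, j:(j + w - 1L), drop = FALSE]
    diffm <- slice != rep(acode[seq_len(w)], each = nrow(slice))
    ov <- rowSums(!is.na(diffm))
    mism <- rowSums(diffm, na.rm = TRUE)
    valid <- ov >= min_overlap & mism <= max_error_rate * ov
    hit <- is.na(trim_at) & valid
    trim_at[hit] <- j
  }

  new_len <- ifelse(is.na(trim_at), lens, trim_at - 1L)
  keep <- new_len >= min_length
  out <- reads[keep, , drop = FALSE]
  out$seq <- substr(out$seq, 1L, new_len[keep])
  out$qual <- substr(out$qual, 1L, new_len[keep])
  rownames(out) <- NULL
  list(reads = out, n_discarded = sum(!keep))
}
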