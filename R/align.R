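#' Build an exact k-mer index over reference contigs
#'
#' Records the (contig, offset) of every forward-strand k-mer of every
#' contig.  K-mers occurring at more than one position are flagged ambiguous
#' and never used as seeds.
#'
#' @param ref a `gbs_reference` (indexes its contigs) or a named character
#'   vector of contig sequences.
#' @param k k-mer length (>= 11; default 21).
#' @return an object of class `kmer_index`.
#' @export
build_index <- function(ref, k = 21L) {
  stopifnot(k >= 11L)
  seqs <- if (inherits(ref, "gbs_reference")) contig_sequences(ref) else ref
  lens <- nchar(seqs)
  usable <- lens >= k
  kmers <- character(0); contig <- character(0); off <- integer(0)
  for (nm in names(seqs)[usable]) {
    n <- lens[[nm]]
    starts <- seq_len(n - k + 1L)
    km <- substring(seqs[[nm]], starts, starts + k - 1L)
    kmers <- c(kmers, km)
    contig <- c(contig, rep(nm, length(km)))
    off <- c(off, starts - 1L)
  }
  dup <- duplicated(kmers) | duplicated(kmers, fromLast = TRUE)
  structure(list(k = k,
                 kmers = kmers[!dup],
                 contig = contig[!dup],
                 offset = off[!dup],
                 ambiguous = unique(kmers[dup]),
                 contig_seqs = seqs,
                 contig_len = lens),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("k-mer index: k=%d, %d contigs, %d unique k-mers, %d ambiguous\n",
              x$k, length(x$contig_seqs), length(x$kmers),
              length(x$ambiguous)))
  invisible(x)
}

#' Place reads on the reference by seed-and-extend
#'
#' Seeds each read with its first non-ambiguous k-mer (scanning both the
#' read and its reverse complement), extends the implied placement ungapped,
#' and accepts it when the mismatch fraction is at most `max_mismatch_frac`
#' and exactly one strand yields a valid placement.  Reads seeding on both
#' strands, overhanging a contig, or exceeding the mismatch gate are
#' dropped, emulating a mapping-quality filter.
#'
#' @param reads data.frame `id, seq` (a `qual` column is ignored).
#' @param index a `kmer_index` from [build_index()].
#' @param max_mismatch_frac maximum mismatch fraction (default 0.05).
#' @param max_seed_offsets how many seed windows to try, spaced k apart so
#'   a single variant or error cannot block every window (default 4).
#' @return data.frame of placements: `id, contig, offset` (0-based start),
#'   `strand, n_mismatch, seq_fwd` (read oriented to the contig's forward
#'   strand).  Unplaced reads are absent.
#' @export
place_reads <- function(reads, index, max_mismatch_frac = 0.05,
                        max_seed_offsets = 4L) {
  k <- index$k
  n <- nrow(reads)
  if (n == 0L)
    return(data.frame(id = character(0), contig = character(0),
                      offset = integer(0), strand = character(0),
                      n_mismatch = integer(0), seq_fwd = character(0),
                      stringsAsFactors = FALSE))
  seq <- reads$seq
  lens <- nchar(seq)
  rcseq <- revcomp(seq)

  res_contig <- rep(NA_character_, n)
  res_off <- rep(NA_integer_, n)
  res_strand <- rep(NA_character_, n)
  res_mm <- rep(NA_integer_, n)
  done <- lens < k          # too short to seed

  for (s in 1L + k * (seq_len(max_seed_offsets) - 1L)) {
    todo <- which(!done & lens >= s + k - 1L)
    if (length(todo) == 0L) break
    fwd_km <- substr(seq[todo], s, s + k - 1L)
    rc_km <- substr(rcseq[todo], s, s + k - 1L)
    fi <- match(fwd_km, index$kmers)
    ri <- match(rc_km, index$kmers)
    amb <- fwd_km %in% index$ambiguous | rc_km %in% index$ambiguous

    for (t in seq_along(todo)) {
      i <- todo[t]
      if (amb[t]) next   # ambiguous seed: try the next offset
      cand <- list()
      if (!is.na(fi[t]))
        cand[[length(cand) + 1L]] <- list(strand = "+", hit = fi[t], sq = seq[i])
      if (!is.na(ri[t]))
        cand[[length(cand) + 1L]] <- list(strand = "-", hit = ri[t], sq = rcseq[i])
      if (length(cand) == 0L) next
      ok <- list()
      for (cc in cand) {
        ctg <- index$contig[cc$hit]
        start0 <- index$offset[cc$hit] - (s - 1L)
        if (start0 < 0L || start0 + lens[i] > index$contig_len[[ctg]]) next
        refsub <- substr(index$contig_seqs[[ctg]], start0 + 1L, start0 + lens[i])
        mm <- sum(utf8ToInt(cc$sq) != utf8ToInt(refsub))
        if (mm <= max_mismatch_frac * lens[i])
          ok[[length(ok) + 1L]] <- list(contig = ctg, off = start0,
                                        strand = cc$strand, mm = mm, sq = cc$sq)
      }
      if (length(ok) == 1L) {
        res_contig[i] <- ok[[1]]$contig
        res_off[i] <- ok[[1]]$off
        res_strand[i] <- ok[[1]]$strand
        res_mm[i] <- ok[[1]]$mm
        seq[i] <- ok[[1]]$sq       # store forward-oriented sequence
        done[i] <- TRUE
      } else if (length(ok) > 1L) {
        done[i] <- TRUE            # multi-strand placement: ambiguous, drop
      }
    }
  }

  placed <- which(!is.na(res_contig))
  data.frame(id = reads$id[placed], contig = res_contig[placed],
             offset = res_off[placed], strand = res_strand[placed],
             n_mismatch = res_mm[placed], seq_fwd = seq[placed],
             stringsAsFactors = FALSE)
}

#' Place a single read
#'
#' Convenience wrapper around [place_reads()] for one sequence.
#'
#' @param read a single character string.
#' @param index a `kmer_index`.
#' @param max_mismatch_frac maximum mismatch fraction.
#' @return a one-row placement data.frame, or NULL if the read cannot be
#'   placed.
#' @export
place_read <- function(read, index, max_mismatch_frac = 0.05) {
  out <- place_reads(data.frame(id = "r", seq = read,
                                stringsAsFactors = FALSE),
                     index, max_mismatch_frac)
  if (nrow(out) == 0L) NULL else out
}
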