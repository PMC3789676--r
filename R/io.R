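#' Read and write the standard pipeline file formats
#'
#' FASTA for references, FASTQ (Phred+33, optionally gzipped) for reads,
#' TSV for barcode tables and contig anchors, VCF 4.2 (`GT:DP:GQ`) for
#' genotype tables.  All coordinates are 0-based half-open internally and
#' 1-based only inside VCF records.
#'
#' @param ref a `gbs_reference`.
#' @param path output or input file path.
#' @name gbs_io
NULL

#' @rdname gbs_io
#' @export
write_reference_fasta <- function(ref, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(ref$chromosomes), path)
  invisible(path)
}

#' @rdname gbs_io
#' @export
write_contig_anchors <- function(ref, path) {
  write.table(ref$contigs, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname gbs_io
#' @param anchors_path path of a contig anchor TSV
#'   (`contig_id, chrom, start, end, cM`).
#' @export
read_reference_fasta <- function(path, anchors_path = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  chromosomes <- setNames(as.character(seqs), names(seqs))
  contigs <- if (is.null(anchors_path)) {
    data.frame(contig_id = names(chromosomes), chrom = names(chromosomes),
               start = 0L, end = nchar(chromosomes), cM = 0,
               stringsAsFactors = FALSE)
  } else {
    read.table(anchors_path, header = TRUE, sep = "\t",
               stringsAsFactors = FALSE)
  }
  structure(list(chromosomes = chromosomes, contigs = contigs),
            class = "gbs_reference")
}

#' @rdname gbs_io
#' @param reads a `read_set` or data.frame `id, seq, qual`.
#' @export
write_fastq <- function(reads, path) {
  rd <- if (inherits(reads, "read_set")) reads$reads else reads
  dss <- Biostrings::DNAStringSet(rd$seq)
  names(dss) <- rd$id
  Biostrings::writeXStringSet(dss, path, format = "fastq",
                              qualities = Biostrings::BStringSet(rd$qual),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' @rdname gbs_io
#' @export
read_fastq <- function(path) {
  dss <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
  data.frame(id = names(dss), seq = as.character(dss),
             qual = as.character(S4Vectors::mcols(dss)$qualities),
             stringsAsFactors = FALSE)
}

#' @rdname gbs_io
#' @param barcodes named character vector (sample -> barcode).
#' @export
write_barcode_table <- function(barcodes, path) {
  write.table(data.frame(sample_id = names(barcodes), barcode = barcodes),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname gbs_io
#' @export
read_barcode_table <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  setNames(d$barcode, d$sample_id)
}

#' Write a genotype table as VCF 4.2
#'
#' Emits one record per site with 1-based positions and per-sample
#' `GT:DP:GQ` fields.
#'
#' @param table a [genotype_table()].
#' @param path output path (vcfR appends `.gz`; pass a `.vcf.gz` name).
#' @return the path written.
#' @export
write_genotype_vcf <- function(table, path) {
  n <- nrow(table$sites)
  meta <- c("##fileformat=VCFv4.2",
            sprintf("##source=gbsim (%s)", table$provenance),
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
            "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">")
  fix <- cbind(CHROM = table$sites$contig,
               POS = as.character(table$sites$pos + 1L),
               ID = rep(".", n),
               REF = table$sites$ref, ALT = table$sites$alt,
               QUAL = rep(".", n), FILTER = rep("PASS", n),
               INFO = rep(".", n))
  gt_codes <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.:0:0", n, length(table$samples))
  called <- !is.na(table$geno)
  gt[called] <- sprintf("%s:%d:%d",
                        gt_codes[table$geno[called] + 1L],
                        as.integer(table$depth[called]),
                        as.integer(table$gq[called]))
  gt <- cbind(FORMAT = rep("GT:DP:GQ", n), gt)
  colnames(gt) <- c("FORMAT", table$samples)
  v <- new("vcfR", meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(v, path)
  invisible(path)
}

#' Read a `GT:DP:GQ` VCF back into a genotype table
#'
#' @param path VCF path (optionally gzipped).
#' @param provenance dataset label to attach.
#' @return a [genotype_table()].
#' @export
read_genotype_vcf <- function(path, provenance = basename(path)) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  sites <- data.frame(contig = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]) - 1L,
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  gq <- vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE)
  geno <- matrix(NA_integer_, nrow(gt), ncol(gt))
  geno[gt == "0/0"] <- 0L
  geno[gt %in% c("0/1", "1/0")] <- 1L
  geno[gt == "1/1"] <- 2L
  dp[is.na(dp)] <- 0
  gq[is.na(gq)] <- 0
  genotype_table(sites, colnames(gt), geno, depth = dp, gq = gq,
                 provenance = provenance)
}

#' Convert simulation truth genotypes into a genotype table
#'
#' Expresses the true A/B/H calls of a simulated population as a
#' [genotype_table()] in chromosome coordinates, with the parent-A allele
#' as reference and parent-B allele as alternate.
#'
#' @param pop a `ril_population`.
#' @param variants the parental variant table.
#' @param provenance dataset label.
#' @return a [genotype_table()] (depth/GQ set to a nominal 99).
#' @export
truth_genotype_table <- function(pop, variants, provenance = "truth") {
  key <- paste(pop$loci$chrom, pop$loci$pos)
  vi <- match(key, paste(variants$chrom, variants$pos))
  sites <- data.frame(contig = pop$loci$chrom, pos = pop$loci$pos,
                      ref = variants$allele_a[vi],
                      alt = variants$allele_b[vi],
                      stringsAsFactors = FALSE)
  geno <- matrix(match(pop$calls, c("A", "H", "B")) - 1L,
                 nrow(pop$calls), ncol(pop$calls))
  hi <- matrix(99, nrow(geno), ncol(geno))
  genotype_table(sites, pop$individuals, geno, depth = hi, gq = hi,
                 provenance = provenance)
}
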