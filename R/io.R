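## Standard-format I/O. FASTA via Biostrings, SAM via plain writer +
## Rsamtools reader, BED via rtracklayer (see regions.R), tables as TSV.

#' Write a reference sequence to FASTA
#'
#' @param x a `twin_reference` or a named character vector of contigs.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  genome <- as_genome(x)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Read a genome FASTA into a named character vector
#'
#' @param path FASTA file.
#' @return named character vector, one element per contig (name = first
#'   whitespace-delimited token of the header).
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  names(ss) <- sub("\\s.*$", "", names(ss))
  stats::setNames(as.character(ss), names(ss))
}

#' Write alignment records as SAM
#'
#' Emits a valid header (`@HD`, `@SQ`) followed by one record per read.
#' Alternative alignments are carried on the standard `XA:Z:` tag; the
#' indel-realignment annotation of the synthetic generator rides on a
#' user-space `XR:i:1` tag so it survives the SAM/BAM round trip.
#'
#' @param reads alignment record `data.frame` (see
#'   [generate_twin_alignments()]).
#' @param path output SAM file.
#' @param genome `twin_reference` or named character vector (for `@SQ`
#'   lines); alternatively a named integer vector of contig lengths.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, path, genome) {
  if (is.numeric(genome) && !is.null(names(genome))) {
    lens <- genome
  } else {
    g <- as_genome(genome)
    lens <- stats::setNames(nchar(g), names(g))
  }
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(lens), as.integer(lens)))
  body <- paste(reads$qname, reads$flag, reads$chrom, reads$pos, reads$mapq,
                reads$cigar, "*", 0L, 0L, reads$seq, reads$qual, sep = "\t")
  xa <- ifelse(is.na(reads$xa), "", paste0("\tXA:Z:", reads$xa))
  xr <- ifelse(isTRUE_vec(reads$realigned), "\tXR:i:1", "")
  writeLines(c(header, paste0(body, xa, xr)), path)
  invisible(path)
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else !is.na(x) & x

#' Read a SAM file into an alignment record data frame
#'
#' Round-trips through Rsamtools (`asBam` + `scanBam`), so anything samtools
#' would reject is rejected here too. Records come back coordinate-sorted.
#'
#' @param path SAM file.
#' @return alignment record `data.frame` with the columns written by
#'   [write_sam()].
#' @export
read_sam <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"),
    tag = c("XA", "XR")
  )
  r <- Rsamtools::scanBam(bam, param = param)[[1L]]
  n <- length(r$qname)
  xa <- r$tag$XA %||% rep(NA_character_, n)
  xr <- r$tag$XR %||% rep(NA_integer_, n)
  data.frame(
    qname = r$qname, flag = r$flag, chrom = as.character(r$rname),
    pos = r$pos, mapq = r$mapq, cigar = r$cigar,
    seq = as.character(r$seq), qual = as.character(r$qual),
    xa = as.character(xa), realigned = !is.na(xr) & xr == 1L,
    stringsAsFactors = FALSE
  )
}

#' Write / read a candidate SNV table as TSV
#'
#' The TSV dialect mirrors the caller-annotated VCF fields (`BQ`, `QSS`,
#' `DP`) as plain columns; [read_candidates()] also accepts a VCF carrying
#' those INFO keys when `VariantAnnotation` is installed.
#'
#' @param candidates candidate `data.frame`
#'   (see [candidates_from_alignments()]).
#' @param path file path.
#' @return `path` (writer) or a candidate `data.frame` (reader).
#' @export
write_candidates <- function(candidates, path) {
  utils::write.table(candidates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_candidates
#' @export
read_candidates <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
      stop("reading VCF candidates requires the VariantAnnotation package",
           call. = FALSE)
    }
    v <- VariantAnnotation::readVcf(path)
    rr <- SummarizedExperiment::rowRanges(v)
    info <- VariantAnnotation::info(v)
    alt <- as.character(unlist(rr$ALT))
    bq <- if (is.null(info$BQ)) rep(NA_real_, length(rr)) else as.numeric(info$BQ)
    qss <- if (is.null(info$QSS)) rep(NA_real_, length(rr)) else as.numeric(info$QSS)
    return(data.frame(
      chrom = as.character(GenomicRanges::seqnames(rr)),
      pos = GenomicRanges::start(rr),
      ref = as.character(rr$REF), alt = alt,
      caller = ifelse(!is.na(qss), "strelka-like", "mutect-like"),
      bq = bq, qss = qss,
      dp = as.integer(info$DP),
      stringsAsFactors = FALSE
    ))
  }
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write candidates as a minimal VCF
#'
#' @param candidates candidate table.
#' @param path output file.
#' @param genome optional genome for `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_candidates_vcf <- function(candidates, path, genome = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Site depth\">",
           "##INFO=<ID=BQ,Number=1,Type=Float,Description=\"Mean alt base quality\">",
           "##INFO=<ID=QSS,Number=1,Type=Integer,Description=\"Quality score for somatic SNV\">")
  if (!is.null(genome)) {
    g <- as_genome(genome)
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(g), nchar(g)))
  }
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  qinfo <- ifelse(!is.na(candidates$bq), sprintf(";BQ=%.1f", candidates$bq),
                  ifelse(!is.na(candidates$qss),
                         sprintf(";QSS=%d", as.integer(candidates$qss)), ""))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d%s",
                  candidates$chrom, candidates$pos, candidates$ref,
                  candidates$alt, candidates$dp, qinfo)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write / read deep-amplicon base-call count tables as TSV
#'
#' Columns: `chrom`, `pos`, `ref`, `alt`, `sample`, `ref_count`,
#' `alt_count`, `other_count`, `depth`.
#'
#' @param counts a TAS count `data.frame` (see [generate_tas_counts()]).
#' @param path file path.
#' @return `path` (writer) or the count `data.frame` (reader).
#' @export
write_tas_counts <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_tas_counts
#' @export
read_tas_counts <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
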