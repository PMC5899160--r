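# Hand-built fixtures: single alignment records, toy genomes, synthetic
# pileups, and a cached end-to-end demo run shared across test files.

make_read <- function(seq, pos = 1L, qname = "r1", chrom = "chr1",
                      qual = NULL, q = 35L, cigar = NULL, mapq = 60L,
                      xa = NA_character_, realigned = FALSE) {
  if (is.null(cigar)) cigar <- sprintf("%dM", nchar(seq))
  if (is.null(qual)) qual <- intToUtf8(rep(q + 33L, nchar(seq)))
  data.frame(qname = qname, flag = 0L, chrom = chrom, pos = as.integer(pos),
             mapq = as.integer(mapq), cigar = cigar, seq = seq, qual = qual,
             xa = xa, realigned = realigned, stringsAsFactors = FALSE)
}

bind_reads <- function(...) {
  out <- do.call(rbind, list(...))
  rownames(out) <- NULL
  out
}

random_genome <- function(len, seed, name = "chr1") {
  withr::with_seed(seed, {
    stats::setNames(paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                          collapse = ""), name)
  })
}

# reads covering a single site at a given alt fraction; returns the reads
# plus which reads were planted. artifact: "none"/"softclip"/"xa"/"edge"
# applied to the planted reads.
make_site_pileup <- function(genome, pos, alt, depth, aaf, seed,
                             chrom = "chr1", read_len = 100L, q = 35L,
                             artifact = "none") {
  withr::with_seed(seed, {
    L <- nchar(genome[[chrom]])
    lo <- max(1L, pos - read_len + 1L)
    hi <- min(pos, L - read_len + 1L)
    starts <- sample(lo:hi, depth, replace = TRUE)
    reads <- lapply(seq_len(depth), function(i) {
      s <- starts[i]
      sq <- substring(genome[[chrom]], s, s + read_len - 1L)
      planted <- runif(1) < aaf
      off <- pos - s + 1L
      cigar <- NULL; mq <- 60L; xa <- NA_character_; p <- s
      if (planted) {
        if (artifact == "edge" && off > 10L && off < read_len - 9L) {
          planted <- FALSE
        } else {
          substr(sq, off, off) <- alt
          if (artifact == "softclip") {
            if (off > read_len / 2) {
              cigar <- sprintf("10S%dM", read_len - 10L)
              p <- s + 10L
            } else {
              cigar <- sprintf("%dM10S", read_len - 10L)
            }
          } else if (artifact == "xa") {
            xa <- sprintf("%s,+1,%dM,2;", chrom, read_len)
            mq <- 25L
          }
        }
      }
      r <- make_read(sq, pos = p, qname = sprintf("p%04d", i), chrom = chrom,
                     q = q, cigar = cigar, mapq = mq, xa = xa)
      r$planted <- planted
      r
    })
    out <- do.call(rbind, reads)
    rownames(out) <- NULL
    out
  })
}

# cached demo pipeline run (built once per test session)
.demo_env <- new.env(parent = emptyenv())
demo_run <- function() {
  if (is.null(.demo_env$res)) {
    out <- file.path(tempdir(), "twinsom-demo-cache")
    cfg <- run_config(outdir = out, seed = 20240411, scenario = demo_scenario())
    .demo_env$res <- run_pipeline(cfg)
  }
  .demo_env$res
}

table2_sites <- function() {
  utils::read.delim(system.file("extdata", "tas_validated_sites.tsv",
                                package = "twinsom"))
}
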