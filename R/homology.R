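#' Second-best homology score of a candidate's flanking sequence
#'
#' Screens a candidate site for homologous copies elsewhere in the genome,
#' the failure mode behind cross-mapped false positives. The ±`flank` bp
#' sequence around the site is scored against every full-length window of
#' the genome on both strands with the BLAT-style convention
#' `score = matches - mismatches`, and the best hit whose footprint does
#' not overlap the flank's own location is reported. A unique flank scores
#' far below zero against unrelated sequence; an exact duplicate scores the
#' full flank length (201 for the default ±100 bp window). Sites whose
#' second-best score reaches the exclusion threshold (< 160 passes, by
#' convention) have a near-identical copy elsewhere and are discarded by
#' [run_cascade()].
#'
#' Gapped alignment is deliberately not attempted: the score is a
#' same-length sliding comparison, which preserves the threshold semantics
#' while staying exactly reproducible. Precomputed scores from an external
#' aligner can be passed to [run_cascade()] instead.
#'
#' @param genome `twin_reference` or named character vector of contigs.
#' @param chrom,pos site location (1-based).
#' @param flank half-width of the window (default 100, i.e. a 201-mer).
#' @param exclude_self drop hits overlapping the site's own flank interval.
#' @return list with `second_best_score`, `top_score` (the self hit, equal
#'   to the flank length), `flank_length`, and `truncated` (flank clipped
#'   at a contig end). Truncation raises a warning of class
#'   `twinsom_truncated_flank` and the score is computed on the available
#'   bases.
#' @export
second_best_homology_score <- function(genome, chrom, pos, flank = 100L,
                                       exclude_self = TRUE) {
  genome <- as_genome(genome)
  stopifnot(chrom %in% names(genome))
  L <- nchar(genome[[chrom]])
  fs <- max(1L, pos - flank)
  fe <- min(L, pos + flank)
  truncated <- (fs != pos - flank) || (fe != pos + flank)
  if (truncated) {
    warning(structure(
      class = c("twinsom_truncated_flank", "warning", "condition"),
      list(message = sprintf(
        "flank around %s:%d truncated to [%d,%d] at contig end; score computed on available bases",
        chrom, pos, fs, fe), call = sys.call())
    ))
  }
  fseq <- substring(genome[[chrom]], fs, fe)
  flen <- nchar(fseq)
  fint <- utf8ToInt(fseq)

  best <- -Inf
  for (ctg in names(genome)) {
    gint <- utf8ToInt(genome[[ctg]])
    Lc <- length(gint)
    # forward strand
    sc <- slide_scores(gint, fint)
    if (length(sc)) {
      if (exclude_self && ctg == chrom) {
        ws <- seq_along(sc)
        mask <- ws <= fe & (ws + flen - 1L) >= fs
        sc[mask] <- -Inf
      }
      best <- max(best, max(sc))
    }
    # reverse strand: score against the reverse complement, mapping each
    # window back to forward coordinates for self-exclusion
    rint <- utf8ToInt(revcomp(genome[[ctg]]))
    scr <- slide_scores(rint, fint)
    if (length(scr)) {
      if (exclude_self && ctg == chrom) {
        ws <- seq_along(scr)
        f_start <- Lc - (ws + flen - 1L) + 1L
        f_end <- Lc - ws + 1L
        mask <- f_start <= fe & f_end >= fs
        scr[mask] <- -Inf
      }
      best <- max(best, max(scr))
    }
  }
  list(second_best_score = if (is.finite(best)) as.integer(best) else NA_integer_,
       top_score = flen, flank_length = flen, truncated = truncated)
}

# matches-minus-mismatches score of `f` against every full-length window of
# `g`, both integer-coded character vectors
slide_scores <- function(g, f) {
  nw <- length(g) - length(f) + 1L
  if (nw < 1L) return(numeric(0))
  matches <- integer(nw)
  for (j in seq_along(f)) {
    matches <- matches + (g[j:(j + nw - 1L)] == f[j])
  }
  2L * matches - length(f)
}
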