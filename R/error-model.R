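#' Sequencing error and artifact model
#'
#' Describes how the synthetic read generator corrupts reads. Per-base
#' substitution errors follow the Phred model: a base emitted with quality
#' `Q` is miscalled with probability `10^(-Q/10)`, uniformly over the three
#' non-reference bases. Qualities are drawn i.i.d. from the discrete
#' distribution (`quality_levels`, `quality_probs`); the default mix gives a
#' mean error rate of roughly 1e-3, i.e. the Q30 regime of quality-trimmed
#' Illumina exome data.
#'
#' Alignment artifacts are the read-level failure modes the downstream
#' filters are designed to catch:
#' \describe{
#'   \item{softclip_rate}{fraction of reads whose first or last 10 bases are
#'     soft-clipped out of the alignment.}
#'   \item{xa_rate}{fraction of reads carrying an `XA` alternative-alignment
#'     tag (multi-mapping ambiguity); these also get a reduced mapQ.}
#'   \item{edge_error_rate}{fraction of reads receiving an extra substitution
#'     within 5 bases of a read end, emulating cycle-end chemistry errors.}
#'   \item{indel_read_rate}{fraction of reads carrying a dispersed spurious
#'     2-bp deletion plus a nearby mismatch cluster. Locus-specific
#'     realignment artifacts are planted separately via `indel_loci` in
#'     [generate_twin_alignments()] because they cluster at positions, not
#'     uniformly over reads.}
#' }
#'
#' @param read_length read length in bases.
#' @param quality_levels Phred scores the per-base qualities are drawn from.
#' @param quality_probs sampling probabilities, same length as
#'   `quality_levels`; need not be normalized.
#' @param softclip_rate,xa_rate,edge_error_rate,indel_read_rate artifact
#'   probabilities in `[0, 1]`, per read.
#' @return an object of class `twinsom_error_model`.
#' @export
error_model <- function(read_length = 100L,
                        quality_levels = c(22L, 30L, 37L),
                        quality_probs = c(0.05, 0.25, 0.70),
                        softclip_rate = 0.01,
                        xa_rate = 0.01,
                        edge_error_rate = 0.01,
                        indel_read_rate = 5e-4) {
  stopifnot(
    read_length >= 30L,
    length(quality_levels) == length(quality_probs),
    all(quality_levels >= 0),
    all(quality_probs >= 0), sum(quality_probs) > 0
  )
  rates <- c(softclip_rate, xa_rate, edge_error_rate, indel_read_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("artifact rates must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      read_length = as.integer(read_length),
      quality_levels = as.integer(quality_levels),
      quality_probs = quality_probs / sum(quality_probs),
      softclip_rate = softclip_rate,
      xa_rate = xa_rate,
      edge_error_rate = edge_error_rate,
      indel_read_rate = indel_read_rate
    ),
    class = "twinsom_error_model"
  )
}

#' Mean per-base substitution error probability of an error model
#'
#' Expectation of `10^(-Q/10)` over the model's quality distribution.
#'
#' @param err a `twinsom_error_model`.
#' @return a probability.
#' @export
mean_error_prob <- function(err) {
  stopifnot(inherits(err, "twinsom_error_model"))
  sum(err$quality_probs * phred_error_prob(err$quality_levels))
}

#' @export
print.twinsom_error_model <- function(x, ...) {
  cat("Sequencing error model\n")
  cat("  read length:", x$read_length, "\n")
  cat("  quality levels:", paste(x$quality_levels, collapse = "/"),
      sprintf("(mean error %.2e)\n", mean_error_prob(x)))
  cat(sprintf("  artifact rates: softclip %.3g, XA %.3g, edge %.3g, indel %.3g\n",
              x$softclip_rate, x$xa_rate, x$edge_error_rate, x$indel_read_rate))
  invisible(x)
}
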