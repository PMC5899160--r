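## Deep-amplicon (TAS) counts, allele fractions, and the Phred-derived
## validation threshold.

#' Simulate deep-amplicon base-call counts at a site
#'
#' Alt base-calls are drawn as `Binomial(depth, p)` with
#' `p = true_aaf + (1 - true_aaf) * error_rate / 3` under a uniform-miscall
#' model (an erroneous base is uniform over the three non-reference bases,
#' so a third of miscalls hit the alt allele); "other"-base calls take the
#' remaining two thirds. Totals always equal `depth`, and output is
#' deterministic under `seed`.
#'
#' @param true_aaf true alternate allele fraction in `[0, 1]` (vectorized).
#' @param depth total qualified base-calls (vectorized).
#' @param error_rate total per-base miscall probability.
#' @param seed RNG seed.
#' @param chrom,pos,ref,alt,sample optional site/sample annotations carried
#'   through to the output.
#' @return `data.frame` with `ref_count`, `alt_count`, `other_count`,
#'   `depth` (one row per site).
#' @export
generate_tas_counts <- function(true_aaf, depth, error_rate = 0, seed,
                                chrom = NULL, pos = NULL, ref = NULL,
                                alt = NULL, sample = NULL) {
  n <- max(length(true_aaf), length(depth))
  true_aaf <- rep_len(true_aaf, n)
  depth <- rep_len(as.integer(depth), n)
  stopifnot(all(true_aaf >= 0 & true_aaf <= 1), all(depth >= 1),
            error_rate >= 0, error_rate <= 1)
  with_seed(seed, {
    p_alt <- true_aaf + (1 - true_aaf) * error_rate / 3
    alt_count <- stats::rbinom(n, depth, p_alt)
    p_other <- (1 - true_aaf) * 2 * error_rate / 3
    rem <- depth - alt_count
    other_count <- stats::rbinom(n, rem, ifelse(p_alt < 1, p_other / (1 - p_alt), 0))
    out <- data.frame(
      ref_count = depth - alt_count - other_count,
      alt_count = alt_count,
      other_count = other_count,
      depth = depth
    )
    if (!is.null(chrom)) {
      out <- cbind(data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                              sample = sample %||% NA_character_,
                              stringsAsFactors = FALSE), out)
    }
    out
  })
}

#' Alternate allele fraction, in percent
#'
#' `100 * alt_count / total` where total is all qualified base-calls at the
#' site (ref + alt + other).
#'
#' @param alt_count alt base-calls, or a TAS count `data.frame` (then
#'   `total` is taken from its columns).
#' @param total total base-calls.
#' @return AAF in percent.
#' @export
compute_aaf <- function(alt_count, total = NULL) {
  if (is.data.frame(alt_count)) {
    total <- alt_count$ref_count + alt_count$alt_count + alt_count$other_count
    alt_count <- alt_count$alt_count
  }
  if (any(total <= 0)) stop("no coverage: total base-calls must be > 0",
                            call. = FALSE)
  100 * alt_count / total
}

#' Display-round an allele fraction percentage
#'
#' Two decimals at or above 1%, three below (so 7.32 and 0.007 print at
#' their conventional precisions).
#'
#' @param aaf AAF in percent.
#' @return numeric, rounded.
#' @export
format_aaf <- function(aaf) {
  ifelse(aaf >= 1, round(aaf, 2), round(aaf, 3))
}

#' Phred score to error rate, in percent
#'
#' `100 * 10^(-q/10)`; quality 25 gives 0.316%, the assumed sequencing
#' error rate used as the amplicon validation threshold.
#'
#' @param q Phred score(s), non-negative.
#' @return error rate in percent.
#' @export
phred_to_error_percent <- function(q) {
  stopifnot(all(q >= 0))
  100 * 10^(-q / 10)
}

#' Validate a candidate from its amplicon allele fractions
#'
#' A candidate is validated iff the case AAF strictly exceeds the
#' error-rate threshold (default: the Phred-25 rate, 0.316%). The control
#' AAF does not enter the validation rule; `control_clean` separately
#' records whether the co-twin's AAF sits below the threshold, so either
#' convention can be audited.
#'
#' @param aaf_case,aaf_control allele fractions in percent (vectorized).
#' @param threshold validation threshold in percent.
#' @return `data.frame` with `aaf_case`, `aaf_control`, `threshold`,
#'   `validated`, `control_clean`.
#' @export
validate_site <- function(aaf_case, aaf_control,
                          threshold = phred_to_error_percent(25)) {
  stopifnot(all(aaf_case >= 0 & aaf_case <= 100),
            all(aaf_control >= 0 & aaf_control <= 100))
  data.frame(
    aaf_case = aaf_case, aaf_control = aaf_control, threshold = threshold,
    validated = aaf_case > threshold,
    control_clean = aaf_control < threshold
  )
}
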