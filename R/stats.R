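## Validation-stage statistics: Fisher contingency test, post hoc
## threshold analysis, monozygosity concordance, mutation spectrum.

#' Fisher's exact test on ref/alt base-call counts of a twin pair
#'
#' Tests whether the case and co-twin control show the same ratio of
#' reference to alternate base-calls at a site — under systematic
#' sequencing error, both samples should; a genuine somatic mutation in
#' one twin makes the ratios differ. Two-sided exact hypergeometric test
#' via [stats::fisher.test()].
#'
#' @param case,control integer pairs `c(ref_count, alt_count)`.
#' @return the two-sided p-value.
#' @export
fisher_ref_alt <- function(case, control) {
  stopifnot(length(case) == 2L, length(control) == 2L,
            all(c(case, control) >= 0))
  m <- matrix(c(case[1L], case[2L], control[1L], control[2L]),
              nrow = 2L, byrow = TRUE,
              dimnames = list(c("case", "control"), c("ref", "alt")))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("degenerate table: every margin must be positive", call. = FALSE)
  }
  stats::fisher.test(m)$p.value
}

#' One-sided t-test comparing validated and unvalidated candidates
#'
#' Alternative hypothesis: the validated group's mean exceeds the
#' unvalidated group's. Welch's unequal-variance form is the default
#' (group sizes are typically unbalanced); set `var_equal = TRUE` for the
#' pooled-variance form.
#'
#' @param validated,unvalidated numeric vectors (each of length >= 2) of a
#'   filtering metric (e.g. BQ or DP) per candidate.
#' @param var_equal use the pooled-variance (Student) form.
#' @return list with `p_value`, `t`, `df`, and per-group `mean`/`sd`/`n`.
#' @export
posthoc_t_test <- function(validated, unvalidated, var_equal = FALSE) {
  if (length(validated) < 2L || length(unvalidated) < 2L) {
    stop("insufficient data: each group needs at least 2 values",
         call. = FALSE)
  }
  tt <- stats::t.test(validated, unvalidated, alternative = "greater",
                      var.equal = var_equal)
  list(
    p_value = tt$p.value, t = unname(tt$statistic), df = unname(tt$parameter),
    mean_validated = mean(validated), sd_validated = stats::sd(validated),
    n_validated = length(validated),
    mean_unvalidated = mean(unvalidated), sd_unvalidated = stats::sd(unvalidated),
    n_unvalidated = length(unvalidated)
  )
}

#' Sensitivity and specificity of a depth threshold
#'
#' Treats amplicon-validated candidates as true positives:
#' sensitivity = % of validated candidates with `dp > threshold`,
#' specificity = % of unvalidated candidates with `dp <= threshold`.
#'
#' @param dp site depths.
#' @param validated logical labels, same length.
#' @param threshold depth cut (strictly-greater rule; default 60).
#' @return list with `sensitivity` and `specificity` in percent.
#' @export
dp_threshold_performance <- function(dp, validated, threshold = 60) {
  stopifnot(length(dp) == length(validated))
  if (!any(validated) || all(validated)) {
    stop("undefined metric: need at least one validated and one unvalidated candidate",
         call. = FALSE)
  }
  list(
    sensitivity = 100 * mean(dp[validated] > threshold),
    specificity = 100 * mean(dp[!validated] <= threshold),
    threshold = threshold
  )
}

#' Genotype concordance between co-twins at putatively credible SNV sites
#'
#' Monozygosity check: restrict to sites that are putatively credible in
#' both samples — depth within `depth_range` (default 80–90), genotype
#' quality at the `gq` ceiling (99), site quality `qual >= qual_min`
#' (1000) — and report the percentage with identical diploid genotypes.
#'
#' @param gt_a,gt_b genotype tables from [call_genotypes()] (columns
#'   `chrom`, `pos`, `gt`, `gq`, `qual`, and counts giving depth).
#' @param depth_range inclusive credible depth interval.
#' @param gq required genotype quality.
#' @param qual_min minimum site quality.
#' @return list with `concordance` (percent), `n_sites`, `n_discordant`.
#' @export
monozygosity_concordance <- function(gt_a, gt_b, depth_range = c(80, 90),
                                     gq = 99, qual_min = 1000) {
  key_a <- paste(gt_a$chrom, gt_a$pos)
  key_b <- paste(gt_b$chrom, gt_b$pos)
  common <- intersect(key_a, key_b)
  a <- gt_a[match(common, key_a), ]
  b <- gt_b[match(common, key_b), ]
  dp_a <- a$ref_count + a$alt_count + a$other_count
  dp_b <- b$ref_count + b$alt_count + b$other_count
  credible <- dp_a >= depth_range[1L] & dp_a <= depth_range[2L] &
    dp_b >= depth_range[1L] & dp_b <= depth_range[2L] &
    a$gq >= gq & b$gq >= gq &
    a$qual >= qual_min & b$qual >= qual_min
  n <- sum(credible)
  if (n == 0L) {
    stop("no credible sites pass the depth/genotype-quality/site-quality filters",
         call. = FALSE)
  }
  same <- a$gt[credible] == b$gt[credible]
  list(concordance = 100 * mean(same), n_sites = n,
       n_discordant = sum(!same))
}

SPECTRUM_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Strand-collapsed single-nucleotide mutation spectrum
#'
#' Collapses each substitution to its pyrimidine-reference representative
#' (`G>A` counts as `C>T`, etc.) and tallies the six classes.
#'
#' @param ref,alt single-base character vectors.
#' @return `data.frame` with `class`, `count`, `percent` (counts sum to
#'   `length(ref)`).
#' @export
mutation_spectrum <- function(ref, alt) {
  stopifnot(length(ref) == length(alt))
  ok <- ref %in% DNA_BASES & alt %in% DNA_BASES
  if (!all(ok)) stop("ref and alt must be single A/C/G/T bases", call. = FALSE)
  if (any(ref == alt)) stop("invalid variant: ref equals alt", call. = FALSE)
  flip <- ref %in% c("G", "A")
  ref[flip] <- comp_base(ref[flip])
  alt[flip] <- comp_base(alt[flip])
  cls <- factor(paste0(ref, ">", alt), levels = SPECTRUM_CLASSES)
  counts <- table(cls)
  data.frame(
    class = SPECTRUM_CLASSES,
    count = as.integer(counts),
    percent = round(100 * as.integer(counts) / length(ref), 1)
  )
}
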