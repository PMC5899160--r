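## The post-caller filter cascade. Order of application:
##   mcr -> indel_window -> quality_depth -> homology -> control_identity
## Every filter is evaluated for every candidate (decisions are
## order-independent in outcome); the cascade order only determines which
## filter is recorded as the excluding one.

CASCADE_FILTERS <- c("mcr", "indel_window", "quality_depth", "homology",
                     "control_identity")

#' Quality and depth thresholds for candidate SNVs
#'
#' MuTect-style candidates are judged on mean alt base quality (`bq`),
#' Strelka-style candidates on the somatic quality score (`qss`, used
#' analogously); both share the site-depth floor. Thresholds are
#' inclusive: `bq = 20, dp = 30` passes.
#'
#' @param candidates candidate `data.frame` with `caller`, `bq`/`qss`,
#'   `dp` columns.
#' @param bq_min,qss_min,dp_min inclusive minima (defaults 20 / 20 / 30).
#' @return `data.frame` with `quality_metric`, `quality_value`,
#'   `quality_pass`, `dp_value`, `dp_pass` and the combined `pass`.
#' @export
filter_quality_depth <- function(candidates, bq_min = 20, qss_min = 20,
                                 dp_min = 30) {
  strelka <- candidates$caller == "strelka-like"
  qval <- ifelse(strelka, candidates$qss, candidates$bq)
  if (anyNA(qval)) {
    i <- which(is.na(qval))[1L]
    stop(sprintf("candidate %s:%d lacks its quality metric (%s)",
                 candidates$chrom[i], candidates$pos[i],
                 if (strelka[i]) "qss" else "bq"), call. = FALSE)
  }
  qmin <- ifelse(strelka, qss_min, bq_min)
  qp <- qval >= qmin
  dpp <- candidates$dp >= dp_min
  data.frame(
    quality_metric = ifelse(strelka, "qss", "bq"),
    quality_value = qval, quality_pass = qp,
    dp_value = candidates$dp, dp_pass = dpp,
    pass = qp & dpp
  )
}

#' Control-identity exclusion
#'
#' A candidate identical to any quality-passing alt base-call in the
#' co-twin control (base quality >= 20, mapQ >= 30) is excluded: the
#' paired callers tolerate one or two control base-calls by default, and
#' this filter removes exactly what they tolerate. A site with no control
#' coverage is retained but flagged, since the absence of control evidence
#' is vacuous.
#'
#' @param control_alt_qualified qualified alt base-call count in the
#'   co-twin at each site.
#' @param control_dp control depth at each site.
#' @return `data.frame` with `pass` and `no_control_coverage` flags.
#' @export
filter_control_identity <- function(control_alt_qualified, control_dp) {
  data.frame(
    pass = control_alt_qualified < 1L,
    control_alt = control_alt_qualified,
    no_control_coverage = control_dp == 0L
  )
}

#' Run the full candidate filter cascade
#'
#' Applies, in cascade order, the multi-copy-region exclusion, the
#' ±`indel_window` bp indel-proximity exclusion, the quality/depth
#' thresholds, the flank-homology exclusion, and the control-identity
#' exclusion. Every filter is evaluated for every candidate so the report
#' carries full per-filter provenance; `excluding_filter` is the first
#' failing filter in `order`.
#'
#' @param candidates candidate table (see [candidates_from_alignments()]
#'   or [read_candidates()]).
#' @param mcr [region_set()] of multi-copy regions (`NULL` = empty).
#' @param indel_regions [region_set()] from [build_indel_exclusion()]
#'   (`NULL` = empty).
#' @param genome genome for homology scoring; may be omitted when
#'   `homology_scores` is supplied.
#' @param control_reads optional control alignment records; when given,
#'   the qualified control alt count is recomputed from the pileup,
#'   otherwise the `control_alt_qualified` / `control_dp` columns of
#'   `candidates` are used.
#' @param thresholds named list overriding `bq_min`, `qss_min`, `dp_min`,
#'   `homology_max` (exclusive, default 160), `indel_window`.
#' @param homology_scores optional precomputed second-best scores (e.g.
#'   from external BLAT output), one per candidate.
#' @param order permutation of the filter names; affects only the
#'   `excluding_filter` labels, never the retained set.
#' @return a filter report `data.frame`: per-filter observed values and
#'   pass flags, `final_status` (`"retained"`/`"excluded"`),
#'   `excluding_filter`, and `notes` (e.g. truncated homology flanks,
#'   missing control coverage).
#' @export
run_cascade <- function(candidates, mcr = NULL, indel_regions = NULL,
                        genome = NULL, control_reads = NULL,
                        thresholds = list(), homology_scores = NULL,
                        order = CASCADE_FILTERS) {
  stopifnot(setequal(order, CASCADE_FILTERS))
  th <- utils::modifyList(
    list(bq_min = 20, qss_min = 20, dp_min = 30, homology_max = 160,
         indel_window = 10L),
    thresholds
  )
  n <- nrow(candidates)
  rep0 <- candidates[, intersect(c("chrom", "pos", "ref", "alt", "caller"),
                                 names(candidates)), drop = FALSE]
  if (n == 0L) {
    rep0$final_status <- character(0)
    rep0$excluding_filter <- character(0)
    return(rep0)
  }
  notes <- character(n)

  mcr_hit <- if (is.null(mcr)) rep(FALSE, n) else {
    in_region(mcr, candidates$chrom, candidates$pos)
  }
  indel_hit <- if (is.null(indel_regions)) rep(FALSE, n) else {
    in_region(indel_regions, candidates$chrom, candidates$pos)
  }
  qd <- filter_quality_depth(candidates, th$bq_min, th$qss_min, th$dp_min)

  if (is.null(homology_scores)) {
    if (is.null(homology_scores <- candidates$homology_second)) {
      if (is.null(genome)) {
        stop("homology filtering needs `genome` or precomputed `homology_scores`",
             call. = FALSE)
      }
      homology_scores <- numeric(n)
      for (i in seq_len(n)) {
        hs <- withCallingHandlers(
          second_best_homology_score(genome, candidates$chrom[i],
                                     candidates$pos[i]),
          twinsom_truncated_flank = function(w) {
            notes[i] <<- paste0(notes[i], "truncated_flank;")
            invokeRestart("muffleWarning")
          }
        )
        homology_scores[i] <- hs$second_best_score
      }
    }
  }

  if (!is.null(control_reads)) {
    cq <- allele_counts(control_reads, candidates, min_bq = 20, min_mapq = 30)
    ctrl_alt <- cq$alt_count
    ctrl_dp <- cq$depth
  } else {
    stopifnot(!is.null(candidates$control_alt_qualified))
    ctrl_alt <- candidates$control_alt_qualified
    ctrl_dp <- candidates$control_dp %||% rep(NA_integer_, n)
  }
  ci <- filter_control_identity(ctrl_alt, ctrl_dp)
  notes[which(ci$no_control_coverage)] <-
    paste0(notes[which(ci$no_control_coverage)], "no_control_coverage;")

  pass <- cbind(
    mcr = !mcr_hit,
    indel_window = !indel_hit,
    quality_depth = qd$pass,
    homology = is.na(homology_scores) | homology_scores < th$homology_max,
    control_identity = ci$pass | ci$no_control_coverage
  )
  retained <- rowSums(!pass) == 0L
  excluding <- rep(NA_character_, n)
  for (f in rev(order)) excluding[!pass[, f]] <- f

  out <- cbind(
    rep0,
    data.frame(
      mcr_hit = mcr_hit, mcr_pass = pass[, "mcr"],
      indel_hit = indel_hit, indel_pass = pass[, "indel_window"],
      quality_metric = qd$quality_metric, quality_value = qd$quality_value,
      dp_value = qd$dp_value, quality_depth_pass = pass[, "quality_depth"],
      homology_second = homology_scores, homology_pass = pass[, "homology"],
      control_alt = ctrl_alt, control_identity_pass = pass[, "control_identity"],
      final_status = ifelse(retained, "retained", "excluded"),
      excluding_filter = excluding,
      notes = notes,
      stringsAsFactors = FALSE
    )
  )
  attr(out, "cascade_order") <- order
  attr(out, "thresholds") <- th
  rownames(out) <- NULL
  out
}
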