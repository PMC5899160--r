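## End-to-end orchestration: simulate/load -> filter -> HC -> amplicon
## validation -> post hoc, with a manifest of counts and content digests.

default_thresholds <- function() {
  list(
    bq_min = 20, qss_min = 20, dp_min = 30,
    homology_max = 160, indel_window = 10L,
    rbsm_bq = 25, rbsm_mapq = 30, rbsm_edge = 10L, rbsm_mm_window = 15L,
    rbsm_min = 2L,
    tas_mapq = 60, tas_bq = 20, validation_q = 25,
    dp_posthoc = 60
  )
}

#' Assemble and validate a pipeline run configuration
#'
#' Every numeric threshold of the workflow is surfaced here with its
#' standard value as default, so a run's parameterization is auditable and
#' overridable in one place; the configuration is serialized next to the
#' results for provenance. Exactly one input mode is used: a synthetic
#' `scenario` (see [demo_scenario()]) or a `paths` list pointing at real
#' files (`genome` FASTA, `case_sam`/`control_sam`, `candidates` TSV/VCF,
#' optional `mcr_bed`, `indels` TSV, `tas_counts` TSV).
#'
#' @param outdir output directory for stage results.
#' @param seed integer seed driving every stochastic stage.
#' @param scenario synthetic scenario description, or `NULL`.
#' @param paths named list of input files, or empty.
#' @param thresholds named overrides of the default thresholds.
#' @param tas_depth amplicon sequencing depth simulated at validation.
#' @return a validated `twinsom_config` object.
#' @export
run_config <- function(outdir, seed, scenario = NULL, paths = list(),
                       thresholds = list(), tas_depth = 200000L) {
  cfg <- structure(
    list(outdir = outdir, seed = seed, scenario = scenario, paths = paths,
         thresholds = utils::modifyList(default_thresholds(), thresholds),
         tas_depth = as.integer(tas_depth)),
    class = "twinsom_config"
  )
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  err <- function(...) stop(structure(
    class = c("twinsom_config_error", "error", "condition"),
    list(message = sprintf(...), call = NULL)
  ))
  if (is.null(cfg$outdir) || !nzchar(cfg$outdir)) err("config: outdir missing")
  if (is.null(cfg$seed) || !is.numeric(cfg$seed) || !is.finite(cfg$seed)) {
    err("config: a numeric seed is required")
  }
  num <- Filter(is.numeric, cfg$thresholds)
  if (any(unlist(num) < 0)) err("config: thresholds must be non-negative")
  if (is.null(cfg$scenario) == (length(cfg$paths) == 0L)) {
    err("config: provide exactly one of `scenario` or `paths`")
  }
  for (nm in names(cfg$paths)) {
    p <- cfg$paths[[nm]]
    if (!is.null(p) && !file.exists(p)) err("config: path `%s` does not exist: %s", nm, p)
  }
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with fields matching [run_config()]'s arguments.
#' @return a `twinsom_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(outdir = y$outdir, seed = y$seed, scenario = y$scenario,
             paths = y$paths %||% list(),
             thresholds = y$thresholds %||% list(),
             tas_depth = y$tas_depth %||% 200000L)
}

#' Run the somatic-mutation pipeline end to end
#'
#' Stages, in order: simulate (or load) the twin data; run the candidate
#' filter cascade; classify alt base-calls and select high-confidence
#' candidates; simulate (or load) deep-amplicon counts and validate
#' against the Phred-derived error threshold; post hoc statistics
#' (per-site Fisher tests, BQ/DP group comparisons, depth-threshold
#' performance, mutation spectrum). All stage tables are written under
#' `config$outdir` together with `manifest.json` (stage records, counts,
#' content digests) and the serialized configuration. Reruns with an
#' identical configuration and seed reproduce byte-identical stage
#' outputs.
#'
#' @param config a `twinsom_config` from [run_config()].
#' @return invisibly, a list with the manifest and the in-memory stage
#'   tables.
#' @export
run_pipeline <- function(config) {
  validate_config(config)
  th <- config$thresholds
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  files <- character(0)
  put <- function(x, name, writer = write_tsv) {
    path <- file.path(outdir, name)
    writer(x, path)
    files <<- c(files, stats::setNames(path, name))
    path
  }

  ## stage 1: simulate or load ------------------------------------------
  if (!is.null(config$scenario)) {
    sim <- build_scenario(config$scenario, seed)
    genome <- as_genome(sim$ref)
    case_reads <- sim$aln$case
    control_reads <- sim$aln$control
    candidates <- sim$candidates
    mcr_rs <- region_set(sim$ref$mcr_regions |> transform(chrom = sim$ref$contig),
                         "mcr")
    indels <- sim$indel_sites
    truth <- sim$truth
    put(sim$ref, "genome.fa", write_fasta)
    put(case_reads, "case.sam", function(x, p) write_sam(x, p, genome))
    put(control_reads, "control.sam", function(x, p) write_sam(x, p, genome))
    if (nrow(sim$ref$mcr_regions)) {
      put(mcr_rs, "mcr.bed", write_region_bed)
    }
    put(indels, "indel_sites.tsv")
    put(candidates, "candidates.tsv", write_candidates)
    put(truth, "truth.tsv")
  } else {
    p <- config$paths
    genome <- read_genome(p$genome)
    case_reads <- read_sam(p$case_sam)
    control_reads <- read_sam(p$control_sam)
    candidates <- read_candidates(p$candidates)
    mcr_rs <- if (!is.null(p$mcr_bed)) load_region_set(p$mcr_bed, "mcr") else NULL
    indels <- if (!is.null(p$indels)) utils::read.delim(p$indels) else NULL
    truth <- NULL
  }

  ## stage 2: filter cascade --------------------------------------------
  indel_rs <- build_indel_exclusion(indels, th$indel_window)
  if (is.null(candidates$control_alt_qualified)) {
    report <- run_cascade(candidates, mcr = mcr_rs, indel_regions = indel_rs,
                          genome = genome, control_reads = control_reads,
                          thresholds = th)
  } else {
    report <- run_cascade(candidates, mcr = mcr_rs, indel_regions = indel_rs,
                          genome = genome, thresholds = th)
  }
  put(report, "filter_report.tsv")
  retained <- report[report$final_status == "retained", , drop = FALSE]

  ## stage 3: RBSM classification and HC selection ----------------------
  hc_tab <- retained[, c("chrom", "pos", "ref", "alt", "quality_value",
                         "dp_value")]
  names(hc_tab)[5L:6L] <- c("bq", "dp")
  hc_tab$rbsm_count <- vapply(seq_len(nrow(hc_tab)), function(i) {
    count_rbsm(case_reads, genome, hc_tab$chrom[i], hc_tab$pos[i],
               hc_tab$alt[i], bq_min = th$rbsm_bq, mapq_min = th$rbsm_mapq,
               edge = th$rbsm_edge, mm_window = th$rbsm_mm_window)
  }, integer(1))
  ctx <- lapply(seq_len(nrow(hc_tab)), function(i) {
    detect_difficult_seqcontext(genome, hc_tab$chrom[i], hc_tab$pos[i])
  })
  hc_tab$seqcontext_difficult <- vapply(ctx, `[[`, TRUE, "is_difficult")
  hc_tab$seqcontext_reason <- vapply(ctx, `[[`, "", "reason")
  hc_tab <- select_hc(hc_tab, min_rbsm = th$rbsm_min)
  put(hc_tab, "hc.tsv")
  hc_sites <- hc_tab[hc_tab$is_hc, , drop = FALSE]

  ## stage 4: amplicon validation ---------------------------------------
  err_rate <- phred_to_error_percent(th$validation_q) / 100
  if (!is.null(config$paths$tas_counts)) {
    tas <- read_tas_counts(config$paths$tas_counts)
  } else if (nrow(hc_sites) == 0L) {
    tas <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      sample = character(0), ref_count = integer(0),
                      alt_count = integer(0), other_count = integer(0),
                      depth = integer(0))
  } else {
    truth_aaf <- if (is.null(truth)) rep(0, nrow(hc_sites)) else {
      truth$tas_truth_aaf[match(hc_sites$pos, truth$pos)]
    }
    truth_aaf[is.na(truth_aaf)] <- 0
    tas_case <- generate_tas_counts(truth_aaf, config$tas_depth, err_rate,
                                    seed = seed + 101L,
                                    chrom = hc_sites$chrom, pos = hc_sites$pos,
                                    ref = hc_sites$ref, alt = hc_sites$alt,
                                    sample = "case")
    tas_ctrl <- generate_tas_counts(rep(0, nrow(hc_sites)), config$tas_depth,
                                    err_rate, seed = seed + 102L,
                                    chrom = hc_sites$chrom, pos = hc_sites$pos,
                                    ref = hc_sites$ref, alt = hc_sites$alt,
                                    sample = "control")
    tas <- rbind(tas_case, tas_ctrl)
  }
  put(tas, "tas_counts.tsv", write_tas_counts)
  tc <- tas[tas$sample == "case", , drop = FALSE]
  tk <- tas[tas$sample == "control", , drop = FALSE]
  validation <- hc_sites[, c("chrom", "pos", "ref", "alt", "bq", "dp")]
  if (nrow(validation)) {
    mi <- match(validation$pos, tc$pos)
    ki <- match(validation$pos, tk$pos)
    vs <- validate_site(compute_aaf(tc[mi, , drop = FALSE]),
                        compute_aaf(tk[ki, , drop = FALSE]),
                        threshold = phred_to_error_percent(th$validation_q))
    validation <- cbind(validation, vs)
    validation$fisher_p <- vapply(seq_len(nrow(validation)), function(i) {
      fisher_ref_alt(
        c(tc$ref_count[mi[i]] + tc$other_count[mi[i]], tc$alt_count[mi[i]]),
        c(tk$ref_count[ki[i]] + tk$other_count[ki[i]], tk$alt_count[ki[i]])
      )
    }, numeric(1))
  } else {
    validation$aaf_case <- validation$aaf_control <- numeric(0)
    validation$threshold <- numeric(0)
    validation$validated <- validation$control_clean <- logical(0)
    validation$fisher_p <- numeric(0)
  }
  put(validation, "validation.tsv")

  ## stage 5: post hoc ---------------------------------------------------
  posthoc <- list(notes = character(0))
  v <- validation$validated
  if (sum(v) >= 2 && sum(!v) >= 2) {
    posthoc$bq_t_test <- posthoc_t_test(validation$bq[v], validation$bq[!v])
    posthoc$dp_t_test <- posthoc_t_test(validation$dp[v], validation$dp[!v])
  } else {
    posthoc$notes <- c(posthoc$notes,
                       "t-tests skipped: fewer than 2 candidates in a group")
  }
  if (any(v) && any(!v)) {
    posthoc$dp_performance <- dp_threshold_performance(validation$dp, v,
                                                       th$dp_posthoc)
  } else {
    posthoc$notes <- c(posthoc$notes,
                       "depth-threshold performance skipped: single-class labels")
  }
  if (any(v)) {
    spectrum <- mutation_spectrum(validation$ref[v], validation$alt[v])
    put(spectrum, "spectrum.tsv")
    posthoc$spectrum <- spectrum
  }
  put(posthoc, "posthoc.json", function(x, p) {
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })

  ## manifest -------------------------------------------------------------
  counts <- list(
    candidates = nrow(candidates),
    retained = nrow(retained),
    hc = nrow(hc_sites),
    validated = sum(validation$validated)
  )
  exclusions <- table(report$excluding_filter[report$final_status == "excluded"])
  manifest <- list(
    seed = seed,
    thresholds = th,
    counts = counts,
    exclusions_by_filter = as.list(exclusions),
    files = as.list(vapply(files, function(p) unname(tools::md5sum(p)), ""))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg_out <- config
  cfg_out$scenario <- config$scenario
  yaml::write_yaml(
    list(outdir = config$outdir, seed = config$seed,
         thresholds = th, tas_depth = config$tas_depth,
         scenario = config$scenario, paths = config$paths),
    file.path(outdir, "config.yaml")
  )
  invisible(list(manifest = manifest, report = report, hc = hc_tab,
                 validation = validation, posthoc = posthoc, truth = truth))
}
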