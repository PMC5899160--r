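#' Bundled synthetic twin-pair demonstration scenario
#'
#' Describes a compact end-to-end test case: ten clean somatic mutations
#' planted at 10% allele fraction in the case twin, plus ten decoys, one
#' per failure mode the pipeline is built to reject:
#' \itemize{
#'   \item `decoy_mcr` — inside an annotated multi-copy region;
#'   \item `decoy_indel` — within 10 bp of a planted deletion locus;
#'   \item `decoy_lowdp` — near the contig end where coverage collapses;
#'   \item `decoy_dup` — inside the copy of a 98%-identical duplicated
#'     block (flank-homology failure);
#'   \item `decoy_control` — carried by both co-twins (control identity);
#'   \item `decoy_softclip`, `decoy_xa`, `decoy_edge` — alt support
#'     confined to artifact reads (RBSM count 0);
#'   \item `decoy_str` — genuine plant adjacent to a tandem repeat
#'     (difficult sequence context);
#'   \item `decoy_wes_artifact` — discovery-stage false positive: alt reads
#'     in the exome data but a true allele fraction of 0, so it reaches HC
#'     and fails amplicon validation.
#' }
#' A correct run validates exactly the ten clean plants.
#'
#' @param length,depth contig length and per-sample coverage.
#' @param n_germline background germline SNVs (2:1 het:hom).
#' @return a scenario description consumed by [run_config()].
#' @export
demo_scenario <- function(length = 60000L, depth = 100L, n_germline = 40L) {
  list(type = "demo", length = as.integer(length), depth = as.integer(depth),
       n_germline = as.integer(n_germline),
       clean_aaf = 0.10, n_clean = 10L)
}

# sample positions clear of annotated features, previous picks, and ends
place_clear_positions <- function(ref, n, taken = integer(0), min_gap = 250L,
                                  margin = 400L, buffer = 100L) {
  feat <- rbind(
    ref$str_regions[, c("start", "end")],
    ref$polyA_regions[, c("start", "end")],
    data.frame(start = c(ref$duplicated_blocks$src_start,
                         ref$duplicated_blocks$copy_start),
               end = c(ref$duplicated_blocks$src_end,
                       ref$duplicated_blocks$copy_end)),
    ref$mcr_regions[, c("start", "end")]
  )
  out <- integer(0)
  for (i in seq_len(n)) {
    for (try in 1:500) {
      p <- sample.int(ref$length - 2L * margin, 1L) + margin
      clear_feat <- nrow(feat) == 0L ||
        all(p < feat$start - buffer | p > feat$end + buffer)
      clear_prev <- all(abs(c(out, taken) - p) >= min_gap)
      if (clear_feat && clear_prev) { out <- c(out, p); break }
      if (try == 500L) stop("cannot place scenario positions", call. = FALSE)
    }
  }
  out
}

# realize a scenario: reference, planted mutations, alignments, candidate
# table, and per-site truth
build_scenario <- function(scenario, seed) {
  stopifnot(identical(scenario$type, "demo"))
  ref <- generate_reference(scenario$length, n_str = 2L, n_polyA = 1L,
                            n_dup_blocks = 1L, n_mcr = 1L, seed = seed + 1L)
  with_seed(seed + 2L, {
    n_g <- scenario$n_germline
    gpos <- place_clear_positions(ref, n_g + scenario$n_clean + 5L)
    germ_pos <- gpos[seq_len(n_g)]
    clean_pos <- gpos[n_g + seq_len(scenario$n_clean)]
    extra <- gpos[(n_g + scenario$n_clean + 1L):length(gpos)]

    gref <- vapply(germ_pos, function(p) substring(ref$sequence, p, p), "")
    germline <- plant_mutations(
      ref, germ_pos, other_base(gref),
      origin = rep(c("germline_het", "germline_het", "germline_hom"),
                   length.out = n_g)
    )

    mk_alt <- function(p) other_base(substring(ref$sequence, p, p))
    dup <- ref$duplicated_blocks[1L, ]
    mcr <- ref$mcr_regions[1L, ]
    str1 <- ref$str_regions[1L, ]
    decoy <- list(
      decoy_mcr = list(pos = (mcr$start + mcr$end) %/% 2L, aaf = 0.10,
                       carrier = "case", artifact = "none"),
      decoy_indel = list(pos = extra[1L], aaf = 0.15, carrier = "case",
                         artifact = "none"),
      decoy_lowdp = list(pos = ref$length - 15L, aaf = 0.30, carrier = "case",
                         artifact = "none"),
      decoy_dup = list(pos = (dup$copy_start + dup$copy_end) %/% 2L,
                       aaf = 0.10, carrier = "case", artifact = "none"),
      decoy_control = list(pos = extra[2L], aaf = 0.08, carrier = "both",
                           artifact = "none"),
      decoy_softclip = list(pos = extra[3L], aaf = 0.10, carrier = "case",
                            artifact = "softclip"),
      decoy_xa = list(pos = extra[4L], aaf = 0.10, carrier = "case",
                      artifact = "xa"),
      decoy_edge = list(pos = extra[5L], aaf = 0.10, carrier = "case",
                        artifact = "edge"),
      decoy_str = list(pos = str1$end + 5L, aaf = 0.10, carrier = "case",
                       artifact = "none")
    )
    som_pos <- c(clean_pos, vapply(decoy, `[[`, 0, "pos"))
    som_aaf <- c(rep(scenario$clean_aaf, scenario$n_clean),
                 vapply(decoy, `[[`, 0, "aaf"))
    som_carrier <- c(rep("case", scenario$n_clean),
                     vapply(decoy, `[[`, "", "carrier"))
    som_artifact <- c(rep("none", scenario$n_clean),
                      vapply(decoy, `[[`, "", "artifact"))
    som_class <- c(rep("clean", scenario$n_clean), names(decoy))

    # discovery-stage false positive: alt reads in WES, nothing real below
    wes_fp_pos <- place_clear_positions(ref, 1L, taken = c(gpos))
    som_pos <- c(som_pos, wes_fp_pos)
    som_aaf <- c(som_aaf, 0.08)
    som_carrier <- c(som_carrier, "case")
    som_artifact <- c(som_artifact, "none")
    som_class <- c(som_class, "decoy_wes_artifact")
    origin <- ifelse(som_class == "decoy_wes_artifact", "wes_artifact",
                     "somatic")

    somatic <- plant_mutations(ref, som_pos, vapply(som_pos, mk_alt, ""),
                               origin = origin, true_aaf = som_aaf,
                               carrier = som_carrier, artifact = som_artifact)
    indel_loci <- data.frame(pos = decoy$decoy_indel$pos + 4L, frac = 0.5,
                             del_len = 2L)

    truth <- data.frame(
      chrom = ref$contig, pos = as.integer(som_pos), class = som_class,
      true_aaf = som_aaf,
      tas_truth_aaf = ifelse(som_artifact == "none" & origin == "somatic",
                             som_aaf, 0),
      stringsAsFactors = FALSE
    )
    truth <- truth[order(truth$pos), ]
  })
  aln <- generate_twin_alignments(ref, germline, somatic,
                                  depth = scenario$depth,
                                  err = error_model(indel_read_rate = 0),
                                  seed = seed + 3L, indel_loci = indel_loci)
  candidates <- candidates_from_alignments(aln, somatic)
  list(ref = ref, aln = aln, candidates = candidates,
       indel_sites = data.frame(chrom = ref$contig, pos = indel_loci$pos),
       truth = truth, germline = germline, somatic = somatic)
}
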