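#!/usr/bin/env Rscript

# Stage 1: simulate a monozygotic twin pair and check monozygosity.
#
# Builds a 60 kb reference with annotated repeat/duplication/MCR contexts,
# plants one shared germline (het + hom SNVs) into both co-twins plus ten
# clean somatic mutations (case twin, AAF 10%) and a panel of decoys that
# should be rejected downstream, writes all inputs as standard formats
# under results/twin_analysis/, and verifies monozygosity by genotype
# concordance at putatively credible SNV sites.

suppressMessages(library(twinsom))

outdir <- "results/twin_analysis"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
seed <- 20240915L

ref <- generate_reference(60000L, n_str = 2, n_polyA = 1, n_dup_blocks = 1,
                          n_mcr = 1, seed = seed + 1L)

pick <- with_seed(seed + 2L, {
  feats <- rbind(
    ref$str_regions[, c("start", "end")],
    ref$polyA_regions[, c("start", "end")],
    data.frame(start = c(ref$duplicated_blocks$src_start,
                         ref$duplicated_blocks$copy_start),
               end = c(ref$duplicated_blocks$src_end,
                       ref$duplicated_blocks$copy_end)),
    ref$mcr_regions
  )
  taken <- integer(0)
  clear_pos <- function(n, gap = 250L) {
    out <- integer(0)
    while (length(out) < n) {
      p <- sample(500:(ref$length - 500L), 1L)
      if (all(p < feats$start - 100L | p > feats$end + 100L) &&
          all(abs(c(taken, out) - p) >= gap)) {
        out <- c(out, p)
      }
    }
    taken <<- c(taken, out)
    out
  }
  ob <- function(p) {
    vapply(p, function(x) sample(setdiff(c("A", "C", "G", "T"),
                                         substring(ref$sequence, x, x)), 1L), "")
  }
  gpos <- clear_pos(150L, gap = 150L)
  germline <- plant_mutations(ref, gpos, ob(gpos),
                              origin = rep(c("germline_het", "germline_het",
                                             "germline_hom"), 50L))
  cpos <- clear_pos(10L)
  dpos <- clear_pos(4L)
  mcr_mid <- with(ref$mcr_regions[1L, ], (start + end) %/% 2L)
  dup_mid <- with(ref$duplicated_blocks[1L, ], (copy_start + copy_end) %/% 2L)
  str_adj <- ref$str_regions$end[1L] + 5L
  som_pos <- c(cpos, mcr_mid, dup_mid, str_adj, dpos)
  somatic <- plant_mutations(
    ref, som_pos, ob(som_pos),
    origin = c(rep("somatic", 16L), "wes_artifact"),
    true_aaf = c(rep(0.10, 10L), 0.10, 0.10, 0.10, 0.08, 0.10, 0.15, 0.08),
    carrier = c(rep("case", 13L), "both", rep("case", 3L)),
    artifact = c(rep("none", 14L), "softclip", "none", "none")
  )
  truth <- data.frame(
    chrom = ref$contig, pos = as.integer(som_pos),
    class = c(rep("clean", 10L), "decoy_mcr", "decoy_dup", "decoy_str",
              "decoy_control", "decoy_softclip", "decoy_indel",
              "decoy_wes_artifact"),
    tas_truth_aaf = c(rep(0.10, 10L), 0.10, 0.10, 0.10, 0.08, 0, 0.15, 0)
  )
  list(germline = germline, somatic = somatic, truth = truth,
       indel_loci = data.frame(pos = dpos[3L] + 4L, frac = 0.5, del_len = 2L))
})

aln <- generate_twin_alignments(ref, pick$germline, pick$somatic, depth = 85,
                                err = error_model(indel_read_rate = 0),
                                seed = seed + 3L, indel_loci = pick$indel_loci)
candidates <- candidates_from_alignments(aln, pick$somatic)

write_fasta(ref, file.path(outdir, "genome.fa"))
write_sam(aln$case, file.path(outdir, "case.sam"), ref)
write_sam(aln$control, file.path(outdir, "control.sam"), ref)
write_region_bed(reference_regions(ref, "mcr"), file.path(outdir, "mcr.bed"))
write.table(data.frame(chrom = ref$contig, pos = pick$indel_loci$pos),
            file.path(outdir, "indel_sites.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write_candidates(candidates, file.path(outdir, "candidates.tsv"))
write.table(pick$truth, file.path(outdir, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# monozygosity QC: genotype concordance at putatively credible SNV sites
sites <- rbind(pick$germline, pick$somatic)[, c("chrom", "pos", "ref", "alt")]
gt_case <- call_genotypes(allele_counts(aln$case, sites))
gt_control <- call_genotypes(allele_counts(aln$control, sites))
conc <- monozygosity_concordance(gt_case, gt_control)

message(sprintf("simulated twin pair: %d + %d reads at depth 85 over %d bp",
                nrow(aln$case), nrow(aln$control), ref$length))
message(sprintf("planted: %d germline SNVs, %d clean somatic, %d decoys",
                nrow(pick$germline), 10L, nrow(pick$truth) - 10L))
message(sprintf("monozygosity QC: %.4g%% concordance at %d credible sites",
                conc$concordance, conc$n_sites))
message("inputs written under ", outdir)
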