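#!/usr/bin/env Rscript

# Stage 4: deep-amplicon validation.
#
# Simulates target amplicon sequencing (200,000x, Phred-25 error model) at
# every HC site in both co-twins, computes allele fractions, and validates
# candidates whose case AAF strictly exceeds the 0.316% error threshold.
# Also runs a per-site Fisher exact test on ref/alt base-call counts
# between the co-twins.

suppressMessages(library(twinsom))

outdir <- "results/twin_analysis"
seed <- 20240915L
hc <- read.delim(file.path(outdir, "hc.tsv"))
truth <- read.delim(file.path(outdir, "truth.tsv"))
hc <- hc[hc$is_hc, ]

tas_depth <- 200000L
err <- phred_to_error_percent(25) / 100
true_aaf <- truth$tas_truth_aaf[match(hc$pos, truth$pos)]
true_aaf[is.na(true_aaf)] <- 0

tas_case <- generate_tas_counts(true_aaf, tas_depth, err, seed = seed + 41L,
                                chrom = hc$chrom, pos = hc$pos, ref = hc$ref,
                                alt = hc$alt, sample = "case")
tas_ctrl <- generate_tas_counts(rep(0, nrow(hc)), tas_depth, err,
                                seed = seed + 42L, chrom = hc$chrom,
                                pos = hc$pos, ref = hc$ref, alt = hc$alt,
                                sample = "control")
write_tas_counts(rbind(tas_case, tas_ctrl), file.path(outdir, "tas_counts.tsv"))

val <- cbind(hc[, c("chrom", "pos", "ref", "alt", "bq", "dp")],
             validate_site(compute_aaf(tas_case), compute_aaf(tas_ctrl)))
val$fisher_p <- vapply(seq_len(nrow(val)), function(i) {
  fisher_ref_alt(
    c(tas_case$ref_count[i] + tas_case$other_count[i], tas_case$alt_count[i]),
    c(tas_ctrl$ref_count[i] + tas_ctrl$other_count[i], tas_ctrl$alt_count[i])
  )
}, numeric(1))
write.table(val, file.path(outdir, "validation.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf("amplicon validation at %dx, threshold %.3f%%:",
                tas_depth, phred_to_error_percent(25)))
for (i in seq_len(nrow(val))) {
  message(sprintf("  %s:%d %s>%s  case %7s%%  control %6s%%  %s", val$chrom[i],
                  val$pos[i], val$ref[i], val$alt[i],
                  format_aaf(val$aaf_case[i]), format_aaf(val$aaf_control[i]),
                  ifelse(val$validated[i], "VALIDATED", "not validated")))
}
message(sprintf("%d of %d HC candidates validated", sum(val$validated),
                nrow(val)))
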