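#!/usr/bin/env Rscript

# Stage 2: candidate filter cascade.
#
# Loads the simulated inputs from stage 1 and applies the post-caller
# filters in cascade order: multi-copy-region exclusion, ±10 bp indel
# window, BQ/DP thresholds, flank-homology exclusion (< 160), and
# control-identity exclusion. Writes the per-candidate provenance report.

suppressMessages(library(twinsom))

outdir <- "results/twin_analysis"
genome <- read_genome(file.path(outdir, "genome.fa"))
candidates <- read_candidates(file.path(outdir, "candidates.tsv"))
mcr <- load_region_set(file.path(outdir, "mcr.bed"), "mcr")
indels <- read.delim(file.path(outdir, "indel_sites.tsv"))

report <- run_cascade(candidates, mcr = mcr,
                      indel_regions = build_indel_exclusion(indels),
                      genome = genome)
write.table(report, file.path(outdir, "filter_report.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

n_ret <- sum(report$final_status == "retained")
message(sprintf("cascade: %d candidates in, %d retained", nrow(report), n_ret))
excl <- table(report$excluding_filter[report$final_status == "excluded"])
for (f in names(excl)) message(sprintf("  excluded by %-17s %d", f, excl[[f]]))
message("filter report written to ", file.path(outdir, "filter_report.tsv"))
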