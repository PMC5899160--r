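#!/usr/bin/env Rscript

# Stage 3: read-level reliability classification and HC selection.
#
# For every candidate retained by the cascade, classifies its
# alt-supporting base-calls against the seven RBSM criteria, scans the
# ±15 bp sequence context for tandem repeats and poly-A/T runs, and keeps
# high-confidence candidates (RBSM count >= 2, no difficult context).

suppressMessages(library(twinsom))

outdir <- "results/twin_analysis"
genome <- read_genome(file.path(outdir, "genome.fa"))
case_reads <- read_sam(file.path(outdir, "case.sam"))
report <- read.delim(file.path(outdir, "filter_report.tsv"))
retained <- report[report$final_status == "retained", ]

hc <- data.frame(chrom = retained$chrom, pos = retained$pos,
                 ref = retained$ref, alt = retained$alt,
                 bq = retained$quality_value, dp = retained$dp_value)
hc$rbsm_count <- vapply(seq_len(nrow(hc)), function(i) {
  count_rbsm(case_reads, genome, hc$chrom[i], hc$pos[i], hc$alt[i])
}, integer(1))
ctx <- lapply(seq_len(nrow(hc)), function(i) {
  detect_difficult_seqcontext(genome, hc$chrom[i], hc$pos[i])
})
hc$seqcontext_difficult <- vapply(ctx, `[[`, TRUE, "is_difficult")
hc$seqcontext_reason <- vapply(ctx, `[[`, "", "reason")
hc <- select_hc(hc)
write.table(hc, file.path(outdir, "hc.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

message(sprintf("%d retained candidates -> %d HC (RBSM >= 2, clean context)",
                nrow(hc), sum(hc$is_hc)))
for (i in which(!hc$is_hc)) {
  message(sprintf("  rejected %s:%d  rbsm=%d context=%s", hc$chrom[i],
                  hc$pos[i], hc$rbsm_count[i], hc$seqcontext_reason[i]))
}
message("HC table written to ", file.path(outdir, "hc.tsv"))
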