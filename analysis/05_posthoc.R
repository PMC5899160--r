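#!/usr/bin/env Rscript

# Stage 5: post hoc analysis.
#
# Compares the filtering metrics (BQ, DP) of validated vs unvalidated HC
# candidates, evaluates the DP > 60 rule as a classifier of validation
# status, and tallies the strand-collapsed mutation spectrum — both for
# the synthetic run and for the bundled table of published
# amplicon-validated twin mutations.

suppressMessages(library(twinsom))

outdir <- "results/twin_analysis"
val <- read.delim(file.path(outdir, "validation.tsv"))
v <- val$validated

if (sum(v) >= 2 && sum(!v) >= 2) {
  for (metric in c("bq", "dp")) {
    t <- posthoc_t_test(val[[metric]][v], val[[metric]][!v])
    message(sprintf(
      "%s: validated %.1f +/- %.1f vs unvalidated %.1f +/- %.1f, one-sided p = %.3g",
      toupper(metric), t$mean_validated, t$sd_validated,
      t$mean_unvalidated, t$sd_unvalidated, t$p_value))
  }
} else {
  message("t-tests skipped: fewer than 2 candidates in a group ",
          sprintf("(%d validated, %d unvalidated)", sum(v), sum(!v)))
}

if (any(v) && any(!v)) {
  perf <- dp_threshold_performance(val$dp, v, threshold = 60)
  message(sprintf("DP > 60 rule: sensitivity %.1f%%, specificity %.1f%%",
                  perf$sensitivity, perf$specificity))
}

sp <- mutation_spectrum(val$ref[v], val$alt[v])
write.table(sp, file.path(outdir, "spectrum.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
message("synthetic validated-set spectrum:")
for (i in which(sp$count > 0)) {
  message(sprintf("  %s  %d (%.1f%%)", sp$class[i], sp$count[i], sp$percent[i]))
}

# published amplicon-validated twin mutations bundled with the package
t2 <- read.delim(system.file("extdata", "tas_validated_sites.tsv",
                             package = "twinsom"))
sp2 <- mutation_spectrum(t2$ref, t2$alt)
ct <- sp2[sp2$class == "C>T", ]
message(sprintf(
  "published validated set (n = %d): C>T transitions %d (%.1f%%); AAF range %.2f-%.2f%%",
  nrow(t2), ct$count, ct$percent, min(t2$tas_aaf_carrier),
  max(t2$tas_aaf_carrier)))
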