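#!/usr/bin/env Rscript
# Stage 4 — OCT layer-thickness statistics and histology group tests.
#
# Reproduces the structural side of the analysis on the simulated
# cohort: per-layer baseline/posthypoxia summaries with paired t-tests,
# the 18h-vs-1h visit deltas, the TRT-GCC correlation, one-way ANOVA +
# Tukey for the glial markers, and the two-way (layer x group) ANOVA for
# apoptotic-cell counts. Also cross-checks the published TRT group means
# by reconstructing the ANOVA from printed mean/SEM/n summaries alone.

library(posthypoxia)

in_dir <- "results/data"
out_dir <- "results"

oct <- utils::read.delim(file.path(in_dir, "oct_thickness.tsv"),
                         stringsAsFactors = FALSE)
class(oct) <- c("oct_table", "data.frame")
rpt <- oct_report(oct)
utils::write.table(rpt$summary, file.path(out_dir, "oct_summary.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(rpt$delta, file.path(out_dir, "oct_delta.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat("OCT paired tests (baseline vs posthypoxia):\n")
for (i in seq_len(nrow(rpt$summary))) {
  r <- rpt$summary[i, ]
  cat(sprintf("  %-8s %-11s diff %+6.2f um, p = %.4f\n",
              r$group, r$layer, r$mean_diff, r$paired_p))
}
cat(sprintf("18h-vs-1h TRT delta: %.1f um (%.1f%%)\n",
            rpt$delta$delta[rpt$delta$layer == "TRT"],
            rpt$delta$pct[rpt$delta$layer == "TRT"]))
cat(sprintf("TRT-GCC Pearson r = %.4f (p = %.2g, n = %d)\n",
            rpt$trt_gcc$r, rpt$trt_gcc$p, rpt$trt_gcc$n))

# cross-check on printed group means alone (mean, SEM, n)
gs <- function(mean, sem, n) structure(list(mean = mean, sem = sem,
                                            n = n),
                                       class = "group_summary")
tk <- anova_tukey_from_summary(list(baseline = gs(223.3, 2.6, 10),
                                    post1h = gs(218.5, 1.1, 8),
                                    post18h = gs(229.1, 0.7, 10)))
cmp <- tk$tukey[tk$tukey$comparison == "post18h-post1h", ]
cat(sprintf(
  "printed TRT summaries: F = %.2f, 18h-vs-1h Tukey p = %.2g\n",
  tk$F, cmp$p))

hist_tab <- utils::read.delim(file.path(in_dir, "histology.tsv"),
                              stringsAsFactors = FALSE)
class(hist_tab) <- c("histology_table", "data.frame")
cat("histology one-way ANOVA + Tukey:\n")
for (m in c("aqp4", "kir41", "gfap")) {
  a <- anova_tukey(split(hist_tab[[m]], hist_tab$group))
  top <- a$tukey[which.min(a$tukey$p), ]
  cat(sprintf("  %-6s F = %6.2f, p = %.4g; smallest Tukey p: %s = %.4g\n",
              m, a$F, a$p, top$comparison, top$p))
}
tw <- two_way_anova(hist_tab)
cat("TUNEL two-way ANOVA (type II):\n")
print(tw$table, row.names = FALSE)
utils::write.table(tw$table, file.path(out_dir, "tunel_anova.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
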