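#!/usr/bin/env Rscript
# Stage 2 — normalize the plates and run the complete-separation screen.
#
# Reads the plates written by stage 1, averages duplicates, normalizes
# against Chex #4, and screens the 1h group against controls: exact
# permutation test per analyte (primary hits = complete separation, the
# smallest possible p-value, 2/252 = 0.008 at 5v5), exact Mann-Whitney +
# Benjamini-Hochberg (FDR 0.1) secondary screen, and the cross-tissue
# Venn partition of the primary hits.

library(posthypoxia)

in_dir <- "results/data"
out_dir <- "results"
stopifnot(file.exists(file.path(in_dir, "plate_plasma.tsv")))

matrices <- lapply(
  c(plasma = "plate_plasma.tsv", retina = "plate_retina.tsv"),
  function(f) chex_normalize(average_duplicates(
    read_plate(file.path(in_dir, f))))
)

screens <- lapply(matrices, run_screen, group = "post1h")
for (tissue in names(screens)) {
  s <- screens[[tissue]]
  write_screen_results(
    s, file.path(out_dir, paste0("screen_", tissue, ".tsv")))
  hits <- s[s$primary_hit, ]
  cat(sprintf(
    "%s: %d primary hits (perm p = %s), %d secondary (MW + BH q=0.1)\n",
    tissue, nrow(hits),
    paste(unique(format(round(hits$perm_p, 3), nsmall = 3)),
          collapse = ", "),
    sum(s$secondary_hit)))
  top <- hits[order(-hits$ratio), c("analyte", "ratio")]
  cat(sprintf("  top ratios: %s\n",
              paste(sprintf("%s %.2f", top$analyte, top$ratio)[
                seq_len(min(5, nrow(top)))], collapse = ", ")))
}

venn <- venn_partition(
  screens$plasma$analyte[screens$plasma$primary_hit],
  screens$retina$analyte[screens$retina$primary_hit]
)
cat(sprintf("shared across tissues: %s\n",
            paste(venn$shared, collapse = ", ")))
cat("note: the simulated ground truth carries 10 plasma / 4 retina",
    "affected analytes;\n      folds below ~1.4 separate only",
    "intermittently at biological CV 0.1,\n      so the recovered",
    "plasma list can be shorter than the configured one.\n")
venn_df <- data.frame(
  set = rep(c("plasma_only", "shared", "retina_only"), lengths(venn)),
  analyte = unlist(venn, use.names = FALSE)
)
utils::write.table(venn_df, file.path(out_dir, "venn_partition.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
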