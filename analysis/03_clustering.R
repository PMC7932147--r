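#!/usr/bin/env Rscript
# Stage 3 — hierarchical clustering of immune profiles.
#
# Clusters the samples of each normalized plate (log, per-analyte
# z-score, Euclidean distance, average linkage) and scores how cleanly
# the 1h posthypoxia group segregates from the rest under a two-cluster
# cut (1.0 = perfect segregation). Leaf orders and dendrograms (Newick)
# are written under results/.

library(posthypoxia)

in_dir <- "results/data"
out_dir <- "results"

matrices <- lapply(
  c(plasma = "plate_plasma.tsv", retina = "plate_retina.tsv"),
  function(f) chex_normalize(average_duplicates(
    read_plate(file.path(in_dir, f))))
)

for (tissue in names(matrices)) {
  m <- matrices[[tissue]]
  cl_samples <- hier_cluster(m, axis = "samples")
  cl_analytes <- hier_cluster(m, axis = "analytes")
  score <- segregation_score(
    cl_samples, stats::setNames(m$group, m$sample_id), "post1h")
  cat(sprintf("%s: 1h segregation score %.3f; leaf order: %s\n",
              tissue, score,
              paste(cl_samples$labels[cl_samples$order],
                    collapse = " ")))

  utils::write.table(
    data.frame(position = seq_along(cl_samples$order),
               sample = cl_samples$labels[cl_samples$order],
               group = m$group[match(cl_samples$labels[cl_samples$order],
                                     m$sample_id)]),
    file.path(out_dir, paste0("leaf_order_", tissue, ".tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE)
  if (requireNamespace("ape", quietly = TRUE)) {
    dendro_newick(cl_samples,
                  file.path(out_dir, paste0("dendro_samples_", tissue,
                                            ".nwk")))
    dendro_newick(cl_analytes,
                  file.path(out_dir, paste0("dendro_analytes_", tissue,
                                            ".nwk")))
  }
}
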