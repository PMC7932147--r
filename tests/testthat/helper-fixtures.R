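# Fixtures are built in code. make_s1_like_matrix() is a SYNTHETIC
# stand-in for a duplicate-averaged 39-analyte supplementary table: it
# carries the published 1h hit structure by construction (completely
# separated analytes with the published fold ratios, a set of
# partially-overlapping secondary analytes, interleaved nulls) but none
# of the published raw values.

# deterministic 5-sample patterns (per analyte, scaled by baseline):
#  - separated: ctrl spread 0.9..1.1, trt = fold * ctrl  (no overlap for
#    any fold > 1.1/0.9 = 1.223)
#  - secondary: one cross-group overlap; rank-sum two-sided p = 4/252
#  - null: perfectly interleaved ranks
s1_patterns <- list(
  spread = c(0.90, 0.95, 1.00, 1.05, 1.10),
  secondary_ctrl = c(1, 2, 3, 4, 6) / 3.2,
  secondary_trt = c(5, 7, 8, 9, 10) / 3.2,
  null_ctrl = c(1, 3, 5, 7, 9) / 5,
  null_trt = c(2, 4, 6, 8, 10) / 5
)

s1_secondary_analytes <- c("IL1A", "TNFA", "MCP1", "IL10", "IL2", "IL5",
                           "IL18")

make_s1_like_matrix <- function(tissue = c("plasma", "retina")) {
  tissue <- match.arg(tissue)
  panel <- default_analyte_panel()
  effects <- if (tissue == "plasma") {
    default_plasma_effects()
  } else {
    default_retina_effects()
  }
  secondary <- if (tissue == "plasma") s1_secondary_analytes else character()
  baseline <- seq(100, 4000, length.out = length(panel$names))
  names(baseline) <- panel$names

  ctrl <- trt <- matrix(NA_real_, nrow = 5, ncol = length(panel$names),
                        dimnames = list(NULL, panel$names))
  for (a in panel$names) {
    if (a %in% effects$analyte) {
      fold <- effects$fold[match(a, effects$analyte)]
      ctrl[, a] <- baseline[a] * s1_patterns$spread
      trt[, a] <- fold * ctrl[, a]
    } else if (a %in% secondary) {
      ctrl[, a] <- baseline[a] * s1_patterns$secondary_ctrl
      trt[, a] <- baseline[a] * s1_patterns$secondary_trt
    } else {
      ctrl[, a] <- baseline[a] * s1_patterns$null_ctrl
      trt[, a] <- baseline[a] * s1_patterns$null_trt
    }
  }

  plate <- data.frame(
    sample_id = sprintf("S%02d", 1:10),
    group = rep(c("control", "post1h"), each = 5),
    tissue = tissue,
    duplicate = 1L,
    rbind(ctrl, trt),
    Chex1 = 12000, Chex2 = 8000, Chex3 = 4000, Chex4 = 2000,
    check.names = FALSE,
    stringsAsFactors = FALSE
  )
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  utils::write.table(plate, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  chex_normalize(average_duplicates(read_plate(path, panel)))
}

# minimal two-analyte plate used by the IO tests
make_toy_plate_df <- function(duplicates = TRUE) {
  df <- data.frame(
    sample_id = c("s1", "s1", "s2", "s2"),
    group = c("control", "control", "post1h", "post1h"),
    tissue = "plasma",
    duplicate = c(1L, 2L, 1L, 2L),
    IL6 = c(100, 120, 200, 220),
    VEGF = c(50, 55, 60, 65),
    Chex1 = 1000, Chex2 = 900, Chex3 = 800,
    Chex4 = c(700, 700, 1400, 1400),
    stringsAsFactors = FALSE
  )
  if (!duplicates) df <- df[df$duplicate == 1L, ]
  rownames(df) <- NULL
  df
}

toy_panel <- function() analyte_panel(c("IL6", "VEGF"))

write_toy_plate <- function(df, envir = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = envir)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

# small luminex_matrix built directly from a numeric matrix (samples x
# analytes), for clustering tests
make_matrix_fixture <- function(values, groups,
                                analytes = sprintf("A%02d", ncol(values))) {
  panel <- analyte_panel(sprintf("A%02d", seq_len(ncol(values))))
  colnames(values) <- panel$names
  out <- data.frame(
    sample_id = sprintf("s%02d", seq_len(nrow(values))),
    group = groups,
    tissue = "plasma",
    values,
    Chex1 = 1, Chex2 = 1, Chex3 = 1, Chex4 = 1,
    check.names = FALSE,
    stringsAsFactors = FALSE
  )
  attr(out, "panel") <- panel
  attr(out, "normalized") <- TRUE
  class(out) <- c("luminex_matrix", "data.frame")
  out
}
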