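#' Configuration for a full pipeline run
#'
#' Exactly one input mode is active: simulation (the default; per-tissue
#' [sim_config()]s with the published fold-effect sets as ground truth) or
#' file input (paths to plate tables read with [read_plate()]).
#'
#' @param simulate logical; simulate the cohort (default TRUE).
#' @param plasma_config,retina_config per-tissue [sim_config()]s used in
#'   simulate mode. Defaults carry the published plasma (10-analyte) and
#'   retina (4-analyte) 1h fold effects; the retina stream is seeded
#'   independently of plasma.
#' @param plasma_path,retina_path plate-table paths used when
#'   `simulate = FALSE`.
#' @param group treated group screened against control (default
#'   `"post1h"`).
#' @param statistic,sided,q screen settings; see [run_screen()].
#' @param seed integer master seed, recorded in the bundle and applied to
#'   the per-tissue simulation configs (plasma: `seed`; retina:
#'   `seed + 1000`; OCT/histology streams offset internally).
#' @return A `run_config`.
#' @export
run_config <- function(simulate = TRUE,
                       plasma_config = NULL, retina_config = NULL,
                       plasma_path = NULL, retina_path = NULL,
                       group = "post1h",
                       statistic = "mean_diff", sided = "two", q = 0.1,
                       seed = 1L) {
  if (simulate && (!is.null(plasma_path) || !is.null(retina_path))) {
    stop("exactly one of simulation and file input may be active",
         call. = FALSE)
  }
  if (!simulate && (is.null(plasma_path) || is.null(retina_path))) {
    stop("file mode needs both plasma_path and retina_path",
         call. = FALSE)
  }
  seed <- as.integer(seed)
  if (simulate) {
    if (is.null(plasma_config)) {
      plasma_config <- sim_config(
        affected_analytes = default_plasma_effects(),
        tissue = "plasma", seed = seed
      )
    }
    if (is.null(retina_config)) {
      retina_config <- sim_config(
        affected_analytes = default_retina_effects(),
        tissue = "retina", seed = seed + 1000L
      )
    }
  }
  structure(
    list(simulate = simulate,
         plasma_config = plasma_config, retina_config = retina_config,
         plasma_path = plasma_path, retina_path = retina_path,
         group = group, statistic = statistic, sided = sided, q = q,
         seed = seed),
    class = "run_config"
  )
}

#' Run the full posthypoxic analysis pipeline
#'
#' Assembles the whole analysis for both tissues: plate acquisition
#' (simulation or file), duplicate averaging, Chex #4 normalization, the
#' complete-separation screen with the Mann-Whitney/BH secondary screen,
#' sample-axis hierarchical clustering with the group-segregation score,
#' the cross-tissue Venn partition of primary hits, and (in simulate
#' mode) the OCT and histology group statistics. Deterministic for a
#' fixed `(config, seed)`.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, tab-separated result
#'   tables are written beneath it via [write_bundle()].
#' @return A `report_bundle`: list with `matrices`, `screens`, `clusters`,
#'   `segregation`, `venn`, `oct`, `oct_report`, `histology`,
#'   `hist_stats`, and the `config` fingerprint.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))

  plates <- if (config$simulate) {
    list(plasma = simulate_luminex_plate(config$plasma_config),
         retina = simulate_luminex_plate(config$retina_config))
  } else {
    list(plasma = read_plate(config$plasma_path),
         retina = read_plate(config$retina_path))
  }

  matrices <- lapply(plates, function(p) chex_normalize(average_duplicates(p)))

  screens <- lapply(matrices, function(m) {
    run_screen(m, group = config$group, statistic = config$statistic,
               sided = config$sided, q = config$q)
  })

  clusters <- lapply(matrices, hier_cluster)
  segregation <- mapply(function(cl, m) {
    segregation_score(cl, stats::setNames(m$group, m$sample_id),
                      target = config$group)
  }, clusters, matrices)

  primary <- lapply(screens, function(s) s$analyte[s$primary_hit])
  venn <- venn_partition(primary$plasma, primary$retina)

  oct <- oct_rep <- histology <- hist_stats <- NULL
  if (config$simulate) {
    oct <- simulate_oct_table(config$plasma_config)
    oct_rep <- oct_report(oct)
    histology <- simulate_histology(config$plasma_config)
    hist_stats <- list(
      aqp4 = anova_tukey(split(histology$aqp4, histology$group)),
      kir41 = anova_tukey(split(histology$kir41, histology$group)),
      gfap = anova_tukey(split(histology$gfap, histology$group)),
      tunel = two_way_anova(histology)
    )
  }

  bundle <- structure(
    list(matrices = matrices, screens = screens, clusters = clusters,
         segregation = segregation, venn = venn,
         oct = oct, oct_report = oct_rep,
         histology = histology, hist_stats = hist_stats,
         config = config),
    class = "report_bundle"
  )
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' Write a report bundle as tab-separated tables
#'
#' @param bundle a `report_bundle`.
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, name) {
    utils::write.table(x, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  for (t in names(bundle$screens)) {
    write_screen_results(bundle$screens[[t]],
                         file.path(out_dir, paste0("screen_", t, ".tsv")))
  }
  venn_df <- data.frame(
    set = rep(c("plasma_only", "shared", "retina_only"),
              lengths(bundle$venn)),
    analyte = unlist(bundle$venn, use.names = FALSE)
  )
  tsv(venn_df, "venn_partition.tsv")
  seg_df <- data.frame(tissue = names(bundle$segregation),
                       segregation_score = as.numeric(bundle$segregation))
  tsv(seg_df, "segregation_scores.tsv")
  if (!is.null(bundle$oct_report)) {
    tsv(bundle$oct_report$summary, "oct_summary.tsv")
    tsv(bundle$oct_report$delta, "oct_delta.tsv")
  }
  if (!is.null(bundle$histology)) {
    tsv(bundle$histology, "histology.tsv")
  }
  writeLines(
    c(sprintf("seed\t%d", bundle$config$seed),
      sprintf("group\t%s", bundle$config$group),
      sprintf("statistic\t%s", bundle$config$statistic),
      sprintf("sided\t%s", bundle$config$sided),
      sprintf("q\t%g", bundle$config$q),
      sprintf("mode\t%s",
              if (bundle$config$simulate) "simulate" else "files")),
    file.path(out_dir, "run_config.tsv")
  )
  invisible(out_dir)
}
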