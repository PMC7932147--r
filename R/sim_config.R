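#' Simulation configuration with known ground truth
#'
#' Bundles every parameter of the synthetic posthypoxic study: a Luminex
#' plate design (three groups, duplicate wells, internal-control beads,
#' log-normal MFI noise, per-well scale drift, group fold-effects on a
#' chosen analyte subset), an OCT thickness design (paired
#' baseline/posthypoxia eyes with additive per-layer group effects and a
#' configurable TRT-GCC coupling), and a histology design
#' (immunofluorescence mean-gray values, glial process counts, Poisson
#' apoptotic-cell counts per retinal layer).
#'
#' Noise model for the plate: analyte MFI in a well is
#' `baseline * fold(analyte, group) * sample_noise * well_scale * dup_noise`
#' where `sample_noise` is log-normal with coefficient of variation
#' `noise_cv` (shared by a sample's duplicate wells), `well_scale` is
#' log-normal with log-scale SD `well_scale_sd` and multiplies analyte and
#' Chex control beads identically, and `dup_noise` is log-normal with CV
#' `duplicate_cv`. All log-normal factors have mean 1. With every noise
#' parameter zero the generator returns the configured ground truth
#' exactly.
#'
#' @param n_per_group samples per group; a single count or a named vector
#'   over `groups`. All counts must be >= 2.
#' @param n_analytes number of analytes on the plate (default 39).
#' @param affected_analytes data frame with columns `analyte` (name or
#'   1-based index), `group`, `fold` (> 0) giving multiplicative group
#'   effects; default none. See [default_plasma_effects()].
#' @param mfi_baseline control-level MFI per analyte; a scalar or a vector
#'   of length `n_analytes`. Default: a deterministic log-spaced ladder
#'   from 80 to 8000, spanning typical bead-assay fluorescence.
#' @param noise_cv coefficient of variation of per-sample log-normal
#'   biological noise (default 0.1).
#' @param well_scale_sd log-scale SD of per-well multiplicative drift
#'   (default 0.15); captured by the Chex beads.
#' @param duplicate_cv within-duplicate technical CV (default 0.05).
#' @param chex_baseline MFI of the four Chex internal-control bead classes.
#' @param tissue plate tissue label, `"plasma"` or `"retina"`.
#' @param panel optional `analyte_panel` naming the analytes; default
#'   [default_analyte_panel()] when `n_analytes == 39`, else generic names.
#' @param oct list of OCT design parameters; see Details. Defaults follow
#'   the printed group means of the study (baseline TRT 222.8 um, GCC
#'   79.13 um, IS/OS 46 um; 1h effects TRT -4.3, GCC -2.1; 18h effects TRT
#'   +5.8, GCC +2.6; eight 1h eyes, ten 18h eyes; TRT-GCC coupling 0.85).
#' @param hist list of histology design parameters; defaults follow the
#'   printed group summaries (AQP-4 1066/2009/1627, Kir4.1
#'   471.5/381.3/527.3 mean gray value, GFAP 10.2/45.1/27.9 processes per
#'   0.5 mm, rare apoptotic cells confined to the outer nuclear layer).
#' @param seed integer RNG seed; every generator call is deterministic in
#'   `(config, seed)`.
#'
#' @details The `oct` list understands `n_eyes` (named, per posthypoxia
#' group), `baseline_mean`, `between_sd` (per-eye baseline variation),
#' `noise_sd` (visit-level measurement noise), `trt_gcc_cor`, and
#' `effects` (named list of per-layer additive um shifts per group).
#' The `hist` list understands `n_per_group`, `means`/`sds` (named lists
#' over `aqp4`, `kir41`, `gfap`, each a vector over groups) and
#' `tunel_lambda` (list over groups of Poisson means for layers GCL, INL,
#' ONL).
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_per_group = 5L,
                       n_analytes = 39L,
                       affected_analytes = NULL,
                       mfi_baseline = NULL,
                       noise_cv = 0.1,
                       well_scale_sd = 0.15,
                       duplicate_cv = 0.05,
                       chex_baseline = c(12000, 8000, 4000, 2000),
                       tissue = "plasma",
                       panel = NULL,
                       oct = list(),
                       hist = list(),
                       seed = 1L) {
  groups <- c("control", "post1h", "post18h")
  if (length(n_per_group) == 1L) {
    n_per_group <- stats::setNames(rep(as.integer(n_per_group), 3L), groups)
  }
  if (is.null(names(n_per_group))) names(n_per_group) <- groups
  if (!all(groups %in% names(n_per_group))) {
    stop_field("n_per_group", "must name counts for control, post1h, post18h")
  }
  n_per_group <- n_per_group[groups]
  if (any(n_per_group < 2)) {
    stop_field("n_per_group", "all group counts must be >= 2")
  }
  n_analytes <- as.integer(n_analytes)
  if (is.na(n_analytes) || n_analytes < 1) {
    stop_field("n_analytes", "must be a positive integer")
  }

  if (is.null(panel)) {
    panel <- if (n_analytes == 39L) {
      default_analyte_panel()
    } else {
      analyte_panel(sprintf("A%02d", seq_len(n_analytes)))
    }
  }
  if (length(panel$names) != n_analytes) {
    stop_field("panel", "panel length must equal n_analytes")
  }

  if (is.null(mfi_baseline)) {
    mfi_baseline <- round(exp(seq(log(80), log(8000),
                                  length.out = n_analytes)), 1)
  }
  if (length(mfi_baseline) == 1L) {
    mfi_baseline <- rep(mfi_baseline, n_analytes)
  }
  if (length(mfi_baseline) != n_analytes || any(mfi_baseline <= 0)) {
    stop_field("mfi_baseline",
               "must be positive, scalar or length n_analytes")
  }

  for (f in c("noise_cv", "well_scale_sd", "duplicate_cv")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      stop_field(f, "must be a single non-negative number")
    }
  }
  if (length(chex_baseline) != 4L || any(chex_baseline <= 0)) {
    stop_field("chex_baseline", "must be 4 positive MFI values")
  }
  tissue <- match.arg(tissue, c("plasma", "retina"))

  if (is.null(affected_analytes)) {
    affected_analytes <- data.frame(analyte = character(), group = character(),
                                    fold = numeric())
  }
  affected_analytes <- as.data.frame(affected_analytes)
  if (nrow(affected_analytes)) {
    need <- c("analyte", "group", "fold")
    if (!all(need %in% names(affected_analytes))) {
      stop_field("affected_analytes",
                 "needs columns analyte, group, fold")
    }
    if (is.numeric(affected_analytes$analyte)) {
      idx <- as.integer(affected_analytes$analyte)
      if (any(idx < 1 | idx > n_analytes)) {
        stop_field("affected_analytes", "analyte index out of range")
      }
      affected_analytes$analyte <- panel$names[idx]
    } else {
      affected_analytes$analyte <-
        resolve_analytes(as.character(affected_analytes$analyte), panel)
    }
    if (!all(affected_analytes$group %in% groups)) {
      stop_field("affected_analytes",
                 "group must be one of control, post1h, post18h")
    }
    if (any(affected_analytes$fold <= 0)) {
      stop_field("affected_analytes", "all folds must be > 0")
    }
    if (anyDuplicated(affected_analytes[c("analyte", "group")])) {
      stop_field("affected_analytes",
                 "(analyte, group) pairs must be unique")
    }
  }

  oct <- utils::modifyList(default_oct_design(), oct)
  bm <- oct$baseline_mean
  for (g in names(oct$effects)) {
    eff <- oct$effects[[g]]
    if ((bm[["GCC"]] + (eff[["GCC"]] %||% 0)) >=
        (bm[["TRT"]] + (eff[["TRT"]] %||% 0))) {
      stop_field("oct", sprintf(
        "effects for %s would force mean GCC >= mean TRT", g))
    }
  }
  if (any(unlist(oct[c("between_sd", "noise_sd")]) < 0)) {
    stop_field("oct", "noise SDs must be non-negative")
  }
  if (abs(oct$trt_gcc_cor) > 1) {
    stop_field("oct", "trt_gcc_cor must lie in [-1, 1]")
  }

  hist <- utils::modifyList(default_hist_design(), hist)
  if (any(unlist(hist$means[c("aqp4", "kir41")]) <= 0)) {
    stop_field("hist", "intensity means must be positive")
  }
  if (any(unlist(hist$sds) < 0)) {
    stop_field("hist", "histology SDs must be non-negative")
  }
  if (any(unlist(hist$tunel_lambda) < 0)) {
    stop_field("hist", "tunel_lambda means must be non-negative")
  }

  structure(
    list(
      groups = groups,
      n_per_group = n_per_group,
      n_analytes = n_analytes,
      affected_analytes = affected_analytes,
      mfi_baseline = mfi_baseline,
      noise_cv = noise_cv,
      well_scale_sd = well_scale_sd,
      duplicate_cv = duplicate_cv,
      chex_baseline = chex_baseline,
      tissue = tissue,
      panel = panel,
      oct = oct,
      hist = hist,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

default_oct_design <- function() {
  list(
    n_eyes = c(post1h = 8L, post18h = 10L),
    baseline_mean = c(TRT = 222.8, GCC = 79.13, ISOS = 46),
    between_sd = c(TRT = 3.5, GCC = 2.0, ISOS = 3.0),
    noise_sd = 1,
    trt_gcc_cor = 0.85,
    effects = list(
      post1h = c(TRT = -4.3, GCC = -2.1, ISOS = -1.9),
      post18h = c(TRT = 5.8, GCC = 2.6, ISOS = -0.2)
    )
  )
}

default_hist_design <- function() {
  groups <- c("control", "post1h", "post18h")
  nm <- function(x) stats::setNames(x, groups)
  list(
    n_per_group = nm(c(5L, 5L, 5L)),
    means = list(
      aqp4 = nm(c(1066, 2009, 1627)),
      kir41 = nm(c(471.5, 381.3, 527.3)),
      gfap = nm(c(10.2, 45.1, 27.9))
    ),
    sds = list(
      aqp4 = nm(c(316, 125, 293)),
      kir41 = nm(c(55, 44, 48)),
      gfap = nm(c(5.6, 24.4, 24.2))
    ),
    tunel_lambda = list(
      control = c(GCL = 0, INL = 0, ONL = 0.2),
      post1h = c(GCL = 0, INL = 0, ONL = 2),
      post18h = c(GCL = 0, INL = 0, ONL = 2)
    )
  )
}

#' Published fold-effect sets for the two tissues
#'
#' The screen's reported fold ratios for the ten plasma and four retinal
#' analytes significantly increased one hour after hypoxia; used as the
#' default ground truth of the synthetic cohort so the simulated study
#' reproduces the published hit structure (two analytes, VEGF and IL1B,
#' shared across tissues).
#'
#' @return Data frame with columns `analyte`, `group`, `fold`.
#' @export
default_plasma_effects <- function() {
  data.frame(
    analyte = c("IL6", "IL13", "VEGF", "GMCSF.CSF2", "MIP1A", "IL9",
                "IL4", "GCSF.CSF3", "IL17A", "IL1B"),
    group = "post1h",
    fold = c(2.192, 1.898, 1.891, 1.628, 1.549, 1.526,
             1.499, 1.399, 1.303, 1.263)
  )
}

#' @rdname default_plasma_effects
#' @export
default_retina_effects <- function() {
  data.frame(
    analyte = c("VEGF", "IL1B", "IL22", "MCP3"),
    group = "post1h",
    fold = c(2.107, 1.898, 1.456, 1.244)
  )
}

#' Strip all noise from a simulation configuration
#'
#' Convenience used in tests of the noise-free limit: zeroes the Luminex
#' CVs and drift, the OCT noise terms, and the histology SDs (Poisson
#' means are left as configured).
#'
#' @param config a `sim_config`.
#' @return The modified `sim_config`.
#' @export
noise_free <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  config$noise_cv <- 0
  config$well_scale_sd <- 0
  config$duplicate_cv <- 0
  config$oct$between_sd[] <- 0
  config$oct$noise_sd <- 0
  config$hist$sds <- lapply(config$hist$sds, function(x) { x[] <- 0; x })
  config
}
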