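# Seeded generators for the three synthetic data streams. Each generator is
# a pure function of (config, config$seed); distinct small offsets keep the
# three streams independent of one another under a shared seed.

lnorm_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a Luminex multiplex plate
#'
#' Generates one plate of well-level mean-fluorescence-intensity records:
#' `n_per_group` samples per group, two duplicate wells per sample, the
#' configured analytes plus four Chex internal-control bead channels. A
#' well's analyte MFI is `baseline x group-fold x sample-noise x
#' well-scale x duplicate-noise`; the well-scale drift multiplies analyte
#' and Chex channels identically, which is what makes control-bead
#' normalization exact in this model.
#'
#' @param config a [sim_config()].
#' @return A `luminex_plate`: data frame with columns `sample_id`,
#'   `group`, `tissue`, `duplicate`, one MFI column per analyte, and
#'   `Chex1`..`Chex4`; the panel is attached as attribute `"panel"`.
#' @export
simulate_luminex_plate <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    groups <- config$groups
    n <- config$n_per_group
    sample_id <- sprintf("M%02d", seq_len(sum(n)))
    group <- rep(groups, n)

    # ground-truth expected MFI per sample x analyte
    fold <- matrix(1, nrow = sum(n), ncol = config$n_analytes,
                   dimnames = list(sample_id, config$panel$names))
    aff <- config$affected_analytes
    if (nrow(aff)) {
      for (k in seq_len(nrow(aff))) {
        fold[group == aff$group[k], aff$analyte[k]] <- aff$fold[k]
      }
    }
    truth <- sweep(fold, 2, config$mfi_baseline, `*`)

    sample_noise <- matrix(
      lnorm_factor(length(truth), config$noise_cv),
      nrow = nrow(truth)
    )
    level <- truth * sample_noise

    n_wells <- 2L * sum(n)
    well_scale <- if (config$well_scale_sd <= 0) {
      rep(1, n_wells)
    } else {
      stats::rlnorm(n_wells, meanlog = -config$well_scale_sd^2 / 2,
                    sdlog = config$well_scale_sd)
    }

    rows <- vector("list", n_wells)
    w <- 0L
    for (i in seq_len(sum(n))) {
      for (d in 1:2) {
        w <- w + 1L
        dup <- lnorm_factor(config$n_analytes, config$duplicate_cv)
        chex <- config$chex_baseline * well_scale[w] *
          lnorm_factor(4L, config$duplicate_cv)
        mfi <- level[i, ] * well_scale[w] * dup
        rows[[w]] <- c(mfi, chex)
      }
    }
    mat <- do.call(rbind, rows)
    colnames(mat) <- c(config$panel$names, paste0("Chex", 1:4))

    plate <- data.frame(
      sample_id = rep(sample_id, each = 2L),
      group = rep(group, each = 2L),
      tissue = config$tissue,
      duplicate = rep(1:2, sum(n)),
      mat,
      check.names = FALSE,
      stringsAsFactors = FALSE
    )
    new_luminex_plate(plate, config$panel)
  })
}

#' Simulate paired OCT layer thicknesses
#'
#' Per-eye baseline and posthypoxia thicknesses (total retinal thickness
#' TRT, ganglion cell complex GCC, photoreceptor segments IS/OS, all um)
#' for the two posthypoxia cohorts. Baseline TRT and GCC are drawn from a
#' bivariate normal with correlation `oct$trt_gcc_cor`; the posthypoxia
#' visit adds the configured per-layer group effect plus visit-level
#' measurement noise to the same eye, giving a paired design. The derived
#' inner-retina remainder INL-to-RPE is always TRT - GCC.
#'
#' @param config a [sim_config()].
#' @return An `oct_table`: data frame with columns `animal`, `eye`,
#'   `group`, `timepoint` (`"baseline"` or the group name), `TRT`, `GCC`,
#'   `ISOS`, `INL_to_RPE`.
#' @export
simulate_oct_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  oct <- config$oct
  with_seed(config$seed + 1L, {
    out <- list()
    eye_counter <- 0L
    for (g in names(oct$n_eyes)) {
      ne <- oct$n_eyes[[g]]
      z1 <- stats::rnorm(ne)
      z2 <- stats::rnorm(ne)
      rho <- oct$trt_gcc_cor
      trt0 <- oct$baseline_mean[["TRT"]] + oct$between_sd[["TRT"]] * z1
      gcc0 <- oct$baseline_mean[["GCC"]] +
        oct$between_sd[["GCC"]] * (rho * z1 + sqrt(1 - rho^2) * z2)
      isos0 <- oct$baseline_mean[["ISOS"]] +
        stats::rnorm(ne, 0, oct$between_sd[["ISOS"]])
      eff <- oct$effects[[g]] %||% c(TRT = 0, GCC = 0, ISOS = 0)
      noise <- function() stats::rnorm(ne, 0, oct$noise_sd)
      trt1 <- trt0 + eff[["TRT"]] + noise()
      gcc1 <- gcc0 + eff[["GCC"]] + noise()
      isos1 <- isos0 + eff[["ISOS"]] + noise()

      eye_id <- sprintf("E%02d", eye_counter + seq_len(ne))
      animal <- sprintf("A%02d", (eye_counter + seq_len(ne) + 1L) %/% 2L)
      eye_counter <- eye_counter + ne
      out[[g]] <- data.frame(
        animal = rep(animal, 2L),
        eye = rep(eye_id, 2L),
        group = g,
        timepoint = rep(c("baseline", g), each = ne),
        TRT = c(trt0, trt1),
        GCC = c(gcc0, gcc1),
        ISOS = c(isos0, isos1),
        stringsAsFactors = FALSE
      )
    }
    tab <- do.call(rbind, out)
    rownames(tab) <- NULL
    if (any(tab$GCC >= tab$TRT) || any(tab$GCC <= 0)) {
      stop("simulated layer thicknesses violate 0 < GCC < TRT; ",
           "reduce noise or adjust effects", call. = FALSE)
    }
    tab$INL_to_RPE <- derive_inl_to_rpe(tab$TRT, tab$GCC)
    class(tab) <- c("oct_table", "data.frame")
    tab
  })
}

#' Simulate per-animal histology quantifications
#'
#' Per-animal immunofluorescence mean-gray values for the water channel
#' AQP-4 and potassium channel Kir4.1, counts of GFAP-positive Muller-glia
#' processes per 0.5 mm, and Poisson counts of apoptotic (TUNEL-positive)
#' cells per retinal layer (GCL, INL, ONL). Intensity and process values
#' are normal with the configured group means and SDs, truncated at zero;
#' with all SDs zero the configured means are returned exactly.
#'
#' @param config a [sim_config()].
#' @return A `histology_table`: data frame with columns `animal`, `group`,
#'   `aqp4`, `kir41`, `gfap`, `tunel_GCL`, `tunel_INL`, `tunel_ONL`.
#' @export
simulate_histology <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  h <- config$hist
  with_seed(config$seed + 2L, {
    out <- list()
    a0 <- 0L
    for (g in config$groups) {
      n <- h$n_per_group[[g]]
      draw <- function(measure) {
        pmax(stats::rnorm(n, h$means[[measure]][[g]], h$sds[[measure]][[g]]),
             0)
      }
      lam <- h$tunel_lambda[[g]]
      out[[g]] <- data.frame(
        animal = sprintf("H%02d", a0 + seq_len(n)),
        group = g,
        aqp4 = draw("aqp4"),
        kir41 = draw("kir41"),
        gfap = draw("gfap"),
        tunel_GCL = stats::rpois(n, lam[["GCL"]]),
        tunel_INL = stats::rpois(n, lam[["INL"]]),
        tunel_ONL = stats::rpois(n, lam[["ONL"]]),
        stringsAsFactors = FALSE
      )
      a0 <- a0 + n
    }
    tab <- do.call(rbind, out)
    rownames(tab) <- NULL
    class(tab) <- c("histology_table", "data.frame")
    tab
  })
}
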