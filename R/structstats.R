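# Group statistics for the OCT layer-thickness tables and the histology
# quantifications: layer derivation, mean/SEM/n summaries, paired t,
# one-way ANOVA with Tukey HSD (raw-data and summary-statistics routes),
# two-way ANOVA for layer x group counts, Pearson correlation.

#' Derive the INL-to-RPE thickness
#'
#' The inner-nuclear-layer-to-retinal-pigmented-epithelium thickness is
#' total retinal thickness minus the ganglion cell complex.
#'
#' @param trt,gcc thicknesses in um; `0 < gcc < trt` required.
#' @return `trt - gcc`, vectorized.
#' @export
#' @examples
#' derive_inl_to_rpe(229.1, 81.4)  # 147.7
derive_inl_to_rpe <- function(trt, gcc) {
  if (any(gcc <= 0) || any(gcc >= trt)) {
    stop("thicknesses must satisfy 0 < gcc < trt", call. = FALSE)
  }
  trt - gcc
}

#' Mean, SEM and n of a group
#'
#' @param values non-empty numeric vector.
#' @return A `group_summary`: list with `mean`, `sem` (sample SD / sqrt(n),
#'   `NA` for n = 1), and `n`.
#' @export
group_summary <- function(values) {
  if (!length(values) || any(!is.finite(values))) {
    stop("values must be a non-empty finite vector", call. = FALSE)
  }
  n <- length(values)
  sem <- if (n > 1) stats::sd(values) / sqrt(n) else NA_real_
  structure(list(mean = mean(values), sem = sem, n = n),
            class = "group_summary")
}

#' Difference and percent change between two group summaries
#'
#' @param a reference summary; @param b comparison summary.
#' @return List with `delta` (`b$mean - a$mean`) and `pct`
#'   (`100 * delta / a$mean`).
#' @export
#' @examples
#' s <- function(m) group_summary(rep(m, 2))
#' group_delta(s(218.5), s(229.1))  # delta 10.6, pct 4.85
group_delta <- function(a, b) {
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  if (a$mean == 0) stop("reference mean is zero", call. = FALSE)
  delta <- b$mean - a$mean
  list(delta = delta, pct = 100 * delta / a$mean)
}

#' Paired t-test with explicit pairing
#'
#' Classical paired t on `post - pre` (positive mean difference means
#' post exceeds pre). When IDs are supplied, `post` is reordered to match
#' `pre`; unmatched IDs are an error. Constant non-zero differences (zero
#' variance) are a degenerate case reported as such with the direction;
#' identical vectors give `t = 0, p = 1`.
#'
#' @param pre,post numeric vectors, length >= 2.
#' @param id_pre,id_post optional pairing IDs.
#' @return List with `t`, `df`, `p`, `mean_diff`, `degenerate`,
#'   `direction`.
#' @export
paired_t <- function(pre, post, id_pre = NULL, id_post = NULL) {
  if (!is.null(id_pre) || !is.null(id_post)) {
    if (is.null(id_pre) || is.null(id_post) ||
        !setequal(id_pre, id_post) || anyDuplicated(id_pre)) {
      stop("pairing IDs do not match one-to-one", call. = FALSE)
    }
    post <- post[match(id_pre, id_post)]
  }
  if (length(pre) != length(post) || length(pre) < 2) {
    stop("need equal-length paired vectors of length >= 2", call. = FALSE)
  }
  d <- post - pre
  direction <- if (mean(d) > 0) "increase" else
    if (mean(d) < 0) "decrease" else "none"
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      return(list(t = 0, df = length(d) - 1, p = 1, mean_diff = 0,
                  degenerate = FALSE, direction = "none"))
    }
    return(list(t = NA_real_, df = length(d) - 1, p = NA_real_,
                mean_diff = mean(d), degenerate = TRUE,
                direction = direction))
  }
  tt <- stats::t.test(post, pre, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = unname(tt$estimate),
       degenerate = FALSE, direction = direction)
}

tukey_kramer <- function(means, ns, mse, df_w) {
  k <- length(means)
  pairs <- utils::combn(k, 2)
  comparison <- apply(pairs, 2, function(ij) {
    paste(names(means)[ij[2]], names(means)[ij[1]], sep = "-")
  })
  diff <- means[pairs[2, ]] - means[pairs[1, ]]
  se <- sqrt(mse / 2 * (1 / ns[pairs[1, ]] + 1 / ns[pairs[2, ]]))
  p <- if (mse > 0) {
    stats::ptukey(abs(diff) / se, k, df_w, lower.tail = FALSE)
  } else {
    ifelse(diff == 0, 1, 0)
  }
  data.frame(comparison = comparison, diff = unname(diff),
             p = unname(p), stringsAsFactors = FALSE)
}

#' One-way ANOVA with Tukey HSD
#'
#' Classical one-way ANOVA across the groups followed by Tukey's honestly
#' significant difference test (Tukey-Kramer for unequal n). Fully
#' degenerate input (every value identical) is reported as `F = 0, p = 1`
#' with all pairwise p = 1.
#'
#' @param groups named list of numeric vectors, each of length >= 2.
#' @return List with `F`, `df`, `p` and a `tukey` data frame
#'   (`comparison`, `diff`, `p`).
#' @export
anova_tukey <- function(groups) {
  if (length(groups) < 2 || any(lengths(groups) < 2)) {
    stop("need >= 2 groups with n >= 2 each", call. = FALSE)
  }
  if (is.null(names(groups))) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))

  if (stats::var(values) == 0) {
    ns <- lengths(groups)
    means <- vapply(groups, mean, numeric(1))
    return(list(F = 0, df = c(length(groups) - 1,
                              length(values) - length(groups)),
                p = 1,
                tukey = tukey_kramer(means, ns, 0,
                                     length(values) - length(groups))))
  }
  fit <- stats::aov(values ~ g)
  an <- summary(fit)[[1]]
  th <- stats::TukeyHSD(fit)$g
  list(
    F = an[["F value"]][1],
    df = an[["Df"]],
    p = an[["Pr(>F)"]][1],
    tukey = data.frame(comparison = rownames(th),
                       diff = unname(th[, "diff"]),
                       p = unname(th[, "p adj"]),
                       stringsAsFactors = FALSE)
  )
}

#' One-way ANOVA with Tukey HSD from printed summaries
#'
#' Reconstructs the ANOVA from (mean, SEM, n) triples alone: group SDs
#' from the SEMs, pooled mean squared error, between-group sum of squares
#' from the means, then the same F and Tukey-Kramer p-values as
#' [anova_tukey()] would give on raw data with those summaries. Useful
#' for cross-checking published tables that print only mean +/- SEM.
#'
#' @param summaries named list of `group_summary` objects with n >= 2.
#' @return Same shape as [anova_tukey()].
#' @export
anova_tukey_from_summary <- function(summaries) {
  if (length(summaries) < 2) stop("need >= 2 groups", call. = FALSE)
  stopifnot(all(vapply(summaries, inherits, logical(1), "group_summary")))
  ns <- vapply(summaries, `[[`, numeric(1), "n")
  if (any(ns < 2)) stop("each summary needs n >= 2", call. = FALSE)
  sems <- vapply(summaries, `[[`, numeric(1), "sem")
  if (any(sems < 0)) stop("SEM must be >= 0", call. = FALSE)
  means <- vapply(summaries, `[[`, numeric(1), "mean")
  if (is.null(names(summaries))) {
    names(means) <- paste0("g", seq_along(means))
  } else {
    names(means) <- names(summaries)
  }

  sds <- sems * sqrt(ns)
  N <- sum(ns)
  k <- length(ns)
  df_b <- k - 1
  df_w <- N - k
  ss_w <- sum((ns - 1) * sds^2)
  grand <- sum(ns * means) / N
  ss_b <- sum(ns * (means - grand)^2)
  mse <- ss_w / df_w

  if (mse == 0) {
    Fv <- if (ss_b == 0) 0 else Inf
    p <- if (ss_b == 0) 1 else 0
  } else {
    Fv <- (ss_b / df_b) / mse
    p <- stats::pf(Fv, df_b, df_w, lower.tail = FALSE)
  }
  list(F = Fv, df = c(df_b, df_w), p = p,
       tukey = tukey_kramer(means, ns, mse, df_w))
}

#' Two-way ANOVA for layer-by-group counts
#'
#' Main effects and interaction with type-II sums of squares, as used for
#' apoptotic-cell counts across retinal layers and experimental groups.
#' Accepts either a `histology_table` (its TUNEL count columns are
#' reshaped to long form) or a long data frame with columns `value`,
#' `group`, `layer`. An all-constant response is reported as degenerate.
#'
#' @param x `histology_table` or long data frame.
#' @return List with `table` (term, df, F, p), `degenerate`.
#' @export
two_way_anova <- function(x) {
  if (inherits(x, "histology_table")) {
    x <- tunel_long(x)
  }
  need <- c("value", "group", "layer")
  if (!all(need %in% names(x))) {
    stop("need columns value, group, layer", call. = FALSE)
  }
  if (any(table(x$group, x$layer) == 0)) {
    stop("empty cell(s) in the group x layer layout", call. = FALSE)
  }
  if (stats::var(x$value) == 0) {
    return(list(table = data.frame(
      term = c("group", "layer", "group:layer"),
      df = NA_integer_, F = NA_real_, p = NA_real_,
      stringsAsFactors = FALSE
    ), degenerate = TRUE))
  }
  fit <- stats::lm(value ~ group * layer, data = x)
  an <- car::Anova(fit, type = 2)
  keep <- c("group", "layer", "group:layer")
  list(
    table = data.frame(
      term = keep,
      df = an[keep, "Df"],
      F = an[keep, "F value"],
      p = an[keep, "Pr(>F)"],
      stringsAsFactors = FALSE
    ),
    degenerate = FALSE
  )
}

#' Reshape TUNEL counts to long form
#'
#' @param hist a `histology_table`.
#' @return Long data frame with columns `animal`, `group`, `layer`,
#'   `value`.
#' @export
tunel_long <- function(hist) {
  stopifnot(inherits(hist, "histology_table"))
  layers <- c("GCL", "INL", "ONL")
  do.call(rbind, lapply(layers, function(l) {
    data.frame(animal = hist$animal, group = hist$group, layer = l,
               value = hist[[paste0("tunel_", l)]],
               stringsAsFactors = FALSE)
  }))
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y numeric vectors of equal length >= 3 with non-zero variance.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("need equal-length vectors of length >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Table-style OCT report for one posthypoxia cohort
#'
#' Per layer: baseline and posthypoxia mean/SEM/n plus the paired-t
#' p-value on the same eyes. A delta block compares the two posthypoxia
#' cohorts' visit means (difference in um and percent change relative to
#' the earlier cohort).
#'
#' @param oct an `oct_table`.
#' @return List with `summary` (one row per group x layer) and `delta`
#'   (18h-vs-1h posthypoxia visit deltas per layer), plus `trt_gcc`
#'   (Pearson correlation of TRT and GCC across all eyes and visits).
#' @export
oct_report <- function(oct) {
  stopifnot(inherits(oct, "oct_table"))
  layers <- c("TRT", "GCC", "INL_to_RPE", "ISOS")
  groups <- unique(oct$group)

  rows <- list()
  post_summ <- list()
  for (g in groups) {
    sub <- oct[oct$group == g, ]
    base <- sub[sub$timepoint == "baseline", ]
    post <- sub[sub$timepoint == g, ]
    for (l in layers) {
      sb <- group_summary(base[[l]])
      sp <- group_summary(post[[l]])
      pt <- paired_t(base[[l]], post[[l]],
                     id_pre = base$eye, id_post = post$eye)
      rows[[paste(g, l)]] <- data.frame(
        group = g, layer = l,
        baseline_mean = sb$mean, baseline_sem = sb$sem, baseline_n = sb$n,
        post_mean = sp$mean, post_sem = sp$sem, post_n = sp$n,
        paired_p = pt$p, mean_diff = pt$mean_diff,
        stringsAsFactors = FALSE
      )
      post_summ[[paste(g, l)]] <- sp
    }
  }
  summary_df <- do.call(rbind, rows)
  rownames(summary_df) <- NULL

  delta_df <- NULL
  if (all(c("post1h", "post18h") %in% groups)) {
    delta_df <- do.call(rbind, lapply(layers, function(l) {
      gd <- group_delta(post_summ[[paste("post1h", l)]],
                        post_summ[[paste("post18h", l)]])
      data.frame(layer = l, delta = gd$delta, pct = gd$pct,
                 stringsAsFactors = FALSE)
    }))
  }

  list(
    summary = summary_df,
    delta = delta_df,
    trt_gcc = pearson_corr(oct$TRT, oct$GCC)
  )
}
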