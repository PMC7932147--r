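#' Run the complete-separation screen over a normalized matrix
#'
#' For every analyte: ratio of the named group to control, the exact
#' enumerated permutation p-value, the complete-separation flag and
#' direction, the exact Mann-Whitney p, and the Benjamini-Hochberg
#' decision at rate `q` across the plate's analytes. Primary hits are the
#' analytes whose permutation p equals the attainable floor (equivalently,
#' whose groups separate completely); secondary hits are BH-significant
#' Mann-Whitney analytes not already primary.
#'
#' @param mat a `luminex_matrix` (normalized; see [chex_normalize()]).
#' @param group treated group label compared with `"control"`.
#' @param statistic permutation statistic, `"mean_diff"` (default) or
#'   `"rank_sum"`.
#' @param sided `"two"` (default) or `"one"`.
#' @param q BH false discovery rate (default 0.1).
#' @param max_splits enumeration cap passed to [exact_perm_test()].
#' @return A `screen_result` data frame, one row per analyte: `analyte`,
#'   `tissue`, `ratio`, `perm_p` (+ exact `perm_num`/`perm_den`), `min_p`,
#'   `separation`, `direction`, `mw_p`, `mw_method`, `bh_p`,
#'   `bh_significant`, `primary_hit`, `secondary_hit`.
#' @export
run_screen <- function(mat, group, statistic = c("mean_diff", "rank_sum"),
                       sided = c("two", "one"), q = 0.1,
                       max_splits = 1e7) {
  stopifnot(inherits(mat, "luminex_matrix"))
  statistic <- match.arg(statistic)
  sided <- match.arg(sided)
  panel <- attr(mat, "panel")
  ratios <- ratio_to_control(mat, group)

  ctrl_rows <- mat$group == "control"
  trt_rows <- mat$group == group

  res <- lapply(panel$names, function(a) {
    ctrl <- mat[[a]][ctrl_rows]
    trt <- mat[[a]][trt_rows]
    perm <- exact_perm_test(ctrl, trt, statistic = statistic,
                            sided = sided, max_splits = max_splits)
    sep <- is_complete_separation(ctrl, trt)
    mw <- mann_whitney_exact(trt, ctrl)
    data.frame(
      analyte = a,
      tissue = mat$tissue[1],
      ratio = unname(ratios[a]),
      perm_p = perm$p,
      perm_num = perm$numerator,
      perm_den = perm$denominator,
      min_p = perm$min_p,
      separation = sep$separated,
      direction = if (sep$separated) sep$direction else
        if (unname(ratios[a]) >= 1) "up" else "down",
      mw_p = mw$p,
      mw_method = mw$method,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)

  bh <- bh_adjust(out$mw_p, q = q)
  out$bh_p <- bh$adjusted
  out$bh_significant <- bh$significant
  # the screen's primary criterion is complete separation, i.e. the
  # smallest possible p-value of the exact test (identical events for the
  # equal-n two-sided design used here)
  out$primary_hit <- out$separation
  out$secondary_hit <- out$bh_significant & !out$primary_hit
  attr(out, "screen_config") <- list(group = group, statistic = statistic,
                                     sided = sided, q = q)
  class(out) <- c("screen_result", "data.frame")
  out
}

#' Partition two hit sets Venn-style
#'
#' @param hits_a,hits_b character vectors of analyte names.
#' @return List with `only_a`, `shared`, `only_b` (disjoint; their union
#'   is the union of the inputs).
#' @export
venn_partition <- function(hits_a, hits_b) {
  list(
    only_a = setdiff(hits_a, hits_b),
    shared = intersect(hits_a, hits_b),
    only_b = setdiff(hits_b, hits_a)
  )
}
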