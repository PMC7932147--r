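# From well-level plate records to the per-sample normalized matrix the
# screen consumes: duplicates are averaged first (deposited tables arrive
# already averaged), then each sample is rescaled by its Chex #4
# control-bead reading relative to the plate median, which removes
# per-well multiplicative drift while keeping values on the MFI scale.

#' Average duplicate wells
#'
#' Collapses a plate to one row per sample by arithmetic mean of the
#' duplicate wells, analyte by analyte (Chex beads included). Samples may
#' have one or two wells; more than two is an error.
#'
#' @param plate a `luminex_plate`.
#' @return A `luminex_matrix`: data frame with one row per sample, columns
#'   `sample_id`, `group`, `tissue`, the analyte MFI columns and
#'   `Chex1`..`Chex4`; panel attached as attribute `"panel"`, and
#'   `normalized = FALSE`.
#' @export
average_duplicates <- function(plate) {
  stopifnot(inherits(plate, "luminex_plate"))
  panel <- attr(plate, "panel")
  counts <- table(plate$sample_id)
  if (any(counts > 2)) {
    stop("sample(s) with more than 2 wells: ",
         paste(names(counts)[counts > 2], collapse = ", "), call. = FALSE)
  }
  ids <- unique(plate$sample_id)
  num_cols <- c(panel$names, CHEX_COLS)
  agg <- stats::aggregate(plate[num_cols],
                          by = list(sample_id = plate$sample_id), mean)
  agg <- agg[match(ids, agg$sample_id), ]
  meta <- plate[!duplicated(plate$sample_id), c("sample_id", "group", "tissue")]
  out <- cbind(meta[match(ids, meta$sample_id), ],
               agg[num_cols])
  rownames(out) <- NULL
  attr(out, "panel") <- panel
  attr(out, "normalized") <- FALSE
  class(out) <- c("luminex_matrix", "data.frame")
  out
}

#' Normalize against Chex #4 control beads
#'
#' Divides each sample's analyte vector by that sample's Chex #4 reading
#' relative to the plate median Chex #4. The median rescaling keeps values
#' on the original MFI scale; because well-scale drift multiplies analyte
#' and control beads identically, this removes it exactly. The Chex
#' columns are rescaled consistently (Chex #4 becomes the plate median for
#' every sample).
#'
#' @param mat a `luminex_matrix` from [average_duplicates()].
#' @param reference reference value for the rescaling; `"median"` (the
#'   default) divides by Chex#4 / median(Chex#4), `"raw"` divides by the
#'   raw Chex #4 reading.
#' @return The normalized `luminex_matrix` (`normalized = TRUE`).
#' @export
chex_normalize <- function(mat, reference = c("median", "raw")) {
  stopifnot(inherits(mat, "luminex_matrix"))
  reference <- match.arg(reference)
  panel <- attr(mat, "panel")
  chex4 <- mat$Chex4
  if (any(!is.finite(chex4) | chex4 <= 0)) {
    stop("missing or non-positive Chex #4 value for sample(s): ",
         paste(mat$sample_id[!is.finite(chex4) | chex4 <= 0],
               collapse = ", "), call. = FALSE)
  }
  ref <- if (reference == "median") stats::median(chex4) else 1
  scale <- chex4 / ref
  cols <- c(panel$names, CHEX_COLS)
  mat[cols] <- sweep(mat[cols], 1, scale, `/`)
  attr(mat, "normalized") <- TRUE
  attr(mat, "chex_reference") <- reference
  mat
}

#' Per-analyte ratio of a group to control
#'
#' For every analyte, the arithmetic mean of the named group's normalized
#' MFI divided by the control-group mean (the screen's "ratio to
#' control").
#'
#' @param mat a `luminex_matrix`.
#' @param group group label to compare against `"control"`.
#' @return Named numeric vector, one ratio per analyte.
#' @export
ratio_to_control <- function(mat, group) {
  stopifnot(inherits(mat, "luminex_matrix"))
  panel <- attr(mat, "panel")
  if (!any(mat$group == group)) {
    stop(sprintf("group '%s' has no samples", group), call. = FALSE)
  }
  if (!any(mat$group == "control")) {
    stop("control group has no samples", call. = FALSE)
  }
  g <- colMeans(mat[mat$group == group, panel$names, drop = FALSE])
  ctl <- colMeans(mat[mat$group == "control", panel$names, drop = FALSE])
  if (any(ctl == 0)) {
    stop("zero control mean for analyte(s): ",
         paste(panel$names[ctl == 0], collapse = ", "), call. = FALSE)
  }
  g / ctl
}
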