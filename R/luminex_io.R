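# Plate tables are tab-separated, one header row, decimal point ".".
# Metadata columns: sample_id, group, tissue, duplicate; then one MFI
# column per analyte (resolvable through the panel's aliases) and the four
# Chex internal-control bead columns. Duplicate-averaged exports (one row
# per sample, as in deposited supplementary tables) are read as
# single-duplicate wells.

CHEX_COLS <- paste0("Chex", 1:4)
META_COLS <- c("sample_id", "group", "tissue", "duplicate")

new_luminex_plate <- function(df, panel) {
  validate_plate(df, panel)
  attr(df, "panel") <- panel
  class(df) <- c("luminex_plate", "data.frame")
  df
}

validate_plate <- function(df, panel) {
  missing_meta <- setdiff(META_COLS, names(df))
  if (length(missing_meta)) {
    stop("plate is missing required column(s): ",
         paste(missing_meta, collapse = ", "), call. = FALSE)
  }
  missing_chex <- setdiff(CHEX_COLS, names(df))
  if (length(missing_chex)) {
    stop("plate is missing Chex control-bead column(s): ",
         paste(missing_chex, collapse = ", "), call. = FALSE)
  }
  missing_an <- setdiff(panel$names, names(df))
  if (length(missing_an)) {
    stop("plate is missing analyte column(s): ",
         paste(missing_an, collapse = ", "), call. = FALSE)
  }
  key <- paste(df$sample_id, df$duplicate)
  if (anyDuplicated(key)) {
    rows <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
    stop("duplicate (sample_id, duplicate) record(s) at row(s) ",
         paste(rows, collapse = ", "), call. = FALSE)
  }
  if (length(unique(df$tissue)) > 1L) {
    stop("all wells on a plate must share one tissue", call. = FALSE)
  }
  vals <- as.matrix(df[c(panel$names, CHEX_COLS)])
  bad <- which(!is.finite(vals) | vals <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-positive or non-finite MFI at row(s) %s",
                 paste(sort(unique(bad[, 1])), collapse = ", ")),
         call. = FALSE)
  }
  invisible(df)
}

#' Read a Luminex plate table
#'
#' Reads a tab-separated plate export, resolves analyte column headings
#' through the panel's alias map, and validates structure (unique
#' (sample, duplicate) records, a single tissue per plate, positive finite
#' MFI). Duplicate-averaged tables without a `duplicate` column are
#' accepted: each row becomes a single-duplicate well (`duplicate = 1`).
#'
#' @param path file path of a tab-separated table with one header row.
#' @param panel an [analyte_panel()]; default the 39-plex panel.
#' @param column_map optional named character vector renaming file columns
#'   to expected names (e.g. `c(ID = "sample_id")`), for externally
#'   exported layouts.
#' @return A `luminex_plate`.
#' @export
read_plate <- function(path, panel = default_analyte_panel(),
                       column_map = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    idx <- match(names(column_map), names(df))
    if (anyNA(idx)) {
      stop("column_map names not found in file: ",
           paste(names(column_map)[is.na(idx)], collapse = ", "),
           call. = FALSE)
    }
    names(df)[idx] <- unname(column_map)
  }
  if (!"duplicate" %in% names(df)) df$duplicate <- 1L
  if (!"tissue" %in% names(df)) {
    stop("plate is missing required column(s): tissue", call. = FALSE)
  }

  other <- setdiff(names(df), c(META_COLS, CHEX_COLS))
  canonical <- resolve_analytes(other, panel)
  names(df)[match(other, names(df))] <- canonical
  keep <- intersect(c(META_COLS, panel$names, CHEX_COLS), names(df))
  new_luminex_plate(df[keep], panel)
}

#' Write a Luminex plate table
#'
#' @param plate a `luminex_plate`.
#' @param path output path; tab-separated, header row included.
#' @return `path`, invisibly.
#' @export
write_plate <- function(plate, path) {
  stopifnot(inherits(plate, "luminex_plate"))
  utils::write.table(plate, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a screen-results table
#'
#' Writes the per-analyte screen table in the published layout: analyte,
#' ratio to control, exact permutation p, complete-separation flag,
#' Mann-Whitney p, and the FDR decision, sorted by descending ratio
#' within tissue with ties broken by analyte name.
#'
#' @param results data frame produced by [run_screen()] (possibly
#'   row-bound across tissues).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_screen_results <- function(results, path) {
  if (!NROW(results)) stop("results must be non-empty", call. = FALSE)
  ord <- order(results$tissue, -results$ratio, results$analyte)
  out <- results[ord, c("analyte", "tissue", "ratio", "perm_p",
                        "separation", "direction", "mw_p", "bh_p",
                        "bh_significant"), drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read back a screen-results table
#'
#' @param path path written by [write_screen_results()].
#' @return Data frame.
#' @export
read_screen_results <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
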