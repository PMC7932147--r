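#' Construct an analyte panel
#'
#' A panel is the ordered roster of analyte names on a multiplex plate plus
#' an alias map so that exported column headings (e.g. `"GMCSF"` for
#' `"GMCSF.CSF2"`) resolve to canonical names.
#'
#' @param names character vector of unique, non-empty analyte names, in
#'   plate order.
#' @param aliases named character vector mapping display names to canonical
#'   names; every value must be one of `names`.
#' @return An object of class `analyte_panel` with elements `names` and
#'   `aliases`.
#' @export
#' @examples
#' p <- analyte_panel(c("IL6", "VEGF"), c(VEGFA = "VEGF"))
#' resolve_analytes(c("IL6", "VEGFA"), p)
analyte_panel <- function(names, aliases = character()) {
  if (!is.character(names) || length(names) == 0 || anyNA(names) ||
      any(!nzchar(names))) {
    stop_field("names", "must be non-empty character strings")
  }
  if (anyDuplicated(names)) {
    stop_field("names", "analyte names must be unique")
  }
  if (length(aliases)) {
    if (is.null(names(aliases)) || any(!nzchar(names(aliases)))) {
      stop_field("aliases", "must be a named character vector")
    }
    bad <- setdiff(aliases, names)
    if (length(bad)) {
      stop_field("aliases", paste0(
        "aliases must resolve to panel names; unknown target(s): ",
        paste(bad, collapse = ", ")
      ))
    }
    if (anyDuplicated(names(aliases))) {
      stop_field("aliases", "each alias must resolve to exactly one name")
    }
  }
  structure(
    list(names = names, aliases = aliases),
    class = "analyte_panel"
  )
}

#' Default 39-plex mouse immune panel
#'
#' The roster of the 39-analyte mouse cytokine/chemokine/growth-factor bead
#' panel used throughout: 36 analytes follow the published abbreviation
#' list (IL1A through MCP3); the remaining three channels are filled with
#' common members of the commercial 39-plex mouse panel (ENA78, EOTAXIN,
#' IL21) since the full roster is not enumerated in the source tables.
#' Composite display names such as `"GMCSF"` alias their canonical
#' dotted forms.
#'
#' @return An `analyte_panel` of 39 analytes.
#' @export
default_analyte_panel <- function() {
  nm <- c(
    "IL1A", "IL6", "LIF", "RANTES", "MCP1", "IFNA", "GROA", "IL9",
    "MCSF.CSF1", "IL13", "IL31", "IL15.IL15R", "MIP1A", "IL3", "IL4",
    "GMCSF.CSF2", "IFNG", "MIP1B", "GCSF.CSF3", "IL12P70", "MIP2", "IL2",
    "IL27", "IL5", "IL17A", "TNFA", "IL18", "TGFB", "IP10", "VEGF",
    "IL23", "IL22", "IL1B", "IL28", "IL10", "MCP3",
    "ENA78", "EOTAXIN", "IL21"
  )
  stopifnot(length(nm) == 39L)
  analyte_panel(
    names = nm,
    aliases = c(
      GMCSF = "GMCSF.CSF2",
      GCSF = "GCSF.CSF3",
      MCSF = "MCSF.CSF1",
      IL15 = "IL15.IL15R",
      IL12 = "IL12P70"
    )
  )
}

#' Resolve analyte display names to canonical panel names
#'
#' @param x character vector of analyte names or aliases.
#' @param panel an `analyte_panel`.
#' @return Character vector of canonical names, same length as `x`.
#'   Unresolvable entries raise an error naming them.
#' @export
resolve_analytes <- function(x, panel) {
  stopifnot(inherits(panel, "analyte_panel"))
  out <- ifelse(x %in% panel$names, x,
                unname(panel$aliases[match(x, names(panel$aliases))]))
  if (anyNA(out)) {
    stop(sprintf(
      "unknown analyte column(s): %s",
      paste(x[is.na(out)], collapse = ", ")
    ), call. = FALSE)
  }
  out
}
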