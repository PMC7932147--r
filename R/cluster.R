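#' Hierarchical clustering of immune profiles
#'
#' Clusters samples (or analytes) of a normalized plate matrix the way
#' multiplex panels are usually displayed in heatmaps: log-transform,
#' per-analyte z-score, Euclidean distance, average linkage — each
#' configurable, and the full preprocessing descriptor is embedded in the
#' result so a dendrogram can be reproduced exactly. Analytes that are
#' constant under z-scoring are dropped with a warning.
#'
#' @param mat a `luminex_matrix`.
#' @param axis `"samples"` (default) or `"analytes"`.
#' @param log_transform log-transform MFI first (default TRUE).
#' @param scale_analytes z-score each analyte (default TRUE).
#' @param distance distance measure for [stats::dist()] (default
#'   `"euclidean"`).
#' @param linkage agglomeration method for [stats::hclust()] (default
#'   `"average"`).
#' @return A `cluster_result`: list with the `hclust` tree, `order` (leaf
#'   order), `labels`, `axis`, `dropped` analytes, and the `descriptor`.
#' @export
hier_cluster <- function(mat, axis = c("samples", "analytes"),
                         log_transform = TRUE, scale_analytes = TRUE,
                         distance = "euclidean", linkage = "average") {
  stopifnot(inherits(mat, "luminex_matrix"))
  axis <- match.arg(axis)
  panel <- attr(mat, "panel")
  x <- as.matrix(mat[panel$names])
  rownames(x) <- mat$sample_id
  if (log_transform) x <- log(x)

  dropped <- character()
  if (scale_analytes) {
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0)) {
      dropped <- colnames(x)[sds == 0]
      warning("dropping constant analyte(s) under z-scoring: ",
              paste(dropped, collapse = ", "), call. = FALSE)
      x <- x[, sds > 0, drop = FALSE]
    }
    x <- scale(x)
  }
  if (axis == "analytes") x <- t(x)
  if (nrow(x) < 2) {
    stop("need at least 2 items on the clustered axis", call. = FALSE)
  }

  hc <- stats::hclust(stats::dist(x, method = distance), method = linkage)
  structure(
    list(
      hclust = hc,
      order = hc$order,
      labels = hc$labels,
      axis = axis,
      dropped = dropped,
      descriptor = list(log_transform = log_transform,
                        scale_analytes = scale_analytes,
                        distance = distance, linkage = linkage)
    ),
    class = "cluster_result"
  )
}

#' Group-segregation score of a sample dendrogram
#'
#' Cuts the tree into two clusters and scores how cleanly a target group
#' segregates: the best achievable two-cluster classification accuracy,
#' `max over clusters C of (#target in C + #non-target outside C) / n`.
#' 1.0 means the cut isolates the target group perfectly; the degenerate
#' case of a single group scores 1.0 by convention.
#'
#' @param result a `cluster_result` with `axis = "samples"`.
#' @param labels group label per sample, named by sample or in leaf-label
#'   order.
#' @param target the group whose segregation is scored.
#' @return A number in `[0, 1]`.
#' @export
segregation_score <- function(result, labels, target) {
  stopifnot(inherits(result, "cluster_result"))
  if (result$axis != "samples") {
    stop("segregation_score requires a sample-axis clustering",
         call. = FALSE)
  }
  n <- length(result$labels)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  if (!is.null(names(labels))) {
    labels <- labels[result$labels]
  }
  if (length(labels) != n || anyNA(labels)) {
    stop("labels must cover every leaf", call. = FALSE)
  }
  is_target <- labels == target
  if (all(is_target) || !any(is_target)) return(1)

  cl <- stats::cutree(result$hclust, k = 2)
  acc <- vapply(1:2, function(k) {
    (sum(is_target & cl == k) + sum(!is_target & cl != k)) / n
  }, numeric(1))
  max(acc)
}

#' Export a dendrogram in Newick format
#'
#' @param result a `cluster_result`.
#' @param path optional output file; when NULL the Newick string is
#'   returned.
#' @return Newick string (invisibly when written to `path`).
#' @export
dendro_newick <- function(result, path = NULL) {
  stopifnot(inherits(result, "cluster_result"))
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop("Newick export requires the 'ape' package", call. = FALSE)
  }
  phy <- ape::as.phylo(result$hclust)
  if (is.null(path)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = path)
    invisible(ape::write.tree(phy))
  }
}
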