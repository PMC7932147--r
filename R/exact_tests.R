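# Exact small-sample inference for the screen. All p-values are exact
# rationals k/N over the N = choose(n1+n2, n1) distinct group-label
# assignments, with the observed assignment always counted, so p can never
# be 0 and the floor of the test is min_attainable_p().

#' Smallest attainable exact permutation p-value
#'
#' The floor of a two-group exact permutation test: one-sided,
#' `1 / choose(n1+n2, n1)`; two-sided with equal group sizes,
#' `2 / choose(2n, n)` (the fully separated split and its mirror image are
#' equally extreme); two-sided with unequal sizes, `1 / choose(n1+n2, n1)`
#' (the mirror split has a different mean-difference magnitude). For the
#' 5-vs-5 design this is 2/252, rendered 0.008.
#'
#' @param n1,n2 group sizes (>= 1).
#' @param sided `"two"` (default) or `"one"`.
#' @return List with `p`, exact `numerator` and `denominator`, and the
#'   3-decimal `rendered` string.
#' @export
#' @examples
#' min_attainable_p(5, 5)$rendered  # "0.008"
min_attainable_p <- function(n1, n2, sided = c("two", "one")) {
  sided <- match.arg(sided)
  if (n1 < 1 || n2 < 1) {
    stop("group sizes must be positive", call. = FALSE)
  }
  den <- choose(n1 + n2, n1)
  num <- if (sided == "two" && n1 == n2) 2 else 1
  list(p = num / den, numerator = num, denominator = den,
       rendered = format_p(num / den))
}

perm_splits <- function(n1, n2, max_splits) {
  n_splits <- choose(n1 + n2, n2)
  if (n_splits > max_splits) {
    stop(sprintf(
      "enumeration of %.3g splits exceeds the cap of %.3g; Monte-Carlo
 approximation is out of scope for this exact screen",
      n_splits, max_splits), call. = FALSE)
  }
  utils::combn(n1 + n2, n2)
}

#' Exact two-group permutation test by full enumeration
#'
#' Enumerates every assignment of the pooled values to a control group of
#' size `n1` and a treated group of size `n2` and counts assignments whose
#' statistic is as or more extreme than observed. The observed assignment
#' is always counted, so the returned p is an exact rational in (0, 1].
#'
#' Statistics: `"mean_diff"` is `mean(trt) - mean(ctrl)`; `"rank_sum"` is
#' the treated-group sum of mid-ranks of the pooled values. Two-sided
#' extremity is judged on the magnitude of the statistic about its
#' permutation mean (0 for the mean difference); one-sided tests the
#' alternative that treated values exceed control.
#'
#' @param ctrl,trt numeric vectors of finite values.
#' @param statistic `"mean_diff"` (default) or `"rank_sum"`.
#' @param sided `"two"` (default) or `"one"`.
#' @param max_splits cap on the enumeration size (default 1e7); larger
#'   designs are an explicit error.
#' @return List with `p`, `numerator`, `denominator`, `observed`
#'   statistic, `statistic`, `sided`, and `min_p` (the attainable floor).
#' @export
#' @examples
#' exact_perm_test(c(1, 2), c(3, 4))$p  # 1/3
exact_perm_test <- function(ctrl, trt,
                            statistic = c("mean_diff", "rank_sum"),
                            sided = c("two", "one"),
                            max_splits = 1e7) {
  statistic <- match.arg(statistic)
  sided <- match.arg(sided)
  if (!length(ctrl) || !length(trt)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  pooled <- c(ctrl, trt)
  if (any(!is.finite(pooled))) {
    stop("all values must be finite", call. = FALSE)
  }
  n1 <- length(ctrl)
  n2 <- length(trt)
  n <- n1 + n2

  vals <- if (statistic == "rank_sum") rank(pooled) else pooled
  splits <- perm_splits(n1, n2, max_splits)
  n_splits <- ncol(splits)

  trt_sums <- colSums(matrix(vals[splits], nrow = n2))
  total <- sum(vals)
  # both statistics are affine in the treated-group sum
  stat_all <- if (statistic == "mean_diff") {
    trt_sums / n2 - (total - trt_sums) / n1
  } else {
    trt_sums
  }
  center <- if (statistic == "mean_diff") 0 else n2 * total / n
  obs <- if (statistic == "mean_diff") {
    mean(trt) - mean(ctrl)
  } else {
    sum(vals[(n1 + 1):n])
  }

  tol <- 1e-8 * max(1, abs(obs - center))
  k <- if (sided == "two") {
    sum(abs(stat_all - center) >= abs(obs - center) - tol)
  } else {
    sum(stat_all >= obs - tol)
  }
  list(p = k / n_splits, numerator = k, denominator = n_splits,
       observed = obs, statistic = statistic, sided = sided,
       min_p = min_attainable_p(n1, n2, sided)$p)
}

#' Complete separation of two groups
#'
#' TRUE when the groups' value ranges do not overlap: every treated value
#' above every control (`direction = "up"`) or below (`"down"`). Ties
#' across groups break separation. On no-ties data this is exactly the
#' event that an exact permutation test attains its minimal possible
#' p-value.
#'
#' @param ctrl,trt numeric vectors.
#' @return List with logical `separated` and `direction` (`"up"`,
#'   `"down"`, or `NA` when not separated).
#' @export
is_complete_separation <- function(ctrl, trt) {
  if (!length(ctrl) || !length(trt)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (min(trt) > max(ctrl)) {
    list(separated = TRUE, direction = "up")
  } else if (max(trt) < min(ctrl)) {
    list(separated = TRUE, direction = "down")
  } else {
    list(separated = FALSE, direction = NA_character_)
  }
}

#' Exact Mann-Whitney U test
#'
#' Two-sided Mann-Whitney test with an exact null distribution for small
#' samples. Without ties and combined n at most `exact_limit`, the exact
#' p comes from the classical U null distribution. With ties (mid-ranks)
#' and small n, the p is computed by full enumeration of label
#' assignments of the mid-ranks, which is the exact conditional test.
#' Otherwise a normal approximation with tie correction and continuity
#' correction is used. The chosen path is reported in `method`.
#'
#' @param x,y numeric vectors.
#' @param exact_limit largest combined sample size for exact computation
#'   (default 20).
#' @return List with `U` (for `x`), two-sided `p`, and `method`
#'   (`"exact"`, `"exact-ties"`, or `"normal"`).
#' @export
mann_whitney_exact <- function(x, y, exact_limit = 20L) {
  if (!length(x) || !length(y)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0

  if (!ties && n1 + n2 <= exact_limit) {
    p_le <- stats::pwilcox(U, n1, n2)
    p_ge <- 1 - stats::pwilcox(U - 1, n1, n2)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else if (ties && n1 + n2 <= exact_limit) {
    perm <- exact_perm_test(y, x, statistic = "rank_sum", sided = "two")
    p <- perm$p
    method <- "exact-ties"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(pooled)
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 *
      ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal"
  }
  list(U = U, p = p, method = method)
}

#' Benjamini-Hochberg step-up decisions
#'
#' Standard BH false-discovery-rate control over a vector of p-values:
#' monotone adjusted values plus the discovery flags at rate `q`.
#'
#' @param pvals numeric p-values in (0, 1].
#' @param q target false discovery rate in (0, 1); default 0.1.
#' @return List with logical `significant` and numeric `adjusted`.
#' @export
bh_adjust <- function(pvals, q = 0.1) {
  if (!is.numeric(q) || length(q) != 1 || q <= 0 || q >= 1) {
    stop("q must lie in (0, 1)", call. = FALSE)
  }
  if (any(!is.finite(pvals) | pvals <= 0 | pvals > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  adjusted <- stats::p.adjust(pvals, method = "BH")
  list(significant = adjusted <= q, adjusted = adjusted)
}
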