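# Layer derivation, summaries, paired t, ANOVA + Tukey (raw and
# from-summary routes), two-way ANOVA, Pearson correlation.

test_that("INL-to-RPE derivation reproduces the printed table values", {
  expect_equal(derive_inl_to_rpe(229.1, 81.4), 147.7)
  expect_lt(abs(derive_inl_to_rpe(222.8, 79.13) - 143.6), 0.1)
  expect_equal(derive_inl_to_rpe(100, 1e-9), 100, tolerance = 1e-6)
  expect_error(derive_inl_to_rpe(80, 81), "gcc < trt")
  expect_error(derive_inl_to_rpe(80, -1), "gcc")
})

test_that("group_summary computes mean, sample-SD SEM and n", {
  gs <- group_summary(c(5, 5, 5))
  expect_equal(gs[c("mean", "sem", "n")],
               list(mean = 5, sem = 0, n = 3), ignore_attr = TRUE)
  gs2 <- group_summary(c(1, 2, 3, 4))
  expect_equal(gs2$mean, 2.5)
  expect_equal(gs2$sem, 0.6454972, tolerance = 1e-6)  # SD 1.2910 / 2
  expect_equal(gs2$sem, stats::sd(c(1, 2, 3, 4)) / 2)
  expect_equal(gs2$n, 4)
  expect_error(group_summary(numeric(0)), "non-empty")
})

test_that("group deltas reproduce the printed thickness changes", {
  s <- function(m) structure(list(mean = m, sem = 0, n = 8),
                             class = "group_summary")
  trt <- group_delta(s(218.5), s(229.1))
  expect_equal(trt$delta, 10.6)
  expect_equal(round(trt$pct, 1), 4.9)
  gcc <- group_delta(s(77), s(81.4))
  expect_equal(gcc$delta, 4.4)
  expect_equal(round(gcc$pct, 1), 5.7)
  same <- group_delta(s(10), s(10))
  expect_equal(same, list(delta = 0, pct = 0))
  expect_error(group_delta(s(0), s(1)), "zero")
})

test_that("paired t matches a hand-computed example and handles edges", {
  res <- paired_t(c(10, 12, 14), c(12, 13, 17))
  # differences 2, 1, 3: mean 2, sd 1, t = 2 / (1/sqrt(3))
  expect_equal(res$t, 2 * sqrt(3), tolerance = 1e-9)
  expect_equal(res$p, 2 * stats::pt(-2 * sqrt(3), 2), tolerance = 1e-9)
  expect_equal(res$mean_diff, 2)
  expect_identical(res$direction, "increase")

  same <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  deg <- paired_t(c(1, 2, 3), c(3, 4, 5))
  expect_true(deg$degenerate)
  expect_identical(deg$direction, "increase")
  expect_equal(deg$mean_diff, 2)

  # pairing by ID reorders before differencing
  byid <- paired_t(c(10, 12, 14), c(17, 12, 13),
                   id_pre = c("a", "b", "c"), id_post = c("c", "a", "b"))
  expect_equal(byid$mean_diff, 2)
  expect_error(paired_t(1:3, 1:3, id_pre = c("a", "b", "c"),
                        id_post = c("a", "b", "d")),
               "IDs")
})

test_that("one-way ANOVA + Tukey matches the classic PlantGrowth values", {
  groups <- split(PlantGrowth$weight, PlantGrowth$group)
  res <- anova_tukey(groups)
  # widely published reference values for this dataset
  expect_equal(res$F, 4.846, tolerance = 1e-3)
  expect_equal(res$p, 0.0159, tolerance = 1e-2)
  ref <- stats::TukeyHSD(stats::aov(weight ~ group, PlantGrowth))$group
  expect_equal(res$tukey$p, unname(ref[, "p adj"]), tolerance = 1e-9)
})

test_that("ANOVA degenerate and directional cases behave", {
  same <- anova_tukey(list(a = c(2, 2), b = c(2, 2), c = c(2, 2)))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)
  expect_equal(same$tukey$p, rep(1, 3))

  set.seed(13)
  shifted <- anova_tukey(list(
    a = 10 + rnorm(5, sd = 0.01),
    b = 10 + rnorm(5, sd = 0.01),
    c = 50 + rnorm(5, sd = 0.01)
  ))
  p_c <- shifted$tukey$p[grepl("c", shifted$tukey$comparison)]
  expect_true(all(p_c < 0.001))
})

test_that("summary-statistics ANOVA is identical to the raw-data route", {
  set.seed(29)
  for (i in 1:5) {
    groups <- list(a = rnorm(4, 10), b = rnorm(6, 11), c = rnorm(5, 12))
    raw <- anova_tukey(groups)
    summ <- anova_tukey_from_summary(lapply(groups, group_summary))
    expect_equal(summ$F, raw$F, tolerance = 1e-9)
    expect_equal(summ$p, raw$p, tolerance = 1e-9)
    expect_equal(summ$tukey$p, raw$tukey$p, tolerance = 1e-9)
    expect_equal(summ$tukey$diff, raw$tukey$diff, tolerance = 1e-9)
  }
})

test_that("printed TRT summaries give a significant 1h-vs-18h Tukey test", {
  gs <- function(mean, sem, n) structure(list(mean = mean, sem = sem,
                                              n = n),
                                         class = "group_summary")
  res <- anova_tukey_from_summary(list(
    baseline = gs(223.3, 2.6, 10),
    post1h = gs(218.5, 1.1, 8),
    post18h = gs(229.1, 0.7, 10)
  ))
  cmp <- res$tukey[res$tukey$comparison == "post18h-post1h", ]
  expect_lt(cmp$p, 0.05)       # printed value 0.0002
  expect_gt(cmp$diff, 0)       # 18h thicker than 1h

  ident <- anova_tukey_from_summary(list(a = gs(5, 1, 4), b = gs(5, 1, 4)))
  expect_equal(ident$tukey$p, 1)
})

test_that("two-way ANOVA matches the classic ToothGrowth values", {
  tg <- data.frame(value = ToothGrowth$len,
                   group = ToothGrowth$supp,
                   layer = factor(ToothGrowth$dose))
  res <- two_way_anova(tg)
  # widely published reference values (balanced, so type II = type I)
  expect_false(res$degenerate)
  tab <- res$table
  expect_equal(tab$F[tab$term == "group"], 15.572, tolerance = 1e-3)
  expect_equal(tab$F[tab$term == "layer"], 92.000, tolerance = 1e-3)
  expect_equal(tab$F[tab$term == "group:layer"], 4.107, tolerance = 1e-3)
  expect_equal(tab$p[tab$term == "group:layer"], 0.0219, tolerance = 1e-2)
})

test_that("two-way ANOVA degenerate and additive cases behave", {
  zero <- data.frame(value = 0,
                     group = rep(c("a", "b"), each = 6),
                     layer = rep(c("x", "y", "z"), 4))
  expect_true(two_way_anova(zero)$degenerate)

  # exactly additive cell means with symmetric within-cell jitter:
  # interaction sum of squares is exactly zero
  grid <- expand.grid(rep_id = 1:2, group = c("a", "b", "c"),
                      layer = c("x", "y", "z"))
  a_eff <- c(a = 0, b = 2, c = 5)
  l_eff <- c(x = 0, y = 1, z = 3)
  grid$value <- 10 + a_eff[grid$group] + l_eff[grid$layer] +
    ifelse(grid$rep_id == 1, -0.1, 0.1)
  res <- two_way_anova(grid)
  tab <- res$table
  expect_equal(tab$F[tab$term == "group:layer"], 0, tolerance = 1e-9)
  expect_lt(tab$p[tab$term == "group"], 1e-6)

  expect_error(two_way_anova(data.frame(value = 1:3,
                                        group = c("a", "a", "b"),
                                        layer = c("x", "y", "x"))),
               "empty cell")
})

test_that("TUNEL counts reshape and feed the two-way ANOVA", {
  cfg <- sim_config(seed = 17)
  h <- simulate_histology(cfg)
  long <- tunel_long(h)
  expect_equal(nrow(long), 3 * nrow(h))
  expect_setequal(unique(long$layer), c("GCL", "INL", "ONL"))
  res <- two_way_anova(h)
  expect_false(res$degenerate)
  expect_equal(res$table$term, c("group", "layer", "group:layer"))
})

test_that("pearson correlation hits its exact limits", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(pearson_corr(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_corr(x, -x)$r, -1)
  expect_error(pearson_corr(x, rep(3, 5)), "variance")
  expect_error(pearson_corr(1:2, 1:2), ">= 3")

  set.seed(37)
  xx <- rnorm(20)
  yy <- xx + rnorm(20)
  ref <- stats::cor.test(xx, yy)
  res <- pearson_corr(xx, yy)
  expect_equal(res$r, unname(ref$estimate))
  expect_equal(res$p, ref$p.value)
})

test_that("oct_report summarizes both cohorts in table form", {
  oct <- simulate_oct_table(sim_config(seed = 51))
  rpt <- oct_report(oct)
  expect_equal(nrow(rpt$summary), 8)  # 2 groups x 4 layers
  expect_setequal(unique(rpt$summary$group), c("post1h", "post18h"))
  expect_equal(rpt$summary$baseline_n[rpt$summary$group == "post1h"],
               rep(8, 4))
  expect_equal(rpt$summary$post_n[rpt$summary$group == "post18h"],
               rep(10, 4))
  expect_equal(nrow(rpt$delta), 4)
  expect_true(abs(rpt$trt_gcc$r) <= 1)
})
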