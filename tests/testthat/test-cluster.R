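# Hierarchical clustering and the group-segregation score.

test_that("identical samples merge first at height zero", {
  vals <- rbind(c(10, 20), c(10, 20), c(50, 80), c(55, 90))
  m <- make_matrix_fixture(vals, groups = c("control", "control",
                                            "post1h", "post1h"))
  cl <- hier_cluster(m, log_transform = FALSE, scale_analytes = FALSE)
  expect_equal(cl$hclust$height[1], 0)
  expect_setequal(abs(cl$hclust$merge[1, ]), 1:2)
})

test_that("clustering is invariant to sample order", {
  set.seed(19)
  vals <- matrix(rlnorm(8 * 5, meanlog = 5), nrow = 8)
  m <- make_matrix_fixture(vals, groups = rep(c("control", "post1h"),
                                              each = 4))
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  mp <- m[perm, ]
  attr(mp, "panel") <- attr(m, "panel")
  class(mp) <- class(m)

  c1 <- hier_cluster(m)
  c2 <- hier_cluster(mp)
  expect_equal(c1$hclust$height, c2$hclust$height)
  d1 <- as.matrix(stats::cophenetic(c1$hclust))
  d2 <- as.matrix(stats::cophenetic(c2$hclust))
  expect_equal(d2[rownames(d1), colnames(d1)], d1)
})

test_that("toy dendrograms match hand-computed merge heights", {
  # four points in the plane: (1,1), (1,2), (5,1), (6,1)
  # pair distances: d12 = 1, d34 = 1, d13 = 4, d14 = 5,
  #                 d23 = sqrt(17), d24 = sqrt(26)
  vals <- rbind(c(1, 1), c(1, 2), c(5, 1), c(6, 1))
  m <- make_matrix_fixture(vals, groups = c("a", "a", "b", "b"))

  single <- hier_cluster(m, log_transform = FALSE,
                         scale_analytes = FALSE, linkage = "single")
  expect_equal(single$hclust$height, c(1, 1, 4))

  avg <- hier_cluster(m, log_transform = FALSE, scale_analytes = FALSE,
                      linkage = "average")
  expect_equal(avg$hclust$height,
               c(1, 1, (4 + 5 + sqrt(17) + sqrt(26)) / 4))
})

test_that("z-scoring makes clustering invariant to analyte rescaling", {
  set.seed(23)
  vals <- matrix(rlnorm(12 * 4, meanlog = 4), nrow = 12)
  m <- make_matrix_fixture(vals, groups = rep(c("control", "post1h",
                                                "post18h"), each = 4))
  m2 <- m
  m2[["A02"]] <- m2[["A02"]] * 37
  c1 <- hier_cluster(m)
  c2 <- hier_cluster(m2)
  expect_equal(c1$hclust$height, c2$hclust$height)
  expect_equal(c1$hclust$merge, c2$hclust$merge)
})

test_that("constant analytes are dropped with a warning", {
  vals <- cbind(c(1, 2, 3, 4), rep(5, 4))
  m <- make_matrix_fixture(vals, groups = c("control", "control",
                                            "post1h", "post1h"))
  expect_warning(cl <- hier_cluster(m), "A02")
  expect_identical(cl$dropped, "A02")
})

test_that("segregation score is 1 for cleanly separated groups", {
  cfg <- noise_free(sim_config(
    n_analytes = 8,
    affected_analytes = data.frame(
      analyte = 1:6, group = "post1h", fold = 3),
    seed = 41
  ))
  cfg$noise_cv <- 0.02  # small jitter so no analyte is constant
  m <- chex_normalize(average_duplicates(simulate_luminex_plate(cfg)))
  cl <- hier_cluster(m)
  sc <- segregation_score(cl, stats::setNames(m$group, m$sample_id),
                          "post1h")
  expect_equal(sc, 1)
})

test_that("degenerate single-group labelling scores 1 by convention", {
  set.seed(3)
  vals <- matrix(rlnorm(6 * 3, 4), nrow = 6)
  m <- make_matrix_fixture(vals, groups = rep("post1h", 6))
  cl <- hier_cluster(m)
  expect_equal(segregation_score(cl, stats::setNames(m$group, m$sample_id),
                                 "post1h"), 1)
})

test_that("random labels score near the enumerated null expectation", {
  set.seed(47)
  vals <- matrix(rlnorm(15 * 6, meanlog = 5), nrow = 15)
  m <- make_matrix_fixture(vals, groups = rep("x", 15))
  cl <- hier_cluster(m)

  # enumerated null expectation for a fixed 2-cut of sizes (s, n - s)
  # and k random target labels: hypergeometric over the count in the
  # first cluster
  n <- 15
  k <- 5
  s <- sum(stats::cutree(cl$hclust, 2) == 1)
  x <- 0:k
  score_x <- pmax((x + (n - s - (k - x))) / n, ((k - x) + (s - x)) / n)
  expected <- sum(stats::dhyper(x, s, n - s, k) * score_x)

  scores <- vapply(1:1000, function(i) {
    lab <- rep("other", n)
    lab[sample.int(n, k)] <- "target"
    segregation_score(cl, stats::setNames(lab, m$sample_id), "target")
  }, numeric(1))
  expect_true(all(scores >= 0 & scores <= 1))
  expect_lt(mean(scores), 1)
  se <- stats::sd(scores) / sqrt(length(scores))
  expect_lt(abs(mean(scores) - expected), 4 * se)
})

test_that("newick export produces a tree on the sample labels", {
  skip_if_not_installed("ape")
  set.seed(5)
  vals <- matrix(rlnorm(5 * 3, 4), nrow = 5)
  m <- make_matrix_fixture(vals, groups = rep(c("control", "post1h"),
                                              c(3, 2)))
  nwk <- dendro_newick(hier_cluster(m))
  tree <- ape::read.tree(text = nwk)
  expect_setequal(tree$tip.label, m$sample_id)
})
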