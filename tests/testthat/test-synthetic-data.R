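# Generators: determinism, the noise-free limit, and Monte-Carlo
# parameter recovery.

test_that("sim_config validates fields and names the offender", {
  expect_error(sim_config(n_per_group = 1), "n_per_group")
  expect_error(sim_config(noise_cv = -0.1), "noise_cv")
  expect_error(sim_config(mfi_baseline = -5), "mfi_baseline")
  expect_error(
    sim_config(affected_analytes = data.frame(
      analyte = "IL6", group = "post1h", fold = 0)),
    "affected_analytes"
  )
  expect_error(
    sim_config(affected_analytes = data.frame(
      analyte = c("IL6", "IL6"), group = "post1h", fold = 2)),
    "affected_analytes"
  )
  expect_error(
    sim_config(oct = list(effects = list(post1h = c(TRT = -200, GCC = 0,
                                                    ISOS = 0)))),
    "GCC >= mean TRT"
  )
  expect_error(
    sim_config(hist = list(means = list(aqp4 = c(control = -1,
                                                 post1h = 1,
                                                 post18h = 1)))),
    "hist"
  )
})

test_that("luminex generator is deterministic and exact when noise-free", {
  cfg <- noise_free(sim_config(
    affected_analytes = data.frame(analyte = 1, group = "post1h",
                                   fold = 2),
    seed = 3
  ))
  p1 <- simulate_luminex_plate(cfg)
  p2 <- simulate_luminex_plate(cfg)
  expect_identical(p1, p2)

  a1 <- attr(p1, "panel")$names[1]
  ctrl <- p1[[a1]][p1$group == "control"]
  trt <- p1[[a1]][p1$group == "post1h"]
  expect_equal(unique(trt), 2 * unique(ctrl))
  expect_equal(length(unique(ctrl)), 1)

  # structure: n samples per group x 2 duplicates
  expect_equal(nrow(p1), 2 * sum(cfg$n_per_group))
  expect_equal(
    as.vector(table(p1$group)[c("control", "post1h", "post18h")]),
    as.vector(2 * cfg$n_per_group)
  )
})

test_that("configured fold is recovered by ratio_to_control across seeds", {
  ratios <- vapply(1:50, function(s) {
    cfg <- sim_config(
      affected_analytes = data.frame(analyte = "IL6", group = "post1h",
                                     fold = 2),
      noise_cv = 0.1, seed = s
    )
    m <- chex_normalize(average_duplicates(simulate_luminex_plate(cfg)))
    ratio_to_control(m, "post1h")[["IL6"]]
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 2) / 2, 0.05)
})

test_that("OCT generator honors the noise-free limit and layer order", {
  cfg <- noise_free(sim_config(
    oct = list(effects = list(post1h = c(TRT = 0, GCC = 0, ISOS = 0),
                              post18h = c(TRT = 0, GCC = 0, ISOS = 0))),
    seed = 5
  ))
  oct <- simulate_oct_table(cfg)
  for (g in c("post1h", "post18h")) {
    base <- oct[oct$group == g & oct$timepoint == "baseline", ]
    post <- oct[oct$group == g & oct$timepoint == g, ]
    expect_equal(post[c("TRT", "GCC", "ISOS")],
                 base[c("TRT", "GCC", "ISOS")],
                 ignore_attr = TRUE)
  }

  cfg2 <- noise_free(sim_config(
    oct = list(effects = list(post1h = c(TRT = -2.1, GCC = -2.1,
                                         ISOS = 0),
                              post18h = c(TRT = 0, GCC = 0, ISOS = 0))),
    seed = 5
  ))
  rep2 <- oct_report(simulate_oct_table(cfg2))
  gcc_1h <- rep2$summary[rep2$summary$group == "post1h" &
                           rep2$summary$layer == "GCC", ]
  expect_equal(gcc_1h$mean_diff, -2.1)

  # invariants on a noisy table
  octn <- simulate_oct_table(sim_config(seed = 11))
  expect_true(all(octn$GCC > 0 & octn$GCC < octn$TRT))
  expect_equal(octn$INL_to_RPE, octn$TRT - octn$GCC)
})

test_that("paired t detects the configured 1h thinning in most runs", {
  rejections <- vapply(1:60, function(s) {
    oct <- simulate_oct_table(sim_config(
      oct = list(noise_sd = 1, between_sd = c(TRT = 3.5, GCC = 2,
                                              ISOS = 3)),
      seed = 100 + s
    ))
    base <- oct[oct$group == "post1h" & oct$timepoint == "baseline", ]
    post <- oct[oct$group == "post1h" & oct$timepoint == "post1h", ]
    paired_t(base$TRT, post$TRT, base$eye, post$eye)$p < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.5)
})

test_that("TRT-GCC coupling is recovered across seeds", {
  n_seeds <- 300
  rs <- vapply(seq_len(n_seeds), function(s) {
    oct <- simulate_oct_table(sim_config(seed = 2000 + s))
    base <- oct[oct$timepoint == "baseline", ]
    pearson_corr(base$TRT, base$GCC)$r
  }, numeric(1))

  # independent oracle for E[sample r] at n = 18, rho = 0.85 (the sample
  # correlation is biased slightly below rho at small n)
  set.seed(99)
  oracle <- replicate(2000, {
    z1 <- rnorm(18)
    z2 <- rnorm(18)
    cor(z1, 0.85 * z1 + sqrt(1 - 0.85^2) * z2)
  })
  se <- sqrt(stats::var(rs) / n_seeds + stats::var(oracle) / 2000)
  expect_lt(abs(mean(rs) - mean(oracle)), 3 * se)
  expect_lt(abs(mean(rs) - 0.85), 0.03)
})

test_that("histology generator reproduces configured means and counts", {
  cfg <- noise_free(sim_config(seed = 9))
  cfg$hist$tunel_lambda <- lapply(cfg$hist$tunel_lambda,
                                  function(x) { x[] <- 0; x })
  h <- simulate_histology(cfg)
  for (g in c("control", "post1h", "post18h")) {
    gs <- group_summary(h$aqp4[h$group == g])
    expect_equal(gs$mean, cfg$hist$means$aqp4[[g]])
    expect_equal(gs$sem, 0)
  }
  expect_equal(unname(unlist(
    h[c("tunel_GCL", "tunel_INL", "tunel_ONL")])),
    rep(0L, 3 * nrow(h)), ignore_attr = TRUE)
  expect_identical(h, simulate_histology(cfg))

  # Poisson mean 4: empirical mean within 3 SE over 1000 seeds
  cfg2 <- sim_config(seed = 1)
  cfg2$hist$tunel_lambda <- lapply(cfg2$hist$tunel_lambda,
                                   function(x) { x[] <- 4; x })
  counts <- unlist(lapply(1:200, function(s) {
    cfg2$seed <- s
    simulate_histology(cfg2)$tunel_ONL
  }))
  se <- sqrt(4 / length(counts))
  expect_lt(abs(mean(counts) - 4), 3 * se)
})
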