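# Statistics layer: descriptives, t tests (vs stats::t.test and a
# permutation oracle), one-way/Tukey-Kramer (vs TukeyHSD), Type III
# factorial ANOVA, pooled means and sample size (vs power.t.test).

test_that("describe computes mean/SD/quartiles by the stated conventions", {
  d <- describe(c(1, 1, 1))
  expect_equal(d$mean, 1); expect_equal(d$sd, 0)
  d <- describe(c(0, 1, 2, 3, 4))
  expect_equal(d$median, 2); expect_equal(d$q1, 1); expect_equal(d$q3, 3)
  expect_error(describe(numeric(0)), class = "guidedev_config_error")
  # two-pass oracle on a random sample
  set.seed(71)
  x <- rnorm(57, 5, 2)
  d <- describe(x)
  m <- sum(x) / length(x)
  expect_equal(d$mean, m, tolerance = 1e-12)
  expect_equal(d$sd, sqrt(sum((x - m)^2) / (length(x) - 1)), tolerance = 1e-12)
  expect_equal(d$min, min(x)); expect_equal(d$max, max(x))
})

test_that("summarise_deviations groups by a factor and validates names", {
  coh <- generate_cohort(seed = 72)
  s <- summarise_deviations(coh, by = "registration_method")
  expect_equal(nrow(s), 12)  # 6 metrics x 2 groups
  expect_true(all(s$n %in% c(21, 35)))
  expect_error(summarise_deviations(coh, by = "bone_quality"),
               class = "guidedev_config_error")
  # absolute-depth reporting flips signs only
  sa <- summarise_deviations(coh, depth = "absolute")
  ss <- summarise_deviations(coh, depth = "signed")
  expect_gte(sa$mean[sa$metric == "depth_mm"], ss$mean[ss$metric == "depth_mm"])
  expect_gte(min(sa$min[sa$metric == "depth_mm"]), 0)
})

test_that("two_sample_t agrees with stats::t.test in both variants", {
  set.seed(73)
  for (i in 1:10) {
    x <- rnorm(sample(5:30, 1), 0, 1)
    y <- rnorm(sample(5:30, 1), 0.3, 1.7)
    for (variant in c("pooled", "welch")) {
      mine <- two_sample_t(x, y, variant = variant)
      ref <- t.test(x, y, var.equal = (variant == "pooled"))
      expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-9)
      expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    }
  }
})

test_that("summary-statistic mode equals raw mode and handles degeneracy", {
  set.seed(74)
  x <- rnorm(12); y <- rnorm(18, 0.5)
  raw <- two_sample_t(x, y)
  summ <- two_sample_t(list(mean = mean(x), sd = sd(x), n = length(x)),
                       list(mean = mean(y), sd = sd(y), n = length(y)))
  expect_equal(raw$statistic, summ$statistic, tolerance = 1e-12)
  expect_equal(raw$p_value, summ$p_value, tolerance = 1e-12)
  # identical groups: t = 0, p = 1
  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0); expect_equal(same$p_value, 1)
  # zero variance in both groups with equal means: p = 1 by convention
  zv <- two_sample_t(list(mean = 2, sd = 0, n = 5), list(mean = 2, sd = 0, n = 7))
  expect_equal(zv$p_value, 1)
  expect_error(two_sample_t(c(1), c(1, 2)), class = "guidedev_config_error")
})

test_that("the pooled t p-value matches a permutation oracle", {
  set.seed(75)
  x <- rnorm(15, 0, 1)
  y <- rnorm(15, 0.6, 1)
  p_t <- two_sample_t(x, y)$p_value
  p_perm <- permutation_p(x, y, n_perm = 99999)
  expect_lt(abs(p_t - p_perm), 0.02)
})

test_that("published-style group summaries give the expected pooled t p-value", {
  res <- two_sample_t(list(mean = 1.24, sd = 0.68, n = 21),
                      list(mean = 0.92, sd = 0.49, n = 35))
  expect_equal(res$df, 54)
  expect_lt(abs(res$p_value - 0.0464), 0.003)
})

test_that("one-way ANOVA: F = t^2 for two groups, ~0 for identical groups", {
  set.seed(76)
  d <- data.frame(y = rnorm(30), g = rep(c("a", "b"), each = 15))
  tab <- one_way_anova(d, "y", "g")
  tt <- two_sample_t(d$y[d$g == "a"], d$y[d$g == "b"])
  expect_equal(tab$statistic[1], tt$statistic^2, tolerance = 1e-9)
  expect_equal(tab$p_value[1], tt$p_value, tolerance = 1e-9)

  d3 <- data.frame(y = rep(c(1, 2, 3), 3), g = rep(c("a", "b", "c"), each = 3))
  tab3 <- one_way_anova(d3, "y", "g")
  expect_equal(tab3$statistic[1], 0, tolerance = 1e-12)
  tk <- tukey_kramer(d3, "y", "g")
  expect_false(any(tk$significant))

  expect_error(one_way_anova(data.frame(y = 1:3, g = c("a", "a", "b")),
                             "y", "g"), class = "guidedev_config_error")
})

test_that("tukey_kramer matches stats::TukeyHSD adjusted p-values", {
  set.seed(77)
  for (i in 1:5) {
    d <- data.frame(y = rnorm(40, rep(c(0, 0.5, 1), c(15, 17, 8)), 1),
                    g = rep(c("a", "b", "c"), c(15, 17, 8)))
    mine <- tukey_kramer(d, "y", "g")
    ref <- TukeyHSD(aov(y ~ g, data = d))$g
    # align pairs: TukeyHSD labels are "b-a", "c-a", "c-b"
    ref_p <- ref[paste0(mine$group2, "-", mine$group1), "p adj"]
    expect_equal(mine$adj_p, unname(ref_p), tolerance = 1e-6)
  }
})

test_that("Tukey-Kramer is never more conservative than Bonferroni pairwise t", {
  set.seed(78)
  for (i in 1:10) {
    k <- sample(3:5, 1)
    n <- 10
    d <- data.frame(y = rnorm(k * n, rep(runif(k, 0, 1), each = n)),
                    g = rep(letters[1:k], each = n))
    tk <- tukey_kramer(d, "y", "g")
    m <- k * (k - 1) / 2
    gs <- split(d$y, d$g)
    df_err <- k * n - k
    mse <- sum(vapply(gs, function(v) sum((v - mean(v))^2), numeric(1))) / df_err
    bonf <- vapply(seq_len(nrow(tk)), function(j) {
      t_stat <- abs(mean(gs[[tk$group1[j]]]) - mean(gs[[tk$group2[j]]])) /
        sqrt(mse * 2 / n)
      min(1, m * 2 * pt(-t_stat, df_err))
    }, numeric(1))
    expect_true(all(tk$adj_p <= bonf + 1e-12))
  }
})

test_that("Tukey flags single out the worst group in three-group simulations", {
  # groups shaped like mucosa/bilateral/distal-extension lateral platform
  # summaries: the distal-extension contrasts should be flagged most often
  counts <- withr::with_seed(79, {
    flags <- replicate(200, {
      d <- data.frame(
        y = c(rnorm(28, 0.62, 0.33), rnorm(20, 0.65, 0.36), rnorm(8, 1.03, 0.61)),
        g = rep(c("mucosa", "bilateral", "distal"), c(28, 20, 8)))
      tk <- tukey_kramer(d, "y", "g")
      key <- paste(pmin(tk$group1, tk$group2), pmax(tk$group1, tk$group2))
      stats::setNames(tk$significant, key)
    })
    rowSums(flags)
  })
  expect_gt(counts[["distal mucosa"]], counts[["bilateral mucosa"]])
  expect_gt(counts[["bilateral distal"]], counts[["bilateral mucosa"]])
})

test_that("Type III equals sequential SS on balanced designs and reduces to one-way", {
  set.seed(80)
  d <- expand.grid(a = c("a1", "a2"), b = c("b1", "b2"), c = c("c1", "c2"),
                   rep = 1:5)
  d$y <- rnorm(nrow(d), ifelse(d$a == "a1", 0, 0.8))
  fit <- factorial_anova(d, "y", c("a", "b", "c"))
  t3 <- tidy(fit)
  seq_tab <- anova(lm(y ~ a * b * c, data = d))  # sequential SS
  for (term in c("a", "b", "c", "a:b", "a:c", "b:c", "a:b:c")) {
    expect_equal(t3$sumsq[t3$term == term],
                 seq_tab[term, "Sum Sq"], tolerance = 1e-9)
  }
  # single factor: identical to one-way ANOVA
  f1 <- tidy(factorial_anova(d, "y", "a"))
  ow <- one_way_anova(d, "y", "a")
  expect_equal(f1$statistic[1], ow$statistic[1], tolerance = 1e-9)
  expect_equal(f1$p_value[1], ow$p_value[1], tolerance = 1e-9)
  # glance reports fit-level statistics
  gl <- glance(fit)
  expect_equal(gl$nobs, nrow(d))
  expect_equal(gl$df.residual, nrow(d) - 8)
})

test_that("factorial_anova drops inestimable terms and validates factors", {
  set.seed(81)
  d <- expand.grid(a = c("a1", "a2"), b = c("b1", "b2"), rep = 1:6)
  d <- d[!(d$a == "a2" & d$b == "b2"), ]  # empty cell
  d$y <- rnorm(nrow(d))
  expect_warning(fit <- factorial_anova(d, "y", c("a", "b")), "inestimable")
  expect_false("a:b" %in% tidy(fit)$term)
  expect_true(all(c("a", "b") %in% tidy(fit)$term))

  d$single <- "only"
  expect_error(factorial_anova(d, "y", c("a", "single")),
               class = "guidedev_config_error")
  expect_error(factorial_anova(d, "y", c("a", "nope")),
               class = "guidedev_config_error")
})

test_that("pooled_mean reproduces marginal means and validates input", {
  expect_equal(round(pooled_mean(c(0.97, 1.84), c(56, 18)), 2), 1.18)
  expect_equal(round(pooled_mean(c(1.24, 0.92), c(21, 35)), 2), 1.04)
  expect_equal(pooled_mean(4.2, 7), 4.2)
  expect_error(pooled_mean(numeric(0), numeric(0)),
               class = "guidedev_config_error")
  expect_error(pooled_mean(c(1, 2), c(1, 0)), class = "guidedev_config_error")
})

test_that("sample size search matches the analytic power oracle", {
  # power.t.test as independent oracle (same noncentral-t formulation)
  for (d in c(0.5, 0.8, 1.0)) {
    oracle <- ceiling(power.t.test(delta = d, sd = 1, power = 0.8,
                                   sig.level = 0.05)$n)
    expect_equal(sample_size_two_group_t(d, 0.8), oracle)
  }
  expect_equal(sample_size_two_group_t(0.5, 0.8), 64)
  # vanishing power target: the minimum n = 2 suffices
  expect_equal(sample_size_two_group_t(1.0, 1e-6), 2)
  expect_error(sample_size_two_group_t(-1, 0.8),
               class = "guidedev_config_error")
  expect_error(sample_size_two_group_t(0.5, 1.2),
               class = "guidedev_config_error")
})

test_that("simulated two-group rejection matches analytic noncentral-t power", {
  # the observed registration-method contrast scale: 0.32 mm difference,
  # SD 0.6, n = 21/35
  delta <- 1.24 - 0.92
  an_power <- guidedev:::t_test_power(delta, 0.6, 21, 35)
  rej <- withr::with_seed(82, mean(replicate(400, {
    x <- rnorm(21, 1.24, 0.6); y <- rnorm(35, 0.92, 0.6)
    two_sample_t(x, y)$p_value < 0.05
  })))
  expect_lt(abs(rej - an_power), 3 * sqrt(an_power * (1 - an_power) / 400) + 0.01)
})

test_that("null p-values are uniform for the t test (KS)", {
  ps <- withr::with_seed(83, replicate(400, {
    two_sample_t(rnorm(21), rnorm(35))$p_value
  }))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})
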