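# Selection-coefficient estimation from competition counts, the two-sided
# variance F test, and group ANOVA with Tukey post hoc comparisons.

test_that("log-ratio slope is exact on noiseless competition data", {
  flat <- data.frame(time_h = c(0, 24, 48, 72), mutant = 300, reference = 300)
  expect_equal(estimate_selection_coefficient(flat)$s_per_hour, 0)
  tt <- c(0, 24, 48, 72)
  for (s in c(0.05, 0.068, -0.03)) {
    d <- data.frame(time_h = tt, mutant = 100 * exp(s * tt), reference = 100)
    fit <- estimate_selection_coefficient(d)
    expect_equal(fit$s_per_hour, s, tolerance = 1e-12)
    expect_equal(fit$slope_se, 0, tolerance = 1e-10)
  }
})

test_that("zero counts are dropped and too-short series are an error", {
  d <- data.frame(time_h = c(0, 24, 48, 72),
                  mutant = c(300, 0, 420, 480),
                  reference = c(300, 250, 180, 120))
  expect_warning(fit <- estimate_selection_coefficient(d), "zero count")
  expect_equal(fit$n_points, 3)
  d2 <- data.frame(time_h = c(0, 24, 48), mutant = c(300, 0, 0),
                   reference = c(300, 1, 1))
  expect_warning(expect_error(estimate_selection_coefficient(d2),
                              "at least 3"), "zero count")
  # day-indexed input converts at 24 h per day
  d3 <- data.frame(day = 0:3, mutant = 100 * exp(0.05 * 24 * (0:3)),
                   reference = 100)
  expect_equal(estimate_selection_coefficient(d3)$s_per_hour, 0.05,
               tolerance = 1e-12)
})

test_that("one simulated cohort recovers the preset advantage roughly", {
  comp <- simulate_competition("wt-competition", n_hosts = 10, seed = 1)
  s <- suppressWarnings(competition_summary(comp))
  expect_equal(nrow(s), 10)
  expect_lt(abs(mean(s$s_per_hour) - 0.068), 0.01)
  # per-host estimates track the realized host-level draws
  expect_lt(max(abs(s$s_per_hour - attr(comp, "s_true"))), 0.02)
})

test_that("variance F test matches the distribution-function oracle", {
  expect_equal(variance_ratio_test(c(1, 2, 3), c(4, 5, 6))$value, 1)
  expect_equal(variance_ratio_test(c(1, 2, 3), c(4, 5, 6))$p_value, 1)
  # F(2,2) CDF is x/(1+x): lower tail at 0.25 is 0.2, doubled
  r <- variance_ratio_test(c(1, 2, 3), c(2, 4, 6))
  expect_equal(r$value, 0.25)
  expect_equal(r$p_value, 0.4, tolerance = 1e-12)
  r2 <- variance_ratio_test(c(2, 4, 6), c(1, 2, 3))
  expect_equal(r2$value, 4)
  expect_equal(r2$p_value, 0.4, tolerance = 1e-12)
  expect_error(variance_ratio_test(c(1, 2), c(3, 3)), "zero variance")
  # random datasets against var.test
  set.seed(11)
  for (i in 1:20) {
    a <- rnorm(sample(3:9, 1)); b <- rnorm(sample(3:9, 1), sd = runif(1, 0.5, 2))
    mine <- variance_ratio_test(a, b)
    ref <- stats::var.test(a, b)
    expect_equal(mine$value, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("one-way ANOVA matches hand-computed sums of squares, with Tukey", {
  v <- c(1, 2, 3, 2, 3, 4); g <- rep(c("a", "b"), each = 3)
  res <- group_anova(v, g)
  orc <- anova_oracle(v, g)
  expect_equal(orc$ssb, 1.5)
  expect_equal(orc$ssw, 4)
  row <- res$table[res$table$term == "group", ]
  expect_equal(row$F, 1.5, tolerance = 1e-12)
  expect_equal(row$df, 1)
  expect_equal(row$p_value, orc$p, tolerance = 1e-10)
  # Tukey adjusted p against the studentized-range distribution directly
  se_pair <- sqrt(orc$ssw / orc$df[2] * (1 / 3 + 1 / 3))
  q_obs <- abs(diff(tapply(v, g, mean))) / (se_pair / sqrt(2))
  expect_equal(res$tukey$p_adj,
               unname(stats::ptukey(q_obs, 2, orc$df[2], lower.tail = FALSE)),
               tolerance = 1e-10)
})

test_that("degenerate and incomplete ANOVA layouts are rejected", {
  expect_error(group_anova(c(1, 1, 2, 2, 3, 3),
                           rep(c("a", "b", "c"), each = 2)),
               "zero within-group variance")
  expect_error(group_anova(c(1, 2, 3), c("a", "a", "b")), "n >= 2")
  # two-way requires a complete factorial
  v <- 1:8 + 0.1 * rnorm(8)
  g1 <- rep(c("WT", "KO"), each = 4)
  g2 <- c("conv", "conv", "germfree", "germfree", "conv", "conv", "conv", "conv")
  expect_error(group_anova(v, g1, g2), "empty cell")
})

test_that("additive two-way cell means give a null interaction", {
  g1 <- rep(c("a", "b", "c"), each = 4)
  g2 <- rep(rep(c("x", "y"), each = 2), times = 3)
  mu <- c(a = 0, b = 1, c = 2)[g1] + c(x = 0, y = 0.5)[g2]
  set.seed(5)
  v <- mu + rep(c(-0.01, 0.01), 6)  # symmetric perturbation, no interaction
  res <- group_anova(v, g1, g2)
  int_row <- res$table[res$table$term == "group:group2", ]
  expect_lt(int_row$F, 1e-20)
  # and the two-way fit flags main effects strongly
  main <- res$table[res$table$term == "group", ]
  expect_lt(main$p_value, 1e-6)
})

test_that("host-level fitness heterogeneity is detectable as a variance ratio", {
  # cohorts with high vs low across-host sd: the F statistic ordering must
  # reflect the generating variance ratio on average
  f_high <- f_low <- numeric(8)
  for (r in 1:8) {
    hi <- simulate_competition("rag2-competition", n_hosts = 8,
                               seed = derive_seed(300, paste0("hi", r)))
    lo <- simulate_competition(NULL, n_hosts = 8, s_mean_per_hour = 0.03,
                               s_sd_per_hour = 0.004, gen_time_min = 66,
                               host = "RAG2KO",
                               seed = derive_seed(300, paste0("lo", r)))
    s_hi <- suppressWarnings(competition_summary(hi))$s_per_hour
    s_lo <- suppressWarnings(competition_summary(lo))$s_per_hour
    f_high[r] <- stats::var(s_hi)
    f_low[r] <- stats::var(s_lo)
  }
  expect_gt(mean(f_high), mean(f_low))
  expect_gt(mean(f_high / f_low), (0.016 / 0.004)^2 / 4)
})
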