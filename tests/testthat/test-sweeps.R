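# Binomial sweep fit with a shared initial frequency and cluster-robust
# errors, plus the per-day phenotype variance.

make_sweep_data <- function(b0, b1, b2, days = 0:6, total = 1e6,
                            mice_per_host = 2) {
  grid <- expand.grid(m = seq_len(mice_per_host), day = days,
                      host = c("RAG2KO", "WT"), stringsAsFactors = FALSE)
  p <- plogis(b0 + (b1 + b2 * (grid$host == "WT")) * grid$day)
  data.frame(mouse_id = paste0(grid$host, grid$m), host = grid$host,
             day = grid$day, gat_neg = p * total, total = total,
             stringsAsFactors = FALSE)
}

test_that("the sweep fit recovers model-generated coefficients exactly", {
  b0 <- qlogis(0.001); b1 <- 0.5; b2 <- 0.4
  d <- make_sweep_data(b0, b1, b2)
  fit <- fit_sweep(d)
  cf <- fit$coefficients
  expect_equal(unname(cf["(Intercept)"]), b0, tolerance = 1e-6)
  expect_equal(unname(cf["day"]), b1, tolerance = 1e-6)
  expect_equal(unname(cf["day:hostWT"]), b2, tolerance = 1e-6)
  expect_gt(fit$z, 0)  # WT sweeps faster under the default coding
})

test_that("identical genotype trajectories give a null interaction", {
  d <- make_sweep_data(qlogis(0.01), 0.6, 0)
  # symmetric binomial jitter so the fit is not degenerate
  set.seed(2)
  d$gat_neg <- rbinom(nrow(d), 1000, d$gat_neg / d$total)
  d$total <- 1000
  fit <- fit_sweep(d)
  expect_lt(abs(fit$z), 2.5)
  expect_lt(abs(fit$coefficients["day:hostWT"]), 0.05)
})

test_that("constrained and free intercepts agree on constrained-generated data", {
  d <- make_sweep_data(qlogis(0.005), 0.5, 0.3)
  set.seed(3)
  d$gat_neg <- rbinom(nrow(d), 5000, d$gat_neg / d$total)
  d$total <- 5000
  shared <- fit_sweep(d)
  free <- glm(cbind(gat_neg, total - gat_neg) ~ host + day + day:host,
              family = binomial(), data = d)
  ints <- coef(free)[c("(Intercept)", "hostWT")]
  # the free second intercept is statistically indistinguishable from 0
  expect_lt(abs(ints["hostWT"]) / sqrt(vcov(free)["hostWT", "hostWT"]), 3)
  expect_equal(unname(coef(free)["(Intercept)"]),
               unname(shared$coefficients["(Intercept)"]), tolerance = 0.2)
})

test_that("cluster-robust errors dominate naive errors under overdispersion", {
  # mouse-level random slopes create within-cluster correlation
  set.seed(14)
  rows <- list()
  for (host in c("RAG2KO", "WT")) for (m in 1:6) {
    slope <- 0.5 + 0.25 * (host == "WT") + rnorm(1, 0, 0.15)
    p <- plogis(qlogis(0.01) + slope * (0:6))
    rows[[length(rows) + 1]] <- data.frame(
      mouse_id = paste0(host, m), host = host, day = 0:6,
      gat_neg = rbinom(7, 400, p), total = 400)
  }
  d <- do.call(rbind, rows)
  fit <- fit_sweep(d)
  idx <- grep("^day", names(fit$coefficients))
  expect_true(all(fit$se_robust[idx] >= fit$se_naive[idx]))
})

test_that("simulated cohorts sweep faster in the immune-competent host", {
  for (r in 1:3) {
    sims <- lapply(c("WT", "RAG2KO"), function(h) {
      cfg <- sim_config(
        n_hosts = 5, host_genotype = h, pop_size = 1e8,
        gen_time_min = if (h == "WT") 76 else 66, days = 10,
        seed = derive_seed(600 + r, h),
        beneficial_loci = list(beneficial_locus(
          "gat", mu_b = 1e-7,
          s_mean_per_hour = if (h == "WT") 0.068 else 0.03,
          s_sd_per_hour = if (h == "WT") 0.008 else 0.016)))
      sim_phenotype_counts(run_simulation(cfg))
    })
    ph <- do.call(rbind, sims)
    fit <- fit_sweep(ph[ph$day >= 1, ])
    expect_gt(fit$z, 0)
  }
})

test_that("input contract violations are caught", {
  d <- make_sweep_data(qlogis(0.01), 0.5, 0.2)
  bad <- d; bad$gat_neg[1] <- bad$total[1] + 1
  expect_error(fit_sweep(bad), "gat_neg")
  single_day <- d[d$day == 0, ]
  expect_error(fit_sweep(single_day), "2 time points")
})

test_that("phenotype variance per day follows the sample variance", {
  d <- data.frame(mouse_id = rep(1:3, 2), day = rep(1:2, each = 3),
                  gat_neg = c(20, 40, 60, 50, 50, 50), total = 100)
  pv <- phenotype_variance(d)
  expect_equal(pv$variance[pv$day == 1], var(c(0.2, 0.4, 0.6)))
  expect_equal(pv$variance[pv$day == 1], 0.04)
  expect_equal(pv$variance[pv$day == 2], 0)
  # single-mouse days are NA, not an error
  d2 <- rbind(d, data.frame(mouse_id = 1, day = 3, gat_neg = 10, total = 100))
  expect_true(is.na(phenotype_variance(d2)$variance[3]))
})

test_that("the phenotype arises and homogenizes faster in WT cohorts", {
  sims <- lapply(c("WT", "RAG2KO"), function(h) {
    cfg <- sim_config(
      n_hosts = 6, host_genotype = h, pop_size = 1e8,
      gen_time_min = if (h == "WT") 76 else 66, days = 16,
      seed = derive_seed(700, h),
      beneficial_loci = list(beneficial_locus(
        "gat", mu_b = 1e-7,
        s_mean_per_hour = if (h == "WT") 0.068 else 0.03,
        s_sd_per_hour = if (h == "WT") 0.008 else 0.016)))
    sim_phenotype_counts(run_simulation(cfg))
  })
  # day at which the cohort-mean phenotype frequency first crosses 1/2
  crossing <- vapply(sims, function(ph) {
    m <- tapply(ph$gat_neg / ph$total, ph$day, mean)
    d <- as.numeric(names(m))[m > 0.5]
    if (length(d)) min(d) else Inf
  }, numeric(1))
  expect_lt(crossing[1], crossing[2])
  # and the across-mouse variance has fallen from its peak in WT by the end,
  # while the slower host is still mid-sweep
  pv <- lapply(sims, phenotype_variance)
  late_var <- vapply(pv, function(v) v$variance[v$day == 16], numeric(1))
  peak_var <- vapply(pv, function(v) max(v$variance, na.rm = TRUE), numeric(1))
  expect_lt(late_var[1], peak_var[1] / 2)
})
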