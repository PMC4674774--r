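# Clone typing, clonal-interference logic, variant filtering/parallelism,
# prevalence arithmetic, and the exact host-specificity test.

test_that("haplotype calls are canonical and flag untyped loci", {
  anc <- call_haplotype(c(gat = "absent", focA = "absent",
                          dcuB = "absent", srlR = "absent"))
  expect_equal(anc$label, "ancestral")
  dbl <- call_haplotype(c(gat = "present", focA = "present",
                          dcuB = "absent", srlR = "absent"))
  expect_equal(dbl$label, "gat+focA")
  tri <- call_haplotype(c(srlR = "present", gat = "present",
                          focA = "present", dcuB = "absent"))
  expect_equal(tri$label, "gat+focA+srlR")  # panel order, not input order
  u <- call_haplotype(c(gat = "present", focA = "untyped",
                        dcuB = "absent", srlR = "absent"))
  expect_equal(u$untyped, "focA")
  expect_error(call_haplotype(c(gat = "untyped", focA = "untyped")),
               "all loci untyped")
  expect_error(call_haplotype(c(gat = "maybe")), "unknown typing state")
})

test_that("clonal interference requires non-nested competing haplotypes", {
  expect_false(detect_clonal_interference(c(gat = 1.0))$interference)
  r <- detect_clonal_interference(c("gat+focA" = 0.5, "gat+srlR" = 0.3,
                                    gat = 0.2))
  expect_true(r$interference)
  expect_equal(nrow(r$pairs), 1)  # only the focA-set vs srlR-set pair competes
  # nested pair: the double mutant descends from the single mutant
  expect_false(detect_clonal_interference(c(gat = 0.6,
                                            "gat+focA" = 0.4))$interference)
  # the ancestral class is nested inside everything
  expect_false(detect_clonal_interference(c(ancestral = 0.5,
                                            gat = 0.5))$interference)
  expect_error(detect_clonal_interference(c(gat = 0.5, focA = 0.3)),
               "sum to 1")
})

test_that("interference detection is label-order invariant and threshold-monotone", {
  f <- c("gat+focA" = 0.45, "gat+srlR" = 0.12, gat = 0.35, ancestral = 0.08)
  perms <- list(f, f[c(3, 1, 4, 2)], rev(f))
  for (ff in perms)
    expect_true(detect_clonal_interference(ff)$interference)
  # monotone: true at theta implies true at any smaller theta
  for (theta in c(0.4, 0.2, 0.12, 0.05, 0.01)) {
    if (detect_clonal_interference(f, threshold = 0.2)$interference &&
        theta <= 0.2)
      expect_true(detect_clonal_interference(f, threshold = theta)$interference)
  }
  # at a threshold above the second competitor it switches off
  expect_false(detect_clonal_interference(f, threshold = 0.4)$interference)
})

test_that("frequency filtering keeps the inclusive 5% boundary", {
  v <- data.frame(population = "p1", target = c("a", "b", "c"),
                  frequency = c(0.04, 0.05, 0.5))
  kept <- filter_variants(v)
  expect_equal(kept$target, c("b", "c"))
  expect_equal(nrow(filter_variants(v[0, , drop = FALSE])), 0)
  expect_error(filter_variants(v, min_freq = 0), "min_freq")
})

test_that("parallel targets need two populations and a 10% peak", {
  v <- data.frame(population = c("p1", "p2", "p3", "p3", "p4", "p5", "p6"),
                  target = c("gat", "gat", "solo", "low", "low", "low", "gat"),
                  frequency = c(0.20, 0.08, 0.50, 0.06, 0.06, 0.06, 0.09))
  par <- parallel_targets(v)
  expect_equal(par$target, "gat")        # 3 populations, peak 0.20
  expect_equal(par$n_populations, 3)
  # "solo" reaches 50% but in one population only; "low" never reaches 10%
  expect_false("solo" %in% par$target)
  expect_false("low" %in% par$target)
})

test_that("prevalence arithmetic reproduces the degenerate-rule report values", {
  p <- target_prevalence(9, 15)
  expect_equal(p$percent_rounded, 60)
  expect_equal(p$sem_rounded, 13)
  p2 <- target_prevalence(4, 14)
  expect_equal(p2$percent_rounded, 29)
  expect_equal(p2$sem_rounded, 12)
  p3 <- target_prevalence(14, 14)
  expect_equal(p3$percent_rounded, 100)
  expect_equal(p3$sem_rounded, 7)     # degenerate rule 1/14
  expect_equal(target_prevalence(0, 15)$percent_rounded, 0)
  expect_equal(target_prevalence(0, 15)$sem_rounded, 7)
  expect_error(target_prevalence(5, 0), "n")
  expect_error(target_prevalence(8, 7), "k")
})

test_that("host specificity equals placement enumeration", {
  expect_equal(host_specificity_test(0, 14, 0, 15)$p_value, 1)
  r <- host_specificity_test(7, 14, 0, 15)
  expect_equal(r$p_value, choose(14, 7) / choose(29, 7), tolerance = 1e-12)
  expect_equal(round(r$p_value, 4), 0.0022)
  # no concentration: one hit in each group is unremarkable
  # (P(X1 >= 1 | K = 2) = 1 - C(15,2)/C(29,2))
  expect_equal(host_specificity_test(1, 14, 1, 15)$p_value,
               1 - choose(15, 2) / choose(29, 2), tolerance = 1e-12)
  expect_gt(host_specificity_test(1, 14, 1, 15)$p_value, 0.5)
  # brute-force placement oracle on random small instances
  set.seed(6)
  for (i in 1:12) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    k1 <- sample(0:n1, 1); k2 <- sample(0:n2, 1)
    mine <- host_specificity_test(k1, n1, k2, n2)
    orc <- hyper_oracle(k1, n1, k2, n2)
    expect_equal(mine$p_value, orc$one_sided, tolerance = 1e-10)
    expect_equal(mine$p_two_sided, orc$two_sided, tolerance = 1e-10)
  }
})

test_that("typing tables collapse to per-population haplotype frequencies", {
  typ <- data.frame(
    mouse_id = "m1",
    clone = rep(1:4, each = 2),
    locus = rep(c("gat", "focA"), 4),
    state = c("present", "absent",   # gat
              "present", "present",  # gat+focA
              "present", "present",  # gat+focA
              "absent", "absent"))   # ancestral
  hf <- haplotype_frequencies(typ)
  expect_equal(sum(hf$frequency), 1)
  expect_equal(hf$frequency[hf$haplotype == "gat+focA"], 0.5)
  expect_equal(hf$frequency[hf$haplotype == "ancestral"], 0.25)
})

test_that("interference is more frequent with two adaptive targets than one", {
  run_cohort <- function(loci, seed) {
    cfg <- sim_config(n_hosts = 10, pop_size = 1e7, days = 8,
                      gen_time_min = 72, seed = seed,
                      beneficial_loci = loci)
    sim <- run_simulation(cfg)
    vapply(unique(sim$trajectories$mouse_id), function(m)
      detect_clonal_interference(class_freq_vector(sim, m))$interference,
      logical(1))
  }
  two <- run_cohort(list(beneficial_locus("gat", 2e-6, 0.06),
                         beneficial_locus("srlR", 2e-6, 0.06)), seed = 31)
  one <- run_cohort(list(beneficial_locus("gat", 2e-6, 0.06)), seed = 32)
  expect_gt(mean(two), mean(one))
  # with a single target every pair of classes is nested, so never flagged
  expect_equal(mean(one), 0)
})
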