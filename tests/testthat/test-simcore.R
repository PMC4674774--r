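# Wright-Fisher simulator core: rate conversions, equilibrium arithmetic,
# conservation/logistic invariants, drift neutrality, and reproducibility.

test_that("generation and equilibrium arithmetic follow their closed forms", {
  expect_equal(gens_per_day(72), 20)
  expect_equal(gens_per_day(76), 1440 / 76)
  expect_equal(gens_per_day(66), 1440 / 66)
  expect_error(gens_per_day(0), "gen_time_min")
  expect_error(gens_per_day(-5), "gen_time_min")

  expect_equal(msb_equilibrium(0, 0.1), 0)
  expect_equal(msb_equilibrium(1e-8, 0.05), 2e-7)
  expect_equal(log10(msb_equilibrium(2.2387e-7, 0.1)), -5.65, tolerance = 1e-4)
  expect_error(msb_equilibrium(1e-8, 0), "s_d")
  expect_error(msb_equilibrium(1e-8, -1), "s_d")
})

test_that("locus and config validators reject impossible parameters", {
  expect_error(beneficial_locus("gat", -1, 0.05), "mu_b")
  expect_error(beneficial_locus("gat", 1e-8, 0.05, -0.1), "s_sd")
  expect_error(resistance_locus("FZD", 1e-7, 0), "s_d")
  expect_error(resistance_locus("FZD", 1e-7, 0.1, 1.5), "is_fraction")
  expect_error(sim_config(initial_marker_ratio = 1.2), "initial_marker_ratio")
  expect_error(sim_config(mode = "magic"))
})

test_that("deterministic neutral dynamics conserve marker frequency exactly", {
  cfg <- sim_config(n_hosts = 1, pop_size = 1e6, days = 5, gen_time_min = 72,
                    mode = "deterministic", initial_marker_ratio = 0.5)
  out <- run_simulation(cfg)
  tr <- out$trajectories
  yfp <- tapply(tr$freq[tr$marker == "YFP"], tr$gen[tr$marker == "YFP"], sum)
  expect_true(all(yfp == 0.5))
  # conservation holds for any starting vector, not just 1:1
  cfg2 <- sim_config(n_hosts = 1, pop_size = 1e6, days = 5, gen_time_min = 72,
                     mode = "deterministic", initial_marker_ratio = 0.173)
  tr2 <- run_simulation(cfg2)$trajectories
  yfp2 <- tapply(tr2$freq[tr2$marker == "YFP"], tr2$gen[tr2$marker == "YFP"], sum)
  expect_true(all(abs(yfp2 - 0.173) < 1e-15))
})

test_that("a deterministic single sweep follows the logistic closed form", {
  p0 <- 0.01
  cfg <- sim_config(
    n_hosts = 1, pop_size = 1e8, days = 4, gen_time_min = 72,
    mode = "deterministic", samples_per_day = 4,
    beneficial_loci = list(beneficial_locus("gat", 0, 0.05)),
    initial_classes = data.frame(marker = c("YFP", "CFP"),
                                 ben = c("gat", ""), res = "",
                                 freq = c(p0, 1 - p0)))
  out <- run_simulation(cfg)
  sigma <- out$s_draws[1, "gat"] * 72 / 60  # per-generation effect
  tr <- out$trajectories
  gens <- unique(tr$gen)
  p <- vapply(gens, function(g)
    sum(tr$freq[tr$gen == g & tr$ben == "gat"]), numeric(1))
  expected <- p0 * exp(sigma * gens) / (1 - p0 + p0 * exp(sigma * gens))
  expect_true(max(abs(p - expected) / expected) <= 1e-12)
})

test_that("stochastic neutral drift keeps the mean marker frequency at 1/2", {
  cfg <- sim_config(n_hosts = 200, pop_size = 1e4, days = 2,
                    gen_time_min = 72, mode = "stochastic", seed = 99)
  out <- run_simulation(cfg)
  tr <- out$trajectories
  last <- tr[tr$gen == max(tr$gen), ]
  p_final <- tapply(last$freq[last$marker == "YFP"],
                    last$mouse_id[last$marker == "YFP"], sum)
  p_final <- unname(p_final[match(unique(last$mouse_id), names(p_final))])
  p_final[is.na(p_final)] <- 0  # lines where YFP drifted to loss
  mc_se <- stats::sd(p_final) / sqrt(length(p_final))
  expect_lt(abs(mean(p_final) - 0.5), 3 * mc_se)
})

test_that("stochastic resistant fraction sits at mutation-selection balance", {
  # pop 3e7: equilibrium count ~67 cells; the time average over the
  # post-burn-in generations must land within 10% of mu_r/s_d
  mu <- 2.2387e-7; s_d <- 0.1
  cfg <- sim_config(n_hosts = 1, pop_size = 3e7, days = 24, gen_time_min = 72,
                    mode = "stochastic", samples_per_day = 4, seed = 17,
                    resistance_loci = list(resistance_locus("FZD", mu, s_d,
                                                            is_fraction = 0.5)))
  out <- run_simulation(cfg)
  tr <- out$trajectories
  res_rows <- grepl("FZD", tr$res)
  frac <- vapply(unique(tr$gen), function(g)
    sum(tr$freq[res_rows & tr$gen == g]), numeric(1))
  burn <- unique(tr$gen) >= 150
  expect_lt(abs(mean(frac[burn]) - mu / s_d) / (mu / s_d), 0.10)
})

test_that("identical config and seed give identical output", {
  cfg <- sim_config(n_hosts = 3, pop_size = 1e5, days = 3, gen_time_min = 70,
                    seed = 123,
                    beneficial_loci = list(beneficial_locus("gat", 1e-5, 0.05,
                                                            0.01)),
                    resistance_loci = list(resistance_locus("FZD", 1e-6, 0.1,
                                                            0.457)))
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(a$trajectories, b$trajectories)
  expect_identical(a$plate_counts, b$plate_counts)
  expect_identical(a$s_draws, b$s_draws)
})

test_that("the class table overflow guard trips with a resource error", {
  cfg <- sim_config(n_hosts = 1, pop_size = 1e6, days = 2, gen_time_min = 72,
                    class_cap = 3, seed = 2,
                    beneficial_loci = list(beneficial_locus("a", 1e-4, 0.05),
                                           beneficial_locus("b", 1e-4, 0.05)))
  expect_error(run_simulation(cfg), "overflow")
})

test_that("plate sampling has binomial margins and honors degenerate states", {
  state0 <- data.frame(marker = "CFP", ben = "", res = "", count = 100)
  pc <- sample_plate(state0, depth = 200, seed = 1)
  expect_equal(pc$count[pc$category == "yfp"], 0)
  expect_equal(pc$count[pc$category == "cfp"], 200)

  state <- data.frame(marker = c("YFP", "CFP"), ben = "", res = "",
                      count = c(25, 75))
  draws <- with(list(), {
    set.seed(42)
    replicate(3000, sample_plate(state, depth = 200)$count[1])
  })
  expect_lt(abs(mean(draws) - 50), 3 * sqrt(37.5 / 3000))
  expect_lt(abs(stats::var(draws) - 37.5) / 37.5, 0.15)

  expect_error(sample_plate(state[0, ], depth = 200), "empty population")
  expect_error(sample_plate(data.frame(marker = "YFP", ben = "", res = "",
                                       count = 0), depth = 200),
               "empty population")
})

test_that("competition sampling starts at the 1:1 inoculum ratio", {
  comp <- simulate_competition("wt-competition", n_hosts = 6, seed = 3)
  d0 <- comp[comp$time_h == 0, ]
  ratio <- d0$mutant / (d0$mutant + d0$reference)
  # binomial(600, 0.5) margins around the 1:1 start
  expect_true(all(abs(ratio - 0.5) < 5 * sqrt(0.25 / 600)))
})
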