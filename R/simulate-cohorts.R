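# Cohort-level generators: produce the tidy tables the inference modules
# consume, by running the Wright-Fisher engine under a named preset (or
# explicit parameters) and plating the simulated populations.

#' Simulate in vivo competition assays
#'
#' Emulates a short-term competition between a marked mutant and the
#' ancestral strain inoculated 1:1. Each host draws one per-hour selective
#' advantage from the preset's Gaussian (host-level antagonistic pleiotropy),
#' the two-class population evolves by Wright-Fisher dynamics, and plates of
#' `depth` colonies are scored at the requested hours. Sampling happens on
#' the generation grid; the emitted `time_h` is the realized time of the
#' sampled generation, so the log-ratio slope estimator is unbiased.
#'
#' @param preset `"wt-competition"` or `"rag2-competition"`; or `NULL` to
#'   supply explicit parameters.
#' @param n_hosts Number of hosts (default 10, as in the assays emulated).
#' @param hours Nominal sampling times in hours (default 0/24/48/72, the
#'   3-day assay).
#' @param depth Colonies scored per plate (default 600).
#' @param seed Integer root seed.
#' @param s_mean_per_hour,s_sd_per_hour,gen_time_min,pop_size,host Explicit
#'   parameters overriding the preset.
#' @param housing Housing label stored in the output
#'   (`"independent"`, `"cohoused"` or `"germfree"`).
#' @param mode `"stochastic"` or `"deterministic"` dynamics.
#' @return A data.frame with columns `mouse_id`, `host`, `housing`,
#'   `time_h`, `mutant`, `reference`, with the per-host true selective
#'   advantages attached as `attr(, "s_true")`.
#' @examples
#' comp <- simulate_competition("wt-competition", n_hosts = 3, seed = 1)
#' head(comp)
#' @export
simulate_competition <- function(preset = "wt-competition", n_hosts = 10,
                                 hours = c(0, 24, 48, 72), depth = 600,
                                 seed = 1L, s_mean_per_hour = NULL,
                                 s_sd_per_hour = NULL, gen_time_min = NULL,
                                 pop_size = NULL, host = NULL,
                                 housing = "independent",
                                 mode = c("stochastic", "deterministic")) {
  mode <- match.arg(mode)
  p <- if (is.null(preset)) list() else sim_preset(preset)
  if (!is.null(preset) && !identical(p$kind, "competition"))
    stop_invalid("preset '", preset, "' is not a competition preset")
  s_mean <- s_mean_per_hour %||% p$s_mean_per_hour
  s_sd <- s_sd_per_hour %||% p$s_sd_per_hour %||% 0
  gt <- gen_time_min %||% p$gen_time_min
  N <- pop_size %||% p$pop_size %||% 1e8
  host <- host %||% p$host %||% "WT"
  stopifnot(!is.null(s_mean), !is.null(gt), all(diff(hours) > 0), depth >= 1)
  gens <- round(hours * 60 / gt)
  s_true <- numeric(n_hosts)
  rows <- vector("list", n_hosts)
  for (h in seq_len(n_hosts)) {
    res_h <- with_seed(derive_seed(seed, paste0("competition-host", h)), {
      s_hour <- stats::rnorm(1, s_mean, s_sd)
      s_gen <- s_hour * gt / 60
      classes <- data.frame(marker = c("YFP", "CFP"),
                            ben = c("mut", ""), res = "",
                            count = c(0.5, 0.5), stringsAsFactors = FALSE)
      snaps <- wf_engine(classes, max(gens), N,
                         s_gen = list(mut = s_gen), s_d = list(),
                         mu_b = numeric(0), res_spec = list(),
                         mode = mode, record_at = gens)
      df <- do.call(rbind, lapply(gens, function(g) {
        st <- snaps[[as.character(g)]]
        p_mut <- sum(st$count[st$ben == "mut"]) / sum(st$count)
        m <- stats::rbinom(1L, as.integer(depth), p_mut)
        data.frame(mouse_id = sprintf("%s_%02d", host, h), host = host,
                   housing = housing, time_h = g * gt / 60,
                   mutant = m, reference = as.integer(depth) - m,
                   stringsAsFactors = FALSE)
      }))
      list(s = s_hour, df = df)
    })
    s_true[h] <- res_h$s
    rows[[h]] <- res_h$df
  }
  out <- do.call(rbind, rows)
  attr(out, "s_true") <- s_true
  out
}

#' Simulate daily antibiotic-resistance plating at mutation-selection balance
#'
#' Runs the Wright-Fisher engine with a single deleterious resistance locus,
#' burns in to the mutation-selection equilibrium, and then plates daily for
#' `days` days on a selective plate of `selective_depth` effective cells.
#'
#' @param preset Resistance preset name (default `"fzd-wt"`).
#' @param n_mice Number of mice (default 6).
#' @param days Days of daily sampling after burn-in (default 15).
#' @param burnin_gens Generations of burn-in before sampling (default 150;
#'   the equilibrium relaxes on a 1/s_d = 10-generation timescale).
#' @param selective_depth Effective cells plated per selective plate.
#' @param seed Integer root seed.
#' @param mode `"stochastic"` or `"deterministic"` dynamics.
#' @return A data.frame with columns `mouse_id`, `host`, `day`, `antibiotic`,
#'   `resistant`, `total`, `dilution_r`, `dilution_t`.
#' @export
simulate_resistance_counts <- function(preset = "fzd-wt", n_mice = 6,
                                       days = 15, burnin_gens = 150,
                                       selective_depth = 1e7, seed = 1L,
                                       mode = c("stochastic", "deterministic")) {
  mode <- match.arg(mode)
  p <- sim_preset(preset)
  if (!identical(p$kind, "resistance"))
    stop_invalid("preset '", preset, "' is not a resistance preset")
  gpd <- gens_per_day(p$gen_time_min)
  sample_gens <- burnin_gens + round(seq_len(days) * gpd)
  rl <- resistance_locus(p$antibiotic, p$mu_r, p$s_d, p$is_fraction)
  rows <- vector("list", n_mice)
  for (m in seq_len(n_mice)) {
    rows[[m]] <- with_seed(derive_seed(seed, paste0("resistance-mouse", m)), {
      classes <- data.frame(marker = "YFP", ben = "", res = "",
                            count = 1, stringsAsFactors = FALSE)
      snaps <- wf_engine(classes, max(sample_gens), p$pop_size,
                         s_gen = list(), s_d = stats::setNames(
                           list(p$s_d), p$antibiotic),
                         mu_b = numeric(0), res_spec = list(rl),
                         mode = mode, record_at = sample_gens)
      do.call(rbind, lapply(seq_len(days), function(d) {
        st <- snaps[[as.character(sample_gens[d])]]
        p_res <- sum(st$count[vapply(st$res, function(s)
          p$antibiotic %in% res_antibiotics(s), TRUE)]) / sum(st$count)
        r <- if (mode == "stochastic")
          stats::rbinom(1L, as.integer(selective_depth), p_res)
        else p_res * selective_depth
        data.frame(mouse_id = sprintf("%s_%02d", p$host, m), host = p$host,
                   day = d, antibiotic = p$antibiotic, resistant = r,
                   total = selective_depth, dilution_r = 1, dilution_t = 1,
                   stringsAsFactors = FALSE)
      }))
    })
  }
  do.call(rbind, rows)
}

#' Simulate a growth-rate vs fluorescence calibration table
#'
#' Emulates the bench calibration linking exponential growth rate to the
#' median fluorescence of an rRNA-targeted probe across growth conditions:
#' a linear map `rate = intercept + slope * F` observed with Gaussian noise
#' on the rate, with duplicate hybridizations per condition.
#'
#' @param n_conditions Number of growth conditions (default 8).
#' @param slope,intercept True calibration line (defaults 9e-4 and 0.05;
#'   rates span ~0.14-1.4 per hour over the default fluorescence range).
#' @param f_range Fluorescence range covered (arbitrary units).
#' @param rate_noise_sd Gaussian noise sd on observed rates (per hour).
#' @param fluor_noise_sd Gaussian noise sd on replicate fluorescence reads.
#' @param replicates Hybridization replicates per condition (default 2).
#' @param seed Integer seed.
#' @return A data.frame with columns `sample`, `replicate`,
#'   `median_fluorescence`, `rate_per_hour`; the true line is attached as
#'   attributes `slope` and `intercept`.
#' @export
simulate_calibration_table <- function(n_conditions = 8, slope = 9e-4,
                                       intercept = 0.05,
                                       f_range = c(100, 1500),
                                       rate_noise_sd = 0.02,
                                       fluor_noise_sd = 10,
                                       replicates = 2, seed = 1L) {
  stopifnot(n_conditions >= 3)
  with_seed(derive_seed(seed, "calibration"), {
    f_true <- seq(f_range[1], f_range[2], length.out = n_conditions)
    rate_obs <- intercept + slope * f_true +
      stats::rnorm(n_conditions, 0, rate_noise_sd)
    out <- do.call(rbind, lapply(seq_len(n_conditions), function(i) {
      data.frame(sample = sprintf("cond_%02d", i),
                 replicate = seq_len(replicates),
                 median_fluorescence = f_true[i] +
                   stats::rnorm(replicates, 0, fluor_noise_sd),
                 rate_per_hour = rate_obs[i], stringsAsFactors = FALSE)
    }))
    attr(out, "slope") <- slope
    attr(out, "intercept") <- intercept
    out
  })
}

#' Simulate in-gut hybridization fluorescence for a growth preset
#'
#' Generates the fluorescence reads a cohort of colonized mice would yield
#' under a true in-gut growth rate, through the same linear calibration map
#' used by [simulate_calibration_table()].
#'
#' @param preset `"wt-growth"` or `"rag2-growth"`; or `NULL` with an explicit
#'   `rate_per_hour`.
#' @param n_mice Number of mice (default 6).
#' @param days Sampling days (default days 1 and 3 of colonization).
#' @param replicates Hybridizations per sample (default 2).
#' @param slope,intercept True calibration line mapping rate to fluorescence.
#' @param fluor_noise_sd Gaussian noise sd on fluorescence reads.
#' @param rate_per_hour Explicit true rate overriding the preset.
#' @param seed Integer seed.
#' @return A data.frame with columns `mouse_id`, `day`, `replicate`,
#'   `median_fluorescence`.
#' @export
simulate_hybridization <- function(preset = "wt-growth", n_mice = 6,
                                   days = c(1, 3), replicates = 2,
                                   slope = 9e-4, intercept = 0.05,
                                   fluor_noise_sd = 10,
                                   rate_per_hour = NULL, seed = 1L) {
  p <- if (is.null(preset)) list() else sim_preset(preset)
  if (!is.null(preset) && !identical(p$kind, "growth"))
    stop_invalid("preset '", preset, "' is not a growth preset")
  rate <- rate_per_hour %||% p$rate_per_hour
  host <- p$host %||% "WT"
  stopifnot(!is.null(rate), rate > 0)
  f_true <- (rate - intercept) / slope
  with_seed(derive_seed(seed, "hybridization"), {
    grid <- expand.grid(mouse = seq_len(n_mice), day = days,
                        replicate = seq_len(replicates))
    data.frame(mouse_id = sprintf("%s_%02d", host, grid$mouse),
               day = grid$day, replicate = grid$replicate,
               median_fluorescence = f_true +
                 stats::rnorm(nrow(grid), 0, fluor_noise_sd),
               stringsAsFactors = FALSE)
  })
}

#' Extract marker-count tables from a simulation
#'
#' @param sim A `sim_output` from [run_simulation()].
#' @return A data.frame with columns `mouse_id`, `host`, `day`, `yfp`,
#'   `cfp` — the input dialect of the marker-trajectory module.
#' @export
sim_marker_counts <- function(sim) {
  pc <- sim$plate_counts
  y <- pc[pc$category == "yfp", c("mouse_id", "host", "day", "count")]
  c_ <- pc[pc$category == "cfp", "count"]
  data.frame(mouse_id = y$mouse_id, host = y$host, day = y$day,
             yfp = y$count, cfp = c_, stringsAsFactors = FALSE)
}

#' Extract gat-phenotype count tables from a simulation
#'
#' @param sim A `sim_output` from [run_simulation()].
#' @return A data.frame with columns `mouse_id`, `host`, `day`, `gat_neg`,
#'   `total` — the input dialect of the sweep module.
#' @export
sim_phenotype_counts <- function(sim) {
  pc <- sim$plate_counts
  g <- pc[pc$category == "gat_neg", c("mouse_id", "host", "day", "count", "depth")]
  data.frame(mouse_id = g$mouse_id, host = g$host, day = g$day,
             gat_neg = g$count, total = g$depth, stringsAsFactors = FALSE)
}

#' Extract resistance-count tables from a simulation
#'
#' @param sim A `sim_output` from [run_simulation()].
#' @return A data.frame in the resistance-count dialect (`mouse_id`, `host`,
#'   `day`, `antibiotic`, `resistant`, `total`, `dilution_r`, `dilution_t`).
#' @export
sim_resistance_table <- function(sim) {
  pc <- sim$plate_counts
  r <- pc[grepl("_resistant$", pc$category), , drop = FALSE]
  if (!nrow(r)) return(NULL)
  data.frame(mouse_id = r$mouse_id, host = r$host, day = r$day,
             antibiotic = toupper(sub("_resistant$", "", r$category)),
             resistant = r$count, total = r$depth,
             dilution_r = 1, dilution_t = 1, stringsAsFactors = FALSE)
}

#' Sample end-point clone typings from a simulation
#'
#' Emulates picking `n_clones` colonies from the last sampled day of each
#' population and screening them at a fixed panel of adaptive loci.
#'
#' @param sim A `sim_output` from [run_simulation()].
#' @param n_clones Clones typed per population (default 20).
#' @param loci Locus panel (default the simulated beneficial loci).
#' @param day Sampling day (default the last sampled day).
#' @param seed Integer seed.
#' @return A data.frame with columns `mouse_id`, `clone`, `locus`, `state`
#'   (`"present"`/`"absent"`), the clone-typing dialect.
#' @export
simulate_clone_typing <- function(sim, n_clones = 20, loci = NULL,
                                  day = NULL, seed = 1L) {
  tr <- sim$trajectories
  if (is.null(day)) day <- max(tr$day)
  if (is.null(loci))
    loci <- vapply(sim$config$beneficial_loci, `[[`, "", "name")
  with_seed(derive_seed(seed, "clone-typing"), {
    out <- lapply(unique(tr$mouse_id), function(m) {
      st <- tr[tr$mouse_id == m & tr$day == day, , drop = FALSE]
      picks <- sample.int(nrow(st), n_clones, replace = TRUE,
                          prob = st$count)
      do.call(rbind, lapply(seq_len(n_clones), function(k) {
        ben <- split_set(st$ben[picks[k]])
        data.frame(mouse_id = m, clone = k, locus = loci,
                   state = ifelse(loci %in% ben, "present", "absent"),
                   stringsAsFactors = FALSE)
      }))
    })
    do.call(rbind, out)
  })
}

#' Population variant-frequency table from a simulation
#'
#' Emulates the per-population mutation-frequency table a resequencing
#' caller would export: for each population and each simulated locus, the
#' summed frequency of classes carrying a mutation at that locus on the
#' chosen day.
#'
#' @param sim A `sim_output` from [run_simulation()].
#' @param day Sampling day (default the last sampled day).
#' @param class_map Named character vector mapping loci to mutation classes
#'   (default: IS insertions for gat/focA/dcuB, SNP otherwise).
#' @return A data.frame with columns `population`, `host`, `target`,
#'   `class`, `frequency`.
#' @export
sim_variant_table <- function(sim, day = NULL, class_map = NULL) {
  tr <- sim$trajectories
  if (is.null(day)) day <- max(tr$day)
  loci <- vapply(sim$config$beneficial_loci, `[[`, "", "name")
  if (is.null(class_map))
    class_map <- stats::setNames(
      ifelse(loci %in% c("gat", "focA", "dcuB"), "IS insertion", "SNP"), loci)
  out <- lapply(unique(tr$mouse_id), function(m) {
    st <- tr[tr$mouse_id == m & tr$day == day, , drop = FALSE]
    tot <- sum(st$count)
    data.frame(population = m, host = st$host[1], target = loci,
               class = unname(class_map[loci]),
               frequency = vapply(loci, function(l)
                 sum(st$count[vapply(st$ben, set_has, TRUE, el = l)]) / tot,
                 numeric(1)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
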