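# End-to-end in-silico driver: simulate a two-genotype colonization cohort
# and push it through every inference stage, writing tidy outputs and a run
# manifest.

#' Run the full in-silico pipeline
#'
#' Simulates a colonization cohort under the `"paper-replica"` preset (one
#' immune-competent and one immune-compromised group, each with beneficial
#' sweeps, clonal interference and a resistance locus at mutation-selection
#' balance), then runs all inference stages: marker divergence, competition
#' fitness, resistance/mutation frequency, division rate, sweep fit, and
#' haplotype statistics. Every stage draws from a named substream of the
#' root seed, so identical configuration and seed give identical outputs.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer root seed.
#' @param n_hosts Optional hosts per genotype, overriding the preset
#'   (14 WT / 15 immune-compromised).
#' @param days Days of colonization simulated (default 24).
#' @param competition_hosts Hosts per genotype in the competition-assay
#'   stage (default 10).
#' @return Invisibly, a list with the per-stage results and the manifest.
#' @export
run_pipeline <- function(out_dir, seed = 1L, n_hosts = NULL, days = 24,
                         competition_hosts = 10) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  results <- list()

  # -- simulate ------------------------------------------------------------
  results$simulate <- stage("simulate", {
    cfg_wt <- replica_config("WT", n_hosts = n_hosts, days = days,
                             seed = derive_seed(seed, "replica-wt"))
    cfg_r2 <- replica_config("RAG2KO", n_hosts = n_hosts, days = days,
                             seed = derive_seed(seed, "replica-rag2"))
    sims <- list(wt = run_simulation(cfg_wt), rag2 = run_simulation(cfg_r2))
    pc <- rbind(sims$wt$plate_counts, sims$rag2$plate_counts)
    write_table(pc, file.path(out_dir, "plate_counts.tsv"))
    write_table(rbind(sims$wt$trajectories, sims$rag2$trajectories),
                file.path(out_dir, "true_trajectories.tsv"))
    sims
  })
  sims <- results$simulate

  # -- markers -------------------------------------------------------------
  results$markers <- stage("markers", {
    mk <- rbind(sim_marker_counts(sims$wt), sim_marker_counts(sims$rag2))
    dv <- suppressWarnings(divergence_summary(mk))
    write_table(dv, file.path(out_dir, "marker_divergence.tsv"))
    by_host <- split(dv, dv$host)
    cmp <- if (length(by_host) == 2) {
      k <- vapply(by_host, function(d) sum(d$diverged, na.rm = TRUE), 0)
      n <- vapply(by_host, function(d) sum(d$evaluable), 0)
      compare_diverged_counts(k[["WT"]], n[["WT"]], k[["RAG2KO"]], n[["RAG2KO"]])
    } else NULL
    jsonlite::write_json(
      list(diverged = lapply(by_host, function(d)
        list(k = sum(d$diverged, na.rm = TRUE), n = sum(d$evaluable))),
        comparison = if (!is.null(cmp)) unclass(cmp)),
      file.path(out_dir, "marker_comparison.json"), auto_unbox = TRUE,
      digits = NA)
    list(divergence = dv, comparison = cmp)
  })

  # -- fitness -------------------------------------------------------------
  results$fitness <- stage("fitness", {
    comp <- rbind(
      simulate_competition("wt-competition", n_hosts = competition_hosts,
                           seed = derive_seed(seed, "competition-wt")),
      simulate_competition("rag2-competition", n_hosts = competition_hosts,
                           seed = derive_seed(seed, "competition-rag2")))
    write_table(comp, file.path(out_dir, "competition_counts.tsv"))
    summ <- competition_summary(comp)
    write_table(summ, file.path(out_dir, "selection_coefficients.tsv"))
    s_wt <- summ$s_per_hour[summ$host == "WT"]
    s_r2 <- summ$s_per_hour[summ$host == "RAG2KO"]
    vr <- variance_ratio_test(s_r2, s_wt)
    av <- group_anova(summ$s_per_hour, summ$host)
    jsonlite::write_json(
      list(mean_s = list(WT = mean(s_wt), RAG2KO = mean(s_r2)),
           variance_ratio = unclass(vr), anova = av$table,
           tukey = av$tukey),
      file.path(out_dir, "fitness_tests.json"), auto_unbox = TRUE,
      digits = NA)
    list(summary = summ, variance_ratio = vr, anova = av)
  })

  # -- mutrate -------------------------------------------------------------
  results$mutrate <- stage("mutrate", {
    rc <- rbind(sim_resistance_table(sims$wt), sim_resistance_table(sims$rag2))
    write_table(rc, file.path(out_dir, "resistance_counts.tsv"))
    ests <- lapply(split(rc, rc$host), summarize_frequency)
    mw <- if (length(ests) == 2)
      mann_whitney(ests$WT$per_mouse, ests$RAG2KO$per_mouse) else NULL
    jsonlite::write_json(
      list(mean_log10 = lapply(ests, `[[`, "mean_log10_frequency"),
           comparison = if (!is.null(mw)) unclass(mw)),
      file.path(out_dir, "mutation_frequency.json"), auto_unbox = TRUE,
      digits = NA)
    list(estimates = ests, comparison = mw)
  })

  # -- growth --------------------------------------------------------------
  results$growth <- stage("growth", {
    cal <- simulate_calibration_table(seed = derive_seed(seed, "calibration"))
    model <- fit_calibration(cal)
    hyb <- list(
      WT = simulate_hybridization("wt-growth",
                                  seed = derive_seed(seed, "growth-wt")),
      RAG2KO = simulate_hybridization("rag2-growth",
                                      seed = derive_seed(seed, "growth-rag2")))
    summ <- lapply(hyb, doubling_time_summary, model = model)
    mw <- mann_whitney(summ$WT$per_sample$doubling_min,
                       summ$RAG2KO$per_sample$doubling_min)
    jsonlite::write_json(
      list(calibration = model[c("slope", "intercept", "residual_sd", "n")],
           mean_doubling_min = lapply(summ, `[[`, "mean_doubling_min"),
           comparison = unclass(mw)),
      file.path(out_dir, "doubling_time.json"), auto_unbox = TRUE,
      digits = NA)
    list(model = model, summary = summ, comparison = mw)
  })

  # -- sweeps --------------------------------------------------------------
  results$sweeps <- stage("sweeps", {
    ph <- rbind(sim_phenotype_counts(sims$wt), sim_phenotype_counts(sims$rag2))
    write_table(ph, file.path(out_dir, "phenotype_counts.tsv"))
    fit <- fit_sweep(ph[ph$day >= 1, ])
    pv <- lapply(split(ph, ph$host), phenotype_variance)
    for (h in names(pv))
      write_table(pv[[h]], file.path(out_dir,
                                     sprintf("phenotype_variance_%s.tsv", h)))
    jsonlite::write_json(
      list(coefficients = as.list(fit$coefficients),
           se_robust = as.list(fit$se_robust), z = fit$z,
           p_value = fit$p_value),
      file.path(out_dir, "sweep_fit.json"), auto_unbox = TRUE, digits = NA)
    list(fit = fit, variance = pv)
  })

  # -- haplotypes ----------------------------------------------------------
  results$haplotypes <- stage("haplotypes", {
    typing <- rbind(
      simulate_clone_typing(sims$rag2, seed = derive_seed(seed, "typing")))
    hf <- haplotype_frequencies(typing)
    write_table(hf, file.path(out_dir, "haplotype_frequencies.tsv"))
    ci <- vapply(split(hf, hf$mouse_id), function(d)
      detect_clonal_interference(
        stats::setNames(d$frequency, d$haplotype))$interference, TRUE)
    vt <- rbind(sim_variant_table(sims$wt), sim_variant_table(sims$rag2))
    seg <- filter_variants(vt, 0.05)
    par <- parallel_targets(seg)
    hits <- do.call(rbind, lapply(par$target, function(tg) {
      hit_pop <- unique(seg$population[seg$target == tg &
                                         seg$frequency >= 0.10])
      data.frame(target = tg,
                 k1 = sum(startsWith(hit_pop, "WT")),
                 n1 = sims$wt$config$n_hosts,
                 k2 = sum(startsWith(hit_pop, "RAG2KO")),
                 n2 = sims$rag2$config$n_hosts, stringsAsFactors = FALSE)
    }))
    prev <- if (!is.null(hits) && nrow(hits)) prevalence_table(hits) else NULL
    if (!is.null(prev))
      write_table(prev, file.path(out_dir, "target_prevalence.tsv"))
    jsonlite::write_json(
      list(interference_fraction = mean(ci),
           parallel_targets = par$target),
      file.path(out_dir, "haplotype_summary.json"), auto_unbox = TRUE,
      digits = NA)
    list(frequencies = hf, interference = ci, parallel = par,
         prevalence = prev)
  })

  manifest <- list(
    command = "run_pipeline",
    preset = "paper-replica",
    seed = seed,
    config_hash = fnv1a(jsonlite::toJSON(list(n_hosts = n_hosts, days = days,
                                              competition_hosts = competition_hosts),
                                         auto_unbox = TRUE, null = "null")),
    package_version = as.character(utils::packageVersion("gutevolve")),
    timestamp = format(Sys.time(), tz = "UTC"),
    outputs = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(results, list(manifest = manifest)))
}
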