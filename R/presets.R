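# Named parameter presets for the study conditions: competition assays,
# in-gut growth rates, resistance at mutation-selection balance, and a full
# in-silico replica cohort.
#
# Values with a measured origin: mean advantages 0.068/h (WT) and 0.03/h
# (Rag2-deficient) for the gat mutant; generation times 76 and 66 min; the
# furazolidone-resistant fraction corresponding to log10 -5.65 at a cost of
# 0.1 per generation. Standard-deviation decompositions and mutation-rate
# splits are documented inferences (see the methods vignette).

.preset_registry <- function() {
  list(
    "wt-competition" = list(
      kind = "competition", host = "WT", gen_time_min = 76,
      s_mean_per_hour = 0.068, s_sd_per_hour = 0.008, pop_size = 1e8),
    "rag2-competition" = list(
      kind = "competition", host = "RAG2KO", gen_time_min = 66,
      s_mean_per_hour = 0.03, s_sd_per_hour = 0.016, pop_size = 1e8),
    "wt-growth" = list(
      kind = "growth", host = "WT", gen_time_min = 76,
      rate_per_hour = 60 * log(2) / 76),
    "rag2-growth" = list(
      kind = "growth", host = "RAG2KO", gen_time_min = 66,
      rate_per_hour = 60 * log(2) / 66),
    "fzd-wt" = list(
      kind = "resistance", host = "WT", gen_time_min = 76, pop_size = 1e8,
      antibiotic = "FZD", mu_r = 2.2387e-7, s_d = 0.1,
      # fraction of furazolidone-resistance events that are IS insertions,
      # back-derived from the measured transposition vs total frequencies
      # (10^(-5.99 + 5.65) ~ 0.457)
      is_fraction = 0.457),
    "paper-replica" = list(
      kind = "replica",
      wt = replica_config("WT"),
      rag2 = replica_config("RAG2KO"))
  )
}

# Full-cohort configuration used by the end-to-end pipeline. Beneficial-locus
# supplies and the non-gat selective effects are not directly measured;
# they are chosen to reproduce the qualitative dynamics (gat sweeping first,
# clonal interference among later targets, dcuB beneficial only in WT).
replica_config <- function(host = c("WT", "RAG2KO"), n_hosts = NULL,
                           days = 24, seed = 1L) {
  host <- match.arg(host)
  if (is.null(n_hosts)) n_hosts <- if (host == "WT") 14L else 15L
  if (host == "WT") {
    ben <- list(
      beneficial_locus("gat",  mu_b = 1e-7, s_mean_per_hour = 0.068,
                       s_sd_per_hour = 0.008),
      beneficial_locus("srlR", mu_b = 1e-8, s_mean_per_hour = 0.045,
                       s_sd_per_hour = 0.010),
      beneficial_locus("focA", mu_b = 5e-9, s_mean_per_hour = 0.040,
                       s_sd_per_hour = 0.010),
      beneficial_locus("dcuB", mu_b = 1e-8, s_mean_per_hour = 0.050,
                       s_sd_per_hour = 0.010))
    gt <- 76
  } else {
    ben <- list(
      beneficial_locus("gat",  mu_b = 1e-7, s_mean_per_hour = 0.030,
                       s_sd_per_hour = 0.016),
      beneficial_locus("srlR", mu_b = 1e-8, s_mean_per_hour = 0.035,
                       s_sd_per_hour = 0.012),
      beneficial_locus("focA", mu_b = 5e-9, s_mean_per_hour = 0.040,
                       s_sd_per_hour = 0.012),
      # neutral on average in the immune-compromised host (antagonistic
      # pleiotropy of the dcuB/dcuR insertions)
      beneficial_locus("dcuB", mu_b = 1e-8, s_mean_per_hour = 0.000,
                       s_sd_per_hour = 0.008))
    gt <- 66
  }
  fzd <- resistance_locus("FZD", mu_r = 2.2387e-7, s_d = 0.1,
                          is_fraction = 0.457)
  sim_config(n_hosts = n_hosts, host_genotype = host, pop_size = 1e8,
             gen_time_min = gt, days = days, beneficial_loci = ben,
             resistance_loci = list(fzd), seed = seed)
}

#' Names of the shipped simulation presets
#'
#' @return Character vector of preset names.
#' @export
preset_names <- function() names(.preset_registry())

#' Look up a shipped simulation preset
#'
#' Presets bundle the study conditions each generator emulates:
#' `"wt-competition"` / `"rag2-competition"` (gat-mutant vs ancestor
#' competition assays), `"wt-growth"` / `"rag2-growth"` (true in-gut growth
#' rates), `"fzd-wt"` (furazolidone resistance at mutation-selection
#' balance), and `"paper-replica"` (a full two-genotype evolution cohort).
#'
#' @param name Preset name; see [preset_names()].
#' @return A named parameter list (for `"paper-replica"`, containing one
#'   [sim_config()] per host genotype under `$wt` and `$rag2`).
#' @examples
#' sim_preset("wt-competition")$s_mean_per_hour
#' @export
sim_preset <- function(name) {
  reg <- .preset_registry()
  if (!name %in% names(reg))
    stop_invalid("unknown preset '", name, "'; available: ",
                 paste(names(reg), collapse = ", "))
  reg[[name]]
}
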