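# Haplotype-class Wright-Fisher simulator of E. coli colonizing individual
# hosts. Populations are tracked as counts over classes defined by
# (fluorescent marker, set of beneficial loci, set of resistance alleles);
# per-cell simulation is impossible at gut loads of ~1e8 cells, and the
# class-level multinomial scheme has the exact same marginal law.

#' Generations per day for a given generation time
#'
#' @param gen_time_min Generation (doubling) time in minutes; must be > 0.
#' @return Number of generations elapsed per 24 h day, `1440 / gen_time_min`.
#' @examples
#' gens_per_day(72)  # 20
#' gens_per_day(76)  # ~18.95, the immune-competent-host generation time
#' @export
gens_per_day <- function(gen_time_min) {
  check_number(gen_time_min, "gen_time_min", lower = 0, strict_lower = TRUE)
  1440 / gen_time_min
}

#' Deterministic mutation-selection balance frequency
#'
#' Equilibrium frequency of a deleterious allele maintained by recurrent
#' mutation at rate `mu_r` against a per-generation selective cost `s_d`.
#'
#' @param mu_r Mutation rate towards the allele, per cell per generation.
#' @param s_d Selective cost per generation; must be > 0.
#' @return The equilibrium frequency `mu_r / s_d`.
#' @examples
#' msb_equilibrium(1e-8, 0.05)
#' log10(msb_equilibrium(2.2387e-7, 0.1))  # ~ -5.65
#' @export
msb_equilibrium <- function(mu_r, s_d) {
  check_number(mu_r, "mu_r", lower = 0)
  check_number(s_d, "s_d", lower = 0, strict_lower = TRUE)
  mu_r / s_d
}

#' Specify a beneficial locus
#'
#' A target of adaptation with its mutation supply and its host-dependent
#' selective effect. The per-hour advantage drawn for a given host is
#' `Normal(s_mean_per_hour, s_sd_per_hour)`; a standard deviation large
#' enough to allow draws at or below zero models antagonistic pleiotropy
#' (beneficial in some hosts, neutral or deleterious in others).
#'
#' @param name Locus label (e.g. `"gat"`, `"dcuB"`).
#' @param mu_b Beneficial mutation rate per cell per generation (>= 0).
#' @param s_mean_per_hour Mean selective advantage per hour in this host
#'   genotype.
#' @param s_sd_per_hour Across-host standard deviation of the advantage
#'   (>= 0).
#' @return A `beneficial_locus` object.
#' @export
beneficial_locus <- function(name, mu_b, s_mean_per_hour, s_sd_per_hour = 0) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (grepl("[+|]", name)) stop_invalid("locus names may not contain '+' or '|'")
  check_number(mu_b, "mu_b", lower = 0)
  check_number(s_mean_per_hour, "s_mean_per_hour")
  check_number(s_sd_per_hour, "s_sd_per_hour", lower = 0)
  structure(list(name = name, mu_b = mu_b,
                 s_mean_per_hour = s_mean_per_hour,
                 s_sd_per_hour = s_sd_per_hour),
            class = "beneficial_locus")
}

#' Specify a resistance locus
#'
#' A deleterious resistance allele held at mutation-selection balance.
#' Mutations arise through two channels: point mutation and insertion-sequence
#' (IS) transposition; `is_fraction` gives the fraction of resistance events
#' that are transpositions (e.g. insertions in *nfsA* for furazolidone).
#'
#' @param name Antibiotic label (e.g. `"FZD"`, `"RIF"`, `"NAL"`).
#' @param mu_r Total mutation rate to resistance per cell per generation.
#' @param s_d Selective cost of resistance per generation (> 0).
#' @param is_fraction Fraction of events through the IS channel, in `[0, 1]`.
#' @return A `resistance_locus` object.
#' @export
resistance_locus <- function(name, mu_r, s_d, is_fraction = 0) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (grepl("[+|:]", name)) stop_invalid("antibiotic names may not contain '+', ':' or '|'")
  check_number(mu_r, "mu_r", lower = 0)
  check_number(s_d, "s_d", lower = 0, strict_lower = TRUE)
  check_number(is_fraction, "is_fraction", lower = 0, upper = 1)
  structure(list(name = name, mu_r = mu_r, s_d = s_d,
                 is_fraction = is_fraction),
            class = "resistance_locus")
}

#' Build a simulation configuration
#'
#' @param n_hosts Number of hosts (mice) to simulate.
#' @param host_genotype One of `"WT"`, `"RAG2KO"`, `"GF_WT"`, `"GF_RAG2KO"`.
#' @param pop_size Effective population size in cells (>= 1).
#' @param gen_time_min Generation time in minutes (> 0).
#' @param days Duration of the experiment in days.
#' @param samples_per_day Plate samples taken per day (default 1).
#' @param plate_depth Colonies counted per non-selective plate (default 200).
#' @param beneficial_loci List of [beneficial_locus()] specs.
#' @param resistance_loci List of [resistance_locus()] specs.
#' @param initial_marker_ratio Initial YFP fraction in `[0, 1]` (default 0.5,
#'   the 1:1 two-marker inoculum).
#' @param mode `"stochastic"` (full Wright-Fisher resampling) or
#'   `"deterministic"` (expected-value dynamics, no resampling).
#' @param seed Integer root seed; every host and plate sample draws from a
#'   named substream derived from it.
#' @param selective_depth Effective number of cells plated on a selective
#'   (antibiotic) plate, so that rare resistant classes are observable
#'   (default 1e7).
#' @param phenotype_locus Beneficial locus whose carriers are scored as the
#'   phenotype-negative class on indicator plates (default `"gat"`).
#' @param initial_classes Optional data.frame with columns `marker`, `ben`,
#'   `res`, `freq` overriding the default two-marker ancestral start (used
#'   e.g. to seed a mutant class at a known frequency).
#' @param class_cap Maximum number of haplotype classes before the simulator
#'   aborts with a resource error (default 512).
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_hosts = 1, host_genotype = "WT", pop_size = 1e8,
                       gen_time_min = 76, days = 24, samples_per_day = 1,
                       plate_depth = 200, beneficial_loci = list(),
                       resistance_loci = list(), initial_marker_ratio = 0.5,
                       mode = c("stochastic", "deterministic"), seed = 1L,
                       selective_depth = 1e7, phenotype_locus = "gat",
                       initial_classes = NULL, class_cap = 512) {
  mode <- match.arg(mode)
  check_number(n_hosts, "n_hosts", lower = 1)
  check_number(pop_size, "pop_size", lower = 1)
  check_number(gen_time_min, "gen_time_min", lower = 0, strict_lower = TRUE)
  check_number(days, "days", lower = 0, strict_lower = TRUE)
  check_number(samples_per_day, "samples_per_day", lower = 1)
  check_number(plate_depth, "plate_depth", lower = 1)
  check_number(initial_marker_ratio, "initial_marker_ratio", lower = 0, upper = 1)
  check_number(selective_depth, "selective_depth", lower = 1)
  host_genotype <- match.arg(host_genotype,
                             c("WT", "RAG2KO", "GF_WT", "GF_RAG2KO"))
  if (inherits(beneficial_loci, "beneficial_locus"))
    beneficial_loci <- list(beneficial_loci)
  if (inherits(resistance_loci, "resistance_locus"))
    resistance_loci <- list(resistance_loci)
  stopifnot(all(vapply(beneficial_loci, inherits, TRUE, "beneficial_locus")),
            all(vapply(resistance_loci, inherits, TRUE, "resistance_locus")))
  ben_names <- vapply(beneficial_loci, `[[`, "", "name")
  res_names <- vapply(resistance_loci, `[[`, "", "name")
  if (anyDuplicated(ben_names) || anyDuplicated(res_names))
    stop_invalid("locus names must be unique")
  structure(list(n_hosts = as.integer(n_hosts), host_genotype = host_genotype,
                 pop_size = pop_size, gen_time_min = gen_time_min,
                 days = days, samples_per_day = samples_per_day,
                 plate_depth = as.integer(plate_depth),
                 beneficial_loci = beneficial_loci,
                 resistance_loci = resistance_loci,
                 initial_marker_ratio = initial_marker_ratio,
                 mode = mode, seed = as.integer(seed),
                 selective_depth = selective_depth,
                 phenotype_locus = phenotype_locus,
                 initial_classes = initial_classes,
                 class_cap = class_cap),
            class = "sim_config")
}

# ---- class-set helpers ----------------------------------------------------

split_set <- function(s) if (is.na(s) || !nzchar(s)) character(0) else
  strsplit(s, "+", fixed = TRUE)[[1]]

join_set <- function(els) paste(sort(unique(els)), collapse = "+")

add_to_set <- function(s, el) join_set(c(split_set(s), el))

set_has <- function(s, el) el %in% split_set(s)

# antibiotic names carried by a resistance-set string like "FZD:IS+RIF:point"
res_antibiotics <- function(s) unique(sub(":.*$", "", split_set(s)))

class_key <- function(marker, ben, res) paste(marker, ben, res, sep = "|")

# Per-generation relative fitness of each class row. Beneficial effects are
# Malthusian (w multiplies by exp(s_gen) per locus), so a deterministic
# single sweep follows the logistic closed form p0*exp(s*t)/(1-p0+p0*exp(s*t))
# exactly and per-hour log-ratio slopes estimate s without discretization
# bias. Resistance costs are per-generation Wright-Fisher costs (w times
# 1 - s_d), so the deterministic mutation-selection equilibrium is exactly
# mu_r / s_d.
class_fitness <- function(classes, s_gen, s_d) {
  vapply(seq_len(nrow(classes)), function(i) {
    w <- 1
    for (l in split_set(classes$ben[i])) w <- w * exp(s_gen[[l]])
    for (a in res_antibiotics(classes$res[i])) w <- w * (1 - s_d[[a]])
    w
  }, numeric(1))
}

empty_classes <- function() data.frame(marker = character(0),
                                       ben = character(0),
                                       res = character(0),
                                       count = numeric(0),
                                       stringsAsFactors = FALSE)

# ---- engine ---------------------------------------------------------------

# One host's trajectory. `classes` holds counts summing to pop_size;
# record_at is a sorted set of generation indices (0 = initial state).
# Mutation fluxes are Poisson (expected-value in deterministic mode); double
# events within one generation are ignored (rates are far below 1/N per
# class pair). Returns a list of snapshots named by generation.
wf_engine <- function(classes, n_gens, pop_size, s_gen, s_d, mu_b, res_spec,
                      mode, record_at, class_cap = 512) {
  stopifnot(nrow(classes) >= 1, all(classes$count >= 0))
  if (mode == "stochastic" && pop_size > .Machine$integer.max)
    stop("pop_size exceeds the multinomial sampler's limit (2^31 - 1); ",
         "use deterministic mode or a smaller population", call. = FALSE)
  classes$count <- classes$count / sum(classes$count) * pop_size
  record_at <- sort(unique(as.integer(record_at)))
  snapshots <- vector("list", length(record_at))
  names(snapshots) <- as.character(record_at)
  if (0L %in% record_at) snapshots[["0"]] <- classes
  ben_names <- names(mu_b)
  stoch <- mode == "stochastic"
  for (g in seq_len(n_gens)) {
    # selection (deterministic update of expected counts)
    w <- class_fitness(classes, s_gen, s_d)
    x <- classes$count * w
    x <- x / sum(x) * pop_size
    classes$count <- x
    # mutation fluxes: all channels draw against the same pre-mutation
    # snapshot, so no channel is depleted by another within one generation
    # (double events in one generation are ignored throughout)
    n0 <- nrow(classes)
    cnt0 <- classes$count
    for (l in ben_names) {
      if (mu_b[[l]] <= 0) next
      src <- which(!vapply(classes$ben[seq_len(n0)], set_has, TRUE, el = l))
      if (!length(src)) next
      lam <- cnt0[src] * mu_b[[l]]
      flux <- if (stoch) stats::rpois(length(lam), lam) else lam
      flux <- pmin(flux, classes$count[src])
      for (j in seq_along(src)) {
        if (flux[j] <= 0) next
        i <- src[j]
        classes <- move_cells(classes, i, flux[j],
                              ben = add_to_set(classes$ben[i], l),
                              res = classes$res[i])
      }
    }
    for (rl in res_spec) {
      for (channel in c("point", "IS")) {
        rate <- rl$mu_r * if (channel == "IS") rl$is_fraction else 1 - rl$is_fraction
        if (rate <= 0) next
        allele <- paste0(rl$name, ":", channel)
        src <- which(!vapply(classes$res[seq_len(n0)], function(s)
          rl$name %in% res_antibiotics(s), TRUE))
        if (!length(src)) next
        lam <- cnt0[src] * rate
        flux <- if (stoch) stats::rpois(length(lam), lam) else lam
        flux <- pmin(flux, classes$count[src])
        for (j in seq_along(src)) {
          if (flux[j] <= 0) next
          i <- src[j]
          classes <- move_cells(classes, i, flux[j],
                                ben = classes$ben[i],
                                res = add_to_set(classes$res[i], allele))
        }
      }
    }
    if (nrow(classes) > class_cap)
      stop(sprintf("haplotype class table overflow: %d classes exceeds cap %d",
                   nrow(classes), class_cap), call. = FALSE)
    # resampling to constant population size
    if (stoch) {
      p <- classes$count / sum(classes$count)
      classes$count <- as.numeric(stats::rmultinom(1L, as.integer(pop_size), p))
    } else {
      classes$count <- classes$count / sum(classes$count) * pop_size
    }
    classes <- classes[classes$count > 0, , drop = FALSE]
    rownames(classes) <- NULL
    if (g %in% record_at) snapshots[[as.character(g)]] <- classes
  }
  snapshots
}

# move n cells from row i to the class (marker_i, ben, res), creating it if new
move_cells <- function(classes, i, n, ben, res) {
  classes$count[i] <- classes$count[i] - n
  key <- class_key(classes$marker, classes$ben, classes$res)
  target <- match(class_key(classes$marker[i], ben, res), key)
  if (is.na(target)) {
    classes <- rbind(classes,
                     data.frame(marker = classes$marker[i], ben = ben,
                                res = res, count = n,
                                stringsAsFactors = FALSE))
  } else {
    classes$count[target] <- classes$count[target] + n
  }
  classes
}

initial_class_table <- function(config) {
  if (!is.null(config$initial_classes)) {
    ic <- config$initial_classes
    stopifnot(all(c("marker", "ben", "res", "freq") %in% names(ic)),
              all(ic$freq >= 0), sum(ic$freq) > 0)
    return(data.frame(marker = ic$marker, ben = ic$ben, res = ic$res,
                      count = ic$freq / sum(ic$freq), stringsAsFactors = FALSE))
  }
  p <- config$initial_marker_ratio
  cls <- data.frame(marker = c("YFP", "CFP"), ben = "", res = "",
                    count = c(p, 1 - p), stringsAsFactors = FALSE)
  cls[cls$count > 0, , drop = FALSE]
}

#' Run the within-host Wright-Fisher simulation
#'
#' For each host, one selective advantage per beneficial locus is drawn from
#' `Normal(s_mean_per_hour, s_sd_per_hour)` and held constant within that
#' host (host-level antagonistic pleiotropy); per-hour effects are converted
#' to per-generation effects via `s_gen = s_hour * gen_time_min / 60`. Each
#' generation applies deterministic selection, Poisson mutation fluxes
#' (beneficial loci, and resistance split between point and IS channels), and
#' multinomial resampling to `pop_size` (skipped in deterministic mode).
#' Plate samples are taken at the configured days.
#'
#' @param config A [sim_config()] object.
#' @return A `sim_output` list with elements `config`, `s_draws` (hosts x
#'   beneficial loci, per hour), `trajectories` (tidy class abundances per
#'   host and sampling time), and `plate_counts` (tidy sampled colony
#'   counts). Fully reproducible from `config$seed`.
#' @examples
#' cfg <- sim_config(n_hosts = 2, pop_size = 1e4, days = 3,
#'                   gen_time_min = 72, mode = "stochastic", seed = 1)
#' out <- run_simulation(cfg)
#' head(out$trajectories)
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gpd <- gens_per_day(config$gen_time_min)
  sample_days <- seq(0, config$days, by = 1 / config$samples_per_day)
  sample_gens <- unique(round(sample_days * gpd))
  n_gens <- max(sample_gens)
  ben <- config$beneficial_loci
  ben_names <- vapply(ben, `[[`, "", "name")
  mu_b <- stats::setNames(vapply(ben, `[[`, 0, "mu_b"), ben_names)
  s_d <- stats::setNames(vapply(config$resistance_loci, `[[`, 0, "s_d"),
                         vapply(config$resistance_loci, `[[`, "", "name"))
  s_draws <- matrix(NA_real_, config$n_hosts, length(ben),
                    dimnames = list(NULL, ben_names))
  traj <- list(); plates <- list()
  for (h in seq_len(config$n_hosts)) {
    mouse <- sprintf("%s_%02d", config$host_genotype, h)
    res <- with_seed(derive_seed(config$seed, paste0("host", h)), {
      s_hour <- vapply(ben, function(b)
        stats::rnorm(1, b$s_mean_per_hour, b$s_sd_per_hour), numeric(1))
      s_gen <- stats::setNames(s_hour * config$gen_time_min / 60, ben_names)
      snaps <- wf_engine(initial_class_table(config), n_gens,
                         config$pop_size, as.list(s_gen), as.list(s_d),
                         mu_b, config$resistance_loci, config$mode,
                         record_at = sample_gens, class_cap = config$class_cap)
      plate_h <- lapply(seq_along(sample_gens), function(k) {
        g <- sample_gens[k]
        st <- snaps[[as.character(g)]]
        pc <- sample_plate(st, depth = config$plate_depth,
                           selective_depth = config$selective_depth,
                           antibiotics = names(s_d),
                           phenotype_locus = config$phenotype_locus)
        cbind(mouse_id = mouse, host = config$host_genotype,
              day = sample_days[k], pc)
      })
      traj_h <- lapply(seq_along(sample_gens), function(k) {
        g <- sample_gens[k]
        st <- snaps[[as.character(g)]]
        data.frame(mouse_id = mouse, host = config$host_genotype,
                   day = sample_days[k], gen = g,
                   time_h = g * config$gen_time_min / 60,
                   marker = st$marker, ben = st$ben, res = st$res,
                   count = st$count, freq = st$count / sum(st$count),
                   stringsAsFactors = FALSE)
      })
      list(s_hour = s_hour, plates = do.call(rbind, plate_h),
           traj = do.call(rbind, traj_h))
    })
    if (length(ben)) s_draws[h, ] <- res$s_hour
    traj[[h]] <- res$traj
    plates[[h]] <- res$plates
  }
  structure(list(config = config, s_draws = s_draws,
                 trajectories = do.call(rbind, traj),
                 plate_counts = do.call(rbind, plates)),
            class = "sim_output")
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf("Within-host simulation: %d %s host(s), %g days, pop %g (%s)\n",
              x$config$n_hosts, x$config$host_genotype, x$config$days,
              x$config$pop_size, x$config$mode))
  cat(sprintf("  %d trajectory rows, %d plate-count rows\n",
              nrow(x$trajectories), nrow(x$plate_counts)))
  invisible(x)
}

#' Sample a plate count from a population state
#'
#' Draws the colony counts a daily plating experiment would record: a
#' multinomial draw of `depth` colonies split by fluorescent marker and
#' (independently) by phenotype, plus, for each antibiotic, a draw from a
#' selective plate with a much larger effective depth so that rare resistant
#' classes at mutation-selection balance are observable.
#'
#' @param state A class-abundance data.frame with columns `marker`, `ben`,
#'   `res`, `count` (as stored in `sim_output$trajectories` snapshots).
#' @param depth Colonies counted on the non-selective plate (>= 1).
#' @param selective_depth Effective cells plated on each selective plate.
#' @param antibiotics Character vector of antibiotic names to plate for
#'   (default: all present in `state`).
#' @param phenotype_locus Locus whose carriers score phenotype-negative.
#' @param seed Optional seed; by default the current RNG stream is used.
#' @return A data.frame with columns `category`, `count`, `depth`. Categories
#'   are `yfp`/`cfp`, `gat_neg`/`gat_pos` (when a phenotype locus is given)
#'   and `<antibiotic>_resistant`.
#' @export
sample_plate <- function(state, depth, selective_depth = 1e7,
                         antibiotics = NULL, phenotype_locus = "gat",
                         seed = NULL) {
  check_number(depth, "depth", lower = 1)
  if (!nrow(state) || sum(state$count) <= 0)
    stop("cannot plate an empty population", call. = FALSE)
  if (!is.null(seed)) return(with_seed(seed, sample_plate(
    state, depth, selective_depth, antibiotics, phenotype_locus)))
  freq <- state$count / sum(state$count)
  p_yfp <- sum(freq[state$marker == "YFP"])
  yfp <- stats::rbinom(1L, depth, p_yfp)
  out <- data.frame(category = c("yfp", "cfp"), count = c(yfp, depth - yfp),
                    depth = depth, stringsAsFactors = FALSE)
  if (!is.null(phenotype_locus) && nzchar(phenotype_locus)) {
    p_neg <- sum(freq[vapply(state$ben, set_has, TRUE, el = phenotype_locus)])
    neg <- stats::rbinom(1L, depth, p_neg)
    out <- rbind(out, data.frame(category = c("gat_neg", "gat_pos"),
                                 count = c(neg, depth - neg), depth = depth,
                                 stringsAsFactors = FALSE))
  }
  if (is.null(antibiotics))
    antibiotics <- unique(unlist(lapply(state$res, res_antibiotics)))
  for (a in antibiotics) {
    p_res <- sum(freq[vapply(state$res, function(s) a %in% res_antibiotics(s), TRUE)])
    r <- stats::rbinom(1L, as.integer(selective_depth), p_res)
    out <- rbind(out, data.frame(category = paste0(tolower(a), "_resistant"),
                                 count = r, depth = selective_depth,
                                 stringsAsFactors = FALSE))
  }
  out
}
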