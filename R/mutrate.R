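# Mutation- and transposition-frequency estimation at mutation-selection
# balance, with the rank-based host comparison.

#' Log10 resistant fraction from a plating record
#'
#' The fraction of resistant cells is the ratio of the scaled resistant and
#' total counts, each corrected by its dilution and plated volume. Days with
#' zero resistant colonies are detection-censored (no finite log exists) and
#' flagged rather than treated as zero.
#'
#' @param resistant Resistant colony count (>= 0).
#' @param total Total colony count (> 0).
#' @param dilution_r,vol_r Dilution factor and plated volume of the
#'   selective plate (defaults 1).
#' @param dilution_t,vol_t Dilution factor and plated volume of the total
#'   count (defaults 1).
#' @return A list with `log10_fraction` (NA when censored) and `censored`.
#' @examples
#' resistant_fraction(10, 1e7)      # -6
#' resistant_fraction(0, 1e7)       # censored
#' @export
resistant_fraction <- function(resistant, total, dilution_r = 1, vol_r = 1,
                               dilution_t = 1, vol_t = 1) {
  check_number(resistant, "resistant", lower = 0)
  check_number(total, "total", lower = 0, strict_lower = TRUE)
  for (v in c(dilution_r, vol_r, dilution_t, vol_t))
    check_number(v, "dilution/volume", lower = 0, strict_lower = TRUE)
  if (resistant == 0)
    return(list(log10_fraction = NA_real_, censored = TRUE))
  frac <- (resistant / dilution_r / vol_r) / (total / dilution_t / vol_t)
  if (frac > 1)
    stop("scaled resistant fraction exceeds 1; check dilution fields",
         call. = FALSE)
  list(log10_fraction = log10(frac), censored = FALSE)
}

#' Summarize resistance frequencies into a mutation-rate estimate
#'
#' Hierarchical average of log10 resistant fractions: daily fractions are
#' log10-transformed, averaged within each mouse, and the per-mouse means
#' are averaged (unweighted) across mice. Censored (zero-resistant) days are
#' excluded, or pseudo-counted with +1 resistant colony when
#' `pseudo_count = TRUE`. If a per-generation cost `s_d` is supplied the
#' balance is inverted to a model-dependent mutation rate
#' `mu = 10^mean * s_d`.
#'
#' @param records Data.frame for one antibiotic with columns `mouse_id`,
#'   `resistant`, `total` and optionally `dilution_r`, `dilution_t`,
#'   `vol_r`, `vol_t`.
#' @param s_d Optional per-generation selective cost for the mu inversion.
#' @param pseudo_count Replace zero resistant counts by 1 instead of
#'   censoring (sensitivity analysis; default `FALSE`).
#' @return A `mutation_rate_estimate` list: `mean_log10_frequency`,
#'   `per_mouse` (named vector), `n_mice`, `n_censored`, and `mu` when
#'   `s_d` was given.
#' @export
summarize_frequency <- function(records, s_d = NULL, pseudo_count = FALSE) {
  stopifnot(all(c("mouse_id", "resistant", "total") %in% names(records)))
  g <- function(col, def) if (col %in% names(records)) records[[col]] else
    rep(def, nrow(records))
  res <- records$resistant
  if (pseudo_count) res[res == 0] <- 1
  lf <- vapply(seq_len(nrow(records)), function(i) {
    r <- resistant_fraction(res[i], records$total[i],
                            g("dilution_r", 1)[i], g("vol_r", 1)[i],
                            g("dilution_t", 1)[i], g("vol_t", 1)[i])
    if (r$censored) NA_real_ else r$log10_fraction
  }, numeric(1))
  n_cens <- sum(is.na(lf))
  if (all(is.na(lf)))
    stop("all records are censored (zero resistant counts)", call. = FALSE)
  per_mouse <- tapply(lf, records$mouse_id, mean, na.rm = TRUE)
  per_mouse <- per_mouse[!is.nan(per_mouse)]
  est <- list(mean_log10_frequency = mean(per_mouse),
              per_mouse = per_mouse, n_mice = length(per_mouse),
              n_censored = n_cens,
              antibiotic = if ("antibiotic" %in% names(records))
                records$antibiotic[1] else NA_character_)
  if (!is.null(s_d)) {
    check_number(s_d, "s_d", lower = 0, strict_lower = TRUE)
    est$mu <- 10^est$mean_log10_frequency * s_d
  }
  structure(est, class = "mutation_rate_estimate")
}

#' @export
print.mutation_rate_estimate <- function(x, ...) {
  cat(sprintf("mean log10 resistant fraction: %.3f (%d mice, %d censored day(s))\n",
              x$mean_log10_frequency, x$n_mice, x$n_censored))
  if (!is.null(x$mu))
    cat(sprintf("implied mutation rate at balance: %.3g per generation\n", x$mu))
  invisible(x)
}

#' Transposition frequency from typed resistant clones
#'
#' Scales a resistance-frequency estimate by the fraction of typed resistant
#' clones whose resistance is caused by an IS insertion, yielding the log10
#' transposition frequency. When none of the typed clones carries an
#' insertion the estimate is censored and the bound implied by 1/n_typed is
#' reported.
#'
#' @param n_is Typed clones carrying an IS insertion (0 <= n_is <= n_typed).
#' @param n_typed Total typed clones (>= 1).
#' @param est A `mutation_rate_estimate` (or its `mean_log10_frequency`).
#' @return A list with `log10_frequency` (NA when censored), `fraction_is`,
#'   `censored` and, when censored, `bound` (the log10 frequency implied by
#'   a single insertion among `n_typed`).
#' @examples
#' transposition_frequency(11, 50, -5.65)  # -5.65 + log10(0.22)
#' @export
transposition_frequency <- function(n_is, n_typed, est) {
  check_number(n_typed, "n_typed", lower = 1)
  check_number(n_is, "n_is", lower = 0, upper = n_typed)
  base <- if (inherits(est, "mutation_rate_estimate"))
    est$mean_log10_frequency else est
  check_number(base, "est")
  if (n_is == 0)
    return(list(log10_frequency = NA_real_, fraction_is = 0, censored = TRUE,
                bound = base + log10(1 / n_typed)))
  list(log10_frequency = base + log10(n_is / n_typed),
       fraction_is = n_is / n_typed, censored = FALSE)
}

#' Mann-Whitney rank-sum test
#'
#' Rank-sum test with midrank ties. The reported statistic `W` is the rank
#' sum of the first sample. The p-value is exact (full null distribution of
#' the rank sum over all group assignments, computed by a generating-
#' function recursion that handles ties) when both groups have n <= 12, and
#' a tie-corrected normal approximation with continuity correction
#' otherwise; `exact` can force either mode.
#'
#' @param a,b Numeric vectors (non-empty).
#' @param exact `NA` (auto), `TRUE` or `FALSE`.
#' @return A `stat_test` with `statistic = "W"`.
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))  # exact two-sided p = 1/3
#' @export
mann_whitney <- function(a, b, exact = NA) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  W <- sum(r[seq_len(n1)])
  use_exact <- if (is.na(exact)) n1 <= 12 && n2 <= 12 else isTRUE(exact)
  if (use_exact) {
    p <- ranksum_exact_p(r, n1, W)
    method <- "exact"
  } else {
    mu <- n1 * (N + 1) / 2
    ties <- table(r)
    sig2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sig2 <= 0) return(stat_test("W", W, 1, method = "normal"))
    z <- (abs(W - mu) - 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-max(0, z)))
    method <- "normal"
  }
  stat_test("W", W, p, n = c(n1, n2), method = method)
}

# Exact null distribution of the rank sum of a size-n1 subset of the pooled
# midranks: dynamic programme over 2x the midranks (always integers).
ranksum_exact_p <- function(r, n1, W) {
  r2 <- as.integer(round(2 * r))
  maxsum <- sum(r2)
  # dp[j+1, s+1] = number of j-subsets with doubled rank sum s
  dp <- matrix(0, n1 + 1L, maxsum + 1L)
  dp[1L, 1L] <- 1
  for (v in r2) {
    jmax <- n1
    for (j in seq.int(jmax, 1L)) {
      src <- dp[j, seq_len(maxsum + 1L - v)]
      nz <- which(src != 0)
      if (length(nz))
        dp[j + 1L, nz + v] <- dp[j + 1L, nz + v] + src[nz]
    }
  }
  dist <- dp[n1 + 1L, ]
  tot <- sum(dist)
  w2 <- as.integer(round(2 * W))
  lower <- sum(dist[seq_len(w2 + 1L)]) / tot
  upper <- sum(dist[seq.int(w2 + 1L, maxsum + 1L)]) / tot
  min(1, 2 * min(lower, upper))
}
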