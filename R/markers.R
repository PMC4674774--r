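# Fluorescent-marker trajectories: frequency estimates with sampling error,
# early-divergence (sweep) detection by log-ratio regression, and the
# cross-host comparison of diverged-line counts.

#' Estimate a marker frequency from colony counts
#'
#' @param count_a Colonies of the focal class (e.g. YFP).
#' @param count_b Colonies of the other class.
#' @return A `frequency_estimate` list with `p = a/(a+b)`, `n = a+b` and the
#'   sampling standard error `sem = sqrt(p(1-p)/n)` for interior
#'   frequencies; for the degenerate cases p = 0 or 1 the rule `sem = 1/n`
#'   is used so that fixed classes still carry a finite uncertainty.
#' @examples
#' estimate_frequency(50, 50)   # p 0.5, sem 0.05
#' estimate_frequency(0, 80)    # p 0, sem 1/80
#' @export
estimate_frequency <- function(count_a, count_b) {
  check_number(count_a, "count_a", lower = 0)
  check_number(count_b, "count_b", lower = 0)
  n <- count_a + count_b
  if (n < 1) stop("total colony count must be >= 1", call. = FALSE)
  p <- count_a / n
  sem <- if (p > 0 && p < 1) sqrt(p * (1 - p) / n) else 1 / n
  structure(list(p = p, n = n, sem = sem), class = "frequency_estimate")
}

#' @export
print.frequency_estimate <- function(x, ...) {
  cat(sprintf("p = %.4g (n = %g, +/- 2 s.e.m. = %.4g)\n", x$p, x$n, 2 * x$sem))
  invisible(x)
}

#' Test a marker trajectory for early divergence
#'
#' Regresses `ln(YFP/CFP)` on day over a day window (default the first six
#' days of colonization) and tests the slope against zero; a significant
#' slope flags a selective sweep carrying one marker background. Days where
#' either marker count is zero are excluded with a warning (optionally a
#' +0.5 pseudo-count is applied instead).
#'
#' @param traj Data.frame with columns `day`, `yfp`, `cfp` for one line.
#' @param day_window Numeric `[first, last]` day window (default `c(1, 6)`).
#' @param alpha Significance level for the diverged flag (default 0.05).
#' @param pseudo_count If `TRUE`, add 0.5 to zero counts instead of dropping
#'   those days.
#' @return A `stat_test` with `statistic = "slope"`, the OLS slope as
#'   `value`, the two-sided t-test `p_value`, plus `n` (days used),
#'   `diverged` (logical) and `evaluable`. With fewer than 4 usable days the
#'   result is not evaluable (`p_value` and `diverged` are `NA`), which is
#'   distinct from non-diverged.
#' @export
divergence_test <- function(traj, day_window = c(1, 6), alpha = 0.05,
                            pseudo_count = FALSE) {
  stopifnot(all(c("day", "yfp", "cfp") %in% names(traj)))
  d <- traj[traj$day >= day_window[1] & traj$day <= day_window[2], , drop = FALSE]
  if (pseudo_count) {
    z <- d$yfp == 0 | d$cfp == 0
    d$yfp[z] <- d$yfp[z] + 0.5
    d$cfp[z] <- d$cfp[z] + 0.5
  }
  zero <- d$yfp <= 0 | d$cfp <= 0
  if (any(zero)) {
    warning(sprintf("%d day(s) with a zero marker count excluded from the log-ratio regression",
                    sum(zero)), call. = FALSE)
    d <- d[!zero, , drop = FALSE]
  }
  if (nrow(d) < 4)
    return(stat_test("slope", NA_real_, NA_real_, n = nrow(d),
                     diverged = NA, evaluable = FALSE))
  y <- log(d$yfp / d$cfp)
  fit <- stats::lm(y ~ d$day)
  slope <- unname(stats::coef(fit)[2])
  rss <- sum(stats::residuals(fit)^2)
  if (rss < 1e-12 * max(1, sum(y^2))) {
    # numerically perfect fit: zero slope cannot diverge, a nonzero exact
    # line is machine-limited significant
    p <- if (abs(slope) < 1e-12) 1 else 0
  } else {
    p <- summary(fit)$coefficients[2, 4]
  }
  stat_test("slope", slope, p, n = nrow(d), diverged = p < alpha,
            evaluable = TRUE)
}

#' Divergence summary over a cohort of lines
#'
#' Applies [divergence_test()] to each line of a marker-count table.
#'
#' @param counts Data.frame with columns `mouse_id`, `host`, `day`, `yfp`,
#'   `cfp` (the marker dialect of the simulated plate counts).
#' @param day_window,alpha,pseudo_count Passed to [divergence_test()].
#' @return A data.frame with one row per line: `mouse_id`, `host`, `slope`,
#'   `p_value`, `diverged`, `evaluable`, `n_days`.
#' @export
divergence_summary <- function(counts, day_window = c(1, 6), alpha = 0.05,
                               pseudo_count = FALSE) {
  stopifnot(all(c("mouse_id", "day", "yfp", "cfp") %in% names(counts)))
  ids <- unique(counts$mouse_id)
  out <- lapply(ids, function(m) {
    d <- counts[counts$mouse_id == m, , drop = FALSE]
    r <- divergence_test(d, day_window, alpha, pseudo_count)
    data.frame(mouse_id = m,
               host = if ("host" %in% names(d)) d$host[1] else NA_character_,
               slope = r$value, p_value = r$p_value, diverged = r$diverged,
               evaluable = r$evaluable, n_days = r$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Compare diverged-line counts between two host groups
#'
#' Conditional binomial test: given `K = k1 + k2` diverged lines in total,
#' the number falling in group 1 is `Binomial(K, n1/(n1+n2))` under the null
#' of equal divergence rates; the two-sided p doubles the smaller tail
#' (capped at 1). With `fisher = TRUE`, Fisher's exact test on the 2x2
#' table is returned instead.
#'
#' @param k1,n1 Diverged and total lines in group 1.
#' @param k2,n2 Diverged and total lines in group 2.
#' @param fisher Use Fisher's exact test instead (default `FALSE`).
#' @return A `stat_test` with the observed `k1` as statistic.
#' @examples
#' compare_diverged_counts(10, 15, 3, 15)
#' @export
compare_diverged_counts <- function(k1, n1, k2, n2, fisher = FALSE) {
  for (v in list(c(k1, n1), c(k2, n2)))
    if (v[1] < 0 || v[1] > v[2]) stop_invalid("need 0 <= k <= n in each group")
  if (fisher) {
    ft <- stats::fisher.test(matrix(c(k1, n1 - k1, k2, n2 - k2), 2))
    return(stat_test("odds_ratio", unname(ft$estimate), ft$p.value,
                     method = "fisher"))
  }
  K <- k1 + k2
  if (K == 0) return(stat_test("k1", 0, 1, method = "conditional_binomial"))
  pr <- n1 / (n1 + n2)
  lower <- stats::pbinom(k1, K, pr)
  upper <- 1 - stats::pbinom(k1 - 1, K, pr)
  stat_test("k1", k1, min(1, 2 * min(lower, upper)),
            method = "conditional_binomial", K = K, prob = pr)
}
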