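# Selection-coefficient estimation from in vivo competition assays, and the
# variance / ANOVA comparisons across host groups.

#' Estimate a selection coefficient from a competition series
#'
#' The per-hour selective advantage of the mutant is the OLS slope of
#' `ln(mutant/reference)` on time in hours over the course of the
#' competition. Time points where either competitor has a zero count carry
#' no usable log-ratio and are dropped with a warning.
#'
#' @param series Data.frame with columns `time_h`, `mutant`, `reference`
#'   (one host); a `day` column is accepted instead of `time_h` and
#'   converted at 24 h/day.
#' @return A `competition_result` list: `s_per_hour` (slope), `intercept`,
#'   `slope_se`, `n_points`.
#' @examples
#' d <- data.frame(time_h = c(0, 24, 48, 72),
#'                 mutant = c(300, 350, 420, 480),
#'                 reference = c(300, 250, 180, 120))
#' estimate_selection_coefficient(d)
#' @export
estimate_selection_coefficient <- function(series) {
  if (!"time_h" %in% names(series) && "day" %in% names(series))
    series$time_h <- series$day * 24
  stopifnot(all(c("time_h", "mutant", "reference") %in% names(series)))
  if (is.unsorted(series$time_h, strictly = TRUE))
    stop_invalid("time points must be strictly increasing")
  keep <- series$mutant > 0 & series$reference > 0
  if (any(!keep))
    warning(sprintf("%d time point(s) with a zero count dropped", sum(!keep)),
            call. = FALSE)
  d <- series[keep, , drop = FALSE]
  if (nrow(d) < 3)
    stop("need at least 3 time points with both competitors present",
         call. = FALSE)
  fit <- stats::lm(log(mutant / reference) ~ time_h, data = d)
  cf <- summary(fit)$coefficients
  structure(list(s_per_hour = unname(cf[2, 1]), intercept = unname(cf[1, 1]),
                 slope_se = unname(cf[2, 2]), n_points = nrow(d)),
            class = "competition_result")
}

#' @export
print.competition_result <- function(x, ...) {
  cat(sprintf("s = %.4g per hour (se %.3g, %d time points)\n",
              x$s_per_hour, x$slope_se, x$n_points))
  invisible(x)
}

#' Per-host selection coefficients over a competition table
#'
#' @param tbl Data.frame with columns `mouse_id`, `time_h`, `mutant`,
#'   `reference` (and optionally `host`, `housing`).
#' @return A data.frame with one row per host: `mouse_id`, `host`,
#'   `housing`, `s_per_hour`, `slope_se`, `n_points`.
#' @export
competition_summary <- function(tbl) {
  stopifnot(all(c("mouse_id", "mutant", "reference") %in% names(tbl)))
  out <- lapply(unique(tbl$mouse_id), function(m) {
    d <- tbl[tbl$mouse_id == m, , drop = FALSE]
    r <- estimate_selection_coefficient(d)
    data.frame(mouse_id = m,
               host = if ("host" %in% names(d)) d$host[1] else NA_character_,
               housing = if ("housing" %in% names(d)) d$housing[1] else NA_character_,
               s_per_hour = r$s_per_hour, slope_se = r$slope_se,
               n_points = r$n_points, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Two-sided F test for equality of variances of selection coefficients
#'
#' `F = var(a)/var(b)` with sample variances (denominator n-1); the
#' two-sided p doubles the smaller F tail, capped at 1.
#'
#' @param s_a,s_b Numeric vectors of per-host selection coefficients
#'   (each length >= 2).
#' @return A `stat_test` with `statistic = "F"` and degrees of freedom.
#' @examples
#' variance_ratio_test(c(1, 2, 3), c(2, 4, 6))  # F 0.25, p 0.4
#' @export
variance_ratio_test <- function(s_a, s_b) {
  stopifnot(length(s_a) >= 2, length(s_b) >= 2)
  vb <- stats::var(s_b)
  if (vb == 0) stop("zero variance in the denominator group", call. = FALSE)
  f <- stats::var(s_a) / vb
  df1 <- length(s_a) - 1L; df2 <- length(s_b) - 1L
  lower <- stats::pf(f, df1, df2)
  p <- min(1, 2 * min(lower, 1 - lower))
  stat_test("F", f, p, df = c(df1, df2))
}

#' ANOVA over groups of selection coefficients
#'
#' One-way ANOVA with Tukey HSD post hoc pairwise comparisons (studentized
#' range), or, when a second factor is supplied, a two-way ANOVA with
#' interaction (used e.g. to test host immune status x microbiota).
#'
#' @param values Numeric vector of selection coefficients.
#' @param group Factor (or coercible) of group labels, e.g. host genotype.
#' @param group2 Optional second factor; triggers the two-way layout, which
#'   must be a complete factorial (every cell populated).
#' @return An `anova_result` list: `table` (data.frame of terms with F, df,
#'   p) and, for the one-way case, `tukey` (data.frame of pairwise adjusted
#'   p-values).
#' @examples
#' group_anova(c(1, 2, 3, 2, 3, 4), rep(c("a", "b"), each = 3))
#' @export
group_anova <- function(values, group, group2 = NULL) {
  group <- factor(group)
  stopifnot(length(values) == length(group), nlevels(group) >= 2)
  cnt <- table(group)
  if (any(cnt < 2)) stop_invalid("every group needs n >= 2")
  if (is.null(group2)) {
    wvar <- tapply(values, group, stats::var)
    if (all(wvar == 0))
      stop("zero within-group variance: the residual mean square is 0 and the F statistic is undefined",
           call. = FALSE)
    fit <- stats::aov(values ~ group)
    at <- summary(fit)[[1]]
    tab <- data.frame(term = trimws(rownames(at)), df = at$Df,
                      sum_sq = at$`Sum Sq`, F = at$`F value`,
                      p_value = at$`Pr(>F)`, stringsAsFactors = FALSE)
    tk <- stats::TukeyHSD(fit)$group
    tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                        lwr = tk[, "lwr"], upr = tk[, "upr"],
                        p_adj = tk[, "p adj"], stringsAsFactors = FALSE)
    rownames(tukey) <- NULL
    return(structure(list(table = tab, tukey = tukey, design = "one-way"),
                     class = "anova_result"))
  }
  group2 <- factor(group2)
  stopifnot(length(group2) == length(values))
  cells <- table(group, group2)
  if (any(cells == 0)) {
    idx <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop_invalid("two-way layout is incomplete: empty cell (",
                 levels(group)[idx[1]], ", ", levels(group2)[idx[2]], ")")
  }
  fit <- stats::aov(values ~ group * group2)
  at <- summary(fit)[[1]]
  tab <- data.frame(term = trimws(rownames(at)), df = at$Df,
                    sum_sq = at$`Sum Sq`, F = at$`F value`,
                    p_value = at$`Pr(>F)`, stringsAsFactors = FALSE)
  structure(list(table = tab, tukey = NULL, design = "two-way"),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("%s ANOVA\n", x$design))
  print(x$table, row.names = FALSE)
  if (!is.null(x$tukey)) {
    cat("Tukey HSD:\n")
    print(x$tukey, row.names = FALSE)
  }
  invisible(x)
}
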