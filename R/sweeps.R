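# Sweep dynamics of the gat-negative phenotype: a binomial logistic fit
# with a shared initial frequency across host genotypes and cluster-robust
# (sandwich) standard errors for the host-genotype contrast in sweep speed.

#' Fit the phenotype sweep across host genotypes
#'
#' Binomial maximum-likelihood fit of
#' `logit(p) = beta0 + (beta1 + beta2 * I[WT]) * day`
#' on phenotype counts weighted by the colonies scored, with the initial
#' frequency `beta0` constrained to a single shared value across host
#' genotypes. Mouse-level dependence between repeated samples is handled by
#' cluster-robust (sandwich) standard errors clustered on mouse. The
#' reported `z = beta2 / se(beta2)` tests whether the reference-vs-other
#' genotype sweep speeds differ; with the default coding (WT as the
#' non-reference level) `z > 0` means WT sweeps faster.
#'
#' @param series Data.frame with columns `mouse_id`, `host`, `day`,
#'   `gat_neg`, `total`.
#' @param reference Optional host genotype to use as the reference level
#'   (default: the first non-WT level present).
#' @return A `sweep_fit` list: `coefficients`, `se_naive`, `se_robust`,
#'   `z` and `p_value` for the genotype-by-day interaction (NA when only
#'   one genotype is present), `separation` flag, and the fitted `glm`.
#' @export
fit_sweep <- function(series, reference = NULL) {
  stopifnot(all(c("mouse_id", "host", "day", "gat_neg", "total") %in%
                  names(series)))
  if (any(series$gat_neg < 0 | series$gat_neg > series$total))
    stop_invalid("need 0 <= gat_neg <= total")
  if (any(series$total < 1)) stop_invalid("total counts must be >= 1")
  hosts <- unique(series$host)
  for (h in hosts)
    if (length(unique(series$day[series$host == h])) < 2)
      stop_invalid("each host genotype needs >= 2 time points")
  if (is.null(reference))
    reference <- if (any(hosts != "WT")) hosts[hosts != "WT"][1] else hosts[1]
  series$host <- stats::relevel(factor(series$host), ref = reference)
  fml <- if (length(hosts) > 1)
    cbind(gat_neg, total - gat_neg) ~ day + day:host
  else
    cbind(gat_neg, total - gat_neg) ~ day
  fit <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(), data = series,
               control = stats::glm.control(maxit = 100)),
    # fractional "counts" are legitimate here: proportions weighted by the
    # colonies scored
    warning = function(w) {
      if (grepl("non-integer counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (!fit$converged)
    stop("binomial sweep fit did not converge within 100 IRLS iterations; ",
         "deviance ", format(fit$deviance), call. = FALSE)
  separation <- any(abs(stats::coef(fit)) > 15)
  vc_naive <- stats::vcov(fit)
  vc_robust <- sandwich::vcovCL(fit, cluster = factor(series$mouse_id))
  cf <- stats::coef(fit)
  se_n <- sqrt(diag(vc_naive)); se_r <- sqrt(diag(vc_robust))
  int_idx <- grep("^day:host", names(cf))
  z <- p <- NA_real_
  if (length(int_idx) >= 1) {
    z <- unname(cf[int_idx[1]] / se_r[int_idx[1]])
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(coefficients = cf, se_naive = se_n, se_robust = se_r,
                 z = z, p_value = p, separation = separation,
                 reference = reference, fit = fit),
            class = "sweep_fit")
}

#' @export
print.sweep_fit <- function(x, ...) {
  cat("Binomial sweep fit (shared initial frequency, cluster-robust se)\n")
  tab <- data.frame(estimate = x$coefficients, se_naive = x$se_naive,
                    se_robust = x$se_robust)
  print(round(tab, 5))
  if (!is.na(x$z))
    cat(sprintf("genotype x day interaction: z = %.3f, p = %.3g (reference %s)\n",
                x$z, x$p_value, x$reference))
  if (x$separation)
    cat("warning: coefficients suggest complete or quasi-complete separation\n")
  invisible(x)
}

#' Across-mouse variance of phenotype frequency per day
#'
#' Sample variance, across mice, of the per-mouse phenotype frequency at
#' each sampling day. The collapse of this variance to zero marks the
#' completion of the sweep.
#'
#' @param series Data.frame with columns `mouse_id`, `day`, `gat_neg`,
#'   `total`.
#' @return A data.frame with columns `day`, `n_mice`, `variance` (NA where
#'   fewer than 2 mice were sampled).
#' @examples
#' d <- data.frame(mouse_id = rep(1:3, 2), day = rep(1:2, each = 3),
#'                 gat_neg = c(20, 40, 60, 90, 95, 100), total = 100)
#' phenotype_variance(d)
#' @export
phenotype_variance <- function(series) {
  stopifnot(all(c("mouse_id", "day", "gat_neg", "total") %in% names(series)))
  freq <- series$gat_neg / series$total
  days <- sort(unique(series$day))
  out <- lapply(days, function(d) {
    f <- freq[series$day == d]
    data.frame(day = d, n_mice = length(f),
               variance = if (length(f) >= 2) stats::var(f) else NA_real_)
  })
  do.call(rbind, out)
}
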