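# Independent oracles used to freeze expected values: closed-form OLS,
# brute-force enumeration of exact tests, and hand-computed ANOVA sums of
# squares. These deliberately avoid the code paths they check.

# Closed-form simple linear regression with the t-test on the slope.
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  rss <- sum((y - intercept - slope * x)^2)
  se <- sqrt(rss / (n - 2) / sxx)
  t <- slope / se
  list(slope = slope, intercept = intercept, se = se,
       p = 2 * stats::pt(-abs(t), n - 2))
}

# Binomial pmf by Pascal-style recursion (no pbinom/dbinom).
binom_pmf_oracle <- function(K, pr) {
  pmf <- 1
  for (i in seq_len(K)) {
    pmf <- c(pmf, 0) * (1 - pr) + c(0, pmf) * pr
  }
  pmf  # length K+1, index k+1 = P(X = k)
}

# Conditional binomial two-sided p by enumeration of the pmf.
cond_binom_oracle <- function(k1, n1, k2, n2) {
  K <- k1 + k2
  if (K == 0) return(1)
  pmf <- binom_pmf_oracle(K, n1 / (n1 + n2))
  lower <- sum(pmf[seq_len(k1 + 1)])
  upper <- sum(pmf[seq.int(k1 + 1, K + 1)])
  min(1, 2 * min(lower, upper))
}

# Hypergeometric tails by explicit enumeration of hit placements among the
# n1 + n2 populations (memberships via combn); feasible for small totals.
hyper_oracle <- function(k1, n1, k2, n2) {
  K <- k1 + k2
  if (K == 0) return(list(one_sided = 1, two_sided = 1))
  placements <- utils::combn(n1 + n2, K)
  in_g1 <- colSums(placements <= n1)
  upper <- mean(in_g1 >= k1)
  lower <- mean(in_g1 <= k1)
  list(one_sided = min(1, upper), two_sided = min(1, 2 * min(lower, upper)))
}

# Rank-sum two-sided p by enumeration of all group assignments.
mw_perm_oracle <- function(a, b) {
  n1 <- length(a); N <- n1 + length(b)
  r <- rank(c(a, b))
  W <- sum(r[seq_len(n1)])
  sums <- apply(utils::combn(N, n1), 2, function(idx) sum(r[idx]))
  lower <- mean(sums <= W + 1e-9)
  upper <- mean(sums >= W - 1e-9)
  min(1, 2 * min(lower, upper))
}

# One-way ANOVA F and p from hand-computed sums of squares.
anova_oracle <- function(values, group) {
  group <- factor(group)
  gm <- mean(values)
  means <- tapply(values, group, mean)
  ns <- tabulate(group)
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((values - means[group])^2)
  df1 <- nlevels(group) - 1
  df2 <- length(values) - nlevels(group)
  f <- (ssb / df1) / (ssw / df2)
  list(F = f, df = c(df1, df2), p = stats::pf(f, df1, df2, lower.tail = FALSE),
       ssb = ssb, ssw = ssw)
}

# Haplotype frequency vector (named by label) from a simulated population's
# final-day class abundances.
class_freq_vector <- function(sim, mouse) {
  tr <- sim$trajectories
  st <- tr[tr$mouse_id == mouse & tr$day == max(tr$day), ]
  agg <- tapply(st$freq, st$ben, sum)
  names(agg)[names(agg) == ""] <- "ancestral"
  agg <- agg / sum(agg)
  stats::setNames(as.numeric(agg), names(agg))
}
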