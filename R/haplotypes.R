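# Clone typing into haplotypes, clonal-interference detection, variant
# filtering and parallel-target calling, prevalence arithmetic, and the
# host-specificity test.

#' Default locus panel order for haplotype labels
#'
#' The fixed ordering used to canonicalize haplotype labels (the order in
#' which mutated loci are joined).
#' @return Character vector of locus names.
#' @export
haplotype_locus_order <- function() c("gat", "focA", "dcuB", "srlR")

#' Call a haplotype from a clone-typing record
#'
#' @param typing Named character vector (or list) of per-locus states, each
#'   `"present"`, `"absent"` or `"untyped"`.
#' @param locus_order Fixed locus order for the canonical label.
#' @return A `haplotype_call` list: `loci` (mutated loci), `label` (loci
#'   joined in panel order; `"ancestral"` when none), `untyped` (loci that
#'   could not be scored).
#' @examples
#' call_haplotype(c(gat = "present", focA = "present",
#'                  dcuB = "absent", srlR = "absent"))$label  # "gat+focA"
#' @export
call_haplotype <- function(typing, locus_order = haplotype_locus_order()) {
  typing <- unlist(typing)
  if (!length(typing) || is.null(names(typing)))
    stop_invalid("typing must be a named vector of per-locus states")
  bad <- setdiff(unique(typing), c("present", "absent", "untyped"))
  if (length(bad))
    stop_invalid("unknown typing state(s): ", paste(bad, collapse = ", "))
  untyped <- names(typing)[typing == "untyped"]
  if (length(untyped) == length(typing))
    stop("all loci untyped; no haplotype can be called", call. = FALSE)
  loci <- names(typing)[typing == "present"]
  ord <- c(intersect(locus_order, loci), sort(setdiff(loci, locus_order)))
  label <- if (length(ord)) paste(ord, collapse = "+") else "ancestral"
  structure(list(loci = ord, label = label, untyped = untyped),
            class = "haplotype_call")
}

#' Haplotype frequency table from a clone-typing table
#'
#' @param typing_tbl Data.frame with columns `mouse_id`, `clone`, `locus`,
#'   `state` (the clone-typing dialect).
#' @param locus_order Fixed locus order for labels.
#' @return A data.frame with columns `mouse_id`, `haplotype`, `n_clones`,
#'   `frequency` (frequencies sum to 1 within each mouse) — suitable for
#'   Muller-style plotting.
#' @export
haplotype_frequencies <- function(typing_tbl,
                                  locus_order = haplotype_locus_order()) {
  stopifnot(all(c("mouse_id", "clone", "locus", "state") %in%
                  names(typing_tbl)))
  out <- lapply(unique(typing_tbl$mouse_id), function(m) {
    d <- typing_tbl[typing_tbl$mouse_id == m, ]
    labels <- vapply(unique(d$clone), function(cl) {
      t <- d[d$clone == cl, ]
      call_haplotype(stats::setNames(t$state, t$locus), locus_order)$label
    }, character(1))
    tab <- table(labels)
    data.frame(mouse_id = m, haplotype = names(tab),
               n_clones = as.integer(tab),
               frequency = as.numeric(tab) / length(labels),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Detect clonal interference among haplotype frequencies
#'
#' Clonal interference is flagged when at least two haplotypes whose
#' mutated-locus sets are non-nested (neither contains the other, so the
#' clones must compete rather than descend from one another) each segregate
#' at or above the threshold frequency.
#'
#' @param freqs Named numeric vector of haplotype frequencies for one
#'   population; names are haplotype labels (`"ancestral"` or loci joined
#'   by `+`). Must sum to 1 within 0.01.
#' @param threshold Minimum frequency for a competing clone (default 0.10).
#' @return A list with `interference` (logical) and `pairs` (data.frame of
#'   competing haplotype pairs).
#' @examples
#' detect_clonal_interference(c("gat+focA" = 0.5, "gat+srlR" = 0.3,
#'                              gat = 0.2))$interference  # TRUE
#' @export
detect_clonal_interference <- function(freqs, threshold = 0.10) {
  if (is.null(names(freqs)) || any(!nzchar(names(freqs))))
    stop_invalid("freqs must be a named frequency vector")
  if (any(freqs < 0) || abs(sum(freqs) - 1) > 0.01)
    stop_invalid("frequencies must be non-negative and sum to 1 (+/- 0.01)")
  check_number(threshold, "threshold", lower = 0, upper = 1)
  lab <- names(freqs)[freqs >= threshold]
  sets <- lapply(lab, function(l)
    if (l == "ancestral") character(0) else split_set(l))
  pairs <- list()
  if (length(sets) >= 2) {
    for (i in seq_len(length(sets) - 1)) for (j in (i + 1):length(sets)) {
      nested <- all(sets[[i]] %in% sets[[j]]) || all(sets[[j]] %in% sets[[i]])
      if (!nested) pairs[[length(pairs) + 1]] <-
          data.frame(hap1 = lab[i], hap2 = lab[j], stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(hap1 = character(0), hap2 = character(0))
  list(interference = nrow(pairs) > 0, pairs = pairs)
}

#' Filter a population variant table by frequency
#'
#' Retains mutations segregating at or above the cutoff frequency
#' (inclusive boundary), the rule used to call high-frequency polymorphisms
#' from population resequencing.
#'
#' @param records Data.frame with a `frequency` column in `[0, 1]`.
#' @param min_freq Cutoff in `(0, 1)` (default 0.05).
#' @return The retained rows.
#' @export
filter_variants <- function(records, min_freq = 0.05) {
  check_number(min_freq, "min_freq", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  stopifnot("frequency" %in% names(records),
            all(records$frequency >= 0 & records$frequency <= 1))
  records[records$frequency >= min_freq, , drop = FALSE]
}

#' Call parallel targets of adaptation
#'
#' A target is parallel when it is mutated in at least `min_populations`
#' populations (pooled across host genotypes) and reaches at least
#' `min_peak_freq` in at least one of them.
#'
#' @param records Variant data.frame with columns `population`, `target`,
#'   `frequency` (already filtered to segregating mutations).
#' @param min_populations Minimum number of hit populations (default 2).
#' @param min_peak_freq Minimum peak frequency in some population
#'   (default 0.10).
#' @return A data.frame of parallel targets with `n_populations` and
#'   `peak_frequency`.
#' @export
parallel_targets <- function(records, min_populations = 2,
                             min_peak_freq = 0.10) {
  stopifnot(all(c("population", "target", "frequency") %in% names(records)))
  if (!nrow(records))
    return(data.frame(target = character(0), n_populations = integer(0),
                      peak_frequency = numeric(0)))
  npop <- tapply(records$population, records$target,
                 function(x) length(unique(x)))
  peak <- tapply(records$frequency, records$target, max)
  keep <- names(npop)[npop >= min_populations & peak >= min_peak_freq]
  out <- data.frame(target = keep,
                    n_populations = as.integer(npop[keep]),
                    peak_frequency = as.numeric(peak[keep]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(-out$n_populations, out$target), , drop = FALSE]
}

#' Prevalence of a target across populations of one host group
#'
#' Percent of populations hit, with the sampling standard error of a
#' proportion: `100 * sqrt(p(1-p)/n)` for interior proportions and the
#' degenerate rule `100/n` when all or none of the populations are hit (so
#' fixed proportions still carry a finite uncertainty).
#'
#' @param k Populations in which the target was found (0 <= k <= n).
#' @param n Total populations screened (> 0).
#' @return A list with `percent`, `sem_percent` and their integer-rounded
#'   report values `percent_rounded`, `sem_rounded`.
#' @examples
#' target_prevalence(9, 15)   # 60% +/- 13%
#' target_prevalence(14, 14)  # 100% +/- 7%
#' @export
target_prevalence <- function(k, n) {
  check_number(n, "n", lower = 1)
  check_number(k, "k", lower = 0, upper = n)
  p <- k / n
  sem <- if (p > 0 && p < 1) sqrt(p * (1 - p) / n) else 1 / n
  list(percent = 100 * p, sem_percent = 100 * sem,
       percent_rounded = round(100 * p), sem_rounded = round(100 * sem))
}

#' Prevalence table across targets and host groups
#'
#' Builds a report-style prevalence table (percent and +/- value per host
#' group, host-specificity p per target) from hit counts.
#'
#' @param hits Data.frame with columns `target`, `k1`, `n1`, `k2`, `n2`
#'   (hits and totals in the two host groups).
#' @param group_names Character length-2 labels for the groups.
#' @return A data.frame with percent/sem columns per group and the
#'   one- and two-sided host-specificity p-values.
#' @export
prevalence_table <- function(hits, group_names = c("WT", "RAG2KO")) {
  stopifnot(all(c("target", "k1", "n1", "k2", "n2") %in% names(hits)))
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    p1 <- target_prevalence(hits$k1[i], hits$n1[i])
    p2 <- target_prevalence(hits$k2[i], hits$n2[i])
    ht <- host_specificity_test(hits$k1[i], hits$n1[i],
                                hits$k2[i], hits$n2[i])
    d <- data.frame(target = hits$target[i],
                    g1_percent = p1$percent_rounded, g1_sem = p1$sem_rounded,
                    g2_percent = p2$percent_rounded, g2_sem = p2$sem_rounded,
                    p_one_sided = ht$p_value, p_two_sided = ht$p_two_sided,
                    stringsAsFactors = FALSE)
    names(d) <- c("target",
                  paste0(group_names[1], c("_percent", "_sem")),
                  paste0(group_names[2], c("_percent", "_sem")),
                  "p_one_sided", "p_two_sided")
    d
  })
  do.call(rbind, rows)
}

#' Exact host-specificity test for a parallel target
#'
#' Conditions on the total number of hit populations and asks how likely it
#' is, under random placement among the `n1 + n2` populations, that at
#' least `k1` of the hits fall in group 1 — an exact hypergeometric tail.
#' The one-sided tail (concentration in group 1) is the default report; a
#' two-sided value by doubling the smaller tail is also returned.
#'
#' @param k1,n1 Hit and total populations in group 1.
#' @param k2,n2 Hit and total populations in group 2.
#' @return A `stat_test` with `statistic = "k1"`, the one-sided tail as
#'   `p_value` and the doubled-tail `p_two_sided`.
#' @examples
#' host_specificity_test(7, 14, 0, 15)$p_value  # choose(14,7)/choose(29,7)
#' @export
host_specificity_test <- function(k1, n1, k2, n2) {
  for (v in list(c(k1, n1), c(k2, n2)))
    if (v[1] < 0 || v[1] > v[2]) stop_invalid("need 0 <= k <= n in each group")
  K <- k1 + k2
  if (K == 0)
    return(stat_test("k1", 0, 1, p_two_sided = 1, K = 0))
  upper <- sum(stats::dhyper(k1:min(K, n1), n1, n2, K))
  lower <- sum(stats::dhyper(max(0, K - n2):k1, n1, n2, K))
  stat_test("k1", k1, min(1, upper),
            p_two_sided = min(1, 2 * min(lower, upper)), K = K)
}
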