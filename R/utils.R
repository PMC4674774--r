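# Internal helpers: argument checking, seed substreams, tiny hashing.

stop_invalid <- function(...) {
  stop(structure(class = c("gutevolve_invalid", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid(name, " must be a single finite number")
  if (strict_lower && x <= lower)
    stop_invalid(name, " must be > ", lower)
  if (!strict_lower && x < lower)
    stop_invalid(name, " must be >= ", lower)
  if (strict_upper && x >= upper)
    stop_invalid(name, " must be < ", upper)
  if (!strict_upper && x > upper)
    stop_invalid(name, " must be <= ", upper)
  x
}

#' Derive a reproducible substream seed
#'
#' All randomness in the package flows from one root seed; each stage or host
#' draws from a named substream so that adding or reordering stages does not
#' perturb the others. The derived seed is a 31-bit integer obtained by mixing
#' the root seed with an FNV-1a hash of the stream name.
#'
#' @param root Integer root seed.
#' @param name Character stream name (e.g. `"host3"`, `"calibration"`).
#' @return A single integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @examples
#' derive_seed(42, "host1")
#' derive_seed(42, "host1") == derive_seed(42, "host1")
#' @export
derive_seed <- function(root, name) {
  stopifnot(is.numeric(root), length(root) == 1L, is.character(name))
  h <- fnv1a(paste0(name, ":", format(root, scientific = FALSE)))
  as.integer(h %% (2^31 - 1))
}

# 32-bit FNV-1a over the UTF-8 bytes of a string; returns a double in [0, 2^32).
fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(enc2utf8(x)))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor_dbl(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  h
}

# xor for doubles holding 32-bit unsigned values (bitwXor needs ints)
bitwXor_dbl <- function(a, b) {
  hi_a <- a %/% 65536; lo_a <- a %% 65536
  hi_b <- b %/% 65536; lo_b <- b %% 65536
  bitwXor(as.integer(hi_a), as.integer(hi_b)) * 65536 +
    bitwXor(as.integer(lo_a), as.integer(lo_b))
}

# Evaluate expr with a temporarily-seeded RNG, restoring the caller's state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Statistical test result container
#'
#' Light-weight container used by the package's hypothesis tests.
#'
#' @param statistic Character name of the statistic (e.g. `"F"`, `"W"`).
#' @param value Numeric statistic value.
#' @param p_value Two-sided p-value in `[0, 1]` (or `NA` for not-evaluable).
#' @param ... Further named fields (df, n, alternative p-values, flags).
#' @return An object of class `stat_test`.
#' @export
stat_test <- function(statistic, value, p_value, ...) {
  if (!is.na(p_value) && (p_value < 0 || p_value > 1))
    stop_invalid("p_value must lie in [0, 1]")
  structure(list(statistic = statistic, value = value, p_value = p_value, ...),
            class = "stat_test")
}

#' @export
print.stat_test <- function(x, ...) {
  cat(sprintf("%s = %.6g, p = %.4g\n", x$statistic, x$value, x$p_value))
  extras <- setdiff(names(x), c("statistic", "value", "p_value"))
  for (nm in extras) {
    v <- x[[nm]]
    if (is.atomic(v) && length(v) <= 4)
      cat(sprintf("  %s: %s\n", nm, paste(format(v), collapse = ", ")))
  }
  invisible(x)
}
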