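#' Binomial confidence interval for a proportion
#'
#' Computes the Wilson score interval (the convention used for every
#' binomial confidence interval reported by this package), or optionally the
#' Clopper-Pearson exact interval. Bounds are clipped to `[0, 1]`.
#'
#' The Wilson interval with normal quantile `z` is
#' \deqn{\frac{\hat p + z^2/2n \pm z\sqrt{\hat p(1-\hat p)/n + z^2/4n^2}}{1 + z^2/n}}
#'
#' @param k Number of successes (vectorized).
#' @param n Number of trials (vectorized).
#' @param conf_level Confidence level, default 0.95.
#' @param method `"wilson"` (default) or `"clopper-pearson"`.
#' @return A tibble with columns `k`, `n`, `estimate`, `conf_low`,
#'   `conf_high`, `conf_level`.
#' @export
#' @examples
#' wilson_ci(2, 49)  # 4.1%, CI 1.1--13.7%
wilson_ci <- function(k, n, conf_level = 0.95,
                      method = c("wilson", "clopper-pearson")) {
  method <- match.arg(method)
  check_count(k, "k")
  check_count(n, "n")
  if (any(n < 1)) abort("`n` must be >= 1: the estimate is undefined at n = 0.")
  if (any(k > n)) abort("`k` must not exceed `n`.")
  if (!is.numeric(conf_level) || conf_level <= 0 || conf_level >= 1) {
    abort("`conf_level` must lie strictly between 0 and 1.")
  }
  p <- k / n
  if (method == "wilson") {
    z <- qnorm(1 - (1 - conf_level) / 2)
    denom <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    lo <- pmax(0, centre - half)
    hi <- pmin(1, centre + half)
    # k = 0 / k = n pin the corresponding bound exactly
    lo[k == 0] <- 0
    hi[k == n] <- 1
  } else {
    alpha <- 1 - conf_level
    lo <- ifelse(k == 0, 0, stats::qbeta(alpha / 2, k, n - k + 1))
    hi <- ifelse(k == n, 1, stats::qbeta(1 - alpha / 2, k + 1, n - k))
  }
  tibble(k = as.integer(k), n = as.integer(n), estimate = p,
         conf_low = lo, conf_high = hi, conf_level = conf_level)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Two-sided p defined by the point-probability criterion: the sum of
#' hypergeometric probabilities of all tables with the observed margins whose
#' probability does not exceed that of the observed table (within relative
#' tolerance 1e-7), the convention of R's `fisher.test`. Degenerate margins
#' (a row or column summing to zero) make the distribution a point mass and
#' return p = 1.
#'
#' @param table A 2x2 matrix of non-negative counts, rows = groups,
#'   columns = outcome yes/no.
#' @return The two-sided p-value in `(0, 1]`.
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(2, 5, 47, 21), nrow = 2))  # p = 0.045
fisher_exact_2x2 <- function(table) {
  if (!is.matrix(table) || !all(dim(table) == c(2L, 2L))) {
    abort("`table` must be a 2x2 matrix.")
  }
  check_count(as.vector(table), "table")
  if (sum(table) == 0) abort("all-zero table has no defined test.")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    return(1)
  }
  stats::fisher.test(table, alternative = "two.sided")$p.value
}

#' Fold change between two proportions
#'
#' `(k1/n1) / (k0/n0)`, rounded to one decimal by default (the reporting
#' convention for fold changes in this package); pass `digits = NULL` for
#' full precision.
#'
#' @param k1,n1 Numerator group's successes and trials.
#' @param k0,n0 Reference group's successes and trials; `k0` must be >= 1.
#' @param digits Decimal places for rounding, or `NULL`.
#' @return The ratio of proportions.
#' @export
#' @examples
#' fold_change(5, 26, 2, 49)  # 4.7
fold_change <- function(k1, n1, k0, n0, digits = 1) {
  check_count(c(k1, n1, k0, n0), "counts")
  if (n1 < 1 || n0 < 1) abort("`n1` and `n0` must be >= 1.")
  if (k0 < 1) abort("`k0` = 0: the reference proportion is zero, ratio undefined.")
  fc <- (k1 / n1) / (k0 / n0)
  if (is.null(digits)) fc else round(fc, digits)
}

#' Proportion of crossovers among scored recombinants
#'
#' Crossovers as a fraction of all recombinants whose class was resolved;
#' undetermined recombinants and mutants are excluded from both numerator
#' and denominator, matching the "all recombinant progeny scored" convention.
#'
#' @param co Crossover recombinant count.
#' @param nco Noncrossover recombinant count.
#' @inheritParams wilson_ci
#' @return A [wilson_ci()] tibble for `co` out of `co + nco`.
#' @export
crossover_proportion <- function(co, nco, conf_level = 0.95) {
  check_count(co, "co")
  check_count(nco, "nco")
  if (any(co + nco < 1)) {
    abort("`co + nco` must be >= 1: no scored recombinants.")
  }
  wilson_ci(co, co + nco, conf_level = conf_level)
}

#' Compare two binomial proportions
#'
#' Builds the 2x2 table `[[k1, n1-k1], [k0, n0-k0]]`, runs the two-sided
#' Fisher exact test, and attaches Wilson interval estimates for both groups.
#'
#' @param k1,n1 First group's successes and trials.
#' @param k0,n0 Second (reference) group's successes and trials.
#' @param labels Length-2 character vector naming the groups.
#' @inheritParams wilson_ci
#' @return An object of class `prop_comparison`: a list with `table`,
#'   `p_value` and `estimates` (a two-row [wilson_ci()] tibble). Use
#'   [tidy()] for a flat tibble.
#' @export
#' @examples
#' compare_proportions(5, 26, 2, 49)  # 19.2% vs 4.1%, p = 0.045
compare_proportions <- function(k1, n1, k0, n0, conf_level = 0.95,
                                labels = c("group1", "group0")) {
  tab <- matrix(c(k1, k0, n1 - k1, n0 - k0), nrow = 2,
                dimnames = list(group = labels, outcome = c("yes", "no")))
  est <- wilson_ci(c(k1, k0), c(n1, n0), conf_level = conf_level)
  est <- mutate(est, group = labels, .before = 1)
  structure(
    list(table = tab, p_value = fisher_exact_2x2(tab), estimates = est),
    class = "prop_comparison"
  )
}

#' @export
print.prop_comparison <- function(x, ...) {
  e <- x$estimates
  cat("Two-proportion comparison (Fisher exact, two-sided)\n")
  for (i in seq_len(nrow(e))) {
    cat(sprintf("  %s: %d/%d = %.1f%% (%.0f%% CI %.1f-%.1f%%)\n",
                e$group[i], e$k[i], e$n[i], 100 * e$estimate[i],
                100 * e$conf_level[i], 100 * e$conf_low[i],
                100 * e$conf_high[i]))
  }
  cat(sprintf("  p = %s\n", format_p(x$p_value)))
  invisible(x)
}

#' @rdname compare_proportions
#' @param x A `prop_comparison` object.
#' @param ... Unused.
#' @method tidy prop_comparison
#' @export
tidy.prop_comparison <- function(x, ...) {
  mutate(x$estimates, p_value = x$p_value)
}

# in-text reporting convention: 3 decimals, 2 significant figures below 0.01
format_p <- function(p) {
  ifelse(p < 0.01, formatC(signif(p, 2), format = "g"),
         formatC(round(p, 3), format = "g"))
}
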