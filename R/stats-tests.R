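#' Two-sample and paired t tests, Pearson correlation, KS normality screen
#'
#' Thin, validated wrappers around the standard tests, returning plain
#' lists so pipeline stages can tabulate them uniformly. `two_sample_t` is
#' the pooled-variance Student test; `ks_normality` compares against a
#' normal with the sample-estimated mean and SD (no Lilliefors correction,
#' matching common statistical-software output; this makes the p-values
#' conservative).
#'
#' @param groupA,groupB Numeric vectors (independent samples).
#' @return For the t tests, a list with `t`, `df`, `p` (and `mean_diff`);
#'   for `pearson_cor` a list with `r`, `p`, `n`; for `ks_normality` a
#'   list with `D`, `p`, `n`.
#' @export
two_sample_t <- function(groupA, groupB) {
  groupA <- groupA[!is.na(groupA)]
  groupB <- groupB[!is.na(groupB)]
  if (length(groupA) < 3L || length(groupB) < 3L) {
    stop("need at least 3 observations per group", call. = FALSE)
  }
  if (stats::var(groupA) == 0 && stats::var(groupB) == 0) {
    if (mean(groupA) == mean(groupB)) {
      return(list(t = 0, df = length(groupA) + length(groupB) - 2, p = 1,
                  mean_diff = 0))
    }
    stop("zero variance in both groups", call. = FALSE)
  }
  ht <- stats::t.test(groupA, groupB, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = unname(diff(rev(ht$estimate))))
}

#' @rdname two_sample_t
#' @param before,after Paired numeric vectors (same length; pairs with a
#'   missing member are dropped).
#' @export
paired_t <- function(before, after) {
  if (length(before) != length(after)) {
    stop("paired vectors must have equal length", call. = FALSE)
  }
  keep <- !is.na(before) & !is.na(after)
  before <- before[keep]; after <- after[keep]
  if (length(before) < 3L) {
    stop("need at least 3 complete pairs", call. = FALSE)
  }
  d <- after - before
  if (stats::var(d) == 0) {
    if (all(d == 0)) {
      return(list(t = 0, df = length(d) - 1, p = 1, mean_diff = 0))
    }
    stop("zero variance of paired differences", call. = FALSE)
  }
  ht <- stats::t.test(after, before, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = unname(ht$estimate))
}

#' @rdname two_sample_t
#' @param x,y Numeric vectors for the correlation (pairwise complete).
#' @export
pearson_cor <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance input to correlation", call. = FALSE)
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p = ht$p.value, n = length(x))
}

#' @rdname two_sample_t
#' @export
ks_normality <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 5L) stop("need at least 5 observations", call. = FALSE)
  if (stats::var(x) == 0) stop("zero variance input", call. = FALSE)
  ht <- suppressWarnings(
    stats::ks.test(x, "pnorm", mean = mean(x), sd = stats::sd(x)))
  list(D = unname(ht$statistic), p = ht$p.value, n = length(x))
}

#' Bonferroni test family
#'
#' Family-wise error control dividing the family alpha by the number of
#' tests. The unrounded threshold is used for decisions; a display value
#' rounded to 3 decimals matches the convention of printed reports
#' (0.05/9 -> 0.006, 0.05/18 -> 0.003).
#'
#' @param alpha_family Family-wise significance level (default 0.05).
#' @param m Number of tests in the family (>= 1).
#' @param name Optional family label.
#' @return A `test_family` list: `name`, `m`, `alpha_family`, `threshold`,
#'   `display`.
#' @examples
#' bonferroni(0.05, 9)$display
#' @export
bonferroni <- function(alpha_family = 0.05, m, name = "family") {
  if (length(m) != 1L || is.na(m) || m < 1) {
    stop("m must be a positive number of tests", call. = FALSE)
  }
  threshold <- alpha_family / m
  structure(list(name = name, m = m, alpha_family = alpha_family,
                 threshold = threshold, display = round(threshold, 3)),
            class = "test_family")
}

#' @export
print.test_family <- function(x, ...) {
  cat("<test_family> ", x$name, ": m = ", x$m, ", alpha = ", x$alpha_family,
      ", threshold = ", signif(x$threshold, 4),
      " (display ", format(x$display), ")\n", sep = "")
  invisible(x)
}

#' Two-group sample size for a mean difference
#'
#' `n = 2 (z_alpha + z_beta)^2 s^2 / diff^2` per group, the standard
#' normal-approximation formula for detecting a difference of means `diff`
#' with common standard deviation `s`. Invariant to the sign of `diff`.
#'
#' @param z_alpha Standard-normal quantile for the two-sided type-I level
#'   (1.96 for alpha = 0.05).
#' @param z_beta Standard-normal quantile for power (1.28 for 90% power).
#' @param s Outcome standard deviation (same units as `diff`).
#' @param diff Mean difference to detect (non-zero).
#' @return List with `n` (per group, real) and `n_ceiling`.
#' @examples
#' sample_size(1.96, 1.28, 18.5, 13.08) # n = 41.96, ceiling 42
#' @export
sample_size <- function(z_alpha, z_beta, s, diff) {
  stopifnot(z_alpha > 0, z_beta > 0, s > 0)
  if (diff == 0) stop("mean difference must be non-zero", call. = FALSE)
  n <- 2 * (z_alpha + z_beta)^2 * s^2 / diff^2
  list(n = n, n_ceiling = ceiling(n))
}
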