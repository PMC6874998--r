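new_neo_test <- function(method, statistic, p_value, estimate = NA_real_,
                         n = integer(), exact = NA, extra = list()) {
  structure(list(method = method, statistic = statistic,
                 p_value = p_value, estimate = estimate, n = n,
                 exact = exact, extra = extra), class = "neo_test")
}

#' @export
print.neo_test <- function(x, ...) {
  cat(sprintf("<neo_test> %s: statistic = %s, p = %.4g (%s)\n",
              x$method, format(x$statistic, digits = 4), x$p_value,
              if (isTRUE(x$exact)) "exact" else "approximate"))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a hypothesis-test result
#'
#' @param x A `neo_test` object.
#' @param ... Unused.
#' @return A one-row tibble with `method`, `statistic`, `estimate`,
#'   `p.value`, `exact` and the per-group sizes.
#' @method tidy neo_test
#' @export
tidy.neo_test <- function(x, ...) {
  tibble(method = x$method, statistic = unname(x$statistic),
         estimate = unname(x$estimate), p.value = x$p_value,
         exact = x$exact, n = sum(x$n))
}

#' @rdname tidy.neo_test
#' @method glance neo_test
#' @export
glance.neo_test <- function(x, ...) tidy(x)

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact test computed by direct hypergeometric enumeration with
#' fixed margins: the p-value is the sum of the probabilities of all
#' tables at most as probable as the observed one (with a relative slack
#' of 1e-12 on the comparison). The reported estimate is the sample odds
#' ratio `ad/bc`; a Haldane-corrected version (0.5 added to every cell) is
#' kept in `extra$odds_ratio_haldane` for display with zero cells, and
#' plays no part in the p-value.
#'
#' @param table A 2x2 matrix (or coercible) of non-negative counts.
#' @return A `neo_test` object with method `"fisher_exact"`.
#' @examples
#' fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2))
#' @export
fisher_exact_2x2 <- function(table) {
  m <- as.matrix(table)
  if (!identical(dim(m), c(2L, 2L)) || any(m < 0) || any(is.na(m))) {
    abort("`table` must be a 2x2 matrix of non-negative counts",
          class = "neocall_parameter_error")
  }
  if (sum(m) == 0) {
    abort("`table` must have a positive total",
          class = "neocall_parameter_error")
  }
  a <- m[1, 1]; b <- m[1, 2]; cc <- m[2, 1]; d <- m[2, 2]
  m1 <- a + b; m2 <- cc + d; k <- a + cc
  support <- seq.int(max(0, k - m2), min(k, m1))
  probs <- dhyper(support, m1, m2, k)
  p_obs <- dhyper(a, m1, m2, k)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
  or <- (a * d) / (b * cc)
  or_h <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
  new_neo_test("fisher_exact", statistic = c(odds_ratio = or),
               p_value = p, estimate = c(odds_ratio = or),
               n = c(row1 = m1, row2 = m2), exact = TRUE,
               extra = list(table = m, odds_ratio_haldane = or_h))
}

#' Wilcoxon rank-sum test
#'
#' Two-sided two-sample Wilcoxon (Mann-Whitney) test. In `"auto"` mode the
#' exact null distribution of the rank sum is used when the combined
#' sample size is at most 20 and there are no ties; otherwise the normal
#' approximation with tie correction and continuity correction is used.
#' The mode actually applied is recorded in the result's `exact` flag.
#'
#' @param x,y Numeric value vectors for the two groups (non-empty).
#' @param mode `"auto"`, `"exact"` or `"approximate"`.
#' @return A `neo_test` object with method `"wilcoxon_rank_sum"`.
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact",
                                             "approximate")) {
  mode <- match.arg(mode)
  if (length(x) == 0 || length(y) == 0) {
    abort("both groups must be non-empty",
          class = "neocall_parameter_error")
  }
  has_ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- switch(mode,
                      auto = (length(x) + length(y) <= 20) && !has_ties,
                      exact = TRUE,
                      approximate = FALSE)
  if (use_exact && has_ties) {
    warn("ties present: falling back to the normal approximation")
    use_exact <- FALSE
  }
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE,
                       alternative = "two.sided"))
  new_neo_test("wilcoxon_rank_sum", statistic = c(W = unname(ht$statistic)),
               p_value = ht$p.value, estimate = NA_real_,
               n = c(n_x = length(x), n_y = length(y)), exact = use_exact)
}

#' Spearman rank correlation
#'
#' Rank correlation computed as the Pearson correlation of mid-ranks
#' (average ranks for ties); the p-value uses the t approximation and is
#' flagged approximate.
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @return A `neo_test` object with method `"spearman"` and the
#'   correlation in `estimate`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("`x` and `y` must have equal length >= 3",
          class = "neocall_parameter_error")
  }
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    abort("correlation undefined: zero variance in ranks",
          class = "neocall_undefined_correlation")
  }
  ht <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  new_neo_test("spearman", statistic = c(S = unname(ht$statistic)),
               p_value = ht$p.value,
               estimate = c(rho = unname(ht$estimate)),
               n = c(n = length(x)), exact = FALSE)
}
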