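#' @name concordance
#' @title Rank concordance between two score vectors
#'
#' @description
#' Spearman's rank correlation and Kendall's tau measure the monotonic
#' agreement between two rankings induced by paired scores. Both take
#' values in \[-1, 1\]: +1 for identical orderings, -1 for exact reversal,
#' 0 for no monotonic relationship. Ties are handled by average ranks.
#'
#' Two Spearman variants are provided: `"paper"` computes
#' `r_s = 1 - 6 * sum(d_i^2) / (n^3 - n)` on average ranks (exact only for
#' tie-free data) and `"tie_corrected"` (default) the product-moment
#' correlation of the average-rank vectors, which is what mainstream
#' statistical software reports when ties are present. The Kendall
#' variants are `"tau_a"` (pair counting, `2 * (p - q) / (n * (n - 1))`
#' with `p` concordant and `q` discordant pairs) and `"tau_b"` (default),
#' which corrects the denominator for ties. Variants coincide on tie-free
#' data.
#'
#' P-values are two-sided against the null of no monotonic association:
#' exact permutation (full enumeration over the `n!` pairings) for
#' `n <= 8`, otherwise a t approximation with `n - 2` degrees of freedom
#' for Spearman and a normal approximation with tie-adjusted variance for
#' Kendall.
#'
#' @param x,y paired numeric score (or rank) vectors of equal length
#'   `n >= 2`, aligned by item.
#' @param variant statistic variant, see Description.
#' @param p_method `"auto"` (exact permutation for `n <= 8`, else
#'   approximation), `"exact"`, or `"approx"`.
#' @return An object of class `concordance`: a list with `statistic`,
#'   `method`, `p_value`, `n`.
#' @examples
#' spearman_concordance(c(1, 2, 3, 4), c(2, 1, 4, 3), variant = "paper")
#' kendall_concordance(c(1, 2, 3, 4), c(2, 1, 4, 3), variant = "tau_a")
NULL

check_paired <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least 2 paired observations")
  if (anyNA(x) || anyNA(y)) stop("missing values in rankings")
  invisible(length(x))
}

spearman_stat <- function(rx, ry, variant) {
  n <- length(rx)
  if (variant == "paper") {
    1 - 6 * sum((rx - ry)^2) / (n^3 - n)
  } else {
    if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
      stop("constant ranking: tie-corrected Spearman is undefined")
    stats::cor(rx, ry)
  }
}

# Concordant / discordant pair counts and tie counts over all i < j pairs.
kendall_counts <- function(x, y) {
  dx <- sign(outer(x, x, `-`))
  dy <- sign(outer(y, y, `-`))
  up <- upper.tri(dx)
  s <- dx[up] * dy[up]
  list(p = sum(s > 0), q = sum(s < 0),
       tx = sum(dx[up] == 0), ty = sum(dy[up] == 0))
}

kendall_stat <- function(x, y, variant) {
  n <- length(x)
  k <- kendall_counts(x, y)
  if (variant == "tau_a") {
    2 * (k$p - k$q) / (n * (n - 1))
  } else {
    n0 <- n * (n - 1) / 2
    den <- sqrt((n0 - k$tx) * (n0 - k$ty))
    if (den == 0) stop("constant ranking: tau-b is undefined")
    (k$p - k$q) / den
  }
}

# All n! permutations of 1..n, one per row. Used for exact tests (n <= 8).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    blk <- cbind(sub, n)[, append(seq_len(n - 1L), n, after = pos - 1L),
                         drop = FALSE]
    out[r + seq_len(nrow(sub)), ] <- blk
    r <- r + nrow(sub)
  }
  out
}

perm_pvalue <- function(stat_fun, x, y, observed) {
  n <- length(y)
  perms <- all_permutations(n)
  stats_null <- apply(perms, 1L, function(p) stat_fun(x, y[p]))
  mean(abs(stats_null) >= abs(observed) - 1e-12)
}

new_concordance <- function(statistic, method, p_value, n) {
  structure(list(statistic = statistic, method = method,
                 p_value = p_value, n = n),
            class = "concordance")
}

#' @rdname concordance
#' @export
spearman_concordance <- function(x, y,
                                 variant = c("tie_corrected", "paper"),
                                 p_method = c("auto", "exact", "approx")) {
  variant <- match.arg(variant)
  p_method <- match.arg(p_method)
  n <- check_paired(x, y)
  rx <- rank(x); ry <- rank(y)
  r <- spearman_stat(rx, ry, variant)
  exact <- p_method == "exact" || (p_method == "auto" && n <= 8L)
  p <- if (exact) {
    perm_pvalue(function(a, b) spearman_stat(rank(a), rank(b), variant),
                x, y, r)
  } else {
    if (abs(r) >= 1) 0
    else 2 * stats::pt(-abs(r * sqrt((n - 2) / (1 - r^2))), df = n - 2)
  }
  new_concordance(r, paste0("spearman_", variant), p, n)
}

#' @rdname concordance
#' @export
kendall_concordance <- function(x, y, variant = c("tau_b", "tau_a"),
                                p_method = c("auto", "exact", "approx")) {
  variant <- match.arg(variant)
  p_method <- match.arg(p_method)
  n <- check_paired(x, y)
  tau <- kendall_stat(x, y, variant)
  exact <- p_method == "exact" || (p_method == "auto" && n <= 8L)
  p <- if (exact) {
    perm_pvalue(function(a, b) kendall_stat(a, b, variant), x, y, tau)
  } else {
    k <- kendall_counts(x, y)
    S <- k$p - k$q
    v <- kendall_S_variance(x, y)
    if (v <= 0) 1 else 2 * stats::pnorm(-abs(S) / sqrt(v))
  }
  new_concordance(tau, paste0("kendall_", variant), p, n)
}

# Tie-adjusted variance of S = p - q under the null (the standard
# normal-approximation variance used for tau with ties).
kendall_S_variance <- function(x, y) {
  n <- length(x)
  t <- table(x); u <- table(y)
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(t * (t - 1) * (2 * t + 5))
  vu <- sum(u * (u - 1) * (2 * u + 5))
  v1 <- sum(t * (t - 1)) * sum(u * (u - 1)) / (2 * n * (n - 1))
  v2 <- if (n > 2)
    sum(t * (t - 1) * (t - 2)) * sum(u * (u - 1) * (u - 2)) /
      (9 * n * (n - 1) * (n - 2))
  else 0
  (v0 - vt - vu) / 18 + v1 + v2
}

#' Test for a monotonic relationship between two rankings
#'
#' Runs both concordance statistics (tie-corrected Spearman and Kendall's
#' tau-b by default) against the null hypothesis of no monotonic
#' relationship, with two-sided p-values and a reject / fail-to-reject
#' decision at the given significance level.
#'
#' @inheritParams concordance
#' @param alpha significance level (default 0.01, two-tailed).
#' @param spearman_variant,kendall_variant statistic variants.
#' @return An object of class `monotonic_test`: list with the two
#'   `concordance` results, `alpha`, and logical `reject` flags.
#' @examples
#' test_monotonic_association(1:10, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
#' @export
test_monotonic_association <- function(x, y, alpha = 0.01,
                                       spearman_variant = "tie_corrected",
                                       kendall_variant = "tau_b",
                                       p_method = "auto") {
  sp <- spearman_concordance(x, y, variant = spearman_variant,
                             p_method = p_method)
  kd <- kendall_concordance(x, y, variant = kendall_variant,
                            p_method = p_method)
  structure(
    list(spearman = sp, kendall = kd, alpha = alpha,
         reject = c(spearman = sp$p_value < alpha,
                    kendall = kd$p_value < alpha),
         n = sp$n),
    class = "monotonic_test"
  )
}

format_pvalue <- function(p, digits = 3L) {
  if (p < 10^(-digits)) sprintf("< %.*f", digits, 10^(-digits))
  else sprintf("%.*f", digits, p)
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf("%s: statistic = %.3f, n = %d, p %s\n", x$method,
              x$statistic, x$n,
              sub("^(?![<])", "= ", format_pvalue(x$p_value), perl = TRUE)))
  invisible(x)
}

#' @export
print.monotonic_test <- function(x, ...) {
  cat(sprintf("Monotonic association test, n = %d (two-tailed, alpha = %g)\n",
              x$n, x$alpha))
  for (r in list(x$spearman, x$kendall)) {
    dec <- if (r$p_value < x$alpha) "reject H0" else "fail to reject H0"
    cat(sprintf("  %-22s %8.3f   p %-8s %s\n", r$method, r$statistic,
                sub("^(?![<])", "= ", format_pvalue(r$p_value), perl = TRUE),
                dec))
  }
  invisible(x)
}

#' Tabular concordance report for two score tables
#'
#' Joins two score tables by alternative identifier and reports both
#' concordance statistics in a small table (method, n, statistic, p-value,
#' significance at `alpha`).
#'
#' @param scores_a,scores_b data frames with columns `alternative` and
#'   `score` (e.g. from [bibeta_pipeline()] or [read_score_table()]).
#' @param alpha significance level.
#' @return Data frame with one row per statistic.
#' @export
concordance_report <- function(scores_a, scores_b, alpha = 0.01) {
  shared <- intersect(scores_a$alternative, scores_b$alternative)
  if (length(shared) < 2L)
    stop("fewer than 2 shared alternatives between the score tables")
  a <- scores_a$score[match(shared, scores_a$alternative)]
  b <- scores_b$score[match(shared, scores_b$alternative)]
  mt <- test_monotonic_association(a, b, alpha = alpha)
  data.frame(
    method = c(mt$spearman$method, mt$kendall$method),
    n = mt$n,
    statistic = c(mt$spearman$statistic, mt$kendall$statistic),
    p_value = c(mt$spearman$p_value, mt$kendall$p_value),
    significant = unname(mt$reject[c("spearman", "kendall")]),
    stringsAsFactors = FALSE
  )
}

#' Read a score table CSV
#'
#' Reads a CSV with at least `alternative` and `score` columns (the format
#' written by [write_score_report()]).
#'
#' @param path CSV path.
#' @return Data frame with the score table.
#' @export
read_score_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  if (!all(c("alternative", "score") %in% names(tab)))
    stop("score table needs columns 'alternative' and 'score'")
  tab
}
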