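#' Resolve per-criterion ideal values
#'
#' Criteria with a supplied ideal keep it; criteria on the mean policy
#' (ideal `NA` in the spec) take the arithmetic mean of their column over
#' all alternatives. Policies may be mixed across criteria.
#'
#' @param dm a [decision_matrix()].
#' @param specs a [criterion_spec()] aligned with `dm`.
#' @return Named numeric vector of ideal values, one per criterion.
#' @export
resolve_ideals <- function(dm, specs) {
  check_spec_alignment(dm, specs)
  ideals <- specs$ideal
  use_mean <- is.na(ideals)
  if (any(use_mean)) ideals[use_mean] <- colMeans(dm)[use_mean]
  stats::setNames(ideals, specs$criterion)
}

#' Difference matrix: absolute deviation from the ideal
#'
#' `F[i, j] = |x[i, j] - ideal[j]|`. Measuring deviation in absolute value
#' makes the stage direction-agnostic: an alternative above or below a
#' criterion's ideal by the same amount deviates equally. All entries are
#' non-negative; an alternative exactly at the ideal deviates by zero.
#'
#' @param dm a [decision_matrix()].
#' @param ideals numeric vector of per-criterion ideal values, aligned with
#'   the criteria of `dm` (see [resolve_ideals()]).
#' @return Numeric matrix `F` of the same shape as `dm`.
#' @export
difference_matrix <- function(dm, ideals) {
  if (length(ideals) != ncol(dm))
    stop("one ideal value per criterion required")
  abs(sweep(unclass(dm), 2L, as.numeric(ideals), `-`))
}

#' Matching matrix: re-express deviations so larger is better
#'
#' The per-criterion maximum deviation `Y_minus[j] = max_i F[i, j]` anchors
#' the worst observed profile. In the default `uniform` mode every column
#' is reflected, `M[i, j] = Y_minus[j] - F[i, j]`, so the alternative
#' closest to the ideal attains the column maximum and the farthest scores
#' zero. In `direction_split` mode, columns whose criterion direction is
#' `max` are carried through unchanged (`M = F`) and only `min`-direction
#' columns are reflected; this mirrors a literal reading of the method's
#' stage description and is provided for comparison (see the package
#' vignette).
#'
#' @param F difference matrix from [difference_matrix()].
#' @param mode `"uniform"` (default) or `"direction_split"`.
#' @param directions character vector of per-criterion directions
#'   (`"max"`/`"min"`), required for `direction_split`.
#' @return List with `M` (matching matrix) and `Y_minus` (per-criterion
#'   maximum deviations).
#' @export
matching_matrix <- function(F, mode = c("uniform", "direction_split"),
                            directions = NULL) {
  mode <- match.arg(mode)
  if (!is.matrix(F) || nrow(F) == 0L || ncol(F) == 0L)
    stop("empty difference matrix")
  if (any(F < 0)) stop("difference matrix must be non-negative")
  Y_minus <- apply(F, 2L, max)
  M <- sweep(-F, 2L, Y_minus, `+`)
  if (mode == "direction_split") {
    if (is.null(directions) || length(directions) != ncol(F))
      stop("direction_split mode needs one direction per criterion")
    keep <- directions == "max"
    M[, keep] <- F[, keep]
  }
  list(M = M, Y_minus = Y_minus)
}

#' Logarithmic transformation matrix
#'
#' `Q[i, j] = ln(M[i, j] + 1)`. The +1 shift keeps zero entries at zero and
#' every entry finite; the natural log compresses large matched values.
#' Strictly increasing, so within a column the ordering of alternatives is
#' preserved.
#'
#' @param M matching matrix (non-negative).
#' @return Numeric matrix `Q` of the same shape.
#' @export
log_transform <- function(M) {
  if (any(M < 0))
    stop("matching matrix has negative entries; upstream stage is broken")
  log1p(M)
}

#' Apply criterion weights
#'
#' `A[i, j] = w[j] * Q[i, j]`, with weights positive and summing to 1.
#' Because the final score is a ratio of sums, equal weights reproduce the
#' unweighted ranking exactly.
#'
#' @param Q log-transformed matrix from [log_transform()].
#' @param specs a [criterion_spec()] supplying the weights, or a bare
#'   numeric weight vector.
#' @return Weighted matrix `A`.
#' @export
apply_weights <- function(Q, specs) {
  w <- if (inherits(specs, "criterion_spec")) specs$weight
       else as.numeric(specs)
  if (length(w) != ncol(Q)) stop("one weight per criterion required")
  if (any(w <= 0)) stop("weights must be positive")
  if (abs(sum(w) - 1) > 1e-9)
    stop(sprintf("weights must sum to 1 (got %.9f)", sum(w)))
  sweep(Q, 2L, w, `*`)
}

#' Index reference values
#'
#' The per-criterion maximum of the weighted transformed values,
#' `R[j] = max_i A[i, j]` — the best attainable contribution of each
#' criterion given the alternatives at hand.
#'
#' @param A weighted matrix from [apply_weights()] (or `Q` directly for an
#'   unweighted analysis).
#' @return Named numeric vector `R`, one entry per criterion.
#' @export
index_reference_values <- function(A) {
  if (!is.matrix(A) || nrow(A) == 0L || ncol(A) == 0L)
    stop("empty matrix")
  apply(A, 2L, max)
}

#' BI-beta scores from the weighted matrix
#'
#' Each alternative's in-class score `t_ci[i] = sum_j A[i, j]` is
#' normalised by the index reference score `b_ri = sum_j R[j]` (the sum of
#' the per-criterion maxima) and scaled to 0-100:
#' `score[i] = 100 * t_ci[i] / b_ri`. An alternative attaining every
#' column maximum scores exactly 100; one at the worst observed deviation
#' on every criterion scores exactly 0.
#'
#' @param A weighted matrix from [apply_weights()].
#' @param R index reference values from [index_reference_values()].
#' @return Data frame of class `bibeta_scores` with columns `alternative`,
#'   `t_ci`, `score`, and attribute `b_ri`; ranks are added by
#'   [rank_alternatives()].
#' @export
bibeta_scores <- function(A, R) {
  if (length(R) != ncol(A)) stop("one reference value per criterion required")
  b_ri <- sum(R)
  if (b_ri <= 0)
    stop("index reference score is 0: every criterion is constant across ",
         "alternatives, the problem is unscorable")
  t_ci <- rowSums(A)
  alt <- rownames(A)
  if (is.null(alt)) alt <- paste0("A", seq_len(nrow(A)))
  # t_ci <= b_ri holds mathematically; clamp the last-bit accumulation
  # overshoot so the [0, 100] bound is exact
  score <- pmin(pmax(100 * t_ci / b_ri, 0), 100)
  structure(
    data.frame(alternative = alt, t_ci = t_ci, score = score,
               row.names = NULL, stringsAsFactors = FALSE),
    b_ri = b_ri,
    class = c("bibeta_scores", "data.frame")
  )
}

#' Rank alternatives by score
#'
#' Descending-score competition ranking: the highest score gets rank 1;
#' scores equal to 12 decimal places share the minimum rank and the next
#' distinct score's rank skips accordingly. Rows are returned sorted by
#' rank, ties broken alphabetically by alternative identifier.
#'
#' @param st a `bibeta_scores` table from [bibeta_scores()].
#' @return The same table with a `rank` column, sorted by rank.
#' @export
rank_alternatives <- function(st) {
  if (!inherits(st, "bibeta_scores")) stop("expected a bibeta_scores table")
  key <- round(st$score, 12L)
  st$rank <- as.integer(rank(-key, ties.method = "min"))
  st[order(st$rank, st$alternative), , drop = FALSE] -> out
  rownames(out) <- NULL
  attr(out, "b_ri") <- attr(st, "b_ri")
  class(out) <- class(st)
  out
}

#' @export
print.bibeta_scores <- function(x, digits = 2L, ...) {
  cat(sprintf("BI-beta scores (%d alternatives, b_ri = %.*f)\n",
              nrow(x), digits, attr(x, "b_ri")))
  df <- as.data.frame(x)
  df$t_ci <- round(df$t_ci, digits)
  df$score <- round(df$score, digits)
  print(df, ...)
  invisible(x)
}
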