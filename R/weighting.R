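#' Build a neutral weight table from category sizes
#'
#' The neutral weighting scheme used by composite health-security indices
#' gives every category the same total weight (1) and splits it evenly over
#' the category's indicators: an indicator in a 6-indicator category gets
#' 1/6, in a 7-indicator category 1/7, and so on. Exact fractions are kept
#' internally; printed 3-decimal roundings (0.167, 0.143, 0.200) are a
#' display convention only.
#'
#' @param category_sizes named integer vector or list mapping category
#'   name to its indicator count.
#' @param criteria optional character vector of criterion identifiers in
#'   category order (lengths must match); defaults to
#'   `<category>_<index>`.
#' @return Data frame of class `neutral_weights` with columns `criterion`,
#'   `category`, `neutral_weight`.
#' @examples
#' neutral_weights(c(Prevent = 6, Respond = 7, Risk = 5))
#' @export
neutral_weights <- function(category_sizes, criteria = NULL) {
  sizes <- unlist(category_sizes)
  if (length(sizes) == 0L) stop("at least one category required")
  if (any(sizes < 1L)) stop("empty category")
  cats <- rep(names(sizes), sizes)
  w <- rep(1 / sizes, sizes)
  if (is.null(criteria)) {
    criteria <- unlist(lapply(seq_along(sizes), function(k)
      paste0(names(sizes)[k], "_", seq_len(sizes[k]))))
  }
  if (length(criteria) != length(w))
    stop("`criteria` must name every indicator across all categories")
  structure(
    data.frame(criterion = criteria, category = cats, neutral_weight = w,
               stringsAsFactors = FALSE),
    class = c("neutral_weights", "data.frame")
  )
}

#' Normalize neutral weights to a BI-beta weight vector
#'
#' Divides each neutral weight by the sum of all neutral weights so the
#' result sums to 1, as the multicriteria literature requires. The
#' operation is scale-invariant: multiplying every neutral weight by the
#' same positive constant leaves the output unchanged.
#'
#' @param t a `neutral_weights` table from [neutral_weights()], or a data
#'   frame with columns `criterion` and `neutral_weight`.
#' @return Named numeric vector of weights summing to 1, in input order.
#' @examples
#' normalize_neutral_weights(neutral_weights(c(A = 2, B = 2)))
#' @export
normalize_neutral_weights <- function(t) {
  if (!all(c("criterion", "neutral_weight") %in% names(t)))
    stop("need columns 'criterion' and 'neutral_weight'")
  g <- t$neutral_weight
  if (length(g) == 0L) stop("empty weight table")
  if (anyNA(g) || any(!is.finite(g)) || any(g <= 0))
    stop("neutral weights must be positive and finite")
  stats::setNames(g / sum(g), t$criterion)
}
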