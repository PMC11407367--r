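#' Construct a criterion specification table
#'
#' Each decision criterion carries an optimality direction, an ideal-value
#' policy and a weight. The ideal value is either supplied (a reference
#' value taken from the literature or from domain knowledge) or resolved at
#' run time as the arithmetic mean of the criterion's column; both policies
#' may be mixed within one problem. Weights must sum to 1.
#'
#' @param criterion character vector of criterion identifiers.
#' @param direction `"max"` or `"min"` per criterion (recycled); the
#'   optimality direction of the raw scores.
#' @param ideal numeric vector of supplied ideal values; `NA` selects the
#'   column-mean policy for that criterion.
#' @param weight numeric weights in (0, 1] summing to 1; `NULL` assigns
#'   equal weights `1/n`.
#' @param normalize if `TRUE`, positive weights that do not sum to 1 are
#'   rescaled to sum to 1 (with a message) instead of being rejected.
#' @return A data frame of class `criterion_spec` with columns
#'   `criterion`, `direction`, `ideal`, `weight`.
#' @examples
#' criterion_spec(c("c1", "c2"), direction = "max")
#' @export
criterion_spec <- function(criterion, direction = "max", ideal = NA_real_,
                           weight = NULL, normalize = FALSE) {
  n <- length(criterion)
  if (n < 1L) stop("at least one criterion required")
  if (anyDuplicated(criterion)) stop("duplicate criterion identifiers")
  direction <- rep_len(as.character(direction), n)
  if (!all(direction %in% c("max", "min")))
    stop("direction must be 'max' or 'min'")
  ideal <- rep_len(as.numeric(ideal), n)
  if (any(!is.na(ideal) & !is.finite(ideal)))
    stop("supplied ideal values must be finite")
  if (is.null(weight)) weight <- rep(1 / n, n)
  weight <- as.numeric(weight)
  if (length(weight) != n) stop("one weight per criterion required")
  if (anyNA(weight) || any(weight <= 0))
    stop("weights must be positive")
  s <- sum(weight)
  if (abs(s - 1) > 1e-9) {
    if (normalize) {
      message(sprintf("rescaling weights (sum %.6f) to sum to 1", s))
      weight <- weight / s
    } else {
      stop(sprintf("weights must sum to 1 (got %.9f); ", s),
           "set normalize = TRUE to rescale")
    }
  }
  structure(
    data.frame(criterion = as.character(criterion), direction = direction,
               ideal = ideal, weight = weight, stringsAsFactors = FALSE),
    class = c("criterion_spec", "data.frame")
  )
}

# Check that a spec table is aligned, one-to-one and in order, with the
# criteria of a decision matrix.
check_spec_alignment <- function(dm, specs) {
  if (!inherits(specs, "criterion_spec"))
    stop("`specs` must be a criterion_spec table")
  if (!identical(specs$criterion, colnames(dm)))
    stop("criterion spec does not match the decision matrix criteria ",
         "(same identifiers, same order, required)")
  invisible(specs)
}

#' Read a criterion specification from CSV
#'
#' Columns: `criterion`, `direction` (max/min; blank = max), `ideal`
#' (blank = column-mean policy), `weight` (all blank = equal weights).
#'
#' @param path path to a CSV file.
#' @param normalize passed to [criterion_spec()].
#' @return A `criterion_spec` data frame.
#' @export
read_criterion_spec <- function(path, normalize = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8",
                         stringsAsFactors = FALSE)
  names(tab) <- tolower(trimws(names(tab)))
  if (!"criterion" %in% names(tab)) stop("column 'criterion' required")
  direction <- if ("direction" %in% names(tab)) {
    d <- tolower(trimws(as.character(tab$direction)))
    d[is.na(d) | d == ""] <- "max"
    d
  } else "max"
  ideal <- if ("ideal" %in% names(tab)) as.numeric(tab$ideal) else NA_real_
  weight <- if ("weight" %in% names(tab) && !all(is.na(tab$weight)))
    as.numeric(tab$weight) else NULL
  criterion_spec(tab$criterion, direction = direction, ideal = ideal,
                 weight = weight, normalize = normalize)
}
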