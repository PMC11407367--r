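#' Construct a decision matrix
#'
#' A decision matrix holds the raw criterion scores of a multicriteria
#' decision problem: one row per decision alternative, one column per
#' decision criterion, every value finite and non-negative. It is the input
#' to the BI-beta scoring pipeline ([bibeta_pipeline()]).
#'
#' Tables arriving with criteria in rows (the transposed layout common in
#' printed method descriptions) are accepted through `orientation =
#' "criteria_in_rows"` and transposed on entry; internally the package
#' always stores alternatives in rows.
#'
#' @param values numeric matrix or data frame of non-negative scores,
#'   labelled on both axes (rownames/colnames or via `alternatives` /
#'   `criteria`).
#' @param alternatives,criteria optional character vectors overriding the
#'   dimnames of `values`.
#' @param orientation `"alternatives_in_rows"` (default) or
#'   `"criteria_in_rows"`; in the latter case `values` is transposed.
#' @return An object of class `decision_matrix`: a numeric matrix with
#'   alternative rownames and criterion colnames.
#' @examples
#' dm <- decision_matrix(rbind(A = c(10, 40), B = c(20, 60), C = c(30, 80)),
#'                       criteria = c("c1", "c2"))
#' dm
#' @export
decision_matrix <- function(values, alternatives = NULL, criteria = NULL,
                            orientation = c("alternatives_in_rows",
                                            "criteria_in_rows")) {
  orientation <- match.arg(orientation)
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values)) stop("`values` must be a matrix or data frame")
  if (orientation == "criteria_in_rows") values <- t(values)
  if (!is.null(alternatives)) rownames(values) <- alternatives
  if (!is.null(criteria)) colnames(values) <- criteria
  if (is.null(rownames(values)))
    rownames(values) <- paste0("A", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("C", seq_len(ncol(values)))
  storage.mode(values) <- "double"
  validate_decision_matrix(values)
  structure(values, class = c("decision_matrix", "matrix", "array"))
}

validate_decision_matrix <- function(values) {
  if (nrow(values) < 2L)
    stop("a decision problem needs at least 2 alternatives")
  if (ncol(values) < 1L)
    stop("a decision problem needs at least 1 criterion")
  if (anyDuplicated(rownames(values)))
    stop("duplicate alternative identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate criterion identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (anyNA(values) || any(!is.finite(values)))
    stop("decision matrix contains missing or non-finite values")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative value at alternative '%s', criterion '%s'",
                 rownames(values)[bad[1L]], colnames(values)[bad[2L]]))
  }
  invisible(values)
}

#' @export
print.decision_matrix <- function(x, ...) {
  cat(sprintf("decision matrix: %d alternatives x %d criteria\n",
              nrow(x), ncol(x)))
  print(unclass(x), ...)
  invisible(x)
}

#' Alternative and criterion identifiers of a decision matrix
#' @param dm a [decision_matrix()].
#' @return Character vector of identifiers, in matrix order.
#' @export
alternatives <- function(dm) rownames(dm)

#' @rdname alternatives
#' @export
criteria <- function(dm) colnames(dm)

#' Read a decision matrix from CSV
#'
#' Expects a header row and a first column of identifiers; with the default
#' orientation the first column holds alternatives and the header holds
#' criteria. UTF-8, "." decimal separator.
#'
#' @param path path to a CSV file.
#' @inheritParams decision_matrix
#' @return A [decision_matrix()].
#' @export
read_decision_matrix <- function(path,
                                 orientation = c("alternatives_in_rows",
                                                 "criteria_in_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (ncol(tab) < 2L) stop("CSV must have an identifier column plus data")
  ids <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cell in decision matrix CSV")
  rownames(m) <- ids
  decision_matrix(m, orientation = orientation)
}

#' Write a decision matrix to CSV
#'
#' The written file round-trips through [read_decision_matrix()] at full
#' double precision.
#'
#' @param dm a [decision_matrix()].
#' @param path output path.
#' @export
write_decision_matrix <- function(dm, path) {
  df <- data.frame(alternative = rownames(dm), unclass(dm),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
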