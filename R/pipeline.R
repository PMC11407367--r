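#' Run the full BI-beta scoring pipeline
#'
#' Composes the six stages — resolve ideals, difference matrix, matching
#' matrix, logarithmic transformation, weighting, index reference values —
#' into BI-beta scores and competition ranks, retaining every intermediate
#' matrix for audit.
#'
#' @param dm a [decision_matrix()].
#' @param specs a [criterion_spec()] aligned with `dm`; `NULL` gives
#'   max-direction, mean-ideal, equal-weight criteria.
#' @param mode matching mode, see [matching_matrix()].
#' @return An object of class `bibeta_result`: a list with
#'   \describe{
#'     \item{scores}{ranked `bibeta_scores` table,}
#'     \item{b_ri}{the index reference score,}
#'     \item{trace}{list of intermediates `ideals`, `F`, `Y_minus`, `M`,
#'       `Q`, `A`, `R`,}
#'     \item{specs}{the criterion specification used.}
#'   }
#' @examples
#' dm <- decision_matrix(rbind(A = c(10, 40), B = c(20, 60), C = c(30, 80)),
#'                       criteria = c("c1", "c2"))
#' res <- bibeta_pipeline(dm)
#' res$scores
#' @export
bibeta_pipeline <- function(dm, specs = NULL,
                            mode = c("uniform", "direction_split")) {
  mode <- match.arg(mode)
  if (!inherits(dm, "decision_matrix")) dm <- decision_matrix(dm)
  if (is.null(specs)) specs <- criterion_spec(colnames(dm))
  check_spec_alignment(dm, specs)

  ideals <- resolve_ideals(dm, specs)
  F <- difference_matrix(dm, ideals)
  mm <- matching_matrix(F, mode = mode, directions = specs$direction)
  Q <- log_transform(mm$M)
  A <- apply_weights(Q, specs)
  R <- index_reference_values(A)
  st <- rank_alternatives(bibeta_scores(A, R))

  structure(
    list(scores = st, b_ri = attr(st, "b_ri"),
         trace = list(ideals = ideals, F = F, Y_minus = mm$Y_minus,
                      M = mm$M, Q = Q, A = A, R = R),
         specs = specs, mode = mode),
    class = "bibeta_result"
  )
}

#' @export
print.bibeta_result <- function(x, n = 10L, ...) {
  cat(sprintf("BI-beta result: %d alternatives x %d criteria (mode %s)\n",
              nrow(x$trace$F), ncol(x$trace$F), x$mode))
  cat(sprintf("index reference score b_ri = %.4f\n", x$b_ri))
  top <- utils::head(as.data.frame(x$scores), n)
  top$t_ci <- round(top$t_ci, 2); top$score <- round(top$score, 2)
  print(top)
  if (nrow(x$scores) > n) cat(sprintf("... %d more rows\n",
                                      nrow(x$scores) - n))
  invisible(x)
}

#' Write the score table (and optionally the stage trace) to CSV
#'
#' The score report has columns `alternative`, `t_ci`, `b_ri`, `score`,
#' `rank` with scores at reporting precision (2 decimals by default; full
#' precision is retained in the R objects). With `trace = TRUE` the
#' intermediate `F`, `M`, `Q`, `A` matrices and the `R` vector are written
#' alongside as `<stem>_trace_<stage>.csv`.
#'
#' @param result a `bibeta_result` from [bibeta_pipeline()], or a
#'   `bibeta_scores` table.
#' @param path output CSV path.
#' @param digits reporting precision for `t_ci`, `b_ri` and `score`.
#' @param trace also export the stage trace (requires a `bibeta_result`).
#' @return Invisibly, the paths written.
#' @export
write_score_report <- function(result, path, digits = 2L, trace = FALSE) {
  st <- if (inherits(result, "bibeta_result")) result$scores else result
  if (!inherits(st, "bibeta_scores")) stop("expected a bibeta result")
  b_ri <- attr(st, "b_ri")
  out <- data.frame(alternative = st$alternative,
                    t_ci = round(st$t_ci, digits),
                    b_ri = round(b_ri, digits),
                    score = round(st$score, digits),
                    rank = st$rank)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  paths <- path
  if (trace) {
    if (!inherits(result, "bibeta_result"))
      stop("trace export needs a full bibeta_result")
    stem <- sub("\\.csv$", "", path)
    for (stage in c("F", "M", "Q", "A")) {
      p <- sprintf("%s_trace_%s.csv", stem, stage)
      m <- result$trace[[stage]]
      utils::write.csv(data.frame(alternative = rownames(m), m,
                                  check.names = FALSE),
                       p, row.names = FALSE, quote = TRUE)
      paths <- c(paths, p)
    }
    p <- sprintf("%s_trace_R.csv", stem)
    utils::write.csv(data.frame(criterion = names(result$trace$R),
                                R = result$trace$R),
                     p, row.names = FALSE, quote = TRUE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
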