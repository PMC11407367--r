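#' @keywords internal
# Run code under a seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("a single integer seed is required")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Simulate a decision problem with optional planted extremes
#'
#' Draws a decision matrix of independent uniform scores on `value_range`
#' (defaults to the 0-100 scale used by composite health-security
#' indicators) together with a matching criterion specification
#' (max-direction, equal weights). Two alternatives with known ground
#' truth can be planted:
#' \describe{
#'   \item{`plant_ideal`}{an alternative `planted_ideal` whose row equals
#'     the per-criterion mean of the freely drawn rows, so it sits exactly
#'     at the resolved ideal and must score exactly 100;}
#'   \item{`plant_worst`}{an alternative `planted_worst` pushed to the end
#'     of `value_range` farthest from each criterion's ideal, attaining
#'     the maximum deviation on every criterion and scoring exactly 0.}
#' }
#' When either plant is requested the specification carries the ideal
#' values explicitly (the per-criterion means of the freely drawn rows):
#' this keeps the planted rows at the exact 100/0 extremes — the worst
#' row's own values do not shift the ideal it is measured against, and
#' the ideal row's deviation is exactly zero rather than zero up to
#' floating-point re-averaging. Without plants the column-mean policy is
#' used.
#'
#' @param n_alternatives,n_criteria problem size (`n_alternatives >= 2`,
#'   or `>= 3` when both plants are requested).
#' @param value_range numeric `c(low, high)` within \[0, 100\].
#' @param plant_ideal,plant_worst logical flags, see Description.
#' @param seed mandatory integer seed; identical arguments give an
#'   identical problem.
#' @return List with `dm` (a [decision_matrix()]), `specs` (a
#'   [criterion_spec()]) and `planted` (named character vector of planted
#'   alternative identifiers).
#' @examples
#' sim <- simulate_decision_problem(10, 4, plant_ideal = TRUE, seed = 7)
#' bibeta_pipeline(sim$dm, sim$specs)$scores[1, ]
#' @export
simulate_decision_problem <- function(n_alternatives, n_criteria,
                                      value_range = c(0, 100),
                                      plant_ideal = FALSE,
                                      plant_worst = FALSE, seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  if (length(value_range) != 2L || value_range[1L] >= value_range[2L] ||
      value_range[1L] < 0 || value_range[2L] > 100)
    stop("value_range must be c(low, high) within [0, 100]")
  n_plant <- plant_ideal + plant_worst
  if (n_alternatives < 2L + (n_plant == 2L))
    stop("infeasible config: too few alternatives for the requested plants")
  n_free <- n_alternatives - n_plant
  if (n_free < 1L)
    stop("infeasible config: at least one free alternative required")

  with_seed(seed, {
    free <- matrix(stats::runif(n_free * n_criteria, value_range[1L],
                                value_range[2L]),
                   nrow = n_free, ncol = n_criteria)
    rows <- free
    alt <- sprintf("alt%03d", seq_len(n_free))
    ideal_vec <- colMeans(free)
    planted <- character(0)
    if (plant_ideal) {
      rows <- rbind(rows, ideal_vec)
      alt <- c(alt, "planted_ideal")
      planted <- c(planted, ideal = "planted_ideal")
    }
    if (plant_worst) {
      # farthest end of the value range from each ideal; ties go high
      lo_dev <- abs(value_range[1L] - ideal_vec)
      hi_dev <- abs(value_range[2L] - ideal_vec)
      worst <- ifelse(hi_dev >= lo_dev, value_range[2L], value_range[1L])
      rows <- rbind(rows, worst)
      alt <- c(alt, "planted_worst")
      planted <- c(planted, worst = "planted_worst")
    }
    crit <- sprintf("crit%02d", seq_len(n_criteria))
    dm <- decision_matrix(rows, alternatives = alt, criteria = crit)
    ideal_arg <- if (n_plant > 0L) ideal_vec else NA_real_
    specs <- criterion_spec(crit, direction = "max", ideal = ideal_arg)
    list(dm = dm, specs = specs, planted = planted)
  })
}

#' Simulate paired rankings with tunable monotone association
#'
#' Generates `n` paired scores whose rank agreement is controlled by
#' `association`: 1 copies the first vector (perfect concordance), -1
#' applies a strictly decreasing transform (perfect discordance), and
#' intermediate values mix the first vector with independent Gaussian
#' noise so the expected rank correlation grows with `association`. Ties
#' are injected into the second vector by equalising consecutive order
#' statistics until about `tie_fraction * n` items share a value.
#'
#' @param n number of paired items, `n >= 2`.
#' @param association target monotone association in \[-1, 1\].
#' @param tie_fraction fraction of items in \[0, 1) to involve in ties.
#' @param seed mandatory integer seed.
#' @return Data frame with columns `item`, `x`, `y`.
#' @examples
#' pr <- simulate_paired_rankings(20, association = 1, seed = 3)
#' spearman_concordance(pr$x, pr$y)$statistic  # exactly 1
#' @export
simulate_paired_rankings <- function(n, association = 0, tie_fraction = 0,
                                     seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  if (n < 2L) stop("need n >= 2")
  if (!is.finite(association) || association < -1 || association > 1)
    stop("association must lie in [-1, 1]")
  if (tie_fraction < 0 || tie_fraction >= 1)
    stop("tie_fraction must lie in [0, 1)")
  with_seed(seed, {
    x <- stats::runif(n, 0, 100)
    y <- if (association == 1) {
      x
    } else if (association == -1) {
      100 - x
    } else {
      z <- as.numeric(scale(x))
      association * z + sqrt(1 - association^2) * stats::rnorm(n)
    }
    n_tied <- round(tie_fraction * n)
    if (n_tied >= 2L) {
      ord <- order(y)
      # equalise consecutive pairs among the first n_tied order statistics
      for (i in seq(1L, n_tied - 1L, by = 2L))
        y[ord[i + 1L]] <- y[ord[i]]
    }
    data.frame(item = sprintf("it%03d", seq_len(n)), x = x, y = y,
               stringsAsFactors = FALSE)
  })
}
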