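# Independent entry-by-entry oracle for the scoring pipeline: explicit
# loops over alternatives and criteria, no calls into the package's stage
# functions. Supplied ideals take precedence; NULL means column means.
naive_bibeta <- function(values, weights = NULL, ideals = NULL) {
  n <- nrow(values); m <- ncol(values)
  if (is.null(weights)) weights <- rep(1 / m, m)
  F <- matrix(0, n, m)
  for (j in seq_len(m)) {
    ideal_j <- if (is.null(ideals)) sum(values[, j]) / n else ideals[j]
    for (i in seq_len(n)) F[i, j] <- abs(values[i, j] - ideal_j)
  }
  A <- matrix(0, n, m)
  for (j in seq_len(m)) {
    y <- max(F[, j])
    for (i in seq_len(n)) A[i, j] <- weights[j] * log(y - F[i, j] + 1)
  }
  b <- 0
  for (j in seq_len(m)) b <- b + max(A[, j])
  t_ci <- numeric(n)
  for (i in seq_len(n)) t_ci[i] <- sum(A[i, ])
  list(t_ci = t_ci, b_ri = b, score = 100 * t_ci / b)
}

# Brute-force Kendall tau-a: double loop over all ordered pairs.
naive_tau_a <- function(x, y) {
  n <- length(x); conc <- 0; disc <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
    if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
  }
  2 * (conc - disc) / (n * (n - 1))
}

# A small GHSI-style wide CSV fixture with all 37 indicator columns,
# written under the given path. Scores are seeded uniforms on [0, 100].
write_ghsi_fixture <- function(path, countries = c("Atlantis", "Borduria",
                                                   "Carpania"),
                               years = 2021, seed = 42,
                               tweak = identity) {
  map <- ghsi_code_map()
  set.seed(seed)
  rows <- expand.grid(Country = countries, Year = years,
                      stringsAsFactors = FALSE)
  scores <- matrix(round(runif(nrow(rows) * nrow(map), 0, 100), 1),
                   nrow = nrow(rows))
  colnames(scores) <- map$indicator
  wide <- cbind(rows, ISO3 = toupper(substr(rows$Country, 1, 3)), scores)
  wide <- tweak(wide)
  utils::write.csv(wide, path, row.names = FALSE)
  invisible(path)
}

# All n! permutations of 1..n (recursive construction, test-side copy kept
# independent of the package internals it is used to check).
combinat_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- combinat_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(pos) {
    cbind(sub, n)[, append(seq_len(n - 1L), n, after = pos - 1L),
                  drop = FALSE]
  }))
}
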