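dm3 <- decision_matrix(rbind(A = c(10, 40), B = c(20, 60), C = c(30, 80)),
                       criteria = c("c1", "c2"))

test_that("ideal resolution honours supplied, mean, and mixed policies", {
  specs_mean <- criterion_spec(c("c1", "c2"))
  expect_equal(resolve_ideals(dm3, specs_mean),
               c(c1 = 20, c2 = 60))
  specs_sup <- criterion_spec(c("c1", "c2"), ideal = c(5, 7))
  expect_equal(resolve_ideals(dm3, specs_sup), c(c1 = 5, c2 = 7))
  specs_mix <- criterion_spec(c("c1", "c2"), ideal = c(5, NA))
  expect_equal(resolve_ideals(dm3, specs_mix), c(c1 = 5, c2 = 60))
  # zero is a legitimate ideal
  dmz <- decision_matrix(matrix(0, 3, 1, dimnames = list(LETTERS[1:3], "z")))
  expect_equal(resolve_ideals(dmz, criterion_spec("z")), c(z = 0))
  # misaligned specs are rejected
  expect_error(resolve_ideals(dm3, criterion_spec(c("c2", "c1"))),
               "does not match")
})

test_that("difference matrix is the absolute deviation from the ideal", {
  F <- difference_matrix(dm3, c(20, 60))
  expect_equal(unname(F), rbind(c(10, 20), c(0, 0), c(10, 20)))
  expect_true(all(F >= 0))
  # every row at the ideal -> all-zero deviations
  dmi <- decision_matrix(matrix(c(20, 20, 60, 60), 2, 2,
                                dimnames = list(c("A", "B"), c("c1", "c2"))))
  expect_true(all(difference_matrix(dmi, c(20, 60)) == 0))
  # symmetric deviation around the ideal
  dms <- decision_matrix(matrix(c(0, 100), 2, 1,
                                dimnames = list(c("A", "B"), "c")))
  expect_equal(unname(difference_matrix(dms, 50)), cbind(c(50, 50)))
})

test_that("matching matrix reflects deviations against the column worst", {
  F <- difference_matrix(dm3, c(20, 60))
  mm <- matching_matrix(F)
  expect_equal(unname(mm$Y_minus), c(10, 20))
  expect_equal(unname(mm$M), rbind(c(0, 0), c(10, 20), c(0, 0)))
  # each column hits zero at the worst alternative
  expect_true(all(apply(mm$M, 2, min) == 0))
  # degenerate constant criterion
  mm0 <- matching_matrix(matrix(0, 3, 2))
  expect_equal(unname(mm0$Y_minus), c(0, 0))
  expect_true(all(mm0$M == 0))
  # direction_split preserves max-direction columns untouched
  mms <- matching_matrix(F, mode = "direction_split",
                         directions = c("max", "max"))
  expect_equal(mms$M, F)
  mmx <- matching_matrix(F, mode = "direction_split",
                         directions = c("max", "min"))
  expect_equal(mmx$M[, 1], F[, 1])
  expect_equal(unname(mmx$M[, 2]), c(0, 20, 0))
})

test_that("log transform is ln(M + 1), zero-preserving and increasing", {
  M <- rbind(c(0, 0), c(10, 20), c(0, 0))
  Q <- log_transform(M)
  expect_equal(Q, rbind(c(0, 0), c(log(11), log(21)), c(0, 0)))
  expect_equal(log_transform(matrix(exp(1) - 1)), matrix(1))
  expect_true(all(log_transform(matrix(0, 2, 2)) == 0))
  expect_error(log_transform(matrix(-1)), "negative")
})

test_that("weighting scales columns and enforces the sum-to-1 contract", {
  Q <- rbind(c(0, 0), c(log(11), log(21)), c(0, 0))
  A <- apply_weights(Q, c(0.5, 0.5))
  expect_equal(A, Q / 2)
  expect_equal(apply_weights(cbind(c(1, 2)), 1.0), cbind(c(1, 2)))
  expect_error(apply_weights(Q, c(0.6, 0.6)), "sum to 1")
})

test_that("index reference values are the column maxima", {
  A <- rbind(c(0, 0), c(1.19895, 1.52226), c(0, 0))
  expect_equal(unname(index_reference_values(A)), c(1.19895, 1.52226))
  expect_equal(unname(index_reference_values(matrix(0, 2, 2))), c(0, 0))
  one <- matrix(c(3, 7), 1, 2)
  expect_equal(unname(index_reference_values(one)), c(3, 7))
})

test_that("scores normalise in-class sums by the reference score", {
  A <- rbind(A = c(0, 0), B = c(1.19895, 1.52226), C = c(0, 0))
  R <- index_reference_values(A)
  st <- bibeta_scores(A, R)
  expect_equal(attr(st, "b_ri"), 2.72121)
  expect_equal(st$score, c(0, 100, 0))
  expect_true(all(st$score >= 0 & st$score <= 100))
  # all-constant criteria are unscorable
  expect_error(bibeta_scores(matrix(0, 2, 2), c(0, 0)), "unscorable")
})

test_that("competition ranking shares the minimum rank on ties", {
  A <- rbind(A = c(0, 0), B = c(1, 2), C = c(0, 0))
  st <- rank_alternatives(bibeta_scores(A, c(1, 2)))
  expect_equal(st$alternative, c("B", "A", "C"))
  expect_equal(st$rank, c(1L, 2L, 2L))
  # full tie -> everyone rank 1
  At <- rbind(A = c(1, 2), B = c(1, 2))
  expect_equal(rank_alternatives(bibeta_scores(At, c(1, 2)))$rank,
               c(1L, 1L))
  # distinct scores -> the permutation sorting scores descending
  Ad <- rbind(A = c(0.1, 0), B = c(0.6, 0), C = c(0.3, 0.2))
  std <- rank_alternatives(bibeta_scores(Ad, c(0.6, 0.2)))
  expect_equal(std$rank, 1:3)
  expect_equal(std$alternative, c("B", "C", "A"))
})
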