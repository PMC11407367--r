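test_that("hand-computed rank statistics are reproduced", {
  x <- c(1, 2, 3, 4); y <- c(2, 1, 4, 3)
  # S_s = 4 -> r_s = 1 - 24/60 = 0.6
  expect_equal(spearman_concordance(x, y, variant = "paper")$statistic, 0.6)
  # p = 4, q = 2 -> tau_a = 2(4-2)/12 = 1/3
  expect_equal(kendall_concordance(x, y, variant = "tau_a")$statistic, 1 / 3)
})

test_that("perfect agreement and perfect reversal hit the bounds", {
  for (n in c(2L, 5L, 20L)) {
    x <- seq_len(n)
    expect_equal(spearman_concordance(x, x)$statistic, 1)
    expect_equal(kendall_concordance(x, x)$statistic, 1)
    expect_equal(spearman_concordance(x, rev(x))$statistic, -1)
    expect_equal(kendall_concordance(x, rev(x))$statistic, -1)
  }
})

test_that("variants coincide on tie-free data and differ under ties", {
  set.seed(31)
  x <- rnorm(12); y <- rnorm(12)
  expect_equal(spearman_concordance(x, y, variant = "paper")$statistic,
               spearman_concordance(x, y)$statistic, tolerance = 1e-12)
  expect_equal(kendall_concordance(x, y, variant = "tau_a")$statistic,
               kendall_concordance(x, y)$statistic, tolerance = 1e-12)
  # with ties tau_b corrects the denominator upward in magnitude
  xt <- c(1, 1, 2, 3, 3, 4); yt <- c(2, 1, 3, 3, 5, 6)
  ta <- kendall_concordance(xt, yt, variant = "tau_a")$statistic
  tb <- kendall_concordance(xt, yt, variant = "tau_b")$statistic
  expect_gt(abs(tb), abs(ta))
})

test_that("tie-corrected variants agree with stats::cor.test estimates", {
  set.seed(77)
  x <- sample(1:8, 30, replace = TRUE)  # heavy ties
  y <- x + sample(1:5, 30, replace = TRUE)
  sp <- spearman_concordance(x, y, p_method = "approx")
  kd <- kendall_concordance(x, y, p_method = "approx")
  expect_equal(sp$statistic,
               unname(suppressWarnings(
                 stats::cor.test(x, y, method = "spearman")$estimate)),
               tolerance = 1e-12)
  expect_equal(kd$statistic,
               unname(suppressWarnings(
                 stats::cor.test(x, y, method = "kendall")$estimate)),
               tolerance = 1e-12)
})

test_that("statistics are invariant to strictly increasing transforms", {
  set.seed(41)
  x <- runif(15); y <- runif(15)
  f <- function(v) exp(3 * v) + 2
  for (fun in list(spearman_concordance, kendall_concordance)) {
    base <- fun(x, y, p_method = "approx")$statistic
    expect_equal(fun(f(x), y, p_method = "approx")$statistic, base,
                 tolerance = 1e-12)
    expect_equal(fun(x, f(y), p_method = "approx")$statistic, base,
                 tolerance = 1e-12)
    # reversing one ranking negates the statistic (tie-free data)
    expect_equal(fun(x, -y, p_method = "approx")$statistic, -base,
                 tolerance = 1e-12)
  }
})

test_that("tau-a matches the brute-force double loop on random data", {
  set.seed(53)
  for (rep in 1:10) {
    n <- sample(3:7, 1)
    x <- sample(n); y <- sample(1:4, n, replace = TRUE)
    expect_equal(kendall_concordance(x, y, variant = "tau_a",
                                     p_method = "approx")$statistic,
                 naive_tau_a(x, y), tolerance = 1e-12)
  }
})

test_that("degenerate inputs are signalled", {
  expect_error(spearman_concordance(1, 1), "at least 2")
  expect_error(spearman_concordance(c(1, 1, 1), c(1, 2, 3)),
               "constant ranking")
  expect_error(kendall_concordance(c(2, 2), c(1, 2)), "undefined")
  # tau_a on a constant vector is 0, not an error
  expect_equal(kendall_concordance(c(1, 1, 1), c(1, 2, 3),
                                   variant = "tau_a")$statistic, 0)
})

test_that("monotonic-association test reports both statistics and H0", {
  mt <- test_monotonic_association(1:20, (1:20)^2)
  expect_equal(mt$spearman$statistic, 1)
  expect_equal(mt$kendall$statistic, 1)
  expect_true(all(mt$reject))
  # n = 2 identical: statistics 1 but never significant (p = 1, the only
  # two permutations both attain |r| = 1)
  mt2 <- test_monotonic_association(1:2, 1:2)
  expect_equal(mt2$spearman$statistic, 1)
  expect_equal(mt2$spearman$p_value, 1)
  expect_false(any(mt2$reject))
})

test_that("concordance report joins score tables by alternative", {
  a <- data.frame(alternative = c("A", "B", "C", "D"),
                  score = c(90, 70, 50, 30))
  rep1 <- concordance_report(a, a)
  expect_equal(rep1$statistic, c(1, 1))
  expect_equal(rep1$n, c(4L, 4L))
  # a reshuffled, partially overlapping table joins on shared ids
  b <- data.frame(alternative = c("D", "C", "B", "E"),
                  score = c(10, 20, 40, 99))
  rep2 <- concordance_report(a, b)
  expect_equal(rep2$n, c(3L, 3L))
  expect_equal(rep2$statistic, c(1, 1))  # same ordering on B, C, D
  disjoint <- data.frame(alternative = c("X", "Y"), score = c(1, 2))
  expect_error(concordance_report(a, disjoint), "shared alternatives")
})
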