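test_that("unconfounded pairs exclude same-subtask combinations", {
  p6 <- unconfounded_pairs(paste0("s", 1:6))
  expect_equal(nrow(p6), 30L)
  expect_true(all(p6$coherence_subtask != p6$accuracy_subtask))
  expect_equal(nrow(unconfounded_pairs(c("a", "b"))), 2L)
  expect_error(unconfounded_pairs(c("a", "a")), "distinct")
})

test_that("correlation table recovers perfect and null relationships", {
  # incoherence identical to inaccuracy for every participant: r = 1 everywhere
  set.seed(3)
  v <- runif(40)
  sc <- make_scores(40, function(i, j) v[i], function(i, j) v[i])
  ct <- correlation_table(sc)
  expect_equal(nrow(ct), 30L)
  expect_true(all(abs(ct$r - 1) < 1e-12))
  # independent random scores: mean r near 0 (Monte-Carlo null, n = 1e4)
  set.seed(4)
  null_sc <- make_scores(1e4, function(i, j) runif(length(i)),
                         function(i, j) runif(length(i)))
  ctn <- correlation_table(null_sc)
  expect_lt(max(abs(ctn$r)), 4 / sqrt(1e4))
  # zero-variance column is flagged undefined
  flat <- make_scores(10, function(i, j) rep(0.5, length(i)),
                      function(i, j) runif(length(i)))
  ctf <- correlation_table(flat)
  expect_true(all(!ctf$defined) && all(is.na(ctf$r)))
})

test_that("sampler cohorts yield positive correlations in all 30 pairs", {
  tp <- cached_truth()
  spec <- cohort_spec(group_sizes = c(expert = 186L))
  co <- generate_cohort(spec, tp, seed = 21)
  ct <- correlation_table(score_cohort(co$responses, tp))
  expect_true(all(ct$defined))
  expect_true(all(ct$r > 0))
})

test_that("bootstrap of the mean correlation: degenerate and perfect cases", {
  set.seed(5)
  v <- runif(30)
  perfect <- make_scores(30, function(i, j) v[i], function(i, j) v[i])
  b <- bootstrap_mean_correlation(perfect, B = 200, seed = 1)
  expect_equal(b$mean_r, 1)
  expect_equal(c(b$ci_low, b$ci_high), c(1, 1))
  identical_rows <- make_scores(10, function(i, j) rep(0.4, length(i)),
                                function(i, j) rep(0.2, length(i)))
  expect_error(bootstrap_mean_correlation(identical_rows, B = 50, seed = 1),
               "degenerate")
  # reproducible under the same seed
  sc <- make_scores(25, function(i, j) runif(length(i)),
                    function(i, j) runif(length(i)))
  expect_identical(bootstrap_mean_correlation(sc, B = 100, seed = 7),
                   bootstrap_mean_correlation(sc, B = 100, seed = 7))
})

test_that("bootstrap CI covers a known positive population mean correlation", {
  tp <- cached_truth()
  spec <- cohort_spec(group_sizes = c(expert = 80L))
  set.seed(31)
  experiments <- lapply(1:30, function(i)
    score_cohort(generate_cohort(spec, tp)$responses, tp))
  points <- vapply(experiments, function(sc) {
    w <- cohacc:::scores_wide(sc)
    cohacc:::mean_cross_correlation(w$incoherence, w$inaccuracy)
  }, numeric(1))
  truth_r <- mean(points)  # Monte-Carlo population value
  covered <- vapply(experiments, function(sc) {
    b <- bootstrap_mean_correlation(sc, B = 400)
    b$ci_low <= truth_r && truth_r <= b$ci_high
  }, logical(1))
  expect_gte(mean(covered), 0.8)  # nominal 95%, 30 experiments
})

test_that("partial correlation matches the closed-form first-order formula", {
  set.seed(8)
  n <- 200
  z <- rnorm(n)
  x <- 0.5 * z + rnorm(n)
  y <- -0.3 * z + 0.4 * x + rnorm(n)
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  closed <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  expect_equal(partial_correlation(x, y, z), closed)
  # covariate independent of both: partial r near the full r
  w <- rnorm(n)
  expect_equal(partial_correlation(x, y, w), rxy, tolerance = 0.05)
  # covariate identical to x: degenerate, flagged NA
  expect_true(is.na(partial_correlation(x, y, x)))
  expect_error(partial_correlation(x[1:3], y[1:3], z[1:3]), "length")
})

test_that("partial reduction for an independent covariate covers zero", {
  tp <- cached_truth()
  spec <- cohort_spec(group_sizes = c(expert = 186L))
  co <- generate_cohort(spec, tp, seed = 41)
  sc <- score_cohort(co$responses, tp)
  pp <- co$responses[!duplicated(co$responses$participant_id), ]
  z <- stats::setNames(pp$GFM, pp$participant_id)
  red <- bootstrap_partial_reduction(sc, z, B = 1000, seed = 2)
  expect_lte(red$ci_low, 0)
  expect_gte(red$ci_high, 0)
  expect_lt(abs(red$reduction), 0.05)
})

test_that("Welch test handles identical samples and the balanced-variance case", {
  x <- c(1, 2, 3, 4, 5)
  w <- welch_t(x, x)
  expect_equal(w$statistic, 0)
  expect_equal(w$p_value, 1)
  set.seed(9)
  a <- rnorm(20); b <- a + 0.3  # equal variances, equal n: df = 2n - 2
  expect_equal(welch_t(a, b)$df, 38)
  expect_error(welch_t(1, x), "at least 2")
})
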