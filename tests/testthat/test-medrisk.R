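test_that("four-question design enforces the ratio constraint", {
  d <- medrisk_design()
  expect_equal(unname(d$truths),
               c(0.177, 0.028, 0.4, 0.8))
  expect_equal(d$truths[["p_c_given_pos"]] / d$truths[["p_pos_given_c"]], 0.5)
  expect_error(medrisk_design(p_pos_given_c = 0), "truths")
})

test_that("cohort simulation: uniform baseline, sampler variance, determinism", {
  d <- medrisk_design()
  set.seed(1)
  u <- simulate_medrisk_cohort(d, "random_uniform")
  expect_equal(dim(u), c(125L, 4L))
  big <- simulate_medrisk_cohort(medrisk_design(n_participants = 2e4),
                              "random_uniform", seed = 2)
  expect_equal(colMeans(big), rep(0.5, 4), tolerance = 0.02,
               ignore_attr = TRUE)
  # forcing every participant to N = 10 removes the mixture variance
  mixed <- sampler_params()
  pure <- sampler_params(mixture = c(novice = 0.7, amateur = 0.7, expert = 0))
  dbig <- medrisk_design(n_participants = 2e4)
  v_mixed <- var(simulate_medrisk_cohort(dbig, "sampler_expert", mixed, seed = 3)[, 1])
  v_pure <- var(simulate_medrisk_cohort(dbig, "sampler_expert", pure, seed = 4)[, 1])
  expect_lt(v_pure, v_mixed)
  expect_identical(simulate_medrisk_cohort(d, "sampler_expert", seed = 5),
                   simulate_medrisk_cohort(d, "sampler_expert", seed = 5))
  expect_error(simulate_medrisk_cohort(d, "telepathic"))
})

test_that("log-percentage scores follow their definitions", {
  d <- medrisk_design()
  est <- rbind(c(0.177, 0.028, 0.4, 0.8),          # truthful: both scores 0
               c(0.354, 0.028, 0.4, 0.4))          # known deviations
  sc <- medrisk_scores(est, d)
  expect_equal(sc$incoherence[1], 0)
  expect_equal(sc$inaccuracy[1], 0)
  expect_equal(sc$inaccuracy[2], 100 * log(2) / 2)  # one question off by 2x
  expect_equal(sc$incoherence[2], 100 * log(2))     # ratio 1 vs required 0.5
  # epsilon floor keeps zero estimates finite
  z <- medrisk_scores(rbind(c(0, 0.028, 0.4, 0.8)), d)
  expect_true(is.finite(z$inaccuracy))
})

test_that("cohort correlation: perfect, degenerate and vectorized p values", {
  sc <- data.frame(incoherence = 1:10, inaccuracy = 1:10)
  expect_equal(medrisk_correlation(sc), 1)
  flat <- data.frame(incoherence = rep(1, 10), inaccuracy = runif(10))
  expect_true(is.na(medrisk_correlation(flat)))
  set.seed(12)
  x <- rnorm(40); y <- rnorm(40)
  expect_equal(cohacc:::pearson_p(cor(x, y), 40),
               cor.test(x, y)$p.value)
})

test_that("power analysis calibrates: alpha = 1 saturates, null mode at 5%", {
  d1 <- medrisk_design(alpha = 1)
  pw1 <- medrisk_power(d1, "sampler_expert", n_experiments = 50, seed = 6)
  expect_equal(pw1$prop_significant, 1)
  d <- medrisk_design()
  pw0 <- medrisk_power(d, "random_uniform", n_experiments = 2000, seed = 7)
  expect_lt(abs(pw0$prop_significant - 0.05), 0.02)  # type-I error
  expect_lt(abs(pw0$mean_r), 0.02)
})

test_that("sensitivity sweep keeps the positive link across assumed conditionals", {
  sens <- medrisk_sensitivity(p_pos_grid = c(0.4, 0.8), n_experiments = 300,
                           seed = 8)
  expect_equal(sens$p_c_given_pos, sens$p_pos_given_c * 0.5)
  expect_true(all(sens$mean_r > 0))
})
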