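test_that("generator modes: truthful is exact, uniform is maximally incoherent", {
  tp <- cached_truth()
  truthful <- generate_cohort(cohort_spec(mode = "truthful"), tp, seed = 1)
  expect_equal(nrow(truthful$responses), 268L * 18L)
  expect_equal(truthful$responses$frequency,
               rep(1000 * tp$probability, 268L), ignore_attr = TRUE)
  # uniform responses: triple sums average 1.5; |1 - sum| averages at least
  # |E(sum) - 1| = 0.5 (Jensen)
  uni <- generate_cohort(cohort_spec(group_sizes = c(expert = 400L),
                                     mode = "random_uniform"), tp, seed = 2)
  sc <- score_cohort(uni$responses, tp)
  sums <- with(uni$responses,
               tapply(frequency / 1000,
                      list(participant_id, paste(task, subtask)), sum))
  expect_equal(mean(sums), 1.5, tolerance = 0.02)
  expect_gte(mean(sc$incoherence), 0.45)
  expect_lte(mean(sc$incoherence), 0.75)
  expect_error(cohort_spec(mode = "psychic"))
})

test_that("default cohorts reproduce the expert advantage and task equivalence", {
  tp <- cached_truth()
  co <- generate_cohort(cohort_spec(), tp, seed = 3)
  expect_equal(as.integer(table(co$latent$group)[c("novice", "amateur", "expert")]),
               c(45L, 37L, 186L))
  sc <- score_cohort(co$responses, tp)
  m <- stats::aggregate(sc[c("incoherence", "inaccuracy")],
                        by = list(group = sc$group), mean)
  expect_lt(m$incoherence[m$group == "expert"], m$incoherence[m$group == "novice"])
  expect_lt(m$inaccuracy[m$group == "expert"], m$inaccuracy[m$group == "novice"])
  # matched card/ball events share the true model: near-equal mean scores
  task <- sub("_.*", "", sc$subtask_id)
  expect_equal(mean(sc$incoherence[task == "card"]),
               mean(sc$incoherence[task == "ball"]), tolerance = 0.05)
  # covariates within their documented ranges
  expect_true(all(co$responses$RPE %in% 0:4))
  expect_true(all(co$responses$GFM %in% 0:10))
  expect_identical(generate_cohort(cohort_spec(), tp, seed = 3), co)
})

test_that("latent sample size is recoverable from responses", {
  tp <- cached_truth()
  co <- generate_cohort(cohort_spec(group_sizes = c(novice = 150L)), tp, seed = 4)
  rec <- recover_sample_size_structure(co, tp)
  # continuous mode: N = 1 responses live on {1/3, 2/3}, perfectly separable
  expect_equal(rec$accuracy, 1)
  # integer-rounded responses: accuracy at least 99% on >= 1e3 participants
  coi <- generate_cohort(cohort_spec(group_sizes = c(novice = 500L, expert = 500L),
                                     integer_frequencies = TRUE), tp, seed = 5)
  expect_true(all(coi$responses$frequency == round(coi$responses$frequency)))
  reci <- recover_sample_size_structure(coi, tp)
  expect_gte(reci$accuracy, 0.99)
  # degenerate single-class spec classifies into the single class
  cod <- generate_cohort(cohort_spec(group_sizes = c(novice = 30L),
    params = sampler_params(mixture = c(novice = 1))), tp, seed = 6)
  recd <- recover_sample_size_structure(cod, tp)
  expect_true(all(recd$classification$recovered_N == 1L))
  expect_error(recover_sample_size_structure(
    generate_cohort(cohort_spec(mode = "truthful"), tp, seed = 7)), "sampler")
})
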