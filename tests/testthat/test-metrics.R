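test_that("additivity incoherence is the absolute deviation of the sum from 1", {
  expect_equal(subtask_incoherence(c(0.3, 0.3, 0.4)), 0)
  expect_equal(subtask_incoherence(c(0.5, 0.4, 0.3)), 0.2)
  expect_equal(subtask_incoherence(rep(1 / 3, 3)), 0)
  expect_equal(subtask_incoherence(c(0.5, 0.3, 0.1)),
               subtask_incoherence(c(0.5, 0.3, 0.3)))  # |.|: 0.9 vs 1.1
  expect_error(subtask_incoherence(c(0.5, 0.5)), "three")
  expect_error(subtask_incoherence(c(0.5, 0.5, 1.5)), "\\[0, 1\\]")
})

test_that("sure loss equals incoherence and the book is verified by outcome enumeration", {
  # oracle: settle the constructed book under each of the three exclusive
  # outcomes; the judge must lose the same amount in every one
  settle <- function(prices, book) {
    vapply(1:3, function(winner) {
      payoff <- as.numeric(1:3 == winner)
      if (book == "buy_all") sum(payoff) - sum(prices)       # opponent buys
      else if (book == "sell_all") sum(prices) - sum(payoff) # opponent sells
      else 0
    }, numeric(1))
  }
  for (prices in list(c(0.5, 0.4, 0.3), c(0.1, 0.2, 0.3), c(0.3, 0.3, 0.4),
                      c(1, 1, 1), c(0, 0, 0.2))) {
    sl <- sure_loss(prices)
    expect_equal(sl$loss, subtask_incoherence(prices))
    gains <- settle(prices, sl$book)
    expect_equal(gains, rep(sl$loss, 3))  # guaranteed in every outcome
  }
  expect_equal(sure_loss(c(0.3, 0.3, 0.4))$book, "none")
})

test_that("inaccuracy sums absolute deviations and is order-symmetric", {
  tr <- c(0.052, 0.551, 0.398)
  expect_equal(subtask_inaccuracy(tr, tr), 0)
  expect_equal(subtask_inaccuracy(c(0.152, 0.451, 0.398), tr), 0.2)
  perm <- c(3, 1, 2)
  expect_equal(subtask_inaccuracy(c(0.2, 0.5, 0.3)[perm], tr[perm]),
               subtask_inaccuracy(c(0.2, 0.5, 0.3), tr))
})

test_that("extension errors count strict violations of set inclusion", {
  stim <- build_stimulus_set()
  np <- stim$nested_pairs[stim$nested_pairs$task == "card", ]
  tp <- cached_truth()
  truthful <- stats::setNames(tp$probability, tp$event_id)
  expect_equal(count_extension_errors(truthful, np), 0L)
  resp <- truthful
  resp["card_kind3"] <- 0.3
  resp["card_suit1"] <- 0.2  # 3-of-a-kind judged above 3-different-suits
  expect_equal(count_extension_errors(resp, np), 1L)
  resp["card_run0"] <- 0.25  # now also above no-2-in-a-row
  expect_equal(count_extension_errors(resp, np), 2L)
  inverted <- truthful
  inverted[np$restricted] <- 0.9
  inverted[np$general] <- 0.1
  expect_equal(count_extension_errors(inverted, np), 4L)
  # ties are not errors
  tied <- truthful
  tied[unique(c(np$restricted, np$general))] <- 0.3
  expect_equal(count_extension_errors(tied, np), 0L)
  expect_error(count_extension_errors(truthful[-1], np), "missing")
})

test_that("matching inconsistency averages |card - ball| over the nine pairs", {
  stim <- build_stimulus_set()
  tp <- cached_truth()
  resp <- stats::setNames(tp$probability, tp$event_id)
  expect_equal(matching_inconsistency(resp, resp, stim$matched_pairs), 0)
  shifted <- resp
  shifted["ball_run3"] <- shifted["ball_run3"] + 0.09
  expect_equal(matching_inconsistency(resp, shifted, stim$matched_pairs), 0.01)
  expect_equal(matching_inconsistency(resp, shifted, stim$matched_pairs,
                                      aggregate = "sum"), 0.09)
  # symmetric in the task labels
  expect_equal(matching_inconsistency(shifted, resp,
                 data.frame(card = stim$matched_pairs$ball,
                            ball = stim$matched_pairs$card)), 0.01)
})

test_that("middle-item inaccuracy uses only the three middle events", {
  tp <- cached_truth()
  resp <- stats::setNames(tp$probability, tp$event_id)
  expect_equal(middle_item_inaccuracy(resp, tp, "card"), 0)
  mids <- tp$event_id[tp$task == "card" & tp$role == "middle"]
  resp[mids] <- pmin(1, resp[mids] + 0.05)
  expect_equal(middle_item_inaccuracy(resp, tp, "card"), 0.15)
  resp[setdiff(names(resp), mids)] <- 0.999  # non-middle responses irrelevant
  expect_equal(middle_item_inaccuracy(resp, tp, "card"), 0.15)
  expect_error(middle_item_inaccuracy(resp[mids[-1]], tp, "card"), "missing")
})

test_that("cohort scoring: zero iff truthful; more samples give better scores", {
  tp <- cached_truth()
  truthful <- generate_cohort(cohort_spec(mode = "truthful"), tp, seed = 1)
  sc <- score_cohort(truthful$responses, tp)
  expect_true(all(sc$incoherence == 0) && all(sc$inaccuracy == 0))
  aux <- score_aux(truthful$responses, tp, build_stimulus_set())
  expect_true(all(aux$extension_errors_card == 0) &&
              all(aux$inconsistency == 0))
  # pure N = 1 vs pure N = 10 populations (Monte Carlo over >= 1e4 participants)
  one_n <- function(n_small_prob, seed) {
    spec <- cohort_spec(group_sizes = c(novice = 600L),
                        params = sampler_params(mixture = c(novice = n_small_prob)))
    sc <- score_cohort(generate_cohort(spec, tp, seed = seed)$responses, tp)
    c(mean(sc$incoherence), mean(sc$inaccuracy))
  }
  m1 <- one_n(1, 11)   # all N = 1
  m10 <- one_n(0, 12)  # all N = 10
  expect_true(all(m10 < m1))
})
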