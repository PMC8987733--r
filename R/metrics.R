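#' Additivity incoherence of an exhaustive triple
#'
#' The three events of a subtask are mutually exclusive and exhaustive, so
#' coherent probability estimates must sum to 1. Incoherence is the absolute
#' deviation of the sum from 1, which equals the maximum guaranteed loss per
#' unit stake of a Dutch book against the stated prices (see [sure_loss()]).
#'
#' @param estimates numeric vector of exactly three probabilities in \[0, 1\].
#' @return non-negative score, 0 iff the triple is additive.
#' @examples
#' subtask_incoherence(c(0.5, 0.4, 0.3))  # 0.2
#' @export
subtask_incoherence <- function(estimates) {
  check_triple(estimates)
  abs(1 - sum(estimates))
}

#' Dutch-book sure loss implied by an incoherent triple
#'
#' If the stated prices of the three exclusive and exhaustive events sum to
#' s != 1, an opponent can guarantee a profit of |1 - s| per unit stake: buy
#' all three claims when s < 1 (pay s, collect 1 whichever event occurs) or
#' sell all three when s > 1. The loss to the judge equals
#' [subtask_incoherence()]; this function additionally reports the book.
#'
#' @inheritParams subtask_incoherence
#' @return list with `loss` (per unit stake) and `book` ("buy_all",
#'   "sell_all", or "none" for an additive triple).
#' @export
sure_loss <- function(estimates) {
  check_triple(estimates)
  s <- sum(estimates)
  list(loss = abs(1 - s),
       book = if (s < 1) "buy_all" else if (s > 1) "sell_all" else "none")
}

check_triple <- function(estimates) {
  if (length(estimates) != 3L)
    stop("a subtask consists of exactly three estimates", call. = FALSE)
  if (any(!is.finite(estimates)) || any(estimates < 0 | estimates > 1))
    stop("estimates must be probabilities in [0, 1]", call. = FALSE)
  invisible(estimates)
}

#' Inaccuracy of an exhaustive triple
#'
#' Sum of the three absolute differences between estimated and true
#' probabilities. On the probability scale; multiply by 1000 for the
#' frequency-out-of-1000 scale.
#'
#' @inheritParams subtask_incoherence
#' @param truths numeric vector of the three true probabilities, in the same
#'   event order as `estimates`.
#' @export
subtask_inaccuracy <- function(estimates, truths) {
  check_triple(estimates)
  check_triple(truths)
  sum(abs(estimates - truths))
}

#' Count extension errors in a set of judgments
#'
#' An extension error occurs when the judged probability of a restricted
#' event strictly exceeds that of an event containing it (e.g. 3-of-a-kind
#' judged more probable than 3-different-suits). Ties are not errors.
#'
#' @param responses named numeric vector of estimates, names are event ids.
#' @param nested_pairs data frame with columns `general` and `restricted`
#'   (event ids), as in [build_stimulus_set()]`$nested_pairs`.
#' @return integer count of violated pairs.
#' @export
count_extension_errors <- function(responses, nested_pairs) {
  need <- unique(c(nested_pairs$general, nested_pairs$restricted))
  miss <- setdiff(need, names(responses))
  if (length(miss))
    stop("responses missing events: ", paste(miss, collapse = ", "), call. = FALSE)
  sum(responses[nested_pairs$restricted] > responses[nested_pairs$general])
}

#' Inconsistency between matching Card and Ball questions
#'
#' Each Card question has a structurally identical Ball question with the
#' same answer; the absolute difference between the two estimates is an
#' incoherence of its own. Aggregated over the nine matched pairs by the
#' mean (default) or the sum.
#'
#' @param card_responses,ball_responses named numeric vectors of estimates
#'   (probability scale), names are event ids.
#' @param matched_pairs data frame with columns `card` and `ball` event ids.
#' @param aggregate "mean" (default) or "sum".
#' @export
matching_inconsistency <- function(card_responses, ball_responses,
                                   matched_pairs,
                                   aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  if (!all(matched_pairs$card %in% names(card_responses)) ||
      !all(matched_pairs$ball %in% names(ball_responses)))
    stop("responses do not cover all matched pairs", call. = FALSE)
  d <- abs(card_responses[matched_pairs$card] - ball_responses[matched_pairs$ball])
  if (aggregate == "mean") mean(d) else sum(d)
}

#' Inaccuracy over the middle stimuli of a task
#'
#' The extension-error count never involves the middle stimulus of any
#' subtask (the "exactly two of a feature" events), so the summed absolute
#' deviation of those three judgments from truth provides an accuracy
#' measure computed from disjoint responses — the unconfounded accuracy
#' partner for extension errors.
#'
#' @param responses named numeric vector of estimates (probability scale).
#' @param truth a [true_probabilities()] table.
#' @param task "card" or "ball".
#' @export
middle_item_inaccuracy <- function(responses, truth, task = c("card", "ball")) {
  task <- match.arg(task)
  mid <- truth[truth$task == task & truth$role == "middle", ]
  miss <- setdiff(mid$event_id, names(responses))
  if (length(miss))
    stop("responses missing middle events: ", paste(miss, collapse = ", "),
         call. = FALSE)
  sum(abs(responses[mid$event_id] - mid$probability))
}

#' Score a cohort: per-participant incoherence and inaccuracy by subtask
#'
#' Converts frequencies (out of 1000) to probabilities and computes, for each
#' participant and each of the six subtasks (card/ball x suit/run/kind), the
#' additivity incoherence and the inaccuracy.
#'
#' @param cohort a cohort table as produced by [generate_cohort()] or
#'   [read_response_table()]: long format with `participant_id`, `group`,
#'   `event_id`, `frequency`.
#' @param truth a [true_probabilities()] table.
#' @return data frame of class `cohacc_scores`: `participant_id`, `group`,
#'   `subtask_id`, `incoherence`, `inaccuracy`.
#' @export
score_cohort <- function(cohort, truth) {
  check_cohort(cohort, truth)
  truth_p <- stats::setNames(truth$probability, truth$event_id)
  subtask_of <- stats::setNames(truth$subtask_id, truth$event_id)
  est <- cohort$frequency / 1000
  key <- interaction(cohort$participant_id, subtask_of[cohort$event_id],
                     drop = TRUE, lex.order = TRUE)
  rows <- split(seq_len(nrow(cohort)), key)
  out <- do.call(rbind, lapply(rows, function(ix) {
    e <- est[ix]
    tr <- truth_p[cohort$event_id[ix]]
    data.frame(participant_id = cohort$participant_id[ix[1L]],
               group = cohort$group[ix[1L]],
               subtask_id = subtask_of[[cohort$event_id[ix[1L]]]],
               incoherence = subtask_incoherence(e),
               inaccuracy = subtask_inaccuracy(e, tr),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("cohacc_scores", "data.frame")
  out
}

#' Auxiliary coherence scores: extension errors, inconsistency, middle-item
#' inaccuracy
#'
#' @inheritParams score_cohort
#' @param stimulus a [build_stimulus_set()] object (for nested and matched
#'   pairs).
#' @return data frame: `participant_id`, `group`, `extension_errors_card`,
#'   `extension_errors_ball`, `inconsistency`, `middle_inaccuracy_card`,
#'   `middle_inaccuracy_ball`.
#' @export
score_aux <- function(cohort, truth, stimulus) {
  check_cohort(cohort, truth)
  pids <- unique(cohort$participant_id)
  rows <- lapply(pids, function(pid) {
    sub <- cohort[cohort$participant_id == pid, ]
    resp <- stats::setNames(sub$frequency / 1000, sub$event_id)
    np <- stimulus$nested_pairs
    data.frame(
      participant_id = pid, group = sub$group[1L],
      extension_errors_card = count_extension_errors(resp, np[np$task == "card", ]),
      extension_errors_ball = count_extension_errors(resp, np[np$task == "ball", ]),
      inconsistency = matching_inconsistency(resp, resp, stimulus$matched_pairs),
      middle_inaccuracy_card = middle_item_inaccuracy(resp, truth, "card"),
      middle_inaccuracy_ball = middle_item_inaccuracy(resp, truth, "ball"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

check_cohort <- function(cohort, truth = NULL) {
  need <- c("participant_id", "group", "event_id", "frequency")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(cohort$frequency < 0 | cohort$frequency > 1000))
    stop("frequencies must lie in [0, 1000]", call. = FALSE)
  if (anyDuplicated(cohort[, c("participant_id", "event_id")]))
    stop("duplicate participant x event records", call. = FALSE)
  if (!is.null(truth)) {
    bad <- setdiff(cohort$event_id, truth$event_id)
    if (length(bad))
      stop("unknown event ids: ", paste(unique(bad), collapse = ", "),
           call. = FALSE)
  }
  invisible(cohort)
}
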