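#' Construct a deck of playing cards
#'
#' Builds a deck as a data frame of distinct (rank, suit) cards. Rank 1 is the
#' Ace, which for straight-counting purposes is adjacent to both the 2 and the
#' King (the urn analogue is a "magic" ball of each colour that can sit at
#' either end of the ranking).
#'
#' @param n_ranks number of ranks (default 13).
#' @param n_suits number of suits (default 4).
#' @return data frame with columns `card_id`, `rank`, `suit`; one row per card.
#' @examples
#' nrow(standard_deck())  # 52
#' @export
standard_deck <- function(n_ranks = 13L, n_suits = 4L) {
  n_ranks <- as.integer(n_ranks)
  n_suits <- as.integer(n_suits)
  stopifnot(n_ranks >= 1L, n_suits >= 1L)
  d <- expand.grid(suit = seq_len(n_suits), rank = seq_len(n_ranks))
  d <- d[, c("rank", "suit")]
  d$card_id <- seq_len(nrow(d))
  d[, c("card_id", "rank", "suit")]
}

#' Enumerate all flops of a deck
#'
#' A flop is an unordered set of three distinct cards. Every 3-subset is
#' produced exactly once; the standard 52-card deck yields choose(52, 3) =
#' 22,100 flops.
#'
#' @param deck a deck from [standard_deck()] (any data frame with `card_id`,
#'   `rank`, `suit`).
#' @return integer matrix with one row per flop and three columns of
#'   `card_id`s in increasing order.
#' @examples
#' nrow(enumerate_flops(standard_deck(2, 2)))  # choose(4, 3) = 4
#' @export
enumerate_flops <- function(deck = standard_deck()) {
  check_deck(deck)
  if (nrow(deck) < 3L)
    stop("deck must contain at least 3 cards to form a flop", call. = FALSE)
  t(utils::combn(deck$card_id, 3L))
}

check_deck <- function(deck) {
  if (!is.data.frame(deck) || !all(c("card_id", "rank", "suit") %in% names(deck)))
    stop("deck must be a data frame with columns card_id, rank, suit", call. = FALSE)
  if (anyDuplicated(deck[, c("rank", "suit")]))
    stop("deck contains duplicate (rank, suit) cards", call. = FALSE)
  invisible(deck)
}

#' Count strategically distinct flops under suit isomorphism
#'
#' Two flops are strategically equivalent when one maps to the other under a
#' permutation of the suits (ranks fixed). Each flop is canonicalized by
#' taking the lexicographically minimal relabelling over all suit
#' permutations and distinct canonical forms are counted. The standard deck
#' has 1,755 classes among its 22,100 flops.
#'
#' @inheritParams enumerate_flops
#' @return integer number of suit-isomorphism classes.
#' @examples
#' canonical_class_count(standard_deck())  # 1755
#' @export
canonical_class_count <- function(deck = standard_deck()) {
  check_deck(deck)
  flops <- enumerate_flops(deck)
  n_suits <- max(deck$suit)
  rank <- matrix(deck$rank[flops], ncol = 3L)
  suit <- matrix(deck$suit[flops], ncol = 3L)
  perms <- perm_matrix(n_suits)
  base <- n_suits * (max(deck$rank) + 1L)
  best <- rep(Inf, nrow(flops))
  for (i in seq_len(nrow(perms))) {
    id <- (rank - 1L) * n_suits + perms[i, ][suit]  # relabelled card codes
    lo <- pmin(id[, 1L], id[, 2L], id[, 3L])
    hi <- pmax(id[, 1L], id[, 2L], id[, 3L])
    mid <- id[, 1L] + id[, 2L] + id[, 3L] - lo - hi
    key <- (lo * base + mid) * base + hi
    best <- pmin(best, key)
  }
  length(unique(best))
}

perm_matrix <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- perm_matrix(n - 1L)
  out <- matrix(0L, 0L, n)
  for (k in seq_len(n)) {
    ins <- cbind(sub[, seq_len(k - 1L), drop = FALSE], n,
                 sub[, seq(k, n - 1L)[seq_len(n - k)], drop = FALSE])
    out <- rbind(out, ins)
  }
  unname(out)
}

# Predicates over a flop, given its three ranks and three suits. "Runs" use
# rank adjacency with the Ace adjacent to both 2 and King, but no wrap-around
# 3-term run (K-A-2 is not a straight).
flop_suit_count <- function(ranks, suits) length(unique(suits))
flop_kind_max <- function(ranks, suits) max(table(ranks))
flop_is_run3 <- function(ranks, suits, n_ranks = 13L) {
  r <- sort(ranks)
  if (anyDuplicated(r)) return(FALSE)
  if (all(diff(r) == 1L)) return(TRUE)
  # Ace high: A-Q-K etc.
  if (r[1L] == 1L) {
    r2 <- sort(c(r[-1L], n_ranks + 1L))
    if (all(diff(r2) == 1L)) return(TRUE)
  }
  FALSE
}
flop_has_adjacent <- function(ranks, suits, n_ranks = 13L) {
  pr <- utils::combn(ranks, 2L)
  d <- abs(pr[1L, ] - pr[2L, ])
  any(d == 1L | d == n_ranks - 1L)
}

#' Build the nine-question stimulus set for the Card and Ball tasks
#'
#' Each task asks nine questions arranged in three subtasks, each a mutually
#' exclusive and exhaustive triple over all flops:
#' \describe{
#'   \item{suit}{all 3 same suit / exactly 2 same suit / 3 different suits}
#'   \item{run}{3 in a row / exactly 2 in a row / no 2 in a row}
#'   \item{kind}{3 of a kind / exactly one pair / no pair}
#' }
#' The Ball task is formally identical (colours for suits, a "magic" ball for
#' the Ace), so each Card question has a matching Ball question with the same
#' predicate. The set also records the four nested event pairs per task that
#' define extension errors: a restricted event whose judged probability
#' exceeding its superset's is an incoherence (e.g. 3-of-a-kind is a subset of
#' 3-different-suits).
#'
#' The construction is verified by full enumeration: each triple must
#' partition the flops and each nested pair must satisfy set inclusion;
#' violations stop with an error.
#'
#' @param deck deck over which predicates are verified (default standard).
#' @return object of class `cohacc_stimuli`: a list with `events` (data frame:
#'   `event_id`, `task`, `subtask`, `subtask_id`, `role`, `description`),
#'   `nested_pairs` (data frame: `task`, `general`, `restricted`),
#'   `matched_pairs` (data frame: `card`, `ball`), and `predicates`.
#' @export
build_stimulus_set <- function(deck = standard_deck()) {
  check_deck(deck)
  n_ranks <- max(deck$rank)
  preds <- list(
    suit3 = function(r, s) flop_suit_count(r, s) == 1L,
    suit2 = function(r, s) flop_suit_count(r, s) == 2L,
    suit1 = function(r, s) flop_suit_count(r, s) == 3L,
    run3  = function(r, s) flop_is_run3(r, s, n_ranks),
    run2  = function(r, s) !flop_is_run3(r, s, n_ranks) && flop_has_adjacent(r, s, n_ranks),
    run0  = function(r, s) !flop_is_run3(r, s, n_ranks) && !flop_has_adjacent(r, s, n_ranks),
    kind3 = function(r, s) flop_kind_max(r, s) == 3L,
    kind2 = function(r, s) flop_kind_max(r, s) == 2L,
    kind0 = function(r, s) flop_kind_max(r, s) == 1L
  )
  stem <- names(preds)
  descriptions <- c(
    suit3 = "all three cards of the same suit",
    suit2 = "exactly two cards of the same suit",
    suit1 = "three different suits",
    run3  = "three cards in a row",
    run2  = "exactly two cards in a row",
    run0  = "no two cards in a row",
    kind3 = "three of a kind",
    kind2 = "exactly one pair",
    kind0 = "no pair"
  )
  events <- data.frame(
    event_id = c(paste0("card_", stem), paste0("ball_", stem)),
    task = rep(c("card", "ball"), each = 9L),
    subtask = rep(rep(c("suit", "run", "kind"), each = 3L), 2L),
    role = rep(rep(c("low", "middle", "high"), 3L), 2L),
    description = rep(unname(descriptions), 2L),
    stringsAsFactors = FALSE
  )
  events$subtask_id <- paste(events$task, events$subtask, sep = "_")
  events <- events[, c("event_id", "task", "subtask", "subtask_id", "role",
                       "description")]
  predicates <- stats::setNames(rep(preds, 2L), events$event_id)

  nested_stem <- data.frame(
    general = c("suit1", "run0", "kind0", "kind0"),
    restricted = c("kind3", "kind3", "run3", "suit3"),
    stringsAsFactors = FALSE
  )
  nested_pairs <- do.call(rbind, lapply(c("card", "ball"), function(task)
    data.frame(task = task,
               general = paste0(task, "_", nested_stem$general),
               restricted = paste0(task, "_", nested_stem$restricted),
               stringsAsFactors = FALSE)))
  matched_pairs <- data.frame(card = paste0("card_", stem),
                              ball = paste0("ball_", stem),
                              stringsAsFactors = FALSE)
  out <- structure(list(events = events, nested_pairs = nested_pairs,
                        matched_pairs = matched_pairs, predicates = predicates,
                        deck = deck),
                   class = "cohacc_stimuli")
  validate_stimulus_set(out)
  out
}

# Exhaustiveness of each triple and inclusion of each nested pair, checked by
# enumerating every flop of the deck.
validate_stimulus_set <- function(stim) {
  deck <- stim$deck
  flops <- enumerate_flops(deck)
  ind <- event_indicators(stim, deck, flops)
  card <- stim$events$event_id[stim$events$task == "card"]
  for (sub in c("suit", "run", "kind")) {
    ids <- stim$events$event_id[stim$events$task == "card" & stim$events$subtask == sub]
    tot <- rowSums(ind[, ids, drop = FALSE])
    if (any(tot != 1L))
      stop("subtask '", sub, "' is not an exclusive and exhaustive partition",
           call. = FALSE)
  }
  np <- stim$nested_pairs[stim$nested_pairs$task == "card", ]
  if (nrow(np) != 4L) stop("expected 4 nested pairs per task", call. = FALSE)
  for (i in seq_len(nrow(np))) {
    if (any(ind[, np$restricted[i]] & !ind[, np$general[i]]))
      stop("nested pair violated: ", np$restricted[i], " not a subset of ",
           np$general[i], call. = FALSE)
  }
  invisible(stim)
}

# logical matrix: flop x card-task event
event_indicators <- function(stim, deck = stim$deck, flops = enumerate_flops(deck)) {
  rank <- matrix(deck$rank[flops], ncol = 3L)
  suit <- matrix(deck$suit[flops], ncol = 3L)
  ids <- stim$events$event_id[stim$events$task == "card"]
  out <- matrix(NA, nrow(flops), length(ids), dimnames = list(NULL, ids))
  for (id in ids) {
    f <- stim$predicates[[id]]
    out[, id] <- vapply(seq_len(nrow(flops)),
                        function(i) f(rank[i, ], suit[i, ]), logical(1L))
  }
  out
}

#' Exact true probabilities of the stimulus events
#'
#' Counts, by full enumeration over all flops, how many flops satisfy each
#' event and converts counts to probabilities and to expected frequencies out
#' of 1000 (the response format). Ball events inherit the values of their
#' matched Card events, since the urn is formally identical to the deck.
#'
#' @param stimulus a [build_stimulus_set()] object.
#' @return data frame of class `cohacc_truth` with columns `event_id`, `task`,
#'   `subtask`, `subtask_id`, `role`, `count`, `probability`,
#'   `frequency_1000` (real) and `frequency_int` (rounded to integer).
#' @examples
#' tp <- true_probabilities(build_stimulus_set())
#' tp[tp$event_id == "card_kind3", "count"]  # 52
#' @export
true_probabilities <- function(stimulus = build_stimulus_set()) {
  stopifnot(inherits(stimulus, "cohacc_stimuli"))
  deck <- stimulus$deck
  flops <- enumerate_flops(deck)
  ind <- event_indicators(stimulus, deck, flops)
  counts <- colSums(ind)
  ev <- stimulus$events
  stem_count <- stats::setNames(counts, sub("^card_", "", names(counts)))
  ev$count <- stem_count[sub("^(card|ball)_", "", ev$event_id)]
  ev$probability <- ev$count / nrow(flops)
  ev$frequency_1000 <- 1000 * ev$probability
  ev$frequency_int <- as.integer(round(ev$frequency_1000))
  for (sid in unique(ev$subtask_id)) {
    if (sum(ev$count[ev$subtask_id == sid]) != nrow(flops))
      stop("triple ", sid, " does not partition the flops", call. = FALSE)
  }
  class(ev) <- c("cohacc_truth", "data.frame")
  rownames(ev) <- NULL
  ev
}

#' @export
print.cohacc_stimuli <- function(x, ...) {
  cat("Stimulus set:", nrow(x$events), "events,",
      nrow(x$nested_pairs), "nested pairs\n")
  print(x$events[, c("event_id", "subtask_id", "role", "description")])
  invisible(x)
}
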