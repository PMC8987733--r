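# Shared fixtures and independent oracles, built in code at test time.

# Brute-force orbit count of flops under suit permutations: repeatedly pick
# an unvisited flop and flood its orbit by applying every suit permutation.
# Independent of the canonicalization-based implementation.
orbit_count_oracle <- function(deck) {
  flops <- t(utils::combn(deck$card_id, 3L))
  n_suits <- max(deck$suit)
  perms <- cohacc:::perm_matrix(n_suits)
  keyof <- function(cards) paste(sort(cards), collapse = "-")
  lookup <- stats::setNames(deck$card_id,
                            paste(deck$rank, deck$suit, sep = "."))
  seen <- new.env(hash = TRUE)
  orbits <- 0L
  for (i in seq_len(nrow(flops))) {
    k <- keyof(flops[i, ])
    if (!is.null(seen[[k]])) next
    orbits <- orbits + 1L
    for (p in seq_len(nrow(perms))) {
      moved <- vapply(flops[i, ], function(cid) {
        r <- deck$rank[deck$card_id == cid]
        s <- perms[p, deck$suit[deck$card_id == cid]]
        lookup[[paste(r, s, sep = ".")]]
      }, numeric(1L))
      seen[[keyof(moved)]] <- TRUE
    }
  }
  orbits
}

# Minimal synthetic score table: n participants x 6 subtasks with supplied
# incoherence/inaccuracy generator functions of (participant, subtask).
make_scores <- function(n, incoh_fun, inacc_fun, group = "g1") {
  sids <- c("ball_kind", "ball_run", "ball_suit",
            "card_kind", "card_run", "card_suit")
  g <- expand.grid(participant_id = sprintf("p%04d", seq_len(n)),
                   subtask_id = sids, stringsAsFactors = FALSE)
  i <- match(g$participant_id, unique(g$participant_id))
  j <- match(g$subtask_id, sids)
  out <- data.frame(participant_id = g$participant_id, group = group,
                    subtask_id = g$subtask_id,
                    incoherence = incoh_fun(i, j), inaccuracy = inacc_fun(i, j),
                    stringsAsFactors = FALSE)
  class(out) <- c("cohacc_scores", "data.frame")
  out
}

cached_truth <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- true_probabilities(build_stimulus_set())
    val
  }
})
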