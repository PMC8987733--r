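#' Specification of a synthetic cohort
#'
#' Describes the three expertise groups (sizes default to the study's 45
#' novices, 37 amateurs, 186 experts), the sampler parameters, the response
#' mode, and the covariate model. Covariates are generated independently of
#' the latent sample size by default: recent poker experience (RPE, ordinal
#' 0-4, increasing with expertise) and a gambling-fallacies score (GFM,
#' integer 0-10, centred at 6 for novices/amateurs and 8 for experts).
#'
#' @param group_sizes named integer vector of cohort sizes.
#' @param params a [sampler_params()].
#' @param mode "sampler" (Bayesian-sampler responses), "random_uniform"
#'   (each response i.i.d. uniform), or "truthful" (responses equal truth).
#' @param integer_frequencies if TRUE, frequencies are rounded to integers
#'   out of 1000 to mimic the response format; if FALSE (default) they are
#'   kept as real numbers, as in the model simulations.
#' @param covariate_n_dependence optional shift added to the RPE location of
#'   participants with the large latent N (default 0: covariates carry no
#'   information about N, matching the finding that RPE/GFM explain none of
#'   the coherence-accuracy link).
#' @return list of class `cohacc_cohort_spec`.
#' @export
cohort_spec <- function(group_sizes = c(novice = 45L, amateur = 37L, expert = 186L),
                        params = sampler_params(),
                        mode = c("sampler", "random_uniform", "truthful"),
                        integer_frequencies = FALSE,
                        covariate_n_dependence = 0) {
  mode <- match.arg(mode)
  stopifnot(all(group_sizes >= 0), !is.null(names(group_sizes)),
            all(names(group_sizes) %in% names(params$mixture)))
  structure(list(group_sizes = group_sizes, params = params, mode = mode,
                 integer_frequencies = integer_frequencies,
                 covariate_n_dependence = covariate_n_dependence),
            class = "cohacc_cohort_spec")
}

# RPE response probabilities by group (ordinal 0-4, higher = more play)
rpe_probs <- list(
  novice = c(0.82, 0.10, 0.05, 0.02, 0.01),
  amateur = c(0.46, 0.20, 0.15, 0.12, 0.07),
  expert = c(0.037, 0.05, 0.10, 0.15, 0.663)
)
# GFM ~ Binomial(10, centre/10): medians 6 (novice/amateur) and 8 (expert)
gfm_centre <- c(novice = 6, amateur = 6, expert = 8)

#' Generate a synthetic cohort of frequency judgments
#'
#' Emulates the study's response tables: each participant receives one
#' latent sample size from their group's mixture and answers all 18
#' questions (9 Card + 9 Ball) with independent sampler draws at the exact
#' true probabilities — or uniform/truthful responses in the other modes.
#' Frequencies are on the 0-1000 scale.
#'
#' @param spec a [cohort_spec()].
#' @param truth a [true_probabilities()] table.
#' @param seed optional integer seed.
#' @return list of class `cohacc_cohort`: `responses` (long data frame:
#'   `participant_id`, `group`, `task`, `subtask`, `event_id`, `frequency`,
#'   `RPE`, `GFM`) and `latent` (sidecar data frame `participant_id`,
#'   `group`, `latent_N` — the oracle kept out of the analysis path).
#' @export
generate_cohort <- function(spec = cohort_spec(), truth = NULL, seed = NULL) {
  stopifnot(inherits(spec, "cohacc_cohort_spec"))
  if (is.null(truth)) truth <- true_probabilities(build_stimulus_set())
  if (!is.null(seed)) set.seed(seed)
  resp <- list(); latent <- list()
  pid0 <- 0L
  for (g in names(spec$group_sizes)) {
    n <- spec$group_sizes[[g]]
    if (n == 0L) next
    N <- assign_sample_sizes(g, n, spec$params)
    rpe_p <- if (g %in% names(rpe_probs)) rpe_probs[[g]] else rep(0.2, 5)
    RPE <- sample(0:4, n, replace = TRUE, prob = rpe_p)
    if (spec$covariate_n_dependence != 0) {
      bump <- spec$covariate_n_dependence * (N == spec$params$n_large)
      RPE <- pmin(4L, pmax(0L, RPE + round(bump)))
    }
    centre <- if (g %in% names(gfm_centre)) gfm_centre[[g]] else 5
    GFM <- stats::rbinom(n, 10L, centre / 10)
    for (i in seq_len(n)) {
      pid <- pid0 + i
      est <- switch(spec$mode,
        truthful = truth$probability,
        random_uniform = stats::runif(nrow(truth)),
        sampler = sampler_estimate(
          stats::rbinom(nrow(truth), N[i], truth$probability),
          N[i], spec$params$beta))
      freq <- 1000 * est
      if (spec$integer_frequencies) freq <- round(freq)
      resp[[pid]] <- data.frame(
        participant_id = sprintf("p%03d", pid), group = g,
        task = truth$task, subtask = truth$subtask,
        event_id = truth$event_id, frequency = freq,
        RPE = RPE[i], GFM = GFM[i], stringsAsFactors = FALSE)
    }
    latent[[g]] <- data.frame(
      participant_id = sprintf("p%03d", pid0 + seq_len(n)), group = g,
      latent_N = N, stringsAsFactors = FALSE)
    pid0 <- pid0 + n
  }
  out <- list(responses = do.call(rbind, resp),
              latent = do.call(rbind, latent), mode = spec$mode)
  rownames(out$responses) <- rownames(out$latent) <- NULL
  class(out) <- "cohacc_cohort"
  out
}

#' @export
print.cohacc_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$latent), "participants,",
      nrow(x$responses), "responses\n")
  print(table(x$latent$group))
  invisible(x)
}

#' Recover the latent sample-size structure from responses
#'
#' Classifies each participant as a small-N or large-N sampler from their 18
#' responses alone, by maximum likelihood over the two candidate sizes: for
#' each candidate N the implied success count M is the admissible value
#' whose sampler estimate is nearest the response, scored by the binomial
#' likelihood of M at the true probability plus a Gaussian reconstruction
#' penalty for the distance between response and implied estimate. Compared
#' against the generator's sidecar to report a confusion matrix.
#'
#' @param cohort a [generate_cohort()] result (sampler mode).
#' @param truth the [true_probabilities()] table used to generate it.
#' @param params the [sampler_params()] used.
#' @return list: `classification` (data frame `participant_id`, `latent_N`,
#'   `recovered_N`), `confusion` (table), `accuracy`.
#' @export
recover_sample_size_structure <- function(cohort, truth = NULL,
                                          params = sampler_params()) {
  stopifnot(inherits(cohort, "cohacc_cohort"))
  if (!identical(cohort$mode, "sampler"))
    stop("sample-size recovery requires a sampler-mode cohort", call. = FALSE)
  if (is.null(truth)) truth <- true_probabilities(build_stimulus_set())
  truth_p <- stats::setNames(truth$probability, truth$event_id)
  cand <- c(params$n_small, params$n_large)
  resp <- cohort$responses
  pids <- unique(resp$participant_id)
  rec <- vapply(pids, function(pid) {
    sub <- resp[resp$participant_id == pid, ]
    est <- sub$frequency / 1000
    p <- truth_p[sub$event_id]
    ll <- vapply(cand, function(N) {
      M <- pmin(N, pmax(0L, round(est * (N + 2 * params$beta) - params$beta)))
      recon <- sampler_estimate(M, N, params$beta)
      # rounding to integer frequencies perturbs estimates by <= 5e-4
      sum(stats::dbinom(M, N, p, log = TRUE) +
            stats::dnorm(est - recon, sd = 1e-3, log = TRUE))
    }, numeric(1L))
    cand[which.max(ll)]
  }, numeric(1L))
  cls <- data.frame(participant_id = pids,
                    latent_N = cohort$latent$latent_N[match(pids, cohort$latent$participant_id)],
                    recovered_N = rec, stringsAsFactors = FALSE)
  conf <- table(truth_N = cls$latent_N, recovered_N = cls$recovered_N)
  list(classification = cls, confusion = conf,
       accuracy = mean(cls$latent_N == cls$recovered_N))
}
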