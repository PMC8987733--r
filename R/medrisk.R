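#' Four-question medical-risk judgment design
#'
#' A design in which respondents estimate four probabilities about prostate
#' cancer: lifetime incidence P(C), lifetime mortality P(D), the positive
#' predictive value P(C|+), and the sensitivity P(+|C). The two lifetime
#' questions have published truths (0.177 and 0.028) and score accuracy; the
#' two conditionals score coherence because their ratio P(C|+)/P(+|C) must
#' equal the stated base-rate ratio of 0.5 regardless of the test's
#' characteristics. The individual conditionals were never published, so
#' their magnitudes are configurable subject to the ratio constraint (see
#' [medrisk_sensitivity()] for how little they matter).
#'
#' @param n_participants respondents per simulated experiment (default 125).
#' @param p_cancer true lifetime incidence (default 0.177).
#' @param p_death true lifetime mortality (default 0.028).
#' @param ratio required value of P(C|+) / P(+|C) (default 0.5).
#' @param p_pos_given_c assumed true sensitivity P(+|C) (default 0.8);
#'   P(C|+) is then `ratio * p_pos_given_c`.
#' @param alpha significance level for the power analysis (default 0.05).
#' @return list of class `cohacc_medrisk_design` with the four `truths` in
#'   question order (C lifetime, D lifetime, C given +, + given C).
#' @export
medrisk_design <- function(n_participants = 125L, p_cancer = 0.177,
                        p_death = 0.028, ratio = 0.5, p_pos_given_c = 0.8,
                        alpha = 0.05) {
  p_c_given_pos <- ratio * p_pos_given_c
  truths <- c(p_cancer = p_cancer, p_death = p_death,
              p_c_given_pos = p_c_given_pos, p_pos_given_c = p_pos_given_c)
  stopifnot(n_participants >= 3, all(truths > 0 & truths < 1),
            alpha > 0, alpha <= 1)
  structure(list(n_participants = as.integer(n_participants), truths = truths,
                 ratio = ratio, alpha = alpha),
            class = "cohacc_medrisk_design")
}

#' Simulate one cohort of four-question judgments
#'
#' In `sampler_expert` mode each respondent gets one latent sample size from
#' the expert mixture (10% N = 1, 90% N = 10 by default, beta = 1) and
#' answers the four questions with independent Bayesian-sampler draws at the
#' design's true probabilities. In `random_uniform` mode all four answers are
#' i.i.d. Uniform(0, 1), the no-signal baseline.
#'
#' @param design a [medrisk_design()].
#' @param mode "sampler_expert" or "random_uniform".
#' @param params a [sampler_params()]; only the expert mixture entry is used.
#' @param seed optional integer seed.
#' @return matrix `n_participants` x 4 of estimates, columns named as the
#'   design's truths.
#' @export
simulate_medrisk_cohort <- function(design, mode = c("sampler_expert", "random_uniform"),
                                 params = sampler_params(), seed = NULL) {
  stopifnot(inherits(design, "cohacc_medrisk_design"))
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  n <- design$n_participants
  est <- if (mode == "random_uniform") {
    matrix(stats::runif(4L * n), n, 4L)
  } else {
    N <- assign_sample_sizes("expert", n, params)
    vapply(design$truths,
           function(p) sampler_estimate(stats::rbinom(n, N, p), N, params$beta),
           numeric(n))
  }
  colnames(est) <- names(design$truths)
  est
}

#' Score a four-question cohort: log-deviation incoherence and inaccuracy
#'
#' Inaccuracy is the mean absolute log percentage deviation of the two
#' lifetime estimates from their truths, 100 |ln(est / truth)| averaged over
#' the two questions. Incoherence is the absolute log percentage deviation
#' of the estimated ratio P(C|+)/P(+|C) from the required ratio. Estimates
#' are floored at `epsilon` before logging.
#'
#' @param estimates matrix from [simulate_medrisk_cohort()].
#' @param design the matching [medrisk_design()].
#' @param epsilon floor applied to estimates before taking logs (default
#'   1e-6; uniform responses can approach 0).
#' @return data frame with columns `incoherence`, `inaccuracy`.
#' @export
medrisk_scores <- function(estimates, design, epsilon = 1e-6) {
  stopifnot(inherits(design, "cohacc_medrisk_design"), ncol(estimates) == 4L)
  e <- pmax(estimates, epsilon)
  dev <- function(x, target) abs(100 * log(x / target))
  inacc <- (dev(e[, 1L], design$truths[[1L]]) +
            dev(e[, 2L], design$truths[[2L]])) / 2
  incoh <- dev(e[, 3L] / e[, 4L], design$ratio)
  data.frame(incoherence = incoh, inaccuracy = inacc)
}

#' Coherence-accuracy correlation of one four-question cohort
#'
#' @param scores a [medrisk_scores()] data frame.
#' @return Pearson r between incoherence and inaccuracy, or NA when either
#'   score has zero variance.
#' @export
medrisk_correlation <- function(scores) {
  if (stats::sd(scores$incoherence) == 0 || stats::sd(scores$inaccuracy) == 0)
    return(NA_real_)
  stats::cor(scores$incoherence, scores$inaccuracy)
}

#' Monte-Carlo correlation and power of the four-question design
#'
#' Repeats simulate -> score -> correlate over many experiments and reports
#' the mean simulated correlation and the proportion of experiments whose
#' two-sided correlation test is significant at the design's alpha — the
#' power of the original n = 125 design to detect the sampler-induced link.
#'
#' @inheritParams simulate_medrisk_cohort
#' @param n_experiments number of simulated experiments.
#' @return list of class `cohacc_power`: `mean_r`, `prop_significant`,
#'   `n_experiments`, `mode`, `alpha`, `n_skipped`.
#' @export
medrisk_power <- function(design, mode = c("sampler_expert", "random_uniform"),
                       n_experiments = 1e4, params = sampler_params(),
                       seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_experiments >= 1)
  if (!is.null(seed)) set.seed(seed)
  rs <- vapply(seq_len(n_experiments), function(i) {
    est <- simulate_medrisk_cohort(design, mode, params)
    medrisk_correlation(medrisk_scores(est, design))
  }, numeric(1L))
  skipped <- sum(is.na(rs))
  rs <- rs[!is.na(rs)]
  p <- pearson_p(rs, design$n_participants)
  structure(list(mean_r = mean(rs), prop_significant = mean(p < design$alpha),
                 n_experiments = n_experiments, mode = mode,
                 alpha = design$alpha, n_skipped = skipped),
            class = "cohacc_power")
}

# two-sided p of a Pearson r at sample size n (t transform, as cor.test)
pearson_p <- function(r, n) {
  df <- n - 2L
  t <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(-abs(t), df)
}

#' Sensitivity of the simulated correlation to the assumed conditionals
#'
#' The magnitudes of the true conditionals are not published, only their
#' ratio. This sweep recomputes the mean sampler-mode correlation over a
#' grid of assumed P(+|C) values (ratio held fixed) to show how the choice
#' affects the result.
#'
#' @inheritParams medrisk_power
#' @param p_pos_grid grid of assumed P(+|C) values.
#' @param n_experiments experiments per grid point.
#' @return data frame: `p_pos_given_c`, `p_c_given_pos`, `mean_r`.
#' @export
medrisk_sensitivity <- function(p_pos_grid = seq(0.3, 0.9, by = 0.15),
                             n_experiments = 500L, params = sampler_params(),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(p_pos_grid, function(pp) {
    d <- medrisk_design(p_pos_given_c = pp)
    pw <- medrisk_power(d, "sampler_expert", n_experiments, params)
    data.frame(p_pos_given_c = pp, p_c_given_pos = d$truths[["p_c_given_pos"]],
               mean_r = pw$mean_r)
  })
  do.call(rbind, rows)
}

#' @export
print.cohacc_power <- function(x, ...) {
  cat(sprintf("%s: mean r = %.3f, P(significant at alpha = %.2f) = %.1f%% (%d experiments)\n",
              x$mode, x$mean_r, x$alpha, 100 * x$prop_significant,
              x$n_experiments))
  invisible(x)
}
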