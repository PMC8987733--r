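#' Bayesian sampler parameters
#'
#' The response model assumes a participant judges a probability by drawing N
#' mental samples from the true distribution, counting the M that satisfy the
#' event, and reading off the posterior mean under a symmetric Beta(beta,
#' beta) prior: (M + beta) / (N + 2 beta). Small N moderates estimates toward
#' 0.5, producing overestimation of small probabilities, underestimation of
#' large ones, and subadditive triples. Individual differences are captured
#' by a two-point mixture over the latent sample size: each participant draws
#' either `n_small` or `n_large` samples, with the probability of the small
#' size depending on expertise group.
#'
#' @param beta prior pseudo-count (default 1, a uniform prior).
#' @param n_small,n_large the two latent sample sizes (defaults 1 and 10).
#' @param mixture named vector of P(N = n_small) per group; defaults are 0.7
#'   for novices and amateurs and 0.1 for experts.
#' @return object of class `cohacc_sampler_params`.
#' @export
sampler_params <- function(beta = 1, n_small = 1L, n_large = 10L,
                           mixture = c(novice = 0.7, amateur = 0.7, expert = 0.1)) {
  stopifnot(beta >= 0, n_small >= 1, n_large >= 1,
            all(mixture >= 0 & mixture <= 1), !is.null(names(mixture)))
  structure(list(beta = beta, n_small = as.integer(n_small),
                 n_large = as.integer(n_large), mixture = mixture),
            class = "cohacc_sampler_params")
}

#' Bayesian sampler point estimate
#'
#' @param M number of mental samples flagged true (0 <= M <= N); vectorized.
#' @param N total number of mental samples (>= 1).
#' @param beta prior pseudo-count (>= 0).
#' @return (M + beta) / (N + 2 beta).
#' @examples
#' sampler_estimate(1, 1, 1)  # 2/3
#' @export
sampler_estimate <- function(M, N, beta = 1) {
  if (any(beta < 0) || any(N < 1) || any(M < 0) || any(M > N))
    stop("require 0 <= M <= N, N >= 1, beta >= 0", call. = FALSE)
  (M + beta) / (N + 2 * beta)
}

#' Expected sampler estimate for a true probability
#'
#' Expectation of [sampler_estimate()] over M ~ Binomial(N, p):
#' (N p + beta) / (N + 2 beta). Exceeds p when p < 0.5 and falls short of it
#' when p > 0.5, shrinking to p as N grows.
#'
#' @param p true probability in \[0, 1\]; vectorized.
#' @inheritParams sampler_estimate
#' @export
expected_estimate <- function(p, N, beta = 1) {
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]", call. = FALSE)
  stopifnot(all(N >= 1), all(beta >= 0))
  (N * p + beta) / (N + 2 * beta)
}

#' Assign latent sample sizes to a cohort
#'
#' Draws each participant's latent N i.i.d. from the two-point mixture for
#' their group: N = `n_small` with probability `mixture[group]`, else
#' `n_large`. One N is shared across all of a participant's questions; this
#' shared latent size is what induces the coherence-accuracy correlation.
#'
#' @param group group label, must name an entry of `params$mixture`.
#' @param n cohort size.
#' @param params a [sampler_params()] object.
#' @param seed optional integer seed for reproducibility.
#' @return integer vector of length `n` with values in
#'   `c(params$n_small, params$n_large)`.
#' @export
assign_sample_sizes <- function(group, n, params = sampler_params(), seed = NULL) {
  stopifnot(inherits(params, "cohacc_sampler_params"), n >= 1)
  if (!group %in% names(params$mixture))
    stop("unknown group label: ", group, call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ifelse(stats::runif(n) < params$mixture[[group]], params$n_small, params$n_large)
}

#' Simulate one sampler response per true probability
#'
#' For each element of `p`, draws M ~ Binomial(N, p) and returns the sampler
#' estimate. Draws are independent across questions given the latent N.
#'
#' @param p true probabilities; vectorized (N and beta recycle).
#' @inheritParams sampler_estimate
#' @param seed optional integer seed.
#' @return data frame with columns `N`, `M`, `estimate`.
#' @export
simulate_response <- function(p, N, beta = 1, seed = NULL) {
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]", call. = FALSE)
  stopifnot(all(N >= 1), all(beta >= 0))
  if (!is.null(seed)) set.seed(seed)
  k <- max(length(p), length(N))
  p <- rep_len(p, k); N <- rep_len(as.integer(N), k)
  M <- stats::rbinom(k, N, p)
  data.frame(N = N, M = M, estimate = sampler_estimate(M, N, beta))
}

#' @export
print.cohacc_sampler_params <- function(x, ...) {
  cat("Bayesian sampler: beta =", x$beta, ", N in {", x$n_small, ",",
      x$n_large, "}\nP(N =", x$n_small, ") by group:\n")
  print(x$mixture)
  invisible(x)
}
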