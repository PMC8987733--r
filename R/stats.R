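#' Unconfounded coherence-accuracy subtask pairs
#'
#' Correlating the coherence and the accuracy of the same three judgments
#' induces a spurious link, so only pairs that take coherence from one
#' subtask and accuracy from a different one are used. With six subtasks
#' this yields 30 ordered pairs.
#'
#' @param subtask_ids character vector of distinct subtask labels.
#' @return data frame with columns `coherence_subtask`, `accuracy_subtask`.
#' @examples
#' nrow(unconfounded_pairs(paste0("s", 1:6)))  # 30
#' @export
unconfounded_pairs <- function(subtask_ids) {
  if (anyDuplicated(subtask_ids))
    stop("subtask ids must be distinct", call. = FALSE)
  g <- expand.grid(coherence_subtask = subtask_ids,
                   accuracy_subtask = subtask_ids,
                   stringsAsFactors = FALSE)
  g[g$coherence_subtask != g$accuracy_subtask, ]
}

# score table (long) -> list of participant x subtask matrices
scores_wide <- function(scores) {
  stopifnot(all(c("participant_id", "subtask_id", "incoherence", "inaccuracy")
                %in% names(scores)))
  pid <- unique(scores$participant_id)
  sid <- sort(unique(scores$subtask_id))
  shape <- function(col) {
    m <- matrix(NA_real_, length(pid), length(sid),
                dimnames = list(pid, sid))
    m[cbind(match(scores$participant_id, pid),
            match(scores$subtask_id, sid))] <- scores[[col]]
    if (anyNA(m)) stop("incomplete scores: every participant needs every subtask",
                       call. = FALSE)
    m
  }
  grp <- scores$group[match(pid, scores$participant_id)]
  list(participant_id = pid, group = grp,
       incoherence = shape("incoherence"), inaccuracy = shape("inaccuracy"))
}

# mean of the 30 cross-subtask correlations from two n x 6 matrices;
# undefined correlations (zero variance) are dropped from the average.
mean_cross_correlation <- function(incoh, inacc, average = "arithmetic") {
  cc <- suppressWarnings(stats::cor(incoh, inacc))
  diag(cc) <- NA
  r <- cc[row(cc) != col(cc)]
  r <- r[is.finite(r)]
  if (!length(r)) return(NA_real_)
  if (average == "fisher") tanh(mean(atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))))
  else mean(r)
}

#' Cross-subtask coherence-accuracy correlations
#'
#' For each expertise group and each of the 30 unconfounded subtask pairs,
#' the Pearson correlation across participants between incoherence on one
#' subtask and inaccuracy on another, with its two-sided p value. Pairs with
#' a zero-variance column are flagged undefined and excluded from averages.
#'
#' @param scores a [score_cohort()] table.
#' @return data frame: `group`, `coherence_subtask`, `accuracy_subtask`, `r`,
#'   `p_value`, `n`, `defined`.
#' @export
correlation_table <- function(scores) {
  out <- list()
  for (g in unique(scores$group)) {
    w <- scores_wide(scores[scores$group == g, ])
    if (length(w$participant_id) < 3L)
      stop("need at least 3 participants per group", call. = FALSE)
    pairs <- unconfounded_pairs(colnames(w$incoherence))
    for (i in seq_len(nrow(pairs))) {
      x <- w$incoherence[, pairs$coherence_subtask[i]]
      y <- w$inaccuracy[, pairs$accuracy_subtask[i]]
      ok <- stats::sd(x) > 0 && stats::sd(y) > 0
      if (ok) {
        ct <- stats::cor.test(x, y)
        r <- unname(ct$estimate); p <- ct$p.value
      } else {
        r <- NA_real_; p <- NA_real_
      }
      out[[length(out) + 1L]] <- data.frame(
        group = g, coherence_subtask = pairs$coherence_subtask[i],
        accuracy_subtask = pairs$accuracy_subtask[i],
        r = r, p_value = p, n = length(x), defined = ok,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Percentile bootstrap of the mean coherence-accuracy correlation
#'
#' Resamples participants with replacement; for each replicate recomputes
#' all 30 unconfounded correlations and their mean, then reports the 2.5th
#' and 97.5th percentiles of the replicate distribution. Replicates in which
#' every correlation is undefined (zero variance) are skipped and counted.
#'
#' @param scores a [score_cohort()] table for a single group (or any set of
#'   participants to be treated as one group).
#' @param B number of bootstrap replicates (the full analysis uses 1e5; a
#'   smaller default keeps interactive use fast).
#' @param seed optional integer seed.
#' @param average "arithmetic" (default) mean of the 30 r values, or
#'   "fisher" for a Fisher-z average.
#' @return list of class `cohacc_boot`: `mean_r` (point estimate on the
#'   original sample), `ci_low`, `ci_high`, `B`, `n_skipped`, `seed`,
#'   `average`.
#' @export
bootstrap_mean_correlation <- function(scores, B = 1e4, seed = NULL,
                                       average = c("arithmetic", "fisher")) {
  average <- match.arg(average)
  stopifnot(B >= 1)
  if (!is.null(seed)) set.seed(seed)
  w <- scores_wide(scores)
  n <- length(w$participant_id)
  point <- mean_cross_correlation(w$incoherence, w$inaccuracy, average)
  reps <- numeric(B)
  for (b in seq_len(B)) {
    ix <- sample.int(n, n, replace = TRUE)
    reps[b] <- mean_cross_correlation(w$incoherence[ix, , drop = FALSE],
                                      w$inaccuracy[ix, , drop = FALSE], average)
  }
  skipped <- sum(is.na(reps))
  reps <- reps[!is.na(reps)]
  if (!length(reps))
    stop("all bootstrap replicates degenerate (zero variance)", call. = FALSE)
  q <- stats::quantile(reps, c(0.025, 0.975), names = FALSE)
  structure(list(mean_r = point, ci_low = q[1L], ci_high = q[2L], B = B,
                 n_skipped = skipped, seed = seed, average = average),
            class = "cohacc_boot")
}

#' @export
print.cohacc_boot <- function(x, ...) {
  cat(sprintf("mean r = %.4f, 95%% CI [%.4f, %.4f] (B = %d, skipped %d)\n",
              x$mean_r, x$ci_low, x$ci_high, x$B, x$n_skipped))
  invisible(x)
}

#' First-order partial correlation
#'
#' Pearson correlation of x and y after linearly removing a covariate from
#' each: the correlation of the residuals of `lm(x ~ z)` and `lm(y ~ z)`.
#'
#' @param x,y,z numeric vectors of equal length (>= 4).
#' @return partial correlation coefficient, or NA if a residual has zero
#'   variance.
#' @export
partial_correlation <- function(x, y, z) {
  n <- length(x)
  if (length(y) != n || length(z) != n || n < 4L)
    stop("x, y, z must have equal length >= 4", call. = FALSE)
  rx <- stats::residuals(stats::lm(x ~ z))
  ry <- stats::residuals(stats::lm(y ~ z))
  tol <- 1e-10 * max(stats::sd(x), stats::sd(y), 1)
  if (stats::sd(rx) < tol || stats::sd(ry) < tol) return(NA_real_)
  stats::cor(rx, ry)
}

# mean cross-subtask partial correlation (removing one covariate) from wide
# matrices, via the first-order formula on the joint correlation matrix
mean_cross_partial <- function(incoh, inacc, z) {
  if (stats::sd(z) == 0) return(NA_real_)
  cc <- suppressWarnings(stats::cor(cbind(incoh, inacc, z = z)))
  k <- ncol(incoh)
  rxz <- cc[seq_len(k), "z"]
  ryz <- cc[k + seq_len(k), "z"]
  rxy <- cc[seq_len(k), k + seq_len(k)]
  pr <- (rxy - outer(rxz, ryz)) / sqrt(outer(1 - rxz^2, 1 - ryz^2))
  diag(pr) <- NA
  pr <- pr[row(pr) != col(pr)]
  pr <- pr[is.finite(pr)]
  if (!length(pr)) NA_real_ else mean(pr)
}

#' Bootstrap the reduction of the mean correlation due to a covariate
#'
#' How much of the mean coherence-accuracy correlation is explained by a
#' covariate (e.g. recent poker experience or gambling-fallacy score):
#' the difference between the mean full correlation and the mean partial
#' correlation removing the covariate, with a percentile bootstrap CI of the
#' difference over resampled participants. A CI covering 0 indicates the
#' covariate does not account for the link.
#'
#' @inheritParams bootstrap_mean_correlation
#' @param covariate named numeric vector, one value per participant (names
#'   are participant ids), or a bare vector in participant order.
#' @return list: `reduction` (point estimate), `ci_low`, `ci_high`, `B`,
#'   `n_skipped`.
#' @export
bootstrap_partial_reduction <- function(scores, covariate, B = 1e4, seed = NULL) {
  stopifnot(B >= 1)
  if (!is.null(seed)) set.seed(seed)
  w <- scores_wide(scores)
  n <- length(w$participant_id)
  z <- if (!is.null(names(covariate))) {
    miss <- setdiff(as.character(w$participant_id), names(covariate))
    if (length(miss)) stop("covariate missing participants: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    unname(covariate[as.character(w$participant_id)])
  } else {
    if (length(covariate) != n) stop("covariate length mismatch", call. = FALSE)
    covariate
  }
  red <- function(ix) {
    full <- mean_cross_correlation(w$incoherence[ix, , drop = FALSE],
                                   w$inaccuracy[ix, , drop = FALSE])
    part <- mean_cross_partial(w$incoherence[ix, , drop = FALSE],
                               w$inaccuracy[ix, , drop = FALSE], z[ix])
    full - part
  }
  point <- red(seq_len(n))
  reps <- vapply(seq_len(B),
                 function(b) red(sample.int(n, n, replace = TRUE)),
                 numeric(1L))
  skipped <- sum(is.na(reps))
  reps <- reps[!is.na(reps)]
  q <- stats::quantile(reps, c(0.025, 0.975), names = FALSE)
  list(reduction = point, ci_low = q[1L], ci_high = q[2L], B = B,
       n_skipped = skipped)
}

#' Welch two-sample t test
#'
#' Unequal-variance t test with Welch-Satterthwaite degrees of freedom,
#' two-sided.
#'
#' @param x,y numeric samples (each n >= 2).
#' @return list: `statistic`, `df`, `p_value`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs at least 2 observations", call. = FALSE)
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}
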