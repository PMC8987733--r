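#' Run the end-to-end coherence-accuracy analysis
#'
#' Generates (or accepts) a cohort, scores it, and runs the full inferential
#' sequence: per-group unconfounded correlation tables, percentile bootstrap
#' of the mean correlation, covariate partial-correlation reductions, Welch
#' group comparisons, the Card-vs-Ball consistency check, and the
#' four-question Monte-Carlo power reconciliation. All randomness is
#' governed by `config$seed`; when `config$out_dir` is set, CSV outputs and
#' a plain-text report are written there together with the resolved
#' configuration.
#'
#' @param config a [run_config()].
#' @param cohort optional pre-built [generate_cohort()] result or a response
#'   data frame from [read_response_table()]; by default a cohort is
#'   generated from `config$cohort`.
#' @return list of class `cohacc_results` with elements `truth`, `cohort`,
#'   `scores`, `aux`, `correlations`, `bootstrap` (per group), `reductions`
#'   (per group x covariate), `group_tests`, `task_tests`, `medrisk`, `config`.
#' @export
run_full_pipeline <- function(config = run_config(), cohort = NULL) {
  stopifnot(inherits(config, "cohacc_config"))
  set.seed(config$seed)
  stimulus <- build_stimulus_set()
  truth <- true_probabilities(stimulus)

  if (is.null(cohort)) cohort <- generate_cohort(config$cohort, truth)
  responses <- if (inherits(cohort, "cohacc_cohort")) cohort$responses else cohort
  check_cohort(responses, truth)

  scores <- score_cohort(responses, truth)
  aux <- score_aux(responses, truth, stimulus)

  degenerate <- all(scores$incoherence == 0) && all(scores$inaccuracy == 0)
  groups <- unique(scores$group)

  correlations <- if (degenerate) NULL else correlation_table(scores)
  boot <- if (degenerate) NULL else
    stats::setNames(lapply(groups, function(g)
      bootstrap_mean_correlation(scores[scores$group == g, ],
                                 B = config$bootstrap_B)), groups)

  cov_cols <- intersect(c("RPE", "GFM"), names(responses))
  reductions <- NULL
  if (!degenerate && length(cov_cols)) {
    per_p <- responses[!duplicated(responses$participant_id),
                       c("participant_id", "group", cov_cols)]
    reductions <- list()
    for (g in groups) for (cv in cov_cols) {
      sub <- per_p[per_p$group == g, ]
      z <- stats::setNames(sub[[cv]], sub$participant_id)
      reductions[[paste(g, cv, sep = ".")]] <-
        bootstrap_partial_reduction(scores[scores$group == g, ], z,
                                    B = config$bootstrap_B)
    }
  }

  # participant-level mean scores for group and task comparisons
  agg <- function(df, cols) stats::aggregate(df[cols],
    by = list(participant_id = df$participant_id, group = df$group), mean)
  person <- agg(scores, c("incoherence", "inaccuracy"))
  group_tests <- list()
  if (all(c("novice", "amateur") %in% groups)) {
    for (m in c("incoherence", "inaccuracy"))
      group_tests[[paste0("novice_vs_amateur_", m)]] <-
        welch_t(person[[m]][person$group == "novice"],
                person[[m]][person$group == "amateur"])
  }
  if ("expert" %in% groups && any(c("novice", "amateur") %in% groups)) {
    pooled <- person$group %in% c("novice", "amateur")
    for (m in c("incoherence", "inaccuracy"))
      group_tests[[paste0("expert_vs_pooled_", m)]] <-
        welch_t(person[[m]][person$group == "expert"], person[[m]][pooled])
  }

  task_scores <- scores
  task_scores$task <- sub("_.*$", "", task_scores$subtask_id)
  task_tests <- list()
  for (g in groups) for (m in c("incoherence", "inaccuracy")) {
    sub <- task_scores[task_scores$group == g, ]
    pm <- stats::aggregate(sub[[m]],
      by = list(participant_id = sub$participant_id, task = sub$task), mean)
    wide <- stats::reshape(pm, idvar = "participant_id", timevar = "task",
                           direction = "wide")
    d <- wide$x.card - wide$x.ball
    task_tests[[paste(g, m, sep = ".")]] <- if (stats::sd(d) == 0)
      list(statistic = 0, df = length(d) - 1L, p_value = 1)
    else {
      tt <- stats::t.test(d)
      list(statistic = unname(tt$statistic), df = unname(tt$parameter),
           p_value = tt$p.value)
    }
  }

  medrisk <- list(
    sampler = medrisk_power(config$medrisk, "sampler_expert",
                         config$medrisk_experiments, config$cohort$params),
    random = medrisk_power(config$medrisk, "random_uniform", config$medrisk_experiments))

  out <- structure(list(truth = truth, cohort = cohort, scores = scores,
                        aux = aux, correlations = correlations,
                        bootstrap = boot, reductions = reductions,
                        group_tests = group_tests, task_tests = task_tests,
                        medrisk = medrisk, degenerate = degenerate, config = config),
                   class = "cohacc_results")
  if (!is.null(config$out_dir)) write_results(out, config$out_dir)
  out
}

write_results <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) if (!is.null(df))
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  if (inherits(res$cohort, "cohacc_cohort"))
    write_response_table(res$cohort, file.path(dir, "cohort.csv"))
  w(res$truth, "true_probabilities.csv")
  w(res$scores, "scores.csv")
  w(res$aux, "aux_scores.csv")
  w(res$correlations, "correlations.csv")
  if (!is.null(res$bootstrap))
    w(do.call(rbind, lapply(names(res$bootstrap), function(g)
        data.frame(group = g, mean_r = res$bootstrap[[g]]$mean_r,
                   ci_low = res$bootstrap[[g]]$ci_low,
                   ci_high = res$bootstrap[[g]]$ci_high,
                   B = res$bootstrap[[g]]$B))), "bootstrap.csv")
  writeLines(utils::capture.output(print(res)), file.path(dir, "report.txt"))
  jsonlite::write_json(list(seed = res$config$seed,
                            bootstrap_B = res$config$bootstrap_B,
                            alpha = res$config$alpha,
                            mode = res$config$cohort$mode,
                            group_sizes = as.list(res$config$cohort$group_sizes),
                            medrisk_experiments = res$config$medrisk_experiments),
                       file.path(dir, "config.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @export
print.cohacc_results <- function(x, ...) {
  cat("Coherence-accuracy analysis (seed", x$config$seed, ")\n\n")
  cat("Participants:\n")
  print(table(x$scores$group[!duplicated(x$scores$participant_id)]))
  cat("\nMean scores by group:\n")
  print(stats::aggregate(x$scores[c("incoherence", "inaccuracy")],
                         by = list(group = x$scores$group), mean))
  if (x$degenerate) {
    cat("\nAll scores are zero; correlations undefined.\n")
  } else {
    cat("\nBootstrap mean coherence-accuracy correlation (95% CI):\n")
    for (g in names(x$bootstrap)) {
      b <- x$bootstrap[[g]]
      cat(sprintf("  %-8s %.3f [%.3f, %.3f]\n", g, b$mean_r, b$ci_low, b$ci_high))
    }
    if (!is.null(x$reductions)) {
      cat("\nCovariate reductions of the mean correlation (95% CI):\n")
      for (k in names(x$reductions)) {
        r <- x$reductions[[k]]
        cat(sprintf("  %-14s %+.4f [%+.4f, %+.4f]\n", k, r$reduction,
                    r$ci_low, r$ci_high))
      }
    }
  }
  if (length(x$group_tests)) {
    cat("\nWelch group comparisons:\n")
    for (k in names(x$group_tests)) {
      t <- x$group_tests[[k]]
      cat(sprintf("  %-28s t(%.2f) = %.2f, p = %.3g\n", k, t$df, t$statistic,
                  t$p_value))
    }
  }
  cat("\nCard vs Ball (paired t by group):\n")
  for (k in names(x$task_tests)) {
    t <- x$task_tests[[k]]
    cat(sprintf("  %-22s t(%d) = %.2f, p = %.3g\n", k, round(t$df),
                t$statistic, t$p_value))
  }
  cat("\nFour-question design (n = ", x$config$medrisk$n_participants, "):\n", sep = "")
  print(x$medrisk$sampler); print(x$medrisk$random)
  invisible(x)
}

#' Command-line dispatcher
#'
#' Backs the `cohacc` Rscript wrapper (installed under `exec/`). Subcommands:
#' `stimuli` (write the true-probability table), `simulate` (write a
#' synthetic cohort), `score` (score a response CSV), `correlate`
#' (correlation table + bootstrap from a scores CSV), `power` (four-question
#' Monte-Carlo power table), `report` (full pipeline). Flags: `--config`,
#' `--seed`, `--bootstrap-reps`, `--mode`, `--out`.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status: 0 success, 1 validation error, 2 runtime
#'   failure.
#' @export
cohacc_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: cohacc <stimuli|simulate|score|correlate|power|report> [--config F] [--seed S] [--bootstrap-reps B] [--mode M] [--out PATH]"
  if (!length(args)) { message(usage); return(1L) }
  cmd <- args[1L]; args <- args[-1L]
  opt <- list(seed = 1L, mode = "sampler", out = ".", config = NULL,
              bootstrap_reps = NULL)
  i <- 1L
  while (i <= length(args)) {
    key <- args[i]
    if (!startsWith(key, "--") || i == length(args)) {
      message("bad argument: ", key); return(1L)
    }
    val <- args[i + 1L]; i <- i + 2L
    switch(key,
      "--config" = opt$config <- val,
      "--seed" = opt$seed <- as.integer(val),
      "--bootstrap-reps" = opt$bootstrap_reps <- as.numeric(val),
      "--mode" = opt$mode <- val,
      "--out" = opt$out <- val,
      { message("unknown flag: ", key); return(1L) })
  }
  status <- tryCatch({
    cfg <- if (!is.null(opt$config)) read_run_config(opt$config) else run_config()
    cfg$seed <- opt$seed
    if (!is.null(opt$bootstrap_reps)) cfg$bootstrap_B <- opt$bootstrap_reps
    if (is.null(opt$config))
      cfg$cohort <- cohort_spec(mode = opt$mode)
    switch(cmd,
      stimuli = {
        truth <- true_probabilities(build_stimulus_set())
        utils::write.csv(truth, file.path(opt$out, "true_probabilities.csv"),
                         row.names = FALSE)
      },
      simulate = {
        set.seed(cfg$seed)
        co <- generate_cohort(cfg$cohort)
        write_response_table(co, file.path(opt$out, "cohort.csv"))
      },
      score = {
        truth <- true_probabilities(build_stimulus_set())
        tab <- read_response_table(file.path(opt$out, "cohort.csv"), truth)
        utils::write.csv(score_cohort(tab, truth),
                         file.path(opt$out, "scores.csv"), row.names = FALSE)
      },
      correlate = {
        sc <- utils::read.csv(file.path(opt$out, "scores.csv"),
                              stringsAsFactors = FALSE)
        class(sc) <- c("cohacc_scores", "data.frame")
        utils::write.csv(correlation_table(sc),
                         file.path(opt$out, "correlations.csv"),
                         row.names = FALSE)
        set.seed(cfg$seed)
        boot <- do.call(rbind, lapply(unique(sc$group), function(g) {
          b <- bootstrap_mean_correlation(sc[sc$group == g, ], cfg$bootstrap_B)
          data.frame(group = g, mean_r = b$mean_r, ci_low = b$ci_low,
                     ci_high = b$ci_high, B = b$B)
        }))
        utils::write.csv(boot, file.path(opt$out, "bootstrap.csv"),
                         row.names = FALSE)
      },
      power = {
        set.seed(cfg$seed)
        rows <- lapply(c("sampler_expert", "random_uniform"), function(m) {
          pw <- medrisk_power(cfg$medrisk, m, cfg$medrisk_experiments)
          data.frame(mode = m, mean_r = pw$mean_r,
                     power = pw$prop_significant,
                     n_experiments = pw$n_experiments, seed = cfg$seed)
        })
        utils::write.csv(do.call(rbind, rows),
                         file.path(opt$out, "power.csv"), row.names = FALSE)
      },
      report = {
        cfg$out_dir <- opt$out
        invisible(run_full_pipeline(cfg))
      },
      { message("unknown subcommand: ", cmd); message(usage); return(1L) })
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  status
}
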