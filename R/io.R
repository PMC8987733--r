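#' Write a cohort's response table (and latent sidecar) to disk
#'
#' The response table goes to a CSV with the documented schema; the latent
#' sample sizes — an oracle the analysis must never see — go to a separate
#' JSON sidecar.
#'
#' @param cohort a [generate_cohort()] result.
#' @param path CSV path for the responses.
#' @param sidecar_path optional JSON path for the latent parameters
#'   (default: `path` with a `.latent.json` suffix).
#' @return `path`, invisibly.
#' @export
write_response_table <- function(cohort, path,
                                 sidecar_path = paste0(path, ".latent.json")) {
  stopifnot(inherits(cohort, "cohacc_cohort"))
  utils::write.csv(cohort$responses, path, row.names = FALSE)
  if (!is.null(sidecar_path))
    jsonlite::write_json(list(mode = cohort$mode, latent = cohort$latent),
                         sidecar_path, dataframe = "columns", auto_unbox = TRUE)
  invisible(path)
}

#' Read and validate a response table
#'
#' Reads a CSV in the cohort schema (`participant_id`, `group`, `event_id`,
#' `frequency`, plus optional `task`, `subtask`, `RPE`, `GFM`) and validates
#' it: required columns present, frequencies within \[0, 1000\] (violations
#' reported with row numbers), no duplicate participant x event records, and
#' — when a truth table is given — every participant covering every event.
#'
#' @param path CSV file path.
#' @param truth optional [true_probabilities()] table to check completeness
#'   against.
#' @return validated data frame of responses.
#' @export
read_response_table <- function(path, truth = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "group", "event_id", "frequency")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("response table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(tab$frequency) | tab$frequency < 0 | tab$frequency > 1000)
  if (length(bad))
    stop("frequency out of [0, 1000] at rows: ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  dup <- duplicated(tab[, c("participant_id", "event_id")])
  if (any(dup))
    stop("duplicate participant x event at rows: ",
         paste(utils::head(which(dup), 10L), collapse = ", "), call. = FALSE)
  if (!is.null(truth)) {
    counts <- table(tab$participant_id)
    incomplete <- names(counts)[counts != nrow(truth)]
    missing_ev <- unique(tab$participant_id[!tab$event_id %in% truth$event_id])
    if (length(incomplete) || length(missing_ev))
      stop("participants with incomplete or unknown events: ",
           paste(utils::head(unique(c(incomplete, missing_ev)), 10L),
                 collapse = ", "), call. = FALSE)
  }
  tab
}

#' Default pipeline configuration
#'
#' @param seed integer seed governing all randomness in a run.
#' @param bootstrap_B bootstrap replicates (1e5 reproduces the full
#'   analysis; the default trades precision for speed).
#' @param alpha two-sided significance level.
#' @param cohort a [cohort_spec()].
#' @param medrisk a [medrisk_design()].
#' @param medrisk_experiments Monte-Carlo experiments for the power analysis.
#' @param out_dir optional output directory; when set, the pipeline writes
#'   its CSV outputs, report and resolved configuration there.
#' @return list of class `cohacc_config`.
#' @export
run_config <- function(seed = 1L, bootstrap_B = 1e4, alpha = 0.05,
                       cohort = cohort_spec(), medrisk = medrisk_design(),
                       medrisk_experiments = 2000L, out_dir = NULL) {
  stopifnot(bootstrap_B >= 1, alpha > 0, alpha <= 1,
            inherits(cohort, "cohacc_cohort_spec"),
            inherits(medrisk, "cohacc_medrisk_design"))
  structure(list(seed = as.integer(seed), bootstrap_B = bootstrap_B,
                 alpha = alpha, cohort = cohort, medrisk = medrisk,
                 medrisk_experiments = medrisk_experiments, out_dir = out_dir),
            class = "cohacc_config")
}

#' Read a pipeline configuration from a key = value file
#'
#' Accepts a flat TOML-style file of `key = value` lines (strings quoted or
#' bare, numbers, true/false; `#` comments). Recognized keys: `seed`,
#' `bootstrap_B`, `alpha`, `mode`, `integer_frequencies`, `medrisk_experiments`,
#' `out_dir`, `group_sizes` (comma-separated `name:size`). Unrecognized keys
#' are an error, so typos fail loudly.
#'
#' @param path config file path.
#' @return a [run_config()] list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1L], call. = FALSE)
  keys <- vapply(kv, `[[`, "", 1L)
  vals <- gsub('^"|"$', "", vapply(kv, `[[`, "", 2L))
  known <- c("seed", "bootstrap_B", "alpha", "mode", "integer_frequencies",
             "medrisk_experiments", "out_dir", "group_sizes")
  unknown <- setdiff(keys, known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  get <- function(k, default) if (k %in% keys) vals[match(k, keys)] else default
  sizes <- get("group_sizes", NULL)
  group_sizes <- if (is.null(sizes)) c(novice = 45L, amateur = 37L, expert = 186L)
  else {
    parts <- strsplit(strsplit(sizes, ",")[[1L]], ":")
    stats::setNames(as.integer(trimws(vapply(parts, `[[`, "", 2L))),
                    trimws(vapply(parts, `[[`, "", 1L)))
  }
  run_config(
    seed = as.integer(get("seed", 1L)),
    bootstrap_B = as.numeric(get("bootstrap_B", 1e4)),
    alpha = as.numeric(get("alpha", 0.05)),
    cohort = cohort_spec(
      group_sizes = group_sizes,
      mode = get("mode", "sampler"),
      integer_frequencies = tolower(get("integer_frequencies", "false")) == "true"),
    medrisk_experiments = as.integer(get("medrisk_experiments", 2000L)),
    out_dir = get("out_dir", NULL))
}
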