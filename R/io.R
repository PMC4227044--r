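trial_log_columns <- c(
  "participant", "run", "block", "rule", "context", "trial", "bandit",
  "rank", "spiral", "decision", "trial_yield", "block_end_yield"
)

#' Write a trial log to CSV
#'
#' @param trials Trial-log tibble (schema of [generate_participant()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(trials, path) {
  missing <- setdiff(trial_log_columns, names(trials))
  if (length(missing) > 0L) {
    stop("trial log is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  readr::write_csv(trials[trial_log_columns], path)
  invisible(path)
}

#' Read and validate a trial log
#'
#' Reads the shared trial-log CSV schema and validates it: required
#' columns, closed decision/rule/context vocabularies, trial and rank
#' ranges, unique (participant, block, trial) keys and rank consistency
#' within blocks. Violations raise an error naming the offending rows.
#'
#' @param path CSV file written by [write_trial_log()] (or matching its
#'   schema).
#' @return Validated trial-log tibble.
#' @export
read_trial_log <- function(path) {
  trials <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(trials) == 0L) {
    stop("trial log ", path, " contains no rows", call. = FALSE)
  }
  missing <- setdiff(trial_log_columns, names(trials))
  if (length(missing) > 0L) {
    stop("trial log is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  fail <- function(rows, why) {
    stop("invalid trial log (", why, ") at row(s) ",
         paste(head(rows, 5L), collapse = ", "),
         if (length(rows) > 5L) sprintf(" and %d more", length(rows) - 5L),
         call. = FALSE)
  }
  check <- function(bad, why) if (any(bad)) fail(which(bad), why)
  check(!trials$decision %in% c("commit", "defer"),
        "decision outside {commit, defer}")
  check(!trials$rule %in% c("rule_in", "rule_out"), "unknown rule")
  check(!trials$context %in% c("short", "medium", "long"),
        "unknown context")
  check(trials$trial < 1 | trials$trial > 12, "trial outside 1..12")
  check(!trials$rank %in% 1:4, "rank outside 1..4")
  check(!trials$bandit %in% 0:3, "bandit id outside 0..3")
  check(trials$spiral <= 0, "non-positive spiral length")
  key <- paste(trials$participant, trials$block, trials$trial)
  check(duplicated(key), "duplicate (participant, block, trial) key")
  rank_map <- paste(trials$participant, trials$block, trials$bandit)
  inconsistent <- stats::ave(
    trials$rank, rank_map, FUN = function(r) length(unique(r))
  ) > 1
  check(inconsistent, "bandit rank inconsistent within block")
  trials
}

#' Write a cohort (trial logs + ground-truth manifest)
#'
#' One trial-log CSV per participant plus `ground_truth.csv` holding the
#' generating agent parameters.
#'
#' @param cohort A `cohort_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (pid in cohort$agents$participant) {
    write_trial_log(
      cohort$trials[cohort$trials$participant == pid, ],
      file.path(dir, sprintf("participant_%03d.csv", pid))
    )
  }
  readr::write_csv(cohort$agents, file.path(dir, "ground_truth.csv"))
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `participant_*.csv` files and,
#'   optionally, `ground_truth.csv`.
#' @return A `cohort_dataset` (with an empty `agents` table when no
#'   manifest is present).
#' @export
read_cohort <- function(dir) {
  files <- sort(list.files(dir, "^participant_.*\\.csv$",
                           full.names = TRUE))
  if (length(files) == 0L) {
    stop("no participant trial logs found in ", dir, call. = FALSE)
  }
  trials <- purrr::map_dfr(files, read_trial_log)
  manifest <- file.path(dir, "ground_truth.csv")
  agents <- if (file.exists(manifest)) {
    readr::read_csv(manifest, show_col_types = FALSE, progress = FALSE)
  } else {
    tibble::tibble(participant = unique(trials$participant))
  }
  structure(list(trials = trials, agents = agents),
            class = "cohort_dataset")
}
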