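#' Commitment probability by task condition
#'
#' Cell-wise commitment probabilities using the task's definition:
#' commitments divided by the number of trials on which the bandit (or
#' trial slot) was under offer. Cells with no offers are reported as
#' missing rows, never as zero probabilities.
#'
#' @param trials Trial-log tibble with `rule`, `context`, `rank`,
#'   `trial`, `decision` columns.
#' @param by `"rank"` (probability per payoff rank, the spiral-length
#'   profile) or `"trial"` (probability per trial number, the temporal
#'   profile).
#' @return Tibble with `rule`, `context`, the `by` variable, `n_offers`,
#'   `n_commits`, `p_commit`.
#' @export
#' @examples
#' cohort <- generate_cohort(n = 2, seed = 1)
#' commit_probability_by_condition(cohort$trials, by = "rank")
commit_probability_by_condition <- function(trials, by = c("rank", "trial")) {
  by <- match.arg(by)
  trials |>
    dplyr::group_by(.data$rule, .data$context,
                    dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n_offers = dplyr::n(),
      n_commits = sum(.data$decision == "commit"),
      p_commit = .data$n_commits / .data$n_offers,
      .groups = "drop"
    )
}

#' Commitment counts and first-commitment trials
#'
#' Per participant and rule: mean commitments per block, the mean trial
#' of the first commitment (over blocks that contain one; blocks with no
#' commitment contribute nothing to that average), and the overall commit
#' proportion. Cohort level: means and SDs across participants, the sum
#' of the two rules' per-block counts, and paired two-sided t tests
#' between rules on both measures.
#'
#' @param trials Cohort trial-log tibble (`participant`, `block`, `rule`,
#'   `trial`, `decision`).
#' @return A `commitment_counts` list: `per_participant`, `summary`
#'   (per rule plus the summed count), `tests`.
#' @export
commitment_counts <- function(trials) {
  per_block <- trials |>
    dplyr::group_by(.data$participant, .data$rule, .data$block) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      n_commits = sum(.data$decision == "commit"),
      first_commit = if (any(.data$decision == "commit")) {
        min(.data$trial[.data$decision == "commit"])
      } else {
        NA_integer_
      },
      .groups = "drop"
    )
  n_empty <- sum(is.na(per_block$first_commit))
  if (n_empty > 0L) {
    message(n_empty, " block(s) without commitments excluded from ",
            "first-commitment averages")
  }
  per_participant <- per_block |>
    dplyr::group_by(.data$participant, .data$rule) |>
    dplyr::summarise(
      commits_per_block = mean(.data$n_commits),
      first_commit_trial = mean(.data$first_commit, na.rm = TRUE),
      commit_proportion = sum(.data$n_commits) / sum(.data$n_trials),
      .groups = "drop"
    )
  summary <- per_participant |>
    dplyr::group_by(.data$rule) |>
    dplyr::summarise(
      dplyr::across(
        c("commits_per_block", "first_commit_trial", "commit_proportion"),
        list(mean = mean, sd = sd)
      ),
      .groups = "drop"
    )
  total <- per_participant |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(total = sum(.data$commits_per_block))
  summary <- dplyr::bind_rows(
    summary,
    tibble::tibble(
      rule = "both",
      commits_per_block_mean = mean(total$total),
      commits_per_block_sd = sd(total$total)
    )
  )
  paired_test <- function(var) {
    wide <- tidyr::pivot_wider(
      per_participant[, c("participant", "rule", var)],
      names_from = "rule", values_from = dplyr::all_of(var)
    )
    ok <- stats::complete.cases(wide$rule_in, wide$rule_out)
    d <- wide$rule_out[ok] - wide$rule_in[ok]
    if (length(d) < 2L || sd(d) == 0) {
      return(tibble::tibble(measure = var, mean_diff = mean(d),
                            statistic = NA_real_, df = NA_real_,
                            p_value = NA_real_))
    }
    tt <- t.test(wide$rule_out[ok], wide$rule_in[ok], paired = TRUE)
    tibble::tibble(
      measure = var, mean_diff = unname(tt$estimate),
      statistic = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value
    )
  }
  tests <- dplyr::bind_rows(
    paired_test("commits_per_block"),
    paired_test("first_commit_trial")
  )
  structure(
    list(per_participant = per_participant, summary = summary,
         tests = tests),
    class = "commitment_counts"
  )
}

#' @export
print.commitment_counts <- function(x, ...) {
  cat("<commitment_counts> cohort summary:\n")
  print(x$summary)
  cat("paired rule-out vs rule-in tests:\n")
  print(x$tests)
  invisible(x)
}

#' Trialwise model-derived regressors for one block
#'
#' For each trial: the decision variable of the offered bandit, the block
#' reference value r, the trial number, the estimated per-trial yield
#' (the mean, over bandits currently in the asset pool, of the difference
#' between the bandit's running length estimate and the reference; zero
#' for an empty pool), and its running accumulation — the estimate of the
#' cumulative payoff given the history of offers and decisions. Under
#' rule-in the asset pool is the committed set; under rule-out it is the
#' complement of the rejected set.
#'
#' @param log A `block_log` from [run_block()], or a tibble of one
#'   block's trials (`trial`, `bandit`, `spiral`, `decision`) with a
#'   `rule` attribute/column.
#' @param dv A [dv_config()] (default current-minus-average).
#' @param refresh_reference When `TRUE` (default) each bandit's pool
#'   contribution is re-evaluated against the current reference every
#'   trial; when `FALSE` the reference is frozen at the value it had when
#'   the bandit entered the pool (rule-out bandits start in the pool with
#'   the first-trial reference).
#' @return Tibble: `trial`, `dv`, `reference`, `est_yield`,
#'   `est_aggregate_yield`.
#' @export
model_regressors <- function(log, dv = NULL, refresh_reference = TRUE) {
  if (is.null(dv)) {
    dv <- dv_config("average", integration = TRUE)
  }
  rule <- if (!is.null(attr(log, "config"))) {
    attr(log, "config")$rule
  } else if ("rule" %in% names(log)) {
    log$rule[1L]
  } else {
    stop("cannot determine the block's rule", call. = FALSE)
  }
  trace <- dv_trace(log, dv)
  n <- nrow(log)
  hist <- new_dv_history(dv)
  in_pool <- rep(rule == "rule_out", 4L) # rule-out pool starts full
  entry_ref <- rep(dv$v_prior, 4L)
  est <- numeric(n)
  for (j in seq_len(n)) {
    hist <- dv_observe(hist, log$bandit[j], log$spiral[j], dv)
    r <- reference_value(hist, "average", log$bandit[j], dv)
    hist <- dv_advance(hist, log$spiral[j])
    if (log$decision[j] == "commit") {
      i <- log$bandit[j] + 1L
      if (rule == "rule_in") {
        in_pool[i] <- TRUE
        entry_ref[i] <- r
      } else {
        in_pool[i] <- FALSE
      }
    }
    pool <- which(in_pool)
    est[j] <- if (length(pool) == 0L) {
      0
    } else {
      # never-sampled pool members carry the prior estimate
      vhat <- ifelse(hist$n[pool] > 0L, hist$vbar[pool], dv$v_prior)
      ref <- if (refresh_reference) r else entry_ref[pool]
      mean(vhat - ref)
    }
  }
  tibble::tibble(
    trial = log$trial,
    dv = trace$dv,
    reference = trace$reference,
    est_yield = est,
    est_aggregate_yield = cumsum(est)
  )
}
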