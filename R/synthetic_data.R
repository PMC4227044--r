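#' Specification of a synthetic agent
#'
#' A noisy criterion agent: commitment probability
#' Phi(slope * (DV - theta_in)) under rule-in and
#' Phi(slope * (theta_out - DV)) under rule-out, deterministic in the
#' limit `slope = Inf`, with an optional per-trial lapse replacing the
#' decision by a coin flip.
#'
#' @param theta_in,theta_out Commitment criteria in DV units (defaults:
#'   the fitted group means 0.39 and 0.12).
#' @param slope Probit slope (> 0, `Inf` = deterministic).
#' @param lapse Lapse probability in `[0, 0.2]`.
#' @param dv A [dv_config()]; default current-minus-average.
#' @return An `agent_spec` object.
#' @export
agent_spec <- function(theta_in = 0.39, theta_out = 0.12, slope = Inf,
                       lapse = 0, dv = NULL) {
  stopifnot(slope > 0, lapse >= 0, lapse <= 0.2)
  if (is.null(dv)) {
    dv <- dv_config("average", integration = TRUE)
  }
  structure(
    list(theta_in = theta_in, theta_out = theta_out, slope = slope,
         lapse = lapse, dv = dv),
    class = "agent_spec"
  )
}

# draw the per-participant ground-truth agent parameters (criteria from
# truncated normals; shared noise parameters); uses the current RNG stream
draw_cohort_agents <- function(n, theta_in_mean, theta_in_sd,
                               theta_out_mean, theta_out_sd,
                               slope, lapse, truncate) {
  tibble::tibble(
    participant = seq_len(n),
    theta_in = pmin(pmax(rnorm(n, theta_in_mean, theta_in_sd),
                         truncate[1L]), truncate[2L]),
    theta_out = pmin(pmax(rnorm(n, theta_out_mean, theta_out_sd),
                          truncate[1L]), truncate[2L]),
    slope = slope,
    lapse = lapse,
    seed = sample.int(.Machine$integer.max - 1L, n)
  )
}

# one session layout: 4 runs x 12 blocks; every run holds exactly two
# blocks of each rule x context cell, giving 6 per rule and 4 per context
session_layout <- function() {
  cells <- tidyr::expand_grid(
    rule = c("rule_in", "rule_out"),
    context = c("short", "medium", "long")
  )
  purrr::map_dfr(1:4, function(run) {
    blocks <- dplyr::bind_rows(cells, cells)
    blocks <- blocks[sample.int(nrow(blocks)), ]
    blocks$run <- run
    blocks
  }) |>
    dplyr::mutate(block = dplyr::row_number()) |>
    dplyr::select("run", "block", "rule", "context")
}

#' Simulate one participant's full session
#'
#' Plays 48 blocks in 4 runs — 6 blocks per rule and 4 per context in
#' every run, order shuffled within run — with decisions generated by the
#' agent's noisy criterion rule on its decision variable.
#'
#' @param agent An [agent_spec()].
#' @param seed Integer seed; the full session is reproducible from it.
#' @param participant Participant id recorded in the log.
#' @return Trial-log tibble: `participant`, `run`, `block`, `rule`,
#'   `context`, `trial`, `bandit`, `rank`, `spiral`, `decision`,
#'   `trial_yield`, `block_end_yield`.
#' @export
#' @examples
#' trials <- generate_participant(agent_spec(), seed = 1)
#' dplyr::count(trials, rule)
generate_participant <- function(agent, seed = NULL, participant = 1L) {
  stopifnot(inherits(agent, "agent_spec"))
  policy <- noisy_criterion_policy(agent$theta_in, agent$theta_out,
                                   agent$slope, agent$lapse)
  with_seed(seed, {
    layout <- session_layout()
    purrr::pmap_dfr(layout, function(run, block, rule, context) {
      cfg <- make_block(rule, context)
      log <- run_block(policy, cfg, agent$dv)
      tibble::tibble(
        participant = participant,
        run = run,
        block = block,
        rule = rule,
        context = context,
        trial = log$trial,
        bandit = log$bandit,
        rank = log$rank,
        spiral = log$spiral,
        decision = log$decision,
        trial_yield = log$trial_yield,
        block_end_yield = attr(log, "block_end_yield")
      )
    })
  })
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws per-participant criteria from normal distributions (defaults:
#' the fitted group means and between-subject SDs, theta_in ~
#' N(0.39, 0.29), theta_out ~ N(0.12, 0.25), truncated to the criterion
#' grid range -1.0..1.5) and simulates a full 48-block session for each
#' participant. The generating parameters are retained for
#' parameter-recovery studies.
#'
#' @param n Number of participants (default 20).
#' @param theta_in_mean,theta_in_sd,theta_out_mean,theta_out_sd Between-
#'   subject criterion distributions.
#' @param slope,lapse Shared agent noise parameters (see [agent_spec()]).
#' @param seed Integer seed.
#' @param truncate Range to which sampled criteria are clipped.
#' @return A `cohort_dataset`: list with `trials` (all participants'
#'   logs) and `agents` (ground-truth tibble: `participant`, `theta_in`,
#'   `theta_out`, `slope`, `lapse`, `seed`).
#' @export
generate_cohort <- function(n = 20L,
                            theta_in_mean = 0.39, theta_in_sd = 0.29,
                            theta_out_mean = 0.12, theta_out_sd = 0.25,
                            slope = Inf, lapse = 0, seed = NULL,
                            truncate = c(-1, 1.5)) {
  stopifnot(n >= 1L)
  if (theta_in_sd < 0 || theta_out_sd < 0) {
    stop("criterion SDs must be non-negative", call. = FALSE)
  }
  with_seed(seed, {
    agents <- draw_cohort_agents(n, theta_in_mean, theta_in_sd,
                                 theta_out_mean, theta_out_sd,
                                 slope, lapse, truncate)
    trials <- purrr::pmap_dfr(agents, function(participant, theta_in,
                                               theta_out, slope, lapse,
                                               seed) {
      generate_participant(
        agent_spec(theta_in, theta_out, slope, lapse),
        seed = seed, participant = participant
      )
    })
    structure(list(trials = trials, agents = agents),
              class = "cohort_dataset")
  })
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat("<cohort_dataset>", nrow(x$agents), "participants,",
      nrow(x$trials), "trials\n")
  print(head(x$agents))
  invisible(x)
}

#' Parameter-recovery experiment on a synthetic cohort
#'
#' Refits the deterministic criterion model (and optionally the probit
#' model) to every participant of a ground-truth cohort and summarizes
#' recovery of the commitment criteria: bias, RMSE and the correlation
#' between true and recovered values, per rule. Failed fits are itemized
#' and excluded.
#'
#' @param cohort A `cohort_dataset` from [generate_cohort()].
#' @param theta_grid Criterion grid passed to [fit_criterion_model()].
#' @param probit Also fit the probit model and report its implied
#'   criteria (-b/c)?
#' @return A `recovery_report`: `per_participant` (true and recovered
#'   criteria) and `summary` (bias, RMSE, correlation per rule).
#' @export
recovery_experiment <- function(cohort,
                                theta_grid = seq(-1, 1.5, by = 0.01),
                                probit = FALSE) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  per <- purrr::map_dfr(cohort$agents$participant, function(pid) {
    truth <- cohort$agents[cohort$agents$participant == pid, ]
    df <- cohort$trials[cohort$trials$participant == pid, ]
    fit <- tryCatch(
      fit_criterion_model(df, theta_grid = theta_grid),
      error = function(e) {
        warning("criterion fit failed for participant ", pid, ": ",
                conditionMessage(e), call. = FALSE)
        NULL
      }
    )
    row <- tibble::tibble(
      participant = pid,
      true_theta_in = truth$theta_in,
      true_theta_out = truth$theta_out,
      fit_theta_in = if (is.null(fit)) NA_real_ else fit$theta_in,
      fit_theta_out = if (is.null(fit)) NA_real_ else fit$theta_out
    )
    if (probit) {
      pf <- tryCatch(
        fit_probit(df, dv_config("average", integration = TRUE)),
        error = function(e) NULL
      )
      row$probit_theta_in <- if (is.null(pf)) NA_real_ else
        pf$params$theta[pf$params$rule == "rule_in"]
      row$probit_theta_out <- if (is.null(pf)) NA_real_ else
        pf$params$theta[pf$params$rule == "rule_out"]
    }
    row
  })
  summarize_rule <- function(truth, fit, rule) {
    ok <- !is.na(fit)
    tibble::tibble(
      rule = rule,
      n = sum(ok),
      bias = mean(fit[ok] - truth[ok]),
      rmse = sqrt(mean((fit[ok] - truth[ok])^2)),
      correlation = if (sum(ok) >= 3L && sd(truth[ok]) > 0 &&
                        sd(fit[ok]) > 0) {
        stats::cor(truth[ok], fit[ok])
      } else {
        NA_real_
      }
    )
  }
  summary <- dplyr::bind_rows(
    summarize_rule(per$true_theta_in, per$fit_theta_in, "rule_in"),
    summarize_rule(per$true_theta_out, per$fit_theta_out, "rule_out")
  )
  structure(list(per_participant = per, summary = summary),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n")
  print(x$summary)
  invisible(x)
}
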