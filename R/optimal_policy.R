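balanced_contexts <- function(n_blocks) {
  rep(0:2, length.out = n_blocks) # 0 short, 1 medium, 2 long
}

#' Expected block-end yield of a threshold agent
#'
#' Monte-Carlo estimate of the mean block-end yield earned by the
#' deterministic criterion agent (current-minus-average decision
#' variable) at a given criterion, over freshly simulated blocks with
#' contexts balanced across the three context types.
#'
#' @param theta Commitment criterion in DV units (`Inf` never commits
#'   under rule-in; `-Inf` never commits under rule-out).
#' @param rule `"rule_in"` or `"rule_out"`.
#' @param n_blocks Number of simulated blocks.
#' @param seed Integer seed; the same seed replays the same blocks.
#' @param v_prior First-trial reference value.
#' @param max_trials Block horizon.
#' @return One-row tibble: `rule`, `theta`, `mean_yield`, `se`,
#'   `n_blocks`.
#' @export
#' @examples
#' simulate_policy_yield(0.39, "rule_in", n_blocks = 1000, seed = 1)
simulate_policy_yield <- function(theta, rule, n_blocks, seed,
                                  v_prior = 3.75, max_trials = 12L) {
  rule <- match.arg(rule, c("rule_in", "rule_out"))
  stopifnot(n_blocks >= 1L)
  sim <- .simulate_threshold_blocks_cpp(
    as.integer(n_blocks), rule == "rule_out", theta,
    balanced_contexts(n_blocks), as.integer(max_trials), v_prior,
    as.double(seed)
  )
  tibble::tibble(
    rule = rule,
    theta = theta,
    mean_yield = mean(sim$yield),
    se = if (n_blocks > 1L) sd(sim$yield) / sqrt(n_blocks) else NA_real_,
    n_blocks = as.integer(n_blocks)
  )
}

#' Simulate many blocks under the threshold agent
#'
#' Block-level outcomes (trials, commitments, first-commitment trial,
#' rounded yield) for a deterministic criterion agent on the
#' current-minus-average decision variable, with contexts balanced.
#' This is the fast path behind the behavioural-reproduction and
#' policy-sweep analyses.
#'
#' @inheritParams simulate_policy_yield
#' @return Tibble with one row per block: `context`, `n_trials`,
#'   `n_commits`, `first_commit` (`NA` when no commitment), `yield`.
#' @export
simulate_threshold_blocks <- function(theta, rule, n_blocks, seed,
                                      v_prior = 3.75, max_trials = 12L) {
  rule <- match.arg(rule, c("rule_in", "rule_out"))
  sim <- .simulate_threshold_blocks_cpp(
    as.integer(n_blocks), rule == "rule_out", theta,
    balanced_contexts(n_blocks), as.integer(max_trials), v_prior,
    as.double(seed)
  )
  out <- tibble::as_tibble(sim)
  out$context <- c("short", "medium", "long")[out$context + 1L]
  out
}

#' Locate the reward-maximizing commitment criterion by grid search
#'
#' Sweeps the criterion over a grid, estimating the expected block-end
#' yield at every point from `n_blocks` simulated blocks. All grid points
#' replay the same per-block random streams (common random numbers), so
#' yield differences between neighbouring criteria are not swamped by
#' stimulus sampling noise. Argmax ties break toward the smaller
#' criterion.
#'
#' @param rule `"rule_in"` or `"rule_out"`.
#' @param grid Ordered criterion grid (default -1.0 to 1.5 by 0.01).
#' @param n_blocks Simulated blocks per grid point (default 10000).
#' @param seed Integer seed.
#' @inheritParams simulate_policy_yield
#' @return A `policy_sweep`: tibble (`rule`, `theta`, `mean_yield`, `se`,
#'   `n_blocks`) with attributes `theta_star` and `seed`.
#' @export
#' @examples
#' sw <- reward_maximizing_criterion("rule_in", grid = seq(0, 1, 0.1),
#'                                   n_blocks = 500, seed = 1)
#' attr(sw, "theta_star")
reward_maximizing_criterion <- function(rule, grid = seq(-1, 1.5, by = 0.01),
                                        n_blocks = 10000L, seed = 1L,
                                        v_prior = 3.75, max_trials = 12L) {
  rule <- match.arg(rule, c("rule_in", "rule_out"))
  if (is.unsorted(grid)) {
    stop("`grid` must be ordered", call. = FALSE)
  }
  sweep <- .sweep_threshold_cpp(
    as.double(grid), rule == "rule_out", as.integer(n_blocks),
    balanced_contexts(n_blocks), as.integer(max_trials), v_prior,
    as.double(seed)
  )
  out <- tibble::as_tibble(sweep)
  out <- dplyr::mutate(out, rule = rule, n_blocks = as.integer(n_blocks),
                       .before = 1L)
  i_star <- which.max(out$mean_yield) # which.max takes the first: ties
  theta_star <- out$theta[i_star]     # break toward the smaller theta
  if (length(grid) >= 3L && (i_star == 1L || i_star == length(grid))) {
    warning("yield maximum lies at the edge of the criterion grid; ",
            "widen `grid` to bracket it", call. = FALSE)
  }
  structure(out,
    theta_star = theta_star, seed = seed,
    class = c("policy_sweep", class(out))
  )
}

#' Sampling distributions of the estimated payoff by rank
#'
#' Simulates defer-only blocks and tracks the current-minus-average
#' decision variable for each offer, grouped by the offered bandit's
#' payoff rank and by how many samples of that bandit have been seen.
#' This reproduces the families of estimated-payoff distributions that
#' motivate criterion placement: ranks separate in mean at every sample
#' count, and the spread shrinks as samples accumulate.
#'
#' @param n_samples Largest per-bandit sample count to summarize.
#' @param n_sims Number of simulated blocks.
#' @param seed Integer seed.
#' @param dv A [dv_config()] (default current-minus-average).
#' @return Tibble: `rank`, `n_samples`, `n`, `mean_dv`, `sd_dv`, `q10`,
#'   `q90`.
#' @export
payoff_estimate_distributions <- function(n_samples = 3L, n_sims = 2000L,
                                          seed = 1L, dv = NULL) {
  stopifnot(n_samples >= 1L)
  if (is.null(dv)) {
    dv <- dv_config("average", integration = TRUE)
  }
  defer_always <- function(value, rule) "defer"
  contexts <- c("short", "medium", "long")
  rows <- with_seed(seed, {
    purrr::map_dfr(seq_len(n_sims), function(b) {
      cfg <- make_block(
        if (b %% 2L == 0L) "rule_in" else "rule_out",
        contexts[(b %% 3L) + 1L]
      )
      log <- run_block(defer_always, cfg, dv)
      counts <- integer(4)
      purrr::map_dfr(seq_len(nrow(log)), function(j) {
        i <- log$bandit[j] + 1L
        counts[i] <<- counts[i] + 1L
        tibble::tibble(rank = log$rank[j], n_samples = counts[i],
                       dv = log$dv[j])
      })
    })
  })
  rows |>
    dplyr::filter(.data$n_samples <= !!n_samples) |>
    dplyr::group_by(.data$rank, .data$n_samples) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_dv = mean(.data$dv),
      sd_dv = sd(.data$dv),
      q10 = unname(stats::quantile(.data$dv, 0.1)),
      q90 = unname(stats::quantile(.data$dv, 0.9)),
      .groups = "drop"
    )
}
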