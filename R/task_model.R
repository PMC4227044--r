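#' Mean spiral lengths for a block context
#'
#' Each block draws its four bandit means from one of three contiguous
#' windows over the six spiral lengths used in the design
#' (2.5, 3.0, ..., 5.0). Payoffs are attached to the *rank* of a bandit's
#' mean within its block, so the same physical length can be valuable in a
#' short context and poor in a long one.
#'
#' @param context One of `"short"`, `"medium"`, `"long"`.
#' @return Numeric vector of four mean spiral lengths, shortest first.
#' @export
#' @examples
#' context_means("short")
context_means <- function(context) {
  switch(match.arg(context, c("short", "medium", "long")),
    short  = c(2.5, 3.0, 3.5, 4.0),
    medium = c(3.0, 3.5, 4.0, 4.5),
    long   = c(3.5, 4.0, 4.5, 5.0)
  )
}

#' Per-trial payoff attached to a payoff rank
#'
#' Ranks 1-4 (shortest to longest mean within the block) earn
#' -15/24, -5/24, +5/24 and +15/24 pounds per trial. The four payoffs sum
#' to zero, so an empty rule-in pool and a full rule-out pool both yield
#' exactly nothing.
#'
#' @param rank Integer vector with values in 1:4.
#' @return Payoff(s) in pounds per trial.
#' @export
#' @examples
#' payoff_for_rank(1:4)
payoff_for_rank <- function(rank) {
  if (!all(rank %in% 1:4)) {
    stop("`rank` must contain values in 1:4", call. = FALSE)
  }
  c(-15, -5, 5, 15)[rank] / 24
}

#' Construct one block of the commitment task
#'
#' Builds the generative definition of a block: four bandits carrying the
#' context's mean spiral lengths, standard deviations 0.5/0.5/1.0/1.0
#' assigned uniformly at random, payoffs assigned by rank of mean length,
#' and a randomized mapping of ranks to screen positions (bandit ids 0-3).
#'
#' @param rule `"rule_in"` (commit = accept into the asset pool) or
#'   `"rule_out"` (commit = reject from an initially full pool).
#' @param context Block context, see [context_means()].
#' @param seed Optional integer seed for the randomized assignments.
#' @param max_trials Block horizon (default 12 trials).
#' @return A `block_config` object: list with `rule`, `context`,
#'   `max_trials` and a `bandits` tibble (`bandit`, `mean`, `sd`,
#'   `payoff`, `rank`).
#' @export
#' @examples
#' cfg <- make_block("rule_in", "short", seed = 1)
#' cfg$bandits
make_block <- function(rule, context, seed = NULL, max_trials = 12L) {
  rule <- match.arg(rule, c("rule_in", "rule_out"))
  means <- context_means(context)
  with_seed(seed, {
    bandit_of_rank <- sample.int(4L) - 1L # rank -> screen position
    sds <- sample(c(0.5, 0.5, 1.0, 1.0))
    bandits <- tibble::tibble(
      bandit = bandit_of_rank,
      mean = means,
      sd = sds,
      payoff = payoff_for_rank(1:4),
      rank = 1:4
    )
    bandits <- dplyr::arrange(bandits, .data$bandit)
    structure(
      list(
        rule = rule,
        context = match.arg(context, c("short", "medium", "long")),
        bandits = bandits,
        max_trials = as.integer(max_trials)
      ),
      class = "block_config"
    )
  })
}

#' @export
print.block_config <- function(x, ...) {
  cat("<block_config>", x$rule, "/", x$context,
      "(horizon", x$max_trials, "trials)\n")
  print(x$bandits)
  invisible(x)
}

#' Fresh state for a block
#'
#' @param config A `block_config`.
#' @return A `block_state`: 1-based upcoming trial index, active bandit
#'   set, committed set (IN under rule-in, OUT under rule-out) and the
#'   per-trial yields recorded so far.
#' @export
new_block_state <- function(config) {
  structure(
    list(
      trial = 1L,
      active = config$bandits$bandit,
      committed = integer(0),
      yields = numeric(0)
    ),
    class = "block_state"
  )
}

#' Is a block state terminal?
#'
#' A block ends when no active bandits remain or when `max_trials` trials
#' have been played.
#'
#' @param state A `block_state`.
#' @param config The block's `block_config`.
#' @return Logical scalar.
#' @export
is_terminal <- function(state, config) {
  length(state$active) == 0L || state$trial > config$max_trials
}

#' Sample the next offer in a block
#'
#' Offers are drawn uniformly from the bandits still in play, and the
#' spiral length from the offered bandit's Gaussian. Spiral lengths are
#' physical magnitudes, so non-positive draws (possible at mean 2.5,
#' sd 1.0 with probability ~0.006) are redrawn; the number of redraws is
#' reported so callers can log it.
#'
#' @param state A non-terminal `block_state`.
#' @param config The block's `block_config`.
#' @return List with `bandit`, `spiral` and `n_resampled`.
#' @export
sample_offer <- function(state, config) {
  if (length(state$active) == 0L) {
    stop("cannot sample an offer: no active bandits remain", call. = FALSE)
  }
  bandit <- if (length(state$active) == 1L) {
    state$active
  } else {
    sample(state$active, 1L)
  }
  row <- config$bandits[config$bandits$bandit == bandit, ]
  spiral <- rnorm(1L, row$mean, row$sd)
  n_resampled <- 0L
  while (spiral <= 0) {
    spiral <- rnorm(1L, row$mean, row$sd)
    n_resampled <- n_resampled + 1L
  }
  list(bandit = bandit, spiral = spiral, n_resampled = n_resampled)
}

#' Per-trial monetary yield of the current asset pool
#'
#' Under rule-in the yield is the mean payoff of the bandits accepted so
#' far (zero while the pool is empty); under rule-out it is the mean
#' payoff of the bandits not yet rejected. Called after the current
#' trial's decision has been applied to the state.
#'
#' @param state A `block_state` reflecting all commitments up to and
#'   including the current trial.
#' @param config The block's `block_config`.
#' @return Yield in pounds for the current trial.
#' @export
per_trial_yield <- function(state, config) {
  payoffs <- config$bandits$payoff
  ids <- config$bandits$bandit
  if (config$rule == "rule_in") {
    if (length(state$committed) == 0L) {
      return(0)
    }
    mean(payoffs[match(state$committed, ids)])
  } else {
    pool <- setdiff(ids, state$committed)
    if (length(pool) == 0L) {
      return(0)
    }
    mean(payoffs[match(pool, ids)])
  }
}

#' Block-end yield: rounded sum of per-trial yields
#'
#' The block's earnings are the sum of the per-trial yields over the k
#' trials that occurred, rounded to the nearest half pound. Exact ties
#' (e.g. 0.25) round away from zero; this is the only place the rounding
#' rule lives.
#'
#' @param yields Numeric vector of per-trial yields (may be empty).
#' @return Rounded block-end yield in pounds.
#' @export
#' @examples
#' block_end_yield(c(0, 5 / 24, 10 / 24)) # 0.625 -> 0.5
block_end_yield <- function(yields) {
  if (length(yields) == 0L) {
    return(0)
  }
  total <- sum(yields)
  sign(total) * floor(abs(total) * 2 + 0.5) / 2
}

#' Apply one trial's decision to a block state
#'
#' A commit moves the offered bandit from the active set to the committed
#' set (IN under rule-in, OUT under rule-out); a defer leaves both sets
#' unchanged. The trial's yield is computed after the decision is applied
#' and appended, and the trial counter advances.
#'
#' @param state A non-terminal `block_state`.
#' @param config The block's `block_config`.
#' @param bandit Offered bandit id (must be active).
#' @param decision `"commit"` or `"defer"`.
#' @return The updated `block_state`.
#' @export
step <- function(state, config, bandit, decision) {
  if (is_terminal(state, config)) {
    stop("cannot step a terminal block state", call. = FALSE)
  }
  decision <- match.arg(decision, c("commit", "defer"))
  if (!bandit %in% state$active) {
    stop("offered bandit ", bandit, " is not active", call. = FALSE)
  }
  if (decision == "commit") {
    state$active <- setdiff(state$active, bandit)
    state$committed <- c(state$committed, bandit)
  }
  state$yields <- c(state$yields, per_trial_yield(state, config))
  state$trial <- state$trial + 1L
  state
}

#' Play one block under a decision policy
#'
#' Composes [sample_offer()], the decision-variable machinery, `policy`
#' and [step()] into a complete block log. The policy sees, on every
#' trial, the scalar decision variable for the offered bandit (computed
#' under `dv_config` from the information available at that trial) and
#' the block's rule, and must return `"commit"` or `"defer"`.
#'
#' @param policy Function `(dv, rule) -> "commit"/"defer"`.
#' @param config A `block_config`.
#' @param dv_config A [dv_config()] describing the decision variable.
#' @param seed Optional seed making the block reproducible.
#' @return A `block_log`: tibble with one row per trial (`trial`,
#'   `bandit`, `rank`, `spiral`, `dv`, `reference`, `decision`,
#'   `trial_yield`) plus attributes `config`, `block_end_yield` and
#'   `n_resampled`.
#' @export
#' @examples
#' cfg <- make_block("rule_out", "medium", seed = 2)
#' pol <- threshold_policy(theta_in = 0.39, theta_out = 0.12)
#' run_block(pol, cfg, dv_config("average", integration = TRUE), seed = 3)
run_block <- function(policy, config, dv_config, seed = NULL) {
  with_seed(seed, {
    state <- new_block_state(config)
    hist <- new_dv_history(dv_config)
    rows <- vector("list", config$max_trials)
    n_resampled <- 0L
    while (!is_terminal(state, config)) {
      offer <- sample_offer(state, config)
      n_resampled <- n_resampled + offer$n_resampled
      hist <- dv_observe(hist, offer$bandit, offer$spiral, dv_config)
      dv_now <- compute_dv(hist, dv_config, offer$bandit)
      hist <- dv_advance(hist, offer$spiral)
      decision <- policy(dv_now$value, config$rule)
      if (!decision %in% c("commit", "defer")) {
        stop("policy must return \"commit\" or \"defer\"", call. = FALSE)
      }
      t_now <- state$trial
      state <- step(state, config, offer$bandit, decision)
      rows[[t_now]] <- tibble::tibble(
        trial = t_now,
        bandit = offer$bandit,
        rank = config$bandits$rank[match(offer$bandit, config$bandits$bandit)],
        spiral = offer$spiral,
        dv = dv_now$value,
        reference = dv_now$reference,
        decision = decision,
        trial_yield = state$yields[t_now]
      )
    }
    log <- dplyr::bind_rows(rows)
    structure(
      log,
      config = config,
      block_end_yield = block_end_yield(log$trial_yield),
      n_resampled = n_resampled,
      class = c("block_log", class(log))
    )
  })
}

#' Deterministic threshold policy
#'
#' Commit when the decision variable reaches the criterion: DV >= theta_in
#' under rule-in, DV <= theta_out under rule-out (inclusive at the
#' criterion; a measure-zero event under continuous noise).
#'
#' @param theta_in,theta_out Commitment criteria in DV units.
#' @return A policy function usable with [run_block()].
#' @export
threshold_policy <- function(theta_in, theta_out) {
  force(theta_in)
  force(theta_out)
  function(dv, rule) {
    hit <- if (rule == "rule_in") dv >= theta_in else dv <= theta_out
    if (hit) "commit" else "defer"
  }
}

#' Noisy criterion policy
#'
#' Probabilistic relaxation of [threshold_policy()]: the commitment
#' probability is Phi(slope * (DV - theta_in)) under rule-in and
#' Phi(slope * (theta_out - DV)) under rule-out, so behaviour becomes
#' deterministic as `slope` grows. With probability `lapse` the decision
#' is replaced by a fair coin flip (emulating occasional forced random
#' choices).
#'
#' @param theta_in,theta_out Criteria in DV units.
#' @param slope Probit slope (> 0; `Inf` = deterministic).
#' @param lapse Lapse probability in `[0, 0.2]`.
#' @return A policy function usable with [run_block()].
#' @export
noisy_criterion_policy <- function(theta_in, theta_out, slope = Inf, lapse = 0) {
  stopifnot(slope > 0, lapse >= 0, lapse <= 0.2)
  function(dv, rule) {
    if (lapse > 0 && runif(1L) < lapse) {
      return(if (runif(1L) < 0.5) "commit" else "defer")
    }
    margin <- if (rule == "rule_in") dv - theta_in else theta_out - dv
    p <- if (is.infinite(slope)) as.numeric(margin >= 0) else pnorm(slope * margin)
    if (runif(1L) < p) "commit" else "defer"
  }
}
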