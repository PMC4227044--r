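#' Probit choice-model parameters
#'
#' Commitment probability is Phi(b + c * DV), with separate intercept and
#' slope per rule. The implied criterion (DV at which commitment reaches
#' 50%) is theta = -b / c, defined when c != 0.
#'
#' @param b_in,c_in,b_out,c_out Intercepts and slopes per rule.
#' @return A `probit_params` object.
#' @export
probit_params <- function(b_in, c_in, b_out, c_out) {
  structure(
    list(b_in = b_in, c_in = c_in, b_out = b_out, c_out = c_out),
    class = "probit_params"
  )
}

#' Commitment probability under the probit model
#'
#' @param dv Decision-variable value(s).
#' @param rule `"rule_in"` or `"rule_out"`.
#' @param params A [probit_params()].
#' @return Probability of committing, Phi(b_rule + c_rule * dv).
#' @export
#' @examples
#' p <- probit_params(-1, 2.5, 0.3, -2.5)
#' commit_probability(0.4, "rule_in", p) # Phi(0)
commit_probability <- function(dv, rule, params) {
  rule <- match.arg(rule, c("rule_in", "rule_out"))
  if (rule == "rule_in") {
    pnorm(params$b_in + params$c_in * dv)
  } else {
    pnorm(params$b_out + params$c_out * dv)
  }
}

# clamp probabilities away from 0/1 before taking logs
.P_EPS <- 1e-12

#' Negative log-likelihood of observed decisions under a probit model
#'
#' Recomputes the decision variable along each block and sums
#' -log P(observed decision) over all trials, rule-in and rule-out
#' together. Probabilities are clamped to `[1e-12, 1 - 1e-12]` to guard
#' against log-of-zero underflow.
#'
#' @param trials Trial-log tibble (see [generate_participant()] for the
#'   schema); needs `rule`, `decision` and the columns required by
#'   [add_decision_variable()].
#' @param dv_config A [dv_config()].
#' @param params A [probit_params()].
#' @return Negative log-likelihood in nats.
#' @export
negative_log_likelihood <- function(trials, dv_config, params) {
  trials <- add_decision_variable(trials, dv_config)
  p <- ifelse(
    trials$rule == "rule_in",
    commit_probability(trials$dv, "rule_in", params),
    commit_probability(trials$dv, "rule_out", params)
  )
  p_obs <- ifelse(trials$decision == "commit", p, 1 - p)
  -sum(log(pmin(pmax(p_obs, .P_EPS), 1 - .P_EPS)))
}

#' Fit the probit choice model by maximum likelihood
#'
#' Separate probit regressions of commit/defer on the decision variable
#' for rule-in and rule-out trials, via iteratively reweighted least
#' squares (`stats::glm` with a probit link). Complete separation is
#' detected (fitted probabilities numerically 0/1) and flagged rather
#' than treated as an error.
#'
#' @inheritParams negative_log_likelihood
#' @return A `probit_fit`: parameters per rule with implied criteria,
#'   total negative log-likelihood, parameter count, n, and BIC.
#' @export
fit_probit <- function(trials, dv_config) {
  trials <- add_decision_variable(trials, dv_config)
  rules <- intersect(c("rule_in", "rule_out"), unique(trials$rule))
  boundary <- FALSE
  fit_one <- function(df) {
    y <- as.integer(df$decision == "commit")
    if (length(unique(y)) < 2L) {
      boundary <<- TRUE
    }
    fit <- withCallingHandlers(
      glm(y ~ dv, data = cbind(df, y = y), family = binomial("probit")),
      warning = function(w) {
        msg <- conditionMessage(w)
        if (grepl("fitted probabilities numerically 0 or 1", msg) ||
            grepl("algorithm did not converge", msg)) {
          boundary <<- TRUE
          invokeRestart("muffleWarning")
        }
      }
    )
    b <- unname(coef(fit))
    p <- pmin(pmax(fit$fitted.values, .P_EPS), 1 - .P_EPS)
    nll <- -sum(ifelse(y == 1L, log(p), log(1 - p)))
    list(b = b[1L], c = b[2L], nll = nll, n = length(y))
  }
  per_rule <- lapply(rules, function(r) fit_one(trials[trials$rule == r, ]))
  names(per_rule) <- rules
  nll <- sum(vapply(per_rule, `[[`, numeric(1), "nll"))
  n_obs <- sum(vapply(per_rule, `[[`, numeric(1), "n"))
  n_params <- 2L * length(rules)
  params <- tibble::tibble(
    rule = rules,
    b = vapply(per_rule, `[[`, numeric(1), "b"),
    c = vapply(per_rule, `[[`, numeric(1), "c"),
    theta = ifelse(.data$c != 0, -.data$b / .data$c, NA_real_)
  )
  structure(
    list(
      params = params,
      neg_log_likelihood = nll,
      n_params = n_params,
      n_obs = n_obs,
      bic = n_params * log(n_obs) + 2 * nll,
      dv_config = dv_config,
      boundary = boundary
    ),
    class = "probit_fit"
  )
}

#' @export
print.probit_fit <- function(x, ...) {
  cat("<probit_fit> anchor =", x$dv_config$anchor,
      "| integration =", x$dv_config$integration, "\n")
  print(x$params)
  cat(sprintf("-LL = %.2f | n = %d | BIC = %.2f%s\n",
              x$neg_log_likelihood, x$n_obs, x$bic,
              if (x$boundary) " | boundary (separation)" else ""))
  invisible(x)
}

#' Compare the eight candidate decision variables across a cohort
#'
#' Fits the probit model under every anchor x integration combination for
#' every participant, tabulates per-participant negative log-likelihoods
#' (summed over the two rules), and contrasts the current-minus-average
#' and current-minus-next variables with a paired two-sided t test.
#' Participants whose fits fail are excluded with a warning.
#'
#' @param trials Cohort trial-log tibble with a `participant` column.
#' @return A `dv_comparison`: `per_participant` (long tibble of -LL and
#'   BIC), `summary` (mean and SD of -LL per DV, best first), and
#'   `contrast` (paired t test, current-minus-average vs
#'   current-minus-next).
#' @export
compare_dvs <- function(trials) {
  stopifnot("participant" %in% names(trials))
  if (dplyr::n_distinct(trials$participant) < 2L) {
    stop("`compare_dvs()` needs at least two participants", call. = FALSE)
  }
  grid <- dv_config_grid()
  per <- purrr::map_dfr(unique(trials$participant), function(pid) {
    df <- trials[trials$participant == pid, ]
    purrr::pmap_dfr(grid, function(anchor, integration, config) {
      fit <- tryCatch(fit_probit(df, config), error = function(e) NULL)
      if (is.null(fit)) {
        warning("fit failed for participant ", pid, " (", anchor, "/",
                integration, "); participant excluded from that cell",
                call. = FALSE)
        return(tibble::tibble(
          participant = pid, anchor = anchor, integration = integration,
          nll = NA_real_, bic = NA_real_, boundary = NA
        ))
      }
      tibble::tibble(
        participant = pid, anchor = anchor, integration = integration,
        nll = fit$neg_log_likelihood, bic = fit$bic,
        boundary = fit$boundary
      )
    })
  })
  summary <- per |>
    dplyr::group_by(.data$anchor, .data$integration) |>
    dplyr::summarise(
      mean_nll = mean(.data$nll, na.rm = TRUE),
      sd_nll = sd(.data$nll, na.rm = TRUE),
      n = sum(!is.na(.data$nll)),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$mean_nll)
  wide <- per |>
    dplyr::filter(.data$integration,
                  .data$anchor %in% c("average", "max_next")) |>
    tidyr::pivot_wider(
      id_cols = "participant", names_from = "anchor", values_from = "nll"
    )
  diffs <- wide$average - wide$max_next
  contrast <- if (sd(diffs, na.rm = TRUE) == 0 || all(is.na(diffs))) {
    warning("zero-variance differences in the cur-ave vs cur-next contrast",
            call. = FALSE)
    tibble::tibble(
      comparison = "cur_minus_average vs cur_minus_next",
      mean_diff = mean(diffs, na.rm = TRUE),
      statistic = if (all(diffs == 0, na.rm = TRUE)) 0 else NA_real_,
      p_value = NA_real_, df = NA_real_, degenerate = TRUE
    )
  } else {
    tt <- t.test(wide$average, wide$max_next, paired = TRUE)
    tibble::tibble(
      comparison = "cur_minus_average vs cur_minus_next",
      mean_diff = unname(tt$estimate),
      statistic = unname(tt$statistic),
      p_value = tt$p.value,
      df = unname(tt$parameter),
      degenerate = FALSE
    )
  }
  structure(
    list(per_participant = per, summary = summary, contrast = contrast),
    class = "dv_comparison"
  )
}

#' @export
print.dv_comparison <- function(x, ...) {
  cat("<dv_comparison> mean -LL per decision variable (best first):\n")
  print(x$summary)
  print(x$contrast)
  invisible(x)
}

# per-condition binomial NLL of a deterministic threshold prediction.
# dv/commit/cell vectors for one rule; returns NLL as a function of theta.
criterion_nll_curve <- function(dv, committed, cell, theta_grid, rule) {
  p_clamp <- function(p) pmin(pmax(p, 1e-3), 1 - 1e-3)
  cells <- split(seq_along(dv), cell)
  vapply(theta_grid, function(theta) {
    pred <- if (rule == "rule_in") dv >= theta else dv <= theta
    nll <- 0
    for (idx in cells) {
      n <- length(idx)
      y <- sum(committed[idx])
      p <- p_clamp(sum(pred[idx]) / n)
      nll <- nll - (y * log(p) + (n - y) * log(1 - p))
    }
    nll
  }, numeric(1))
}

# maximum-likelihood plateau: deterministic predictions change only when
# theta crosses an observed DV, so the argmin is typically an interval;
# report its midpoint (max-margin tie-break) and its extent
plateau_stats <- function(grid, nll) {
  best <- which(nll <= min(nll) + 1e-9)
  list(
    mid = grid[best[ceiling(length(best) / 2)]],
    range = c(grid[min(best)], grid[max(best)])
  )
}

#' Fit the deterministic criterion model on the 24 task conditions
#'
#' A threshold agent (commit iff DV >= theta_in under rule-in, commit iff
#' DV <= theta_out under rule-out) is replayed on the dataset's own
#' stimulus sequences; its predicted commitment probabilities in the 24
#' conditions (4 payoff ranks x 3 contexts x 2 rules) are scored against
#' the observed commitment counts with a binomial likelihood, and the
#' criteria are chosen by grid search. The two rules separate, so each
#' criterion is searched on its own grid. Ties (likelihood plateaus,
#' common for deterministic data) resolve to the plateau midpoint.
#' Predicted probabilities are clamped to `[1e-3, 1 - 1e-3]` so the
#' deterministic model keeps a finite likelihood under mismatches.
#'
#' Optional extensions add a leak rate (exponential moving-average
#' integration) and a free reference prior, each fit by adding a grid
#' dimension; they carry 3 and 4 free parameters against the base
#' model's 2.
#'
#' @param trials Trial-log tibble with `rule`, `context`, `rank`,
#'   `trial`, `bandit`, `spiral`, `decision` (single participant).
#' @param dv_config A [dv_config()]; its `leak`/`free_prior` fields are
#'   overridden by the search grids when those are supplied.
#' @param theta_grid Criterion grid (default -1.0 to 1.5 by 0.01).
#' @param leak_grid Optional grid of leak rates; turns on the leaky model.
#' @param v_prior_grid Optional grid of reference priors; with
#'   `leak_grid`, turns on the leaky free-prior model.
#' @return A `criterion_fit`: fitted `theta_in`, `theta_out` (plus `leak`
#'   and `v_prior` when searched), the 24-condition table of observed and
#'   predicted commitment probabilities, -LL, parameter count, n and BIC
#'   (BIC uses the total trial count as n).
#' @export
fit_criterion_model <- function(trials, dv_config = NULL,
                                theta_grid = seq(-1, 1.5, by = 0.01),
                                leak_grid = NULL, v_prior_grid = NULL) {
  stopifnot(all(c("rule", "context", "rank", "decision") %in% names(trials)))
  if (is.null(dv_config)) {
    dv_config <- banditpool::dv_config("average", integration = TRUE)
  }
  search <- tidyr::expand_grid(
    leak = if (is.null(leak_grid)) NA_real_ else leak_grid,
    v_prior = if (is.null(v_prior_grid)) dv_config$v_prior else v_prior_grid
  )
  n_params <- 2L + (!is.null(leak_grid)) + (!is.null(v_prior_grid))
  best <- NULL
  for (s in seq_len(nrow(search))) {
    cfg <- dv_config(
      anchor = dv_config$anchor, integration = dv_config$integration,
      v_prior = search$v_prior[s],
      leak = if (is.na(search$leak[s])) NULL else search$leak[s],
      free_prior = !is.null(v_prior_grid)
    )
    dat <- add_decision_variable(trials, cfg)
    dat$cell <- interaction(dat$context, dat$rank, drop = FALSE)
    fit_rule <- function(rule) {
      df <- dat[dat$rule == rule, ]
      if (nrow(df) == 0L) {
        return(list(theta = NA_real_, range = c(NA_real_, NA_real_),
                    nll = 0))
      }
      nll <- criterion_nll_curve(
        df$dv, df$decision == "commit", df$cell, theta_grid, rule
      )
      pl <- plateau_stats(theta_grid, nll)
      list(theta = pl$mid, range = pl$range, nll = min(nll))
    }
    f_in <- fit_rule("rule_in")
    f_out <- fit_rule("rule_out")
    total <- f_in$nll + f_out$nll
    if (is.null(best) || total < best$nll) {
      best <- list(
        theta_in = f_in$theta, theta_out = f_out$theta,
        theta_in_range = f_in$range, theta_out_range = f_out$range,
        leak = search$leak[s], v_prior = search$v_prior[s],
        nll = total, cfg = cfg, dat = dat
      )
    }
  }
  dat <- best$dat
  cond <- dat |>
    dplyr::mutate(
      predicted = ifelse(
        .data$rule == "rule_in",
        .data$dv >= best$theta_in,
        .data$dv <= best$theta_out
      )
    ) |>
    dplyr::group_by(.data$rule, .data$context, .data$rank) |>
    dplyr::summarise(
      n_offers = dplyr::n(),
      n_commits = sum(.data$decision == "commit"),
      p_observed = .data$n_commits / .data$n_offers,
      p_predicted = mean(.data$predicted),
      .groups = "drop"
    )
  if (nrow(cond) < 24L) {
    warning("only ", nrow(cond), " of 24 conditions observed; ",
            "empty conditions dropped", call. = FALSE)
  }
  n_obs <- nrow(dat)
  structure(
    list(
      theta_in = best$theta_in,
      theta_out = best$theta_out,
      theta_in_range = best$theta_in_range,
      theta_out_range = best$theta_out_range,
      leak = if (is.null(leak_grid)) NULL else best$leak,
      v_prior = best$v_prior,
      condition_table = cond,
      neg_log_likelihood = best$nll,
      n_params = n_params,
      n_obs = n_obs,
      bic = n_params * log(n_obs) + 2 * best$nll,
      dv_config = best$cfg,
      model = if (is.null(leak_grid)) {
        "base"
      } else if (is.null(v_prior_grid)) {
        "leaky"
      } else {
        "leaky_free_prior"
      }
    ),
    class = "criterion_fit"
  )
}

#' @export
print.criterion_fit <- function(x, ...) {
  cat(sprintf(
    "<criterion_fit> model = %s | theta_in = %.3f | theta_out = %.3f%s\n",
    x$model, x$theta_in, x$theta_out,
    if (!is.null(x$leak) && !is.na(x$leak)) {
      sprintf(" | leak = %.2f | v_prior = %.2f", x$leak, x$v_prior)
    } else {
      ""
    }
  ))
  cat(sprintf("-LL = %.2f | n = %d | BIC = %.2f\n",
              x$neg_log_likelihood, x$n_obs, x$bic))
  invisible(x)
}

#' Rank criterion-model variants by BIC
#'
#' @param ... `criterion_fit` (or `probit_fit`) objects fitted on the
#'   same dataset, optionally named.
#' @return Tibble ranked by BIC (best first) with `delta_bic` relative to
#'   the best model.
#' @export
#' @examples
#' \dontrun{
#' bic_compare(base = fit_base, leaky = fit_leaky)
#' }
bic_compare <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1L]]) &&
      !inherits(fits[[1L]], c("criterion_fit", "probit_fit"))) {
    fits <- fits[[1L]]
  }
  nm <- names(fits)
  if (is.null(nm)) {
    nm <- vapply(fits, function(f) f$model %||% "model", character(1))
  }
  n_obs <- vapply(fits, `[[`, numeric(1), "n_obs")
  if (length(unique(n_obs)) != 1L) {
    stop("fits being compared must share the same n_obs", call. = FALSE)
  }
  out <- tibble::tibble(
    model = nm,
    n_params = vapply(fits, `[[`, numeric(1), "n_params"),
    nll = vapply(fits, `[[`, numeric(1), "neg_log_likelihood"),
    n_obs = n_obs,
    bic = vapply(fits, `[[`, numeric(1), "bic")
  ) |>
    dplyr::arrange(.data$bic) |>
    dplyr::mutate(delta_bic = .data$bic - .data$bic[1L])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
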