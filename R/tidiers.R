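#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname tidy.probit_fit
#' @method glance probit_fit
#' @export
glance.probit_fit <- function(x, ...) {
  tibble::tibble(
    nll = x$neg_log_likelihood,
    n_params = x$n_params,
    n_obs = x$n_obs,
    bic = x$bic,
    anchor = x$dv_config$anchor,
    integration = x$dv_config$integration,
    boundary = x$boundary
  )
}

#' Tidy methods for fitted choice models
#'
#' `tidy()` returns one row per parameter; `glance()` returns a one-row
#' model-level summary (-LL, parameter count, n, BIC).
#'
#' @param x A `probit_fit` or `criterion_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy probit_fit
#' @export
tidy.probit_fit <- function(x, ...) {
  x$params |>
    tidyr::pivot_longer(c("b", "c", "theta"),
                        names_to = "term", values_to = "estimate") |>
    dplyr::mutate(term = paste(.data$term, sub("rule_", "", .data$rule),
                               sep = "_")) |>
    dplyr::select("term", "estimate")
}

#' @rdname tidy.probit_fit
#' @method tidy criterion_fit
#' @export
tidy.criterion_fit <- function(x, ...) {
  out <- tibble::tibble(
    term = c("theta_in", "theta_out"),
    estimate = c(x$theta_in, x$theta_out)
  )
  if (!is.null(x$leak) && !is.na(x$leak)) {
    out <- dplyr::bind_rows(out, tibble::tibble(term = "leak",
                                                estimate = x$leak))
  }
  if (x$model == "leaky_free_prior") {
    out <- dplyr::bind_rows(out, tibble::tibble(term = "v_prior",
                                                estimate = x$v_prior))
  }
  out
}

#' @rdname tidy.probit_fit
#' @method glance criterion_fit
#' @export
glance.criterion_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    nll = x$neg_log_likelihood,
    n_params = x$n_params,
    n_obs = x$n_obs,
    bic = x$bic
  )
}

#' @rdname tidy.probit_fit
#' @method tidy dv_comparison
#' @export
tidy.dv_comparison <- function(x, ...) {
  x$summary
}

#' @rdname tidy.probit_fit
#' @method tidy recovery_report
#' @export
tidy.recovery_report <- function(x, ...) {
  x$summary
}

#' @rdname tidy.probit_fit
#' @method tidy commitment_counts
#' @export
tidy.commitment_counts <- function(x, ...) {
  x$summary
}
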