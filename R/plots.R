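#' Interval plot of between-level posterior summaries
#'
#' @param object A [dsem_fit()] object.
#' @param parameters Regular expression selecting parameters (default: the
#'   intercepts and predictor slopes).
#' @param ... Unused.
#' @returns A ggplot object.
#' @method autoplot dsem_fit
#' @export
autoplot.dsem_fit <- function(object, parameters = "^gamma", ...) {
  td <- tidy(object)
  td <- td[grepl(parameters, td$parameter), ]
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$parameter)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high), height = 0.2
    ) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "posterior median and 95% credibility interval", y = NULL,
      title = "Between-level parameters"
    ) +
    ggplot2::theme_minimal()
}

#' Trace plot of between-level draws
#'
#' @param fit A [dsem_fit()] object.
#' @param parameters Character vector of parameter names (see
#'   `fixed_param_names`); default the eight intercepts.
#' @returns A ggplot object.
#' @export
plot_trace <- function(fit, parameters = paste0("gamma0[", dsem_effect_names(), "]")) {
  stopifnot(inherits(fit, "dsem_fit"))
  long <- purrr::map_dfr(seq_along(fit$chains), function(k) {
    m <- fit$chains[[k]]$fixed[, parameters, drop = FALSE]
    as_tibble(m) |>
      dplyr::mutate(draw = dplyr::row_number(), chain = factor(k)) |>
      tidyr::pivot_longer(-c("draw", "chain"),
        names_to = "parameter", values_to = "value"
      )
  })
  ggplot2::ggplot(long, ggplot2::aes(.data$draw, .data$value, colour = .data$chain)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "kept draw", y = NULL) +
    ggplot2::theme_minimal()
}

#' Stacked daily bar chart of wear time split into SB and PA
#'
#' @param desc Output of [descriptives()].
#' @returns A ggplot object.
#' @export
plot_descriptives <- function(desc) {
  long <- desc |>
    dplyr::select("day_index", "sb_mean", "pa_mean") |>
    tidyr::pivot_longer(-"day_index", names_to = "behavior", values_to = "minutes") |>
    dplyr::mutate(behavior = dplyr::recode(.data$behavior,
      sb_mean = "sedentary", pa_mean = "active"
    ))
  ggplot2::ggplot(long, ggplot2::aes(
    factor(.data$day_index), .data$minutes, fill = .data$behavior
  )) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_grey(start = 0.3, end = 0.7) +
    ggplot2::labs(x = "day", y = "mean minutes/day", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Dot plot of person-level standardized coefficients
#'
#' @param std Output of [standardize_within()].
#' @returns A ggplot object.
#' @export
plot_person_effects <- function(std) {
  stopifnot(inherits(std, "dsem_std_within"))
  long <- std$person |>
    tidyr::pivot_longer(
      c("phi_sb", "phi_pa", "beta_sb", "beta_pa"),
      names_to = "coefficient", values_to = "value"
    )
  ggplot2::ggplot(long, ggplot2::aes(.data$value, .data$person_id)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~coefficient, nrow = 1) +
    ggplot2::labs(
      x = "posterior-mean standardized coefficient", y = NULL,
      title = "Person-level dynamics (negative autoregression = antipersistence)"
    ) +
    ggplot2::theme_minimal()
}
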