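#' Learning curves of cue-period responding
#'
#' Mean head-entry rate per session and cue (with SEM ribbons across
#' animals), the behavioural readout of discrimination learning.
#'
#' @param trials a trial table with `animal_id`, `session`, `cue`,
#'   `cue_rate`.
#' @param max_session last session to display (default 9, the training
#'   phase).
#' @return a ggplot.
#' @export
plot_learning_curves <- function(trials, max_session = 9) {
  summ <- trials |>
    dplyr::filter(.data$session <= max_session) |>
    dplyr::group_by(.data$animal_id, .data$session, .data$cue) |>
    dplyr::summarise(rate = mean(.data$cue_rate), .groups = "drop") |>
    dplyr::group_by(.data$session, .data$cue) |>
    dplyr::summarise(mean_rate = mean(.data$rate),
                     sem = sd(.data$rate) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(.data$session, .data$mean_rate,
                                     colour = .data$cue)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean_rate - .data$sem,
                   ymax = .data$mean_rate + .data$sem, fill = .data$cue),
      alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = seq_len(max_session)) +
    ggplot2::labs(x = "Session", y = "Cue-period head entries (rate)",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_model Observed vs predicted cue-period rates per trial.
#' @param object an `rw_fit`.
#' @param ... unused.
#' @export
#' @method autoplot rw_fit
autoplot.rw_fit <- function(object, ...) {
  d <- dplyr::mutate(object$latents, idx = dplyr::row_number())
  ggplot2::ggplot(d, ggplot2::aes(.data$idx, .data$predicted_rate,
                                  colour = .data$cue)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Trial (across sessions)",
                  y = "Predicted cue-period rate",
                  title = sprintf("Model %s (BIC %.1f)", object$spec$label,
                                  object$bic)) +
    ggplot2::theme_minimal()
}

#' @describeIn compare_models BIC per model, summed over animals.
#' @param object an `rw_model_comparison`.
#' @param ... unused.
#' @export
#' @method autoplot rw_model_comparison
autoplot.rw_model_comparison <- function(object, ...) {
  d <- dplyr::left_join(object$summed_bic,
                        dplyr::rename(object$best_counts, n = "n_best"),
                        by = "model")
  d$model <- factor(d$model, levels = object$summed_bic$model)
  ggplot2::ggplot(d, ggplot2::aes(.data$model, .data$total_bic)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4,
                       size = 3) +
    ggplot2::labs(x = NULL, y = "Summed BIC",
                  subtitle = "Label: animals for which the model is best") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Mean event-locked oxygen response per cue
#'
#' @param epochs an `epoch_set` from [extract_epochs()].
#' @param trial_info optional tibble `(trial, cue)` to colour by cue.
#' @return a ggplot of the trial-averaged epoch.
#' @export
plot_epochs <- function(epochs, trial_info = NULL) {
  d <- epochs
  if (!is.null(trial_info)) {
    d <- dplyr::left_join(d, trial_info, by = "trial")
  } else {
    d$cue <- "all"
  }
  summ <- d |>
    dplyr::group_by(.data$cue, .data$rel_time_s) |>
    dplyr::summarise(mean_signal = mean(.data$signal), .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(.data$rel_time_s, .data$mean_signal,
                                     colour = .data$cue)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "Time from event (s)", y = "Signal (a.u.)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Group-level effect sizes per region and regressor
#'
#' @param effects a [group_effects()] tibble (or several row-bound).
#' @return a ggplot of mean standardized betas with SEM error bars.
#' @export
plot_group_effects <- function(effects) {
  ggplot2::ggplot(effects, ggplot2::aes(.data$term, .data$mean_beta)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_beta - .data$sem,
                   ymax = .data$mean_beta + .data$sem), width = 0.2) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::facet_wrap(~region) +
    ggplot2::labs(x = NULL, y = "Standardized effect size") +
    ggplot2::theme_minimal()
}
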