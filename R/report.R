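#' Measured-versus-predicted scatter plot
#'
#' @param data Tibble with columns `measured` and `predicted` (for instance
#'   the test-set observations and their model predictions).
#' @return A ggplot object with the identity line for reference.
#' @export
plot_measured_vs_predicted <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$measured,
                                     y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(shape = 1, size = 3) +
    ggplot2::labs(x = "Measured consumption (standard units / 1000 population)",
                  y = "Predicted consumption (standard units / 1000 population)") +
    ggplot2::theme_bw()
}

#' Loading bar plot for a fitted PLS model
#'
#' @param fit A [fit_pls1()] model.
#' @param components Component indices to show (default: all).
#' @return A ggplot object, one facet per component.
#' @export
plot_loadings <- function(fit, components = seq_len(fit$ncomp)) {
  df <- purrr::map_dfr(components, function(a) loading_values(fit, a))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$determinant,
                                   y = .data$loading)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~component, ncol = 1,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "Loading value") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @method autoplot pls1
#' @export
autoplot.pls1 <- function(object, type = c("loadings", "fitted"), ...) {
  type <- match.arg(type)
  if (type == "loadings") {
    plot_loadings(object)
  } else {
    plot_measured_vs_predicted(
      tibble::tibble(measured = object$y, predicted = object$fitted))
  }
}

format_ci <- function(point, low, high) {
  sprintf("%.0f (%.0f, %.0f)", point, low, high)
}

#' Render comparison, forecast and state reports to a directory
#'
#' Writes deterministic CSV and aligned-text versions of the
#' cross-validation comparison (rows: CV and adjusted CV RMSEP; columns:
#' candidates), the forecast table (one row per year, interval formatted
#' `point (low, high)`), and -- when any states are supplied -- the
#' state-disaggregation table. Optional plots: a measured-versus-predicted
#' scatter (when `test_points` is given) and a loadings bar chart (when
#' `fit` is given).
#'
#' @param cv_results Tibble from [crossvalidate_candidates()] or
#'   [search_determinant_model()] (needs `label`, `rmsep_cv`,
#'   `rmsep_adjcv` when available).
#' @param forecasts Tibble of [prediction_interval()] rows.
#' @param states Tibble of [disaggregate_state()] rows, or `NULL`.
#' @param out_dir Output directory (created if needed).
#' @param fit Optional [fit_pls1()] model for the loadings plot.
#' @param test_points Optional tibble with `measured` and `predicted`.
#' @param plots Write image files? (default `TRUE`).
#' @return Character vector of files written, invisibly.
#' @export
render_reports <- function(cv_results, forecasts, states = NULL, out_dir,
                           fit = NULL, test_points = NULL, plots = TRUE) {
  ok <- tryCatch({
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    file.access(out_dir, 2) == 0
  }, error = function(e) FALSE)
  if (!ok) {
    abort(paste0("Cannot write to ", out_dir), class = "abx_io_error")
  }
  written <- character(0)
  emit <- function(df, name) {
    csv <- file.path(out_dir, paste0(name, ".csv"))
    txt <- file.path(out_dir, paste0(name, ".txt"))
    readr::write_csv(df, csv, na = "")
    writeLines(utils::capture.output(print(as.data.frame(df),
                                           row.names = FALSE)), txt)
    c(csv, txt)
  }

  comparison <- tibble::tibble(statistic = c("Cross-validation",
                                             "Adjusted cross-validation"))
  for (i in seq_len(nrow(cv_results))) {
    adj <- if ("rmsep_adjcv" %in% names(cv_results)) {
      cv_results$rmsep_adjcv[i]
    } else {
      NA_real_
    }
    comparison[[cv_results$label[i]]] <- c(cv_results$rmsep_cv[i], adj)
  }
  written <- c(written, emit(comparison, "model_comparison"))

  fc <- forecasts |>
    dplyr::mutate(consumption_95ci = format_ci(.data$point, .data$ci_low,
                                               .data$ci_high)) |>
    dplyr::select("year", "point", "ci_low", "ci_high", "consumption_95ci")
  written <- c(written, emit(fc, "forecasts"))

  if (!is.null(states) && nrow(states) > 0) {
    written <- c(written, emit(states, "state_estimates"))
  }

  if (plots) {
    if (!is.null(test_points)) {
      f <- file.path(out_dir, "measured_vs_predicted.png")
      ggplot2::ggsave(f, plot_measured_vs_predicted(test_points),
                      width = 5, height = 5, dpi = 120)
      written <- c(written, f)
    }
    if (!is.null(fit)) {
      f <- file.path(out_dir, "loadings.png")
      ggplot2::ggsave(f, plot_loadings(fit), width = 7, height = 5, dpi = 120)
      written <- c(written, f)
    }
  }
  invisible(written)
}
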