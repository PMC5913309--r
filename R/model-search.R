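# Determinant-subset search: screen by VIP + loading, enumerate small
# candidate subsets, compare by leave-one-out RMSEP, prune the winner.

# Fast exact LOO squared errors for a full-component candidate.
# A k-component PLS fit on k (full-rank) determinants equals OLS on that
# subset, so the leave-one-out residuals follow the hat-matrix identity
# e_i / (1 - h_ii); this is algebraically identical to refitting per fold
# (verified against loocv_rmsep in the test suite) and keeps the search
# affordable over hundreds of candidates.
loo_sq_errors_ols <- function(x, y) {
  xs <- cbind(1, x)
  qr_x <- qr(xs)
  h <- rowSums(qr.Q(qr_x)^2)
  e <- qr.resid(qr_x, y)
  (e / (1 - h))^2
}

#' Search for the best small determinant subset
#'
#' The full search pipeline behind a determinant analysis on a short panel:
#'
#' 1. Fit a PLS model on all determinants (`n_screen_components`, autoscaled
#'    by default since panel scales span orders of magnitude) and screen by
#'    VIP and maximum absolute loading ([select_determinants()]).
#' 2. Enumerate candidate subsets: every singleton and pair from the screened
#'    set, plus triples from the `pool_size` top-VIP screened determinants
#'    (full enumeration of larger subsets is deliberately avoided).
#' 3. Compare candidates by leave-one-out RMSEP ([compare_models()] rule:
#'    smallest `rmsep_cv`, ties to fewer components).
#' 4. Prune the winner backwards: repeatedly drop the determinant whose
#'    removal increases the LOO error least, as long as a one-sided paired
#'    t-test on the per-year LOO squared errors cannot show (at level
#'    `prune_alpha`) that the drop makes prediction worse. This guards
#'    against spurious inflation of the winning subset, the dominant failure
#'    mode when tens of collinear determinants compete over ~11 years.
#'
#' Every candidate is fitted with as many components as determinants, the
#' convention under which the final model is an affine equation in the
#' selected determinants.
#'
#' @param panel Fully imputed panel tibble (first column `year`).
#' @param response Consumption tibble.
#' @param n_screen_components Components of the screening fit (default 2).
#' @param scale Autoscale in the screening fit (default `TRUE`).
#' @param vip_threshold,loading_threshold Screening cutoffs.
#' @param max_size Largest candidate subset (default 3).
#' @param pool_size Top-VIP pool from which subsets of size 3 are drawn.
#' @param prune_alpha Significance level of the backward-pruning test.
#' @return List of class `abx_model_search`: `screening` (tibble with VIP,
#'   max |loading| and selection flag for every determinant), `cv_results`
#'   (tibble, one row per candidate), `best` (pruned winning candidate),
#'   `fit` (final PLS refit of `best` on all years, raw scale), and
#'   `pruned_from` (the pre-pruning winner).
#' @examples
#' sim <- generate_panel(panel_config(n_determinants = 8, seed = 2))
#' search <- search_determinant_model(sim$panel, sim$response)
#' search$best$determinants
#' @export
search_determinant_model <- function(panel, response,
                                     n_screen_components = 2L,
                                     scale = TRUE,
                                     vip_threshold = 0.5,
                                     loading_threshold = 0.05,
                                     max_size = 3L,
                                     pool_size = 8L,
                                     prune_alpha = 0.05) {
  x <- as_determinant_matrix(panel, "panel")
  y <- as_response_vector(response)
  n <- nrow(x)

  screen_fit <- fit_pls1(x, y, ncomp = n_screen_components, scale = scale)
  vip <- vip_scores(screen_fit)
  loads <- all_loadings(screen_fit)
  selected <- select_determinants(vip, loads, vip_threshold, loading_threshold)
  screening <- vip |>
    dplyr::left_join(
      loads |>
        dplyr::group_by(.data$determinant) |>
        dplyr::summarise(max_abs_loading = max(abs(.data$loading)),
                         .groups = "drop"),
      by = "determinant") |>
    dplyr::mutate(selected = .data$determinant %in% selected$determinant) |>
    dplyr::arrange(dplyr::desc(.data$vip))
  sel <- selected$determinant
  if (length(sel) == 0L) {
    abort("No determinant passed the VIP/loading screen.",
          class = "abx_degenerate_error")
  }
  pool <- head(sel, pool_size)

  subsets <- c(
    lapply(sel, function(d) d),
    if (length(sel) >= 2) combn(sel, 2L, simplify = FALSE),
    if (max_size >= 3L && length(pool) >= 3L) combn(pool, 3L, simplify = FALSE)
  )
  subsets <- purrr::keep(subsets, function(s) length(s) <= n - 2L)

  loo_errors <- function(dets) loo_sq_errors_ols(x[, dets, drop = FALSE], y)
  sq_errs <- lapply(subsets, loo_errors)
  msep <- vapply(sq_errs, mean, numeric(1))
  cv_results <- tibble::tibble(
    label = vapply(subsets, paste, character(1), collapse = " + "),
    determinants = subsets,
    n_components = lengths(subsets),
    rmsep_cv = sqrt(msep)
  )
  best <- compare_models(cv_results)
  pruned_from <- best

  # backward pruning: drop while not significantly worse
  dets <- best$determinants
  best_err <- loo_errors(dets)
  while (length(dets) > 1L) {
    drops <- lapply(seq_along(dets), function(j) dets[-j])
    drop_errs <- lapply(drops, loo_errors)
    jb <- which.min(vapply(drop_errs, mean, numeric(1)))
    d <- drop_errs[[jb]] - best_err
    t_stat <- mean(d) / (sd(d) / sqrt(length(d)))
    p_val <- pt(t_stat, df = length(d) - 1L, lower.tail = FALSE)
    if (p_val > prune_alpha) {
      dets <- drops[[jb]]
      best_err <- drop_errs[[jb]]
    } else {
      break
    }
  }
  best <- candidate_model(paste(dets, collapse = " + "), dets)

  fit <- fit_pls1(x[, best$determinants, drop = FALSE], y,
                  ncomp = best$n_components, scale = scale)
  structure(list(screening = screening, cv_results = cv_results,
                 best = best, best_rmsep_cv = sqrt(mean(best_err)),
                 fit = fit, pruned_from = pruned_from),
            class = "abx_model_search")
}

#' @export
print.abx_model_search <- function(x, ...) {
  cat("Determinant model search over", nrow(x$cv_results), "candidates\n")
  cat("Winner: ", x$best$label,
      sprintf(" (LOO RMSEP %.1f)\n", x$best_rmsep_cv), sep = "")
  invisible(x)
}

#' @method tidy abx_model_search
#' @export
tidy.abx_model_search <- function(x, ...) {
  x$cv_results |> dplyr::arrange(.data$rmsep_cv)
}

#' @method glance abx_model_search
#' @export
glance.abx_model_search <- function(x, ...) {
  tibble::tibble(
    n_candidates = nrow(x$cv_results),
    n_screened = sum(x$screening$selected),
    best_label = x$best$label,
    best_size = length(x$best$determinants),
    best_rmsep_cv = x$best_rmsep_cv
  )
}
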