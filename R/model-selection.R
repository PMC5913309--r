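#' Split panel years into training and test sets
#'
#' Years are sampled without replacement; the training set holds
#' `round(train_fraction * n)` rows (half-up, so 75% of 11 years gives 8)
#' with at least one row in each set.
#'
#' @param panel Panel tibble (first column `year`).
#' @param response Tibble with `year` and `consumption`.
#' @param train_fraction Fraction in `(0, 1)` (default 0.75).
#' @param seed Integer seed; the split is irreproducible without one, so it
#'   is required.
#' @return List with elements `train` and `test`, each a list of `panel` and
#'   `response` tibbles (rows in year order).
#' @export
split_train_test <- function(panel, response, train_fraction = 0.75, seed) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must lie in (0, 1).", class = "abx_config_error")
  }
  n <- nrow(panel)
  if (n < 4L) {
    abort("Need at least 4 rows to split.", class = "abx_data_error")
  }
  if (!identical(panel$year, response$year)) {
    abort("`panel` and `response` years must match.",
          class = "abx_schema_error")
  }
  n_train <- min(max(round_half_up(train_fraction * n), 1L), n - 1L)
  idx <- with_seed(seed, sort(sample.int(n, n_train)))
  list(
    train = list(panel = panel[idx, ], response = response[idx, ]),
    test = list(panel = panel[-idx, ], response = response[-idx, ])
  )
}

#' Root mean square error of prediction
#'
#' @param y_obs,y_pred Equal-length numeric vectors.
#' @return `sqrt(mean((y_obs - y_pred)^2))`.
#' @export
rmsep <- function(y_obs, y_pred) {
  if (length(y_obs) != length(y_pred) || length(y_obs) < 1L) {
    abort("`y_obs` and `y_pred` must be non-empty and of equal length.",
          class = "abx_dimension_error")
  }
  sqrt(mean((y_obs - y_pred)^2))
}

#' Adjusted R-squared
#'
#' `1 - (1 - R^2) (n - 1) / (n - k - 1)` with `R^2 = 1 - SSE/SST`.
#'
#' @param y_obs,y_pred Observed and predicted values.
#' @param n_predictors Number of predictors `k`; requires `n > k + 1`.
#' @return Adjusted R-squared (at most 1, possibly negative).
#' @export
adjusted_r2 <- function(y_obs, y_pred, n_predictors) {
  n <- length(y_obs)
  if (n <= n_predictors + 1) {
    abort("Need n > n_predictors + 1.", class = "abx_dimension_error")
  }
  sst <- sum((y_obs - mean(y_obs))^2)
  if (sst == 0) {
    abort("Zero total sum of squares.", class = "abx_degenerate_error")
  }
  r2 <- 1 - sum((y_obs - y_pred)^2) / sst
  1 - (1 - r2) * (n - 1) / (n - n_predictors - 1)
}

#' Describe a candidate model
#'
#' A candidate is a named subset of determinants fitted with a given number
#' of PLS components; by convention a k-determinant candidate uses k
#' components, making it equivalent to ordinary least squares on that subset
#' and hence to an affine prediction equation.
#'
#' @param label Candidate label.
#' @param determinants Character vector of determinant names.
#' @param n_components Component count, at most `length(determinants)`.
#' @return An `abx_candidate` list.
#' @export
candidate_model <- function(label, determinants,
                            n_components = length(determinants)) {
  determinants <- as.character(determinants)
  if (n_components > length(determinants) || n_components < 1L) {
    abort("`n_components` must lie in [1, length(determinants)].",
          class = "abx_config_error")
  }
  structure(list(label = label, determinants = determinants,
                 n_components = as.integer(n_components)),
            class = "abx_candidate")
}

#' @export
print.abx_candidate <- function(x, ...) {
  cat(x$label, ": ", x$n_components, " component(s) on {",
      paste(x$determinants, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Leave-one-out cross-validated RMSEP with bias correction
#'
#' For each row i the candidate model is refitted on the remaining rows and
#' used to predict row i; `rmsep_cv` is the RMSEP of those held-out
#' predictions. `rmsep_adjcv` is the bias-corrected estimate
#' `sqrt(MSEP_cv + MSEP_train - mean_i MSEP(model_i on all rows))`, where the
#' correction term re-evaluates each fold model on the full data; it is
#' typically slightly below `rmsep_cv` on overfit-prone small samples.
#'
#' @param x Predictor matrix or data frame (columns cover the candidate's
#'   determinants; a `year` column is ignored).
#' @param y Response vector or consumption tibble.
#' @param candidate An [candidate_model()].
#' @param scale Autoscale predictors inside each fold fit?
#' @return Tibble with `rmsep_cv` and `rmsep_adjcv`.
#' @export
loocv_rmsep <- function(x, y, candidate, scale = FALSE) {
  x <- as_determinant_matrix(x, "x")
  y <- as_response_vector(y)
  missing <- setdiff(candidate$determinants, colnames(x))
  if (length(missing)) {
    abort(paste0("Candidate determinant(s) absent from `x`: ",
                 paste(missing, collapse = ", ")),
          class = "abx_schema_error")
  }
  xs <- x[, candidate$determinants, drop = FALSE]
  n <- length(y)
  if (n < candidate$n_components + 2L) {
    abort("Too few rows for the candidate's component count.",
          class = "abx_dimension_error")
  }
  pred_cv <- numeric(n)
  msep_fold_all <- numeric(n)
  for (i in seq_len(n)) {
    fit_i <- fit_pls1(xs[-i, , drop = FALSE], y[-i],
                      ncomp = candidate$n_components, scale = scale)
    pred_cv[i] <- predict(fit_i, xs[i, , drop = FALSE])
    msep_fold_all[i] <- mean((y - predict(fit_i, xs))^2)
  }
  fit_all <- fit_pls1(xs, y, ncomp = candidate$n_components, scale = scale)
  msep_cv <- mean((y - pred_cv)^2)
  msep_train <- mean(fit_all$residuals^2)
  msep_adj <- msep_cv + msep_train - mean(msep_fold_all)
  tibble::tibble(rmsep_cv = sqrt(msep_cv),
                 rmsep_adjcv = sqrt(max(msep_adj, 0)))
}

#' Screen determinants by VIP and loading value
#'
#' Keeps determinants whose VIP score passes `vip_threshold` and whose
#' largest absolute loading over the fitted components passes
#' `loading_threshold` -- the combined rule that excludes series with high
#' apparent importance but near-zero loadings.
#'
#' @param vip Tibble with columns `determinant` and `vip`
#'   (from [vip_scores()]).
#' @param loadings Tibble with columns `determinant` and `loading`
#'   (long over components, e.g. from [all_loadings()]).
#' @param vip_threshold,loading_threshold Cutoffs (defaults 0.5 and 0.05).
#' @return Tibble of selected determinants with `vip` and
#'   `max_abs_loading`, sorted by VIP descending.
#' @export
select_determinants <- function(vip, loadings,
                                vip_threshold = 0.5,
                                loading_threshold = 0.05) {
  if (!setequal(vip$determinant, loadings$determinant)) {
    abort("`vip` and `loadings` must cover identical determinant sets.",
          class = "abx_schema_error")
  }
  ml <- loadings |>
    dplyr::group_by(.data$determinant) |>
    dplyr::summarise(max_abs_loading = max(abs(.data$loading)),
                     .groups = "drop")
  vip |>
    dplyr::left_join(ml, by = "determinant") |>
    dplyr::filter(.data$vip >= vip_threshold,
                  .data$max_abs_loading >= loading_threshold) |>
    dplyr::arrange(dplyr::desc(.data$vip))
}

#' Cross-validate a list of candidate models
#'
#' Optionally splits the years into train/test sets, runs leave-one-out
#' cross-validation on the training years, and reports training and test
#' RMSEP plus adjusted R-squared for each candidate, one row per candidate.
#'
#' @param panel Fully imputed panel tibble.
#' @param response Consumption tibble.
#' @param candidates List of [candidate_model()] objects.
#' @param train_fraction,seed Split controls (see [split_train_test()]);
#'   ignored when `holdout = FALSE`.
#' @param scale Autoscale predictors in each fit?
#' @param holdout Reserve a test set? When `FALSE`, cross-validation runs on
#'   all years and `rmsep_test` is `NA`.
#' @return Tibble with columns `label`, `determinants` (list-column),
#'   `n_components`, `rmsep_cv`, `rmsep_adjcv`, `rmsep_train`, `rmsep_test`,
#'   `adjusted_r2`.
#' @export
crossvalidate_candidates <- function(panel, response, candidates,
                                     train_fraction = 0.75, seed = 1L,
                                     scale = FALSE, holdout = TRUE) {
  if (holdout) {
    sp <- split_train_test(panel, response, train_fraction, seed)
    train <- sp$train
    test <- sp$test
  } else {
    train <- list(panel = panel, response = response)
    test <- NULL
  }
  purrr::map_dfr(candidates, function(cand) {
    cv <- loocv_rmsep(train$panel, train$response, cand, scale = scale)
    fit <- fit_pls1(train$panel[cand$determinants],
                    train$response, ncomp = cand$n_components, scale = scale)
    y_tr <- train$response$consumption
    rmsep_tr <- rmsep(y_tr, fit$fitted)
    rmsep_te <- if (!is.null(test)) {
      rmsep(test$response$consumption,
            predict(fit, test$panel[cand$determinants]))
    } else {
      NA_real_
    }
    adj <- if (length(y_tr) > length(cand$determinants) + 1) {
      adjusted_r2(y_tr, fit$fitted, length(cand$determinants))
    } else {
      NA_real_
    }
    tibble::tibble(label = cand$label,
                   determinants = list(cand$determinants),
                   n_components = cand$n_components,
                   rmsep_cv = cv$rmsep_cv, rmsep_adjcv = cv$rmsep_adjcv,
                   rmsep_train = rmsep_tr, rmsep_test = rmsep_te,
                   adjusted_r2 = adj)
  })
}

#' Pick the best candidate by cross-validated RMSEP
#'
#' Returns the candidate with the smallest `rmsep_cv`; ties are broken by
#' fewer components, then lexicographic label. Permutation-invariant in the
#' input rows.
#'
#' @param results Cross-validation tibble
#'   (from [crossvalidate_candidates()], or any tibble with `label`,
#'   `determinants`, `n_components`, `rmsep_cv`).
#' @return The winning candidate as an [candidate_model()].
#' @examples
#' tbl <- tibble::tibble(
#'   label = c("1 component", "2 components", "3 components"),
#'   determinants = list("a", c("b", "c"), c("d", "e", "f")),
#'   n_components = 1:3,
#'   rmsep_cv = c(583.2, 376.0, 492.2)
#' )
#' compare_models(tbl)$label
#' @export
compare_models <- function(results) {
  if (is.null(results) || nrow(results) == 0L) {
    abort("`results` must contain at least one candidate.",
          class = "abx_input_error")
  }
  ord <- order(results$rmsep_cv, results$n_components, results$label)
  best <- results[ord[1L], ]
  candidate_model(best$label, best$determinants[[1]], best$n_components)
}
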