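#' Affine prediction equation
#'
#' A fitted consumption model in closed form: an intercept plus one
#' coefficient per determinant, all in standard units per 1000 population
#' (per determinant unit for the coefficients).
#'
#' @param intercept Intercept.
#' @param coefficients Named numeric vector; names must be unique.
#' @return An `abx_equation` object.
#' @export
affine_equation <- function(intercept, coefficients) {
  if (is.null(names(coefficients)) || any(names(coefficients) == "") ||
      anyDuplicated(names(coefficients))) {
    abort("`coefficients` must have unique non-empty names.",
          class = "abx_schema_error")
  }
  structure(list(intercept = as.numeric(intercept),
                 coefficients = coefficients),
            class = "abx_equation")
}

#' @export
print.abx_equation <- function(x, ...) {
  terms <- paste(sprintf("%g*%s", x$coefficients, names(x$coefficients)),
                 collapse = " + ")
  cat("Y =", sprintf("%g", x$intercept), "+", terms, "\n")
  invisible(x)
}

#' Convert a fitted PLS model to its affine equation
#'
#' @param fit A [fit_pls1()] model.
#' @return An [affine_equation()] with the raw-scale intercept and
#'   coefficients.
#' @export
as_equation <- function(fit) {
  stopifnot(inherits(fit, "pls1"))
  affine_equation(fit$intercept, fit$coefficients)
}

#' Reference consumption equation: health + surface transport infrastructure
#'
#' The published two-determinant national prediction equation,
#' `Y = -2639.6 + 0.000257 * health_infrastructure +
#' 0.00263 * surface_transport_infrastructure`, with Y in standard units per
#' 1000 population. Shipped as a fixture for prediction and disaggregation
#' examples; its coefficients come from a panel that is not redistributable,
#' so the package never attempts to re-derive them.
#'
#' @return An [affine_equation()].
#' @examples
#' histi_predict(histi_equation(),
#'               c(health_infrastructure = 0,
#'                 surface_transport_infrastructure = 0))
#' @export
histi_equation <- function() {
  affine_equation(-2639.6,
                  c(health_infrastructure = 0.000257,
                    surface_transport_infrastructure = 0.00263))
}

#' Evaluate an affine consumption equation
#'
#' @param eq An [affine_equation()].
#' @param values Named numeric vector, or a data frame with one column per
#'   determinant (a `year` column is carried through untouched); every
#'   equation determinant must be present.
#' @return Numeric vector of predictions, one per row of `values`.
#' @export
histi_predict <- function(eq, values) {
  stopifnot(inherits(eq, "abx_equation"))
  need <- names(eq$coefficients)
  if (is.data.frame(values)) {
    missing <- setdiff(need, names(values))
    if (length(missing)) {
      abort(paste0("Missing determinant value(s): ",
                   paste(missing, collapse = ", ")),
            class = "abx_schema_error")
    }
    m <- as.matrix(values[need])
    return(as.numeric(eq$intercept + m %*% eq$coefficients))
  }
  if (is.null(names(values)) || !all(need %in% names(values))) {
    abort(paste0("Missing determinant value(s): ",
                 paste(setdiff(need, names(values)), collapse = ", ")),
          class = "abx_schema_error")
  }
  as.numeric(eq$intercept + sum(eq$coefficients * values[need]))
}

#' Bootstrap percentile prediction interval
#'
#' Resamples training years with replacement, refits the candidate model on
#' each resample, predicts at `x_new`, and reports the percentile interval of
#' the bootstrap predictions around the full-data point prediction.
#' Resamples whose response is constant (so no model can be fitted) are
#' skipped and counted; at least half the replicates must be usable.
#'
#' @param x_train Training predictor matrix/data frame.
#' @param y_train Training response.
#' @param candidate An [candidate_model()].
#' @param x_new One new observation: named numeric vector or one-row data
#'   frame covering the candidate's determinants.
#' @param level Interval level in `(0, 1)` (default 0.95).
#' @param n_boot Bootstrap replicates (at least 200; default 2000).
#' @param seed Integer seed.
#' @param year Optional calendar year attached to the result.
#' @return One-row tibble: `year`, `point`, `ci_low`, `ci_high`, `ci_level`,
#'   `n_boot_used`.
#' @export
prediction_interval <- function(x_train, y_train, candidate, x_new,
                                level = 0.95, n_boot = 2000L, seed = 1L,
                                year = NA_integer_) {
  if (level <= 0 || level >= 1) {
    abort("`level` must lie in (0, 1).", class = "abx_config_error")
  }
  if (n_boot < 200L) {
    abort("`n_boot` must be at least 200.", class = "abx_config_error")
  }
  x <- as_determinant_matrix(x_train, "x_train")[, candidate$determinants,
                                                 drop = FALSE]
  y <- as_response_vector(y_train)
  n <- length(y)
  if (is.data.frame(x_new)) {
    x_new_v <- unlist(x_new[1, candidate$determinants])
  } else {
    x_new_v <- x_new[candidate$determinants]
  }
  if (anyNA(x_new_v)) {
    abort("`x_new` must carry every candidate determinant.",
          class = "abx_schema_error")
  }
  x_new_m <- matrix(x_new_v, nrow = 1,
                    dimnames = list(NULL, candidate$determinants))

  fit_full <- fit_pls1(x, y, ncomp = candidate$n_components)
  point <- predict(fit_full, x_new_m)

  preds <- with_seed(seed, {
    out <- rep(NA_real_, n_boot)
    for (b in seq_len(n_boot)) {
      rows <- sample.int(n, n, replace = TRUE)
      yb <- y[rows]
      if (var(yb) < .Machine$double.eps) next # degenerate resample, skipped
      fit_b <- fit_pls1(x[rows, , drop = FALSE], yb,
                        ncomp = candidate$n_components)
      out[b] <- predict(fit_b, x_new_m)
    }
    out
  })
  used <- sum(!is.na(preds))
  if (used < n_boot / 2) {
    abort("Fewer than half the bootstrap replicates were usable.",
          class = "abx_degenerate_error")
  }
  ci <- quantile(preds, c((1 - level) / 2, 1 - (1 - level) / 2),
                 na.rm = TRUE, names = FALSE)
  tibble::tibble(year = year, point = point,
                 ci_low = min(ci[1], point), ci_high = max(ci[2], point),
                 ci_level = level, n_boot_used = used)
}

#' Disaggregate a national prediction to one state
#'
#' Each determinant's state-level value is taken as the national value times
#' the state's average share of that determinant; the equation is then
#' applied to the scaled values (`method = "scale_determinants"`, the
#' default). Alternatively the national prediction itself is scaled by the
#' mean share (`method = "scale_prediction"`). Negative raw predictions are
#' floored at zero and flagged, since a consumption rate cannot be negative.
#' A missing share suppresses the estimate and flags the state.
#'
#' @param eq An [affine_equation()].
#' @param national_values Named numeric vector of national determinant
#'   values.
#' @param state_shares Named numeric vector of state-to-national proportions
#'   in `[0, 1]`; a missing or `NA` share for an equation determinant
#'   suppresses the estimate.
#' @param population State population in persons, or `NULL` to skip totals.
#' @param state State name for the output row.
#' @param method See above.
#' @return One-row tibble: `state`, `per_1000`, `total`, `data_flags`.
#' @export
disaggregate_state <- function(eq, national_values, state_shares,
                               population = NULL, state = "state",
                               method = c("scale_determinants",
                                          "scale_prediction")) {
  method <- match.arg(method)
  need <- names(eq$coefficients)
  shares <- state_shares[need]
  known <- !is.na(shares)
  if (any(shares[known] < 0 | shares[known] > 1)) {
    abort("State shares must lie in [0, 1].", class = "abx_input_error")
  }
  flags <- character(0)
  if (!all(known)) {
    flags <- paste0("missing share: ",
                    paste(need[!known], collapse = ", "),
                    "; estimate suppressed")
    return(tibble::tibble(state = state, per_1000 = NA_real_,
                          total = NA_real_,
                          data_flags = paste(flags, collapse = "; ")))
  }
  raw <- if (method == "scale_determinants") {
    histi_predict(eq, stats::setNames(national_values[need] * shares, need))
  } else {
    histi_predict(eq, national_values) * mean(shares)
  }
  per_1000 <- max(0, raw)
  if (raw < 0) flags <- c(flags, "negative prediction floored at 0")
  total <- if (is.null(population)) {
    NA_real_
  } else if (per_1000 > 0) {
    total_consumption(per_1000, population)
  } else {
    0
  }
  tibble::tibble(state = state, per_1000 = per_1000, total = total,
                 data_flags = if (length(flags)) paste(flags, collapse = "; ")
                              else NA_character_)
}

#' Total consumption from a per-1000 rate
#'
#' @param per_1000 Consumption in standard units per 1000 population
#'   (positive).
#' @param population Population in persons (positive).
#' @return Total standard units, `per_1000 * population / 1000`.
#' @examples
#' total_consumption(1000, 1e6) # 1,000,000 standard units
#' @export
total_consumption <- function(per_1000, population) {
  if (!is.numeric(per_1000) || !is.numeric(population) ||
      any(per_1000 <= 0) || any(population <= 0)) {
    abort("`per_1000` and `population` must be positive.",
          class = "abx_input_error")
  }
  per_1000 * population / 1000
}
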