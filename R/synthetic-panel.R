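#' Configure a synthetic determinant panel
#'
#' Describes the study conditions the generator emulates: a short run of
#' calendar years, many more determinants than years, strong collinearity
#' through a shared latent factor plus common upward trends, per-determinant
#' scales spanning several orders of magnitude, and a response that is linear
#' in a small subset of determinants plus Gaussian noise. Defaults mirror a
#' national consumption panel: 11 years, 37 determinants of which 2 carry
#' signal, response around 7000-11000 standard units per 1000 population.
#'
#' @param n_years Number of consecutive years in the panel.
#' @param start_year First calendar year.
#' @param n_determinants Number of determinant columns.
#' @param n_informative Number of determinants with nonzero true coefficient.
#' @param true_intercept Intercept of the true response model, in standard
#'   units per 1000 population.
#' @param signal_sd Approximate standard deviation of the true linear
#'   predictor across years (response units); used to size default
#'   coefficients so that `noise_sd / signal_sd` is the noise-to-signal ratio.
#' @param true_coefficients Optional length-`n_determinants` vector with
#'   exactly `n_informative` nonzero entries (response units per determinant
#'   unit). When `NULL`, informative determinants are drawn by seed and
#'   coefficients are sized from `signal_sd`.
#' @param collinearity_rho Correlation in `[0, 1)` among determinant noise,
#'   induced by a single shared latent factor.
#' @param trend_rel Common upward trend, expressed per year as a fraction of
#'   each determinant's own scale. Ignored when `trend_slopes` is given.
#' @param trend_slopes Optional length-`n_determinants` vector of trends in
#'   determinant units per year.
#' @param noise_sd Standard deviation of the response noise (response units).
#' @param missing_rate Fraction in `[0, 1)` of eligible panel cells to mark
#'   missing (see [inject_missingness()]).
#' @param seed Integer seed; identical seeds give bit-identical panels.
#' @param scale_log10_range Range of `log10` determinant scales; defaults to
#'   scales between 1 and 1e6, emulating series as different as percentages
#'   and total population.
#'
#' @return A `panel_config` list, validated.
#' @seealso [generate_panel()]
#' @export
panel_config <- function(n_years = 11L,
                         start_year = 2000L,
                         n_determinants = 37L,
                         n_informative = 2L,
                         true_intercept = 7000,
                         signal_sd = 1000,
                         true_coefficients = NULL,
                         collinearity_rho = 0.3,
                         trend_rel = 0.3,
                         trend_slopes = NULL,
                         noise_sd = 200,
                         missing_rate = 0,
                         seed = 1L,
                         scale_log10_range = c(0, 6)) {
  cfg <- list(
    n_years = as.integer(n_years), start_year = as.integer(start_year),
    n_determinants = as.integer(n_determinants),
    n_informative = as.integer(n_informative),
    true_intercept = true_intercept, signal_sd = signal_sd,
    true_coefficients = true_coefficients,
    collinearity_rho = collinearity_rho, trend_rel = trend_rel,
    trend_slopes = trend_slopes, noise_sd = noise_sd,
    missing_rate = missing_rate, seed = as.integer(seed),
    scale_log10_range = scale_log10_range
  )
  validate_panel_config(cfg)
  structure(cfg, class = "panel_config")
}

validate_panel_config <- function(cfg) {
  stop_cfg <- function(msg) abort(msg, class = "abx_config_error")
  if (cfg$n_years < 3L) stop_cfg("`n_years` must be at least 3.")
  if (cfg$n_determinants < 1L) stop_cfg("`n_determinants` must be positive.")
  if (cfg$n_informative < 0L || cfg$n_informative > cfg$n_determinants) {
    stop_cfg("`n_informative` must lie in [0, n_determinants].")
  }
  if (!is.null(cfg$true_coefficients)) {
    if (length(cfg$true_coefficients) != cfg$n_determinants) {
      stop_cfg("`true_coefficients` must have length `n_determinants`.")
    }
    if (sum(cfg$true_coefficients != 0) != cfg$n_informative) {
      stop_cfg("`true_coefficients` must have exactly `n_informative` nonzero entries.")
    }
  }
  if (!is.null(cfg$trend_slopes) && length(cfg$trend_slopes) != cfg$n_determinants) {
    stop_cfg("`trend_slopes` must have length `n_determinants`.")
  }
  if (cfg$collinearity_rho < 0 || cfg$collinearity_rho >= 1) {
    stop_cfg("`collinearity_rho` must lie in [0, 1).")
  }
  if (cfg$noise_sd < 0) stop_cfg("`noise_sd` must be >= 0.")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop_cfg("`missing_rate` must lie in [0, 1).")
  }
  invisible(cfg)
}

#' Generate a synthetic determinant panel with known ground truth
#'
#' Draws a year-by-determinant panel and a response series under the
#' structure described in [panel_config()]: each determinant is
#' `mu_j + trend_j * (year - start_year) + scale_j * z_tj` where the
#' standardized core `z_tj = sqrt(rho) f_t + sqrt(1 - rho) e_tj` shares a
#' latent factor across determinants; the response is
#' `intercept + sum_j beta_j x_tj + eps_t` with Gaussian noise.
#'
#' @param config A [panel_config()].
#' @return A list of class `abx_synthetic_panel` with elements
#'   * `panel`: tibble, first column `year`, one column per determinant
#'     (`det_01`, ...), possibly with missing cells when
#'     `config$missing_rate > 0`;
#'   * `response`: tibble with columns `year`, `consumption`;
#'   * `truth`: list recording the informative determinants, the full
#'     coefficient vector, intercept, noise draws, scales and trend slopes.
#' @examples
#' sim <- generate_panel(panel_config(seed = 7))
#' sim$truth$informative
#' @export
generate_panel <- function(config) {
  if (!inherits(config, "panel_config")) config <- do.call(panel_config, config)
  validate_panel_config(config)
  n <- config$n_years
  p <- config$n_determinants
  years <- seq(config$start_year, length.out = n)

  out <- with_seed(config$seed, {
    scales <- 10^runif(p, config$scale_log10_range[1], config$scale_log10_range[2])
    trend <- config$trend_slopes %||% (config$trend_rel * scales)
    beta <- config$true_coefficients
    informative <- if (is.null(beta)) {
      sort(sample.int(p, config$n_informative))
    } else {
      which(beta != 0)
    }
    if (is.null(beta)) {
      # size each informative coefficient so the informative columns jointly
      # contribute ~signal_sd of response variation (theoretical column sd)
      yr0 <- years - config$start_year
      pop_var <- mean(yr0^2) - mean(yr0)^2
      col_sd <- scales * sqrt((config$trend_rel)^2 * pop_var + 1)
      beta <- numeric(p)
      if (config$n_informative > 0) {
        beta[informative] <-
          (config$signal_sd / sqrt(config$n_informative)) / col_sd[informative]
      }
    }
    f <- rnorm(n)
    e <- matrix(rnorm(n * p), n, p)
    z <- sqrt(config$collinearity_rho) * matrix(f, n, p) +
      sqrt(1 - config$collinearity_rho) * e
    x <- matrix(10 * scales, n, p, byrow = TRUE) +
      outer(years - config$start_year, trend) +
      sweep(z, 2, scales, "*")
    colnames(x) <- sprintf("det_%02d", seq_len(p))
    eps <- rnorm(n, 0, config$noise_sd)
    y <- config$true_intercept + as.numeric(x %*% beta) + eps
    list(x = x, y = y, eps = eps, beta = beta, scales = scales,
         trend = trend, informative = informative)
  })

  panel <- dplyr::bind_cols(tibble::tibble(year = years),
                            tibble::as_tibble(out$x))
  if (config$missing_rate > 0) {
    panel <- inject_missingness(panel, config$missing_rate, config$seed + 1L)
  }
  truth <- list(
    informative = colnames(out$x)[out$informative],
    coefficients = stats::setNames(out$beta, colnames(out$x)),
    intercept = config$true_intercept,
    noise = out$eps,
    scales = stats::setNames(out$scales, colnames(out$x)),
    trend_slopes = stats::setNames(out$trend, colnames(out$x)),
    seed = config$seed
  )
  structure(
    list(panel = panel,
         response = tibble::tibble(year = years, consumption = out$y),
         truth = truth),
    class = "abx_synthetic_panel"
  )
}

#' @export
print.abx_synthetic_panel <- function(x, ...) {
  cat("Synthetic determinant panel:",
      nrow(x$panel), "years x", ncol(x$panel) - 1L, "determinants\n")
  cat("Informative:", paste(x$truth$informative, collapse = ", "), "\n")
  invisible(x)
}

#' Mark panel cells missing completely at random
#'
#' Each eligible cell (every determinant cell except those of the first two
#' years, which the backward-looking trend imputation needs as anchors) is
#' independently set to `NA` with probability `rate`.
#'
#' @param panel A determinant panel tibble (first column `year`).
#' @param rate Fraction in `[0, 1)`.
#' @param seed Integer seed; the same seed marks the same cells.
#' @return The panel with missing cells.
#' @export
inject_missingness <- function(panel, rate, seed) {
  if (!is.numeric(rate) || length(rate) != 1L || rate < 0 || rate >= 1) {
    abort("`rate` must lie in [0, 1).", class = "abx_config_error")
  }
  if (rate == 0) return(panel)
  det_cols <- setdiff(names(panel), "year")
  n <- nrow(panel)
  if (n <= 2L) return(panel)
  with_seed(seed, {
    for (col in det_cols) {
      hit <- runif(n - 2L) < rate
      panel[[col]][c(rep(FALSE, 2L), hit)] <- NA_real_
    }
  })
  panel
}

#' Published India antibiotic consumption series, 2000-2010
#'
#' The national human antibiotic consumption series used as the response in
#' the determinant analysis, in standard units per 1000 population (a
#' standard unit is one dose sold: a pill, capsule, or ampoule).
#'
#' @return Tibble with columns `year` (2000-2010) and `consumption`.
#' @examples
#' india_consumption()
#' @export
india_consumption <- function() {
  tibble::tibble(
    year = 2000:2010,
    consumption = c(7413, 7031, 7392, 7564, 7371, 7721,
                    8926, 9160, 9460, 10152, 10608)
  )
}

#' Write a determinant panel to CSV
#'
#' First column `year`, one column per determinant; missing cells are written
#' as empty fields. The format round-trips through [read_panel()].
#'
#' @param panel Panel tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  readr::write_csv(panel, path, na = "")
  invisible(path)
}

#' Write a ground-truth record to a plain-text key-value sidecar
#'
#' @param truth The `truth` element of [generate_panel()] output.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  fmt <- function(v) {
    if (is.numeric(v)) paste(sprintf("%.17g", v), collapse = ",")
    else paste(v, collapse = ",")
  }
  lines <- vapply(names(truth), function(k) paste0(k, "=", fmt(truth[[k]])),
                  character(1))
  writeLines(lines, path)
  invisible(path)
}
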