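#' Read a determinant panel from CSV
#'
#' Expects a header row of determinant names with `year` as the first column.
#' Empty cells are flagged missing; any non-empty cell that does not parse as
#' a number is a format error, as are duplicated or non-consecutive years.
#'
#' @param path CSV file path.
#' @return Panel tibble with `year` first and numeric determinant columns,
#'   missing cells as `NA`.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Panel file not found: ", path), class = "abx_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (names(raw)[1] != "year") {
    abort("First column of a panel CSV must be `year`.",
          class = "abx_format_error")
  }
  if (anyDuplicated(names(raw))) {
    abort("Determinant names must be unique.", class = "abx_format_error")
  }
  parse_num <- function(v, col) {
    v[!is.na(v) & trimws(v) == ""] <- NA_character_
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(out))
    if (length(bad)) {
      abort(paste0("Non-numeric value ", v[bad[1]], " in column `", col,
                   "` (row ", bad[1], ")."),
            class = "abx_format_error")
    }
    out
  }
  panel <- purrr::imap(raw, parse_num)
  panel <- tibble::as_tibble(panel)
  years <- panel$year
  if (anyNA(years)) {
    abort("Every row must carry a year.", class = "abx_format_error")
  }
  if (anyDuplicated(years)) {
    abort(paste0("Duplicated year: ", years[duplicated(years)][1], "."),
          class = "abx_format_error")
  }
  if (is.unsorted(years, strictly = TRUE) || any(diff(years) != 1)) {
    abort("Years must be consecutive and strictly increasing.",
          class = "abx_format_error")
  }
  panel$year <- as.integer(years)
  panel
}

#' Impute missing values by backward linear-trend extrapolation
#'
#' Each missing value is filled with the ordinary-least-squares linear trend
#' fitted to all values observed strictly before it (by year), evaluated at
#' the missing year -- the behaviour of a spreadsheet `FORECAST` over prior
#' years. Filling is sequential, so an imputed value feeds the trend fit of
#' any later gap. Applying the rule to a complete series returns it
#' unchanged.
#'
#' @param x Numeric vector, possibly with `NA` gaps.
#' @param years Optional x-axis (defaults to `seq_along(x)`).
#' @return `x` with gaps filled.
#' @examples
#' impute_linear_trend(c(2, 4, 6, 8, NA)) # 10
#' impute_linear_trend(c(1, 2, 2, 4, NA)) # 4.5
#' @export
impute_linear_trend <- function(x, years = seq_along(x)) {
  if (length(years) != length(x)) {
    abort("`years` must match `x` in length.", class = "abx_schema_error")
  }
  for (i in which(is.na(x))) {
    prior <- which(!is.na(x[seq_len(i - 1L)]))
    if (length(prior) < 2L) {
      abort(paste0("Cannot impute position ", i,
                   ": fewer than 2 prior observations."),
            class = "abx_imputation_error")
    }
    fit <- stats::lm.fit(cbind(1, years[prior]), x[prior])
    x[i] <- sum(coef(fit) * c(1, years[i]))
  }
  x
}

#' Impute every determinant column of a panel
#'
#' Applies [impute_linear_trend()] to each determinant column, using the
#' panel's years as the trend axis. Errors name the offending determinant and
#' year when a gap cannot be anchored.
#'
#' @param panel Panel tibble (first column `year`).
#' @return The fully imputed panel (no missing cells).
#' @export
impute_panel <- function(panel) {
  det_cols <- setdiff(names(panel), "year")
  for (col in det_cols) {
    v <- panel[[col]]
    if (!anyNA(v)) next
    filled <- tryCatch(
      impute_linear_trend(v, panel$year),
      abx_imputation_error = function(e) {
        bad <- which(is.na(v))[1]
        abort(paste0("Cannot impute determinant `", col, "` at year ",
                     panel$year[bad], ": fewer than 2 prior observations."),
              class = "abx_imputation_error")
      }
    )
    panel[[col]] <- filled
  }
  panel
}

#' Specify a derived determinant
#'
#' A derived determinant is the row-wise sum of same-unit primary
#' determinants within a category (for instance, total road length plus total
#' railway route length forming a surface-transport-infrastructure series).
#'
#' @param name Name of the new column.
#' @param components Character vector of component column names (non-empty).
#' @param category Category label.
#' @return One-row tibble with a list-column `components`.
#' @export
derived_spec <- function(name, components, category = "derived") {
  if (length(components) == 0) {
    abort("`components` must be non-empty.", class = "abx_spec_error")
  }
  tibble::tibble(name = name, category = category,
                 components = list(as.character(components)))
}

#' Default derived-determinant specifications
#'
#' The four standard aggregates: health infrastructure (hospitals + beds +
#' professionals + providers), surface transport infrastructure (road length
#' + railway route length), bacterial disease cases (leprosy + pertussis +
#' diphtheria + tetanus + neonatal tetanus + cholera + tuberculosis) and
#' infectious disease cases (bacterial cases + malaria + Japanese
#' encephalitis + measles). Note the last one builds on the previous derived
#' column, so order matters and [build_derived()] adds columns sequentially.
#'
#' @return Tibble of specs as produced by [derived_spec()].
#' @export
default_derived_specs <- function() {
  dplyr::bind_rows(
    derived_spec("health_infrastructure",
                 c("tot_hosp", "tot_beds", "profes", "providers"),
                 "health_system"),
    derived_spec("surface_transport_infrastructure",
                 c("road_len", "rail_route_len"), "transport"),
    derived_spec("bacterial_disease_cases",
                 c("leprosy", "pertussis", "diphtheria", "tetanus",
                   "neonatal_tetanus", "cholera", "tuberculosis"), "disease"),
    derived_spec("infectious_disease_cases",
                 c("bacterial_disease_cases", "malaria",
                   "japanese_encephalitis", "measles"), "disease")
  )
}

#' Add derived determinants to a panel
#'
#' Appends one column per spec, equal to the row-wise sum of its components.
#' Existing columns are never altered. Specs are processed in order, so a
#' spec may reference a derived column created by an earlier spec.
#'
#' @param panel Fully imputed panel tibble.
#' @param specs Tibble of [derived_spec()] rows.
#' @return Panel with the derived columns appended.
#' @export
build_derived <- function(panel, specs = default_derived_specs()) {
  if (anyNA(panel)) {
    abort("Panel must be fully imputed before deriving determinants.",
          class = "abx_spec_error")
  }
  for (i in seq_len(nrow(specs))) {
    comps <- specs$components[[i]]
    if (length(comps) == 0) {
      abort("Derived spec with empty components.", class = "abx_spec_error")
    }
    missing <- setdiff(comps, names(panel))
    if (length(missing)) {
      abort(paste0("Component column(s) absent for `", specs$name[i], "`: ",
                   paste(missing, collapse = ", ")),
            class = "abx_spec_error")
    }
    panel[[specs$name[i]]] <- rowSums(panel[comps])
  }
  panel
}

#' Percent change of a consumption series between two years
#'
#' @param series Tibble with columns `year` and `consumption`.
#' @param year_from,year_to Years to compare (both must be present).
#' @return `100 * (v_to - v_from) / v_from`.
#' @examples
#' percent_change(india_consumption(), 2000, 2010) # about 43.1
#' @export
percent_change <- function(series, year_from, year_to) {
  lookup <- function(yr) {
    i <- match(yr, series$year)
    if (is.na(i)) {
      abort(paste0("Year ", yr, " not present in the series."),
            class = "abx_lookup_error")
    }
    series$consumption[i]
  }
  v_from <- lookup(year_from)
  v_to <- lookup(year_to)
  100 * (v_to - v_from) / v_from
}
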