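# internal helpers shared across modules

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so seeded generation never perturbs a session.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single non-missing integer.", class = "abx_config_error")
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Coerce a determinant block (data frame or matrix, no year column) to a
# numeric matrix with column names, failing loudly on non-numeric columns.
as_determinant_matrix <- function(x, arg = "x") {
  if (is.data.frame(x)) {
    if ("year" %in% names(x)) x <- x[setdiff(names(x), "year")]
    bad <- names(x)[!vapply(x, is.numeric, logical(1))]
    if (length(bad)) {
      abort(paste0("Non-numeric determinant column(s) in `", arg, "`: ",
                   paste(bad, collapse = ", ")),
            class = "abx_schema_error")
    }
    x <- as.matrix(x)
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(paste0("`", arg, "` must be a numeric matrix or data frame."),
          class = "abx_schema_error")
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  x
}

# Extract the response vector from a consumption tibble or plain vector.
as_response_vector <- function(y) {
  if (is.data.frame(y)) {
    if (!"consumption" %in% names(y)) {
      abort("Response data frame must have a `consumption` column.",
            class = "abx_schema_error")
    }
    y <- y$consumption
  }
  if (!is.numeric(y)) {
    abort("Response must be numeric.", class = "abx_schema_error")
  }
  as.numeric(y)
}

# round-half-up, used for the train-set size so 0.75 * 11 -> 8
round_half_up <- function(x) floor(x + 0.5)
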