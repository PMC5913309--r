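#' Center (and optionally autoscale) predictors and response
#'
#' Columns of `x` are mean-centered and, when `scale = TRUE`, divided by
#' their sample standard deviation; `y` is mean-centered. Constant columns
#' get a scale factor of 1 with a warning rather than an error, since a
#' panel may legitimately carry a flat series.
#'
#' @param x Numeric matrix or data frame of predictors (at least 2 rows,
#'   no missing cells).
#' @param y Numeric response vector.
#' @param scale Autoscale the predictor columns?
#' @return List with elements `x`, `y` (transformed) and `record`
#'   (`center_x`, `scale_x`, `center_y`).
#' @export
center_scale <- function(x, y, scale = FALSE) {
  x <- as_determinant_matrix(x, "x")
  y <- as_response_vector(y)
  if (nrow(x) < 2L) {
    abort("`x` must have at least 2 rows.", class = "abx_dimension_error")
  }
  if (anyNA(x) || anyNA(y)) {
    abort("Missing cells must be imputed before fitting.",
          class = "abx_schema_error")
  }
  center_x <- colMeans(x)
  xc <- sweep(x, 2, center_x)
  scale_x <- rep(1, ncol(x))
  if (scale) {
    s <- apply(x, 2, sd)
    flat <- s == 0
    if (any(flat)) {
      warn(paste0("Constant column(s) left unscaled: ",
                  paste(colnames(x)[flat], collapse = ", ")))
      s[flat] <- 1
    }
    scale_x <- s
    xc <- sweep(xc, 2, scale_x, "/")
  }
  center_y <- mean(y)
  list(x = xc, y = y - center_y,
       record = list(center_x = center_x, scale_x = scale_x,
                     center_y = center_y))
}

#' Fit univariate-response partial least squares regression (NIPALS)
#'
#' Extracts `ncomp` latent components sequentially. For a univariate
#' response the NIPALS weight vector is closed-form per component:
#' `w_a` is proportional to `X_a' y_a` (unit length), the x-scores are
#' `t_a = X_a w_a`, the x-loadings `p_a = X_a' t_a / (t_a' t_a)`, the
#' y-loading `q_a = y_a' t_a / (t_a' t_a)`, and both blocks are deflated
#' (`X - t p'`, `y - t q`) before the next component. The sign of each
#' `w_a` is fixed so its largest-magnitude entry is positive, which removes
#' the sign indeterminacy and makes fits bit-reproducible. Coefficients are
#' always back-transformed to the original units, so the fitted model is the
#' affine equation `y = intercept + X b` regardless of scaling.
#'
#' With `ncomp` equal to the number of (full-rank) predictors the fit
#' coincides with ordinary least squares, which is why a k-component model on
#' k selected determinants is an affine formula in those determinants.
#'
#' @param x Predictor matrix or data frame, n rows by p determinants.
#' @param y Response: numeric vector or a tibble with a `consumption` column.
#' @param ncomp Number of components, at most `min(n - 1, p)`.
#' @param scale Autoscale predictors before fitting (default `FALSE`;
#'   centering is always applied).
#' @return An object of class `pls1`: weights `weights` (p x A), x-scores
#'   `x_scores` (n x A), y-scores `y_scores`, x-loadings `x_loadings`,
#'   y-loadings `y_loadings` (length A), raw-scale `coefficients` and
#'   `intercept`, the centering/scaling record, `fitted` values and
#'   `residuals`.
#' @examples
#' sim <- generate_panel(panel_config(n_determinants = 5, seed = 3))
#' fit <- fit_pls1(sim$panel, sim$response, ncomp = 2)
#' glance(fit)
#' @export
fit_pls1 <- function(x, y, ncomp = 2L, scale = FALSE) {
  x <- as_determinant_matrix(x, "x")
  y <- as_response_vector(y)
  n <- nrow(x)
  p <- ncol(x)
  if (length(y) != n) {
    abort("`x` and `y` must have the same number of rows.",
          class = "abx_dimension_error")
  }
  ncomp <- as.integer(ncomp)
  if (ncomp < 1L || ncomp > min(n - 1L, p)) {
    abort(paste0("`ncomp` must lie in [1, min(n - 1, p)] = [1, ",
                 min(n - 1L, p), "]."),
          class = "abx_dimension_error")
  }
  cs <- center_scale(x, y, scale = scale)
  if (sd(cs$y) == 0) {
    abort("Response has zero variance after centering; fit is degenerate.",
          class = "abx_degenerate_error")
  }

  W <- P <- matrix(0, p, ncomp)
  TT <- U <- matrix(0, n, ncomp)
  q <- numeric(ncomp)
  xa <- cs$x
  ya <- cs$y
  a_used <- 0L
  for (a in seq_len(ncomp)) {
    w <- crossprod(xa, ya)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      warn(paste0("Weight vector vanished at component ", a,
                  "; model truncated to ", a - 1L, " component(s)."))
      break
    }
    w <- w / nw
    imax <- which.max(abs(w))
    if (w[imax] < 0) w <- -w
    t_a <- as.numeric(xa %*% w)
    tt <- sum(t_a^2)
    p_a <- as.numeric(crossprod(xa, t_a)) / tt
    q_a <- sum(ya * t_a) / tt
    W[, a] <- w
    TT[, a] <- t_a
    P[, a] <- p_a
    q[a] <- q_a
    U[, a] <- ya * q_a # univariate convention: u_a = y_a q_a
    xa <- xa - tcrossprod(t_a, p_a)
    ya <- ya - t_a * q_a
    a_used <- a
  }
  if (a_used == 0L) {
    abort("No usable component: X'y is numerically zero.",
          class = "abx_degenerate_error")
  }
  keep <- seq_len(a_used)
  W <- W[, keep, drop = FALSE]
  P <- P[, keep, drop = FALSE]
  TT <- TT[, keep, drop = FALSE]
  U <- U[, keep, drop = FALSE]
  q <- q[keep]

  b_scaled <- as.numeric(W %*% solve(crossprod(P, W), q))
  coef_raw <- b_scaled / cs$record$scale_x
  intercept <- cs$record$center_y - sum(coef_raw * cs$record$center_x)
  fitted <- intercept + as.numeric(x %*% coef_raw)

  dn <- colnames(x)
  names(coef_raw) <- dn
  rownames(W) <- rownames(P) <- dn
  structure(list(
    ncomp = a_used,
    weights = W, x_scores = TT, y_scores = U,
    x_loadings = P, y_loadings = q,
    coefficients = coef_raw, intercept = intercept,
    center_x = cs$record$center_x, scale_x = cs$record$scale_x,
    center_y = cs$record$center_y, scaled = scale,
    determinants = dn,
    fitted = fitted, residuals = y - fitted, y = y, n = n
  ), class = "pls1")
}

#' @export
print.pls1 <- function(x, ...) {
  cat("PLS1 regression (NIPALS): ", x$ncomp, " component(s), ",
      length(x$determinants), " determinant(s), n = ", x$n,
      if (x$scaled) ", autoscaled" else ", centered only", "\n", sep = "")
  cat("Intercept:", format(x$intercept), "\n")
  print(x$coefficients)
  invisible(x)
}

#' Predict from a fitted PLS1 model
#'
#' Predictions use the back-transformed affine form
#' `intercept + X_new %*% coefficients`, which agrees with the
#' score/loading pathway to machine precision.
#'
#' @param object A [fit_pls1()] model.
#' @param newdata Matrix or data frame carrying every model determinant
#'   (matched by name when names are available; a bare unnamed matrix must
#'   have the model's column count and order). A `year` column is ignored.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.pls1 <- function(object, newdata, ...) {
  unnamed <- is.matrix(newdata) && is.null(colnames(newdata))
  x <- as_determinant_matrix(newdata, "newdata")
  if (unnamed) {
    if (ncol(x) != length(object$determinants)) {
      abort("`newdata` has the wrong number of columns.",
            class = "abx_schema_error")
    }
    colnames(x) <- object$determinants
  } else if (!identical(colnames(x), object$determinants)) {
    if (all(object$determinants %in% colnames(x))) {
      x <- x[, object$determinants, drop = FALSE]
    } else {
      abort("`newdata` columns do not match the model determinants.",
            class = "abx_schema_error")
    }
  }
  as.numeric(object$intercept + x %*% object$coefficients)
}

#' Variable importance in projection (VIP) scores
#'
#' For determinant j over A components,
#' `VIP_j = sqrt(p * sum_a SS_a (w_ja / ||w_a||)^2 / sum_a SS_a)` with
#' `SS_a = q_a^2 t_a' t_a`, the response variance explained by component a.
#' The scores satisfy `sum_j VIP_j^2 = p`.
#'
#' @param fit A [fit_pls1()] model.
#' @return Tibble with columns `determinant` and `vip`, in model column
#'   order.
#' @export
vip_scores <- function(fit) {
  stopifnot(inherits(fit, "pls1"))
  ss <- fit$y_loadings^2 * colSums(fit$x_scores^2)
  wn <- sweep(fit$weights, 2, sqrt(colSums(fit$weights^2)), "/")
  p <- nrow(fit$weights)
  vip <- sqrt(p * as.numeric(wn^2 %*% ss) / sum(ss))
  tibble::tibble(determinant = fit$determinants, vip = vip)
}

#' Loading values of one component
#'
#' The x-loadings measure how strongly each determinant correlates with a
#' component's score vector; determinants whose loadings sit near zero on
#' every component contribute little to the fitted relationship even when
#' their VIP is large, which is why screening combines both.
#'
#' @param fit A [fit_pls1()] model.
#' @param component Component index in `[1, ncomp]`.
#' @return Tibble with columns `determinant`, `component` and `loading`.
#' @export
loading_values <- function(fit, component) {
  stopifnot(inherits(fit, "pls1"))
  component <- as.integer(component)
  if (component < 1L || component > fit$ncomp) {
    abort(paste0("`component` must lie in [1, ", fit$ncomp, "]."),
          class = "abx_index_error")
  }
  loading <- unname(fit$x_loadings[, component])
  tibble::tibble(determinant = fit$determinants,
                 component = component,
                 loading = loading)
}

#' All loadings of a fit, long format
#'
#' @param fit A [fit_pls1()] model.
#' @return Tibble with one row per determinant per component.
#' @export
all_loadings <- function(fit) {
  purrr::map_dfr(seq_len(fit$ncomp), function(a) loading_values(fit, a))
}

#' @method tidy pls1
#' @export
tidy.pls1 <- function(x, ...) {
  vip <- vip_scores(x)
  tibble::tibble(
    term = c("(Intercept)", x$determinants),
    estimate = c(x$intercept, unname(x$coefficients)),
    vip = c(NA_real_, vip$vip)
  )
}

#' @method glance pls1
#' @export
glance.pls1 <- function(x, ...) {
  sse <- sum(x$residuals^2)
  sst <- sum((x$y - mean(x$y))^2)
  r2 <- 1 - sse / sst
  tibble::tibble(
    ncomp = x$ncomp,
    n = x$n,
    n_determinants = length(x$determinants),
    rmsep_train = sqrt(mean(x$residuals^2)),
    r_squared = r2
  )
}

#' @method augment pls1
#' @export
augment.pls1 <- function(x, ...) {
  tibble::tibble(
    .observed = x$y,
    .fitted = x$fitted,
    .resid = x$residuals
  )
}

#' Serialize a PLS1 model to a plain-text file
#'
#' Key-value header plus one matrix block per array, written at full float
#' precision (`%.17g`) so [read_pls1()] round-trips exactly.
#'
#' @param fit A [fit_pls1()] model.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pls1 <- function(fit, path) {
  stopifnot(inherits(fit, "pls1"))
  num <- function(v) paste(sprintf("%.17g", v), collapse = ",")
  lines <- c(
    "format=pls1/1",
    paste0("ncomp=", fit$ncomp),
    paste0("n=", fit$n),
    paste0("scaled=", as.integer(fit$scaled)),
    paste0("determinants=", paste(fit$determinants, collapse = ",")),
    paste0("intercept=", sprintf("%.17g", fit$intercept)),
    paste0("coefficients=", num(fit$coefficients)),
    paste0("center_x=", num(fit$center_x)),
    paste0("scale_x=", num(fit$scale_x)),
    paste0("center_y=", sprintf("%.17g", fit$center_y)),
    paste0("y_loadings=", num(fit$y_loadings)),
    paste0("y=", num(fit$y))
  )
  mat_block <- function(name, m) {
    c(paste0("matrix=", name, ",", nrow(m), ",", ncol(m)),
      apply(m, 1, num))
  }
  lines <- c(lines,
             mat_block("weights", fit$weights),
             mat_block("x_scores", fit$x_scores),
             mat_block("y_scores", fit$y_scores),
             mat_block("x_loadings", fit$x_loadings))
  writeLines(lines, path)
  invisible(path)
}

#' Read a PLS1 model written by [write_pls1()]
#'
#' @param path File path.
#' @return A `pls1` object identical to the one written.
#' @export
read_pls1 <- function(path) {
  lines <- readLines(path)
  if (!identical(lines[1], "format=pls1/1")) {
    abort("Not a pls1 serialization file.", class = "abx_format_error")
  }
  kv <- list()
  mats <- list()
  i <- 2L
  while (i <= length(lines)) {
    ln <- lines[i]
    key <- sub("=.*$", "", ln)
    val <- sub("^[^=]*=", "", ln)
    if (key == "matrix") {
      spec <- strsplit(val, ",")[[1]]
      nr <- as.integer(spec[2])
      nc <- as.integer(spec[3])
      rows <- lines[(i + 1L):(i + nr)]
      m <- do.call(rbind, lapply(rows, function(r) as.numeric(strsplit(r, ",")[[1]])))
      m <- matrix(m, nr, nc)
      mats[[spec[1]]] <- m
      i <- i + nr + 1L
    } else {
      kv[[key]] <- val
      i <- i + 1L
    }
  }
  nums <- function(k) as.numeric(strsplit(kv[[k]], ",")[[1]])
  dets <- strsplit(kv$determinants, ",")[[1]]
  coefs <- stats::setNames(nums("coefficients"), dets)
  for (nm in c("weights", "x_loadings")) rownames(mats[[nm]]) <- dets
  y <- nums("y")
  intercept <- as.numeric(kv$intercept)
  fitted <- NULL
  fit <- structure(list(
    ncomp = as.integer(kv$ncomp),
    weights = mats$weights, x_scores = mats$x_scores,
    y_scores = mats$y_scores, x_loadings = mats$x_loadings,
    y_loadings = nums("y_loadings"),
    coefficients = coefs, intercept = intercept,
    center_x = stats::setNames(nums("center_x"), dets),
    scale_x = nums("scale_x"),
    center_y = as.numeric(kv$center_y),
    scaled = kv$scaled == "1",
    determinants = dets,
    fitted = NULL, residuals = NULL, y = y, n = as.integer(kv$n)
  ), class = "pls1")
  # fitted values are recoverable from scores/loadings:
  fit$fitted <- fit$center_y +
    as.numeric(fit$x_scores %*% fit$y_loadings)
  fit$residuals <- y - fit$fitted
  fit
}
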