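test_that("center_scale centers, scales and tolerates constant columns", {
  x <- matrix(c(1, 2, 3, 5, 5, 5), ncol = 2,
              dimnames = list(NULL, c("a", "flat")))
  y <- c(10, 20, 30)

  cs <- center_scale(x, y, scale = FALSE)
  expect_equal(colMeans(cs$x), c(a = 0, flat = 0))
  expect_equal(cs$record$scale_x, c(1, 1))
  expect_equal(cs$y, y - 20)

  # already-centered input is unchanged
  xc <- x - rep(colMeans(x), each = 3)
  cs2 <- center_scale(xc, y - mean(y), scale = FALSE)
  expect_equal(cs2$x, xc, ignore_attr = TRUE)
  expect_equal(unname(cs2$record$center_x), c(0, 0))

  # unit-variance scaling: column (1,2,3) has sd 1 already
  expect_warning(cs3 <- center_scale(x, y, scale = TRUE), "flat")
  expect_equal(unname(cs3$x[, "a"]), c(-1, 0, 1))
  expect_equal(unname(cs3$record$scale_x[2]), 1)
})

test_that("a single predictor equal to y is fitted perfectly", {
  y <- c(3, 1, 4, 1, 5, 9)
  x <- matrix(y, ncol = 1, dimnames = list(NULL, "same"))
  fit <- fit_pls1(x, y, ncomp = 1)
  expect_equal(unname(fit$coefficients), 1, tolerance = 1e-10)
  expect_lt(max(abs(fit$residuals)), 1e-10)
})

test_that("degenerate and infeasible fits error cleanly", {
  x <- matrix(rnorm(12), 6, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(fit_pls1(x, rep(5, 6), ncomp = 1),
               class = "abx_degenerate_error")
  expect_error(fit_pls1(x, rnorm(6), ncomp = 3),
               class = "abx_dimension_error")
  expect_error(fit_pls1(x, rnorm(5), ncomp = 1),
               class = "abx_dimension_error")
})

test_that("NIPALS matches the SIMPLS oracle and collapses to OLS", {
  for (s in 1:25) {
    inst <- random_instance(s)
    A <- min(inst$n - 1, inst$p)
    fit <- fit_pls1(inst$x, inst$y, ncomp = max(1, A - 1))
    orc <- simpls_oracle(inst$x, inst$y, max(1, A - 1))
    expect_lt(max(abs(fit$coefficients - orc$coefficients)), 1e-8)
    expect_lt(abs(fit$intercept - orc$intercept), 1e-8)
  }

  # full-component fit equals lm
  inst <- random_instance(7, n = 12, p = 4)
  fit <- fit_pls1(inst$x, inst$y, ncomp = 4)
  ols <- unname(coef(lm(inst$y ~ inst$x)))
  expect_equal(unname(c(fit$intercept, fit$coefficients)), ols,
               tolerance = 1e-8)
})

test_that("NIPALS agrees with an independent library implementation", {
  skip_if_not_installed("mixOmics")
  inst <- random_instance(42, n = 10, p = 4)
  fit <- fit_pls1(inst$x, inst$y, ncomp = 2)
  m <- mixOmics::pls(inst$x, inst$y, ncomp = 2, scale = FALSE,
                     mode = "regression")
  pred <- predict(m, inst$x)$predict[, 1, 2]
  expect_equal(unname(fit$fitted), unname(pred), tolerance = 1e-10)
})

test_that("score orthogonality, deflation decrease and dual prediction paths hold", {
  for (s in 1:20) {
    inst <- random_instance(s + 100)
    A <- min(inst$n - 1, inst$p)
    fit <- fit_pls1(inst$x, inst$y, ncomp = A)

    # pairwise orthogonality of x-scores
    G <- crossprod(fit$x_scores)
    nrm <- sqrt(diag(G))
    off <- abs(G) / outer(nrm, nrm)
    diag(off) <- 0
    expect_lt(max(off), 1e-8)

    # prediction via coefficients equals centered score/loading pathway
    yhat_scores <- fit$center_y +
      as.numeric(fit$x_scores %*% fit$y_loadings)
    expect_equal(fit$fitted, yhat_scores, tolerance = 1e-10)

    # deflated X shrinks in Frobenius norm across components
    cs <- center_scale(inst$x, inst$y)
    xa <- cs$x
    norms <- numeric(A)
    for (a in seq_len(A)) {
      xa <- xa - tcrossprod(fit$x_scores[, a], fit$x_loadings[, a])
      norms[a] <- sqrt(sum(xa^2))
    }
    expect_true(all(diff(c(sqrt(sum(cs$x^2)), norms)) < 0))
  }
})

test_that("predict handles self-consistency, centering and affinity", {
  inst <- random_instance(3, n = 9, p = 3)
  fit <- fit_pls1(inst$x, inst$y, ncomp = 3)
  expect_equal(predict(fit, inst$x), fit$fitted)

  # at the training column means a full-component model predicts mean(y)
  xbar <- matrix(colMeans(inst$x), 1, dimnames = list(NULL, colnames(inst$x)))
  expect_equal(predict(fit, xbar), mean(inst$y), tolerance = 1e-10)

  # affine map: f(2x) + f(0) = 2 f(x)
  x1 <- inst$x[4, , drop = FALSE]
  x0 <- x1 * 0
  expect_equal(predict(fit, 2 * x1) + predict(fit, x0),
               2 * predict(fit, x1), tolerance = 1e-10)

  expect_error(predict(fit, inst$x[, 1:2]), class = "abx_schema_error")
})

test_that("VIP scores obey the closed forms and the normalization", {
  # p = 1 forces VIP = 1
  y <- rnorm(8)
  x1 <- matrix(y + rnorm(8, 0, .1), ncol = 1, dimnames = list(NULL, "only"))
  expect_equal(vip_scores(fit_pls1(x1, y, 1))$vip, 1, tolerance = 1e-10)

  # A = 1: VIP_j = sqrt(p) |w_j| / ||w||
  inst <- random_instance(9, n = 10, p = 5)
  fit1 <- fit_pls1(inst$x, inst$y, ncomp = 1)
  w <- fit1$weights[, 1]
  expect_equal(vip_scores(fit1)$vip,
               unname(sqrt(5) * abs(w) / sqrt(sum(w^2))), tolerance = 1e-10)

  # multi-component: matches brute-force formula and sums to p
  for (s in 1:10) {
    inst <- random_instance(s + 50, n = 8, p = 3)
    fit <- fit_pls1(inst$x, inst$y, ncomp = 2)
    v <- vip_scores(fit)$vip
    expect_equal(v, vip_bruteforce(fit), tolerance = 1e-10)
    expect_equal(sum(v^2), 3, tolerance = 1e-6)
    expect_true(all(v >= 0))
  }
})

test_that("loading accessors return labeled stored columns", {
  inst <- random_instance(12, n = 9, p = 4)
  fit <- fit_pls1(inst$x, inst$y, ncomp = 2)
  lv <- loading_values(fit, 2)
  expect_identical(nrow(lv), 4L)
  expect_identical(lv$determinant, colnames(inst$x))
  expect_equal(lv$loading, unname(fit$x_loadings[, 2]))
  expect_error(loading_values(fit, 3), class = "abx_index_error")

  # single perfect predictor has a nonzero loading
  y <- c(1, 4, 2, 8, 5)
  xp <- matrix(y, ncol = 1, dimnames = list(NULL, "v"))
  fitp <- fit_pls1(xp, y, 1)
  expect_gt(abs(loading_values(fitp, 1)$loading), 0)
})

test_that("the weight sign convention makes refits bit-identical", {
  inst <- random_instance(31, n = 10, p = 6)
  f1 <- fit_pls1(inst$x, inst$y, ncomp = 3)
  f2 <- fit_pls1(inst$x, inst$y, ncomp = 3)
  expect_identical(f1$weights, f2$weights)
  expect_true(all(apply(f1$weights, 2, function(w) w[which.max(abs(w))] > 0)))
})

test_that("models serialize to text and round-trip exactly", {
  inst <- random_instance(17, n = 11, p = 5)
  fit <- fit_pls1(inst$x, inst$y, ncomp = 3, scale = TRUE)
  f <- withr::local_tempfile(fileext = ".pls")
  write_pls1(fit, f)
  back <- read_pls1(f)
  expect_identical(back$coefficients, fit$coefficients)
  expect_identical(back$intercept, fit$intercept)
  expect_identical(back$weights, fit$weights)
  expect_identical(back$x_loadings, fit$x_loadings)
  expect_identical(back$y_loadings, fit$y_loadings)
  expect_equal(back$fitted, fit$fitted, tolerance = 1e-10)
  expect_equal(predict(back, inst$x), predict(fit, inst$x))
})

test_that("tidy, glance and augment expose the fit as tibbles", {
  inst <- random_instance(23, n = 10, p = 3)
  fit <- fit_pls1(inst$x, inst$y, ncomp = 2)
  td <- tidy(fit)
  expect_identical(td$term, c("(Intercept)", colnames(inst$x)))
  expect_equal(td$estimate, unname(c(fit$intercept, fit$coefficients)))
  gl <- glance(fit)
  expect_identical(gl$ncomp, 2L)
  expect_equal(gl$rmsep_train, sqrt(mean(fit$residuals^2)))
  au <- augment(fit)
  expect_equal(au$.fitted + au$.resid, au$.observed)
})
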