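# OSC, PLS, splitting, prediction: closed-form oracles and invariants.

test_that("OSC on X = [y, z] with z orthogonal to y removes exactly z", {
  y <- c(-1, 0, 1, 2, -2)
  y <- y - mean(y)
  z <- c(1, -1, 1, 0, -1)
  z <- z - mean(z)
  z <- z - y * sum(y * z) / sum(y^2)   # force orthogonality
  x <- cbind(y, z)
  o <- osc_fit(x, y, 1)
  expect_equal(o$x_corrected[, 2], rep(0, 5), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(o$x_corrected[, 1], y, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("OSC removes nothing when all columns are proportional to y", {
  y <- c(1, 1, 2, 2, 1, 2)
  yc <- y - mean(y)
  x <- outer(yc, c(1, -2, 0.5))
  o <- osc_fit(x, y, 1)
  expect_lt(sum(o$removed), 1e-16)
  expect_equal(o$x_corrected, x, tolerance = 1e-8)
})

test_that("OSC scores are orthogonal to y and apply() reproduces the fit", {
  co <- toy_cohort(n_per_class = 10, noise_sd = 0.002)
  pt <- pretreat(co$spectra)
  y <- label_code(co$spectra$label)
  o <- osc_fit(pt$x, y, 2)
  for (k in 1:2) {
    tt <- o$t[, k]
    expect_lt(abs(sum(tt * (y - mean(y)))) / sqrt(sum(tt^2) * sum((y - mean(y))^2)),
              1e-8)
  }
  expect_equal(osc_apply(o, pt$x), o$x_corrected, tolerance = 1e-10)
  expect_equal(osc_apply(o, matrix(0, 2, ncol(pt$x))),
               matrix(0, 2, ncol(pt$x)), ignore_attr = TRUE)
  expect_error(osc_apply(o, matrix(0, 2, 3)), "grid mismatch")
})

test_that("OSC does not worsen cross-validated error on nuisance-laden data", {
  # X = class signal + strong shared nuisance direction + noise
  set.seed(11)
  n <- 24; p <- 30
  y <- rep(c(1, 2), each = n / 2)
  sig <- outer(y - mean(y), rnorm(p))
  nuis <- outer(rnorm(n, sd = 4), rnorm(p))
  x <- sig + nuis + matrix(rnorm(n * p, sd = 0.5), n, p)
  press <- function(n_osc) {
    sum(vapply(seq_len(n), function(i) {
      mc <- mean_center(x[-i, , drop = FALSE])
      xt <- mc$x
      osc <- NULL
      if (n_osc > 0) {
        osc <- osc_fit(xt, y[-i], n_osc)
        xt <- osc$x_corrected
      }
      fit <- pls_fit(xt, y[-i] - mean(y[-i]), 1)
      xn <- x[i, , drop = FALSE] - rep(mc$means, each = 1)
      if (!is.null(osc)) xn <- osc_apply(osc, xn)
      (mean(y[-i]) + drop(xn %*% fit$b) - y[i])^2
    }, numeric(1)))
  }
  expect_lte(press(1), press(0) * 1.001)
})

test_that("first PLS weight is the normalized covariance direction", {
  x <- matrix(c(1, 0, -1, 2, 1, -3), 3, 2)
  x <- sweep(x, 2, colMeans(x))
  y <- c(-1, 0, 1)
  fit <- pls_fit(x, y, 1)
  w_direct <- drop(crossprod(x, y))
  w_direct <- w_direct / sqrt(sum(w_direct^2))
  expect_equal(fit$w[, 1], w_direct, tolerance = 1e-12)
  expect_equal(fit$b, fit$w[, 1] * fit$q[1] / sum(fit$p[, 1] * fit$w[, 1]),
               tolerance = 1e-12)
})

test_that("full-rank PLS reproduces ordinary least squares", {
  set.seed(4)
  x <- matrix(rnorm(24), 8, 3)
  x <- sweep(x, 2, colMeans(x))
  y <- rnorm(8)
  y <- y - mean(y)
  fit <- pls_fit(x, y, 3)
  ols <- lm.fit(x, y)
  expect_equal(drop(x %*% fit$b), unname(ols$fitted.values), tolerance = 1e-8)
})

test_that("degenerate PLS inputs error", {
  x <- matrix(rnorm(20), 5, 4)
  expect_error(pls_fit(x, rep(0, 5), 1), "constant")
  expect_error(pls_fit(matrix(0, 5, 4), rnorm(5), 1), "zero variance")
})

test_that("training predictions reproduce the NIPALS fitted values", {
  co <- toy_cohort(n_per_class = 6, noise_sd = 0.002)
  m <- plsda(co$spectra, model_config(n_osc = 1, n_lv = 1))
  y <- label_code(co$spectra$label)
  pls <- m$pls
  nipals_fitted <- m$ybar + drop(pls$scores %*% pls$q)
  expect_equal(m$fitted, nipals_fitted, tolerance = 1e-10)
  # with n_osc = 0 and 1 LV the regression vector is proportional to X'y
  m0 <- plsda(co$spectra, model_config(n_osc = 0, n_lv = 1))
  xty <- drop(crossprod(m0$pretreatment$x, y - mean(y)))
  expect_equal(m0$pls$b / sqrt(sum(m0$pls$b^2)), xty / sqrt(sum(xty^2)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("prediction midpoint rule assigns ties to LC", {
  co <- toy_cohort(n_per_class = 3, noise_sd = 0.002)
  m <- plsda(co$spectra)
  m$pls$b <- m$pls$b * 0   # forces y_score == ybar == 1.5 exactly
  pred <- predict(m, co$spectra)
  expect_true(all(pred$y_score == 1.5))
  expect_true(all(pred$class_pred == "LC"))
})

test_that("a training exemplar from a separated cohort is classified correctly", {
  co <- toy_cohort(n_per_class = 6, noise_sd = 0.002)
  m <- plsda(co$spectra)
  pred <- predict(m, co$spectra[co$spectra$label == "FM", ][1, ])
  expect_equal(pred$class_pred, "FM")
})

test_that("stratified split has the printed fold sizes and is seed-deterministic", {
  co <- toy_cohort(n_per_class = 50, noise_sd = 0.002)
  sp <- split_cohort(co$spectra, 0.8, seed = 42)
  expect_equal(unname(table(sp$train$label)[c("FM", "LC")]), c(40L, 40L),
               ignore_attr = TRUE)
  expect_equal(unname(table(sp$validation$label)[c("FM", "LC")]), c(10L, 10L),
               ignore_attr = TRUE)
  expect_length(intersect(sp$train$sample_id, sp$validation$sample_id), 0)
  sp2 <- split_cohort(co$spectra, 0.8, seed = 42)
  expect_identical(sp, sp2)
  sp3 <- split_cohort(co$spectra[1:8, ], 0.5, seed = 1)
  expect_equal(nrow(sp3$train), 4L)
})

test_that("regression vector extrema align with the discriminating band centers", {
  co <- toy_cohort(n_per_class = 15, noise_sd = 0.002)
  m <- plsda(co$spectra)
  b <- tidy(m)
  top <- b$wavenumber[order(abs(b$coefficient), decreasing = TRUE)][1:2]
  # the FM 1565/1588 doublet vs the LC 1581 band dominate the contrast
  expect_true(all(vapply(top, function(w) {
    min(abs(w - c(1565, 1581, 1588))) <= 10
  }, logical(1))))
})
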