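# Standardized linear models, subset search, LOO validation, error scaling.

test_that("standardization matches hand arithmetic and is idempotent", {
  s <- standardize(data.frame(a = c(1, 2, 3)))
  expect_equal(s$data$a, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(unname(s$center["a"]), 2)
  expect_equal(unname(s$scale["a"]), sqrt(2 / 3), tolerance = 1e-12)
  s2 <- standardize(s$data)
  expect_equal(s2$data$a, s$data$a, tolerance = 1e-12)
  expect_error(standardize(data.frame(a = rep(3, 5))), "constant.*a")
  # sample-sd convention is available
  ss <- standardize(data.frame(a = c(1, 2, 3)), sd_type = "sample")
  expect_equal(ss$data$a, c(-1, 0, 1), tolerance = 1e-12)
})

test_that("R-squared identities and the hand-computed case are exact", {
  y <- c(1, 2, 3)
  expect_identical(r_squared(y, y), 1)
  expect_identical(r_squared(y, rep(mean(y), 3)), 0)
  expect_equal(r_squared(y, c(1.1, 1.9, 3.0)), 1 - 0.02 / 2,
               tolerance = 1e-12)
  expect_error(r_squared(y, c(1, 2)), "length")
  expect_error(r_squared(rep(1, 4), rep(1, 4)), "constant")
})

test_that("intercept-free least squares reduces to a correlation for p = 1", {
  voidshape:::with_seed(5, {
    x <- stats::rnorm(30)
    y <- 0.6 * x + stats::rnorm(30, sd = 0.4)
    sx <- standardize(data.frame(x = x, y = y))
    fit <- fit_linear(as.matrix(sx$data[, "x", drop = FALSE]), sx$data$y)
    expect_equal(unname(fit$weights["x"]), stats::cor(x, y),
                 tolerance = 1e-10)
    # exact linear data: perfect fit
    y2 <- 2 * x
    sx2 <- standardize(data.frame(x = x, y = y2))
    fit2 <- fit_linear(as.matrix(sx2$data[, "x", drop = FALSE]), sx2$data$y)
    expect_equal(fit2$r2, 1, tolerance = 1e-12)
    # orthogonal response: weights and R2 near zero
    yo <- stats::rnorm(3000)
    xo <- stats::rnorm(3000)
    so <- standardize(data.frame(x = xo, y = yo))
    fo <- fit_linear(as.matrix(so$data[, "x", drop = FALSE]), so$data$y)
    expect_lt(abs(unname(fo$weights["x"])), 0.06)
    # rank deficiency is reported with the offending column
    X <- cbind(a = x, b = x)
    expect_error(fit_linear(X, y), "collinear")
  })
})

test_that("leave-one-out matches a hand-executed fold-by-fold computation", {
  x <- c(0, 1, 2, 4)
  y <- c(0.1, 0.9, 2.2, 3.9)
  res <- loo_cv(matrix(x, ncol = 1, dimnames = list(NULL, "x")), y)
  # independent hand loop: per-fold population standardization,
  # intercept-free slope on standardized data, prediction on original scale
  psd <- function(v) sqrt(mean((v - mean(v))^2))
  pred <- numeric(4)
  for (k in 1:4) {
    tr <- setdiff(1:4, k)
    mx <- mean(x[tr]); sx <- psd(x[tr])
    my <- mean(y[tr]); sy <- psd(y[tr])
    zx <- (x[tr] - mx) / sx
    zy <- (y[tr] - my) / sy
    w <- sum(zx * zy) / sum(zx^2)
    pred[k] <- w * (x[k] - mx) / sx * sy + my
  }
  expect_equal(res$predictions, pred, tolerance = 1e-10)
  expect_equal(res$mse_loo, mean((y - pred)^2), tolerance = 1e-10)
  expect_equal(res$r2_loo, 1 - sum((y - pred)^2) / sum((y - mean(y))^2),
               tolerance = 1e-10)
  # exactly collinear data predict perfectly
  y_lin <- 2 * x + 1
  res_lin <- loo_cv(matrix(x, ncol = 1), y_lin)
  expect_equal(res_lin$mse_loo, 0, tolerance = 1e-16)
  expect_equal(res_lin$r2_loo, 1, tolerance = 1e-12)
})

test_that("best subset agrees with an independent exhaustive oracle", {
  voidshape:::with_seed(31, {
    for (rep in 1:3) {
      fx <- generate_regression_fixture(
        16, stats::setNames(c(0.8, -0.6, 0, 0, 0), paste0("f", 1:5)),
        noise_sd = 0.3, seed = 300 + rep)
      tab <- cbind(fx$X, y = fx$y)
      got <- best_subset(tab, "y", paste0("f", 1:5))
      want <- oracle_best_subset(tab, "y", paste0("f", 1:5))
      expect_identical(got$features, want$features)
      expect_equal(got$mse_loo, want$mse_loo, tolerance = 1e-10)
    }
  })
})

test_that("best subset recovers a planted two-feature model", {
  fx <- generate_regression_fixture(
    20, stats::setNames(c(0.8, -0.6, 0, 0, 0, 0, 0, 0),
                        c("V", "S", "L", "nbr", "dmin", "dmax", "dave",
                          "dtotal")),
    noise_sd = 0.05, seed = 17)
  tab <- cbind(fx$X, y = fx$y)
  res <- best_subset(tab, "y", names(fx$X))
  expect_true(all(c("V", "S") %in% res$features))
  expect_equal(unname(res$weights["V"]),
               0.8 * voidshape:::pop_sd(fx$X$V) / voidshape:::pop_sd(fx$y),
               tolerance = 0.1)
  expect_gt(res$r2, 0.95)
  # single candidate feature is selected trivially
  one <- best_subset(tab, "y", "V")
  expect_identical(one$features, "V")
  # R2 criterion warns about monotonicity
  expect_warning(best_subset(tab, "y", c("V", "S"), criterion = "r2"),
                 "monotone")
})

test_that("standardized results are invariant to raw feature scaling", {
  fx <- generate_regression_fixture(20, c(a = 0.5, b = -0.7), 0.1, seed = 23)
  tab1 <- cbind(fx$X, y = fx$y)
  tab2 <- tab1
  tab2$a <- tab2$a * 1000
  r1 <- best_subset(tab1, "y", c("a", "b"))
  r2 <- best_subset(tab2, "y", c("a", "b"))
  expect_equal(r1$weights, r2$weights, tolerance = 1e-10)
  expect_equal(r1$r2, r2$r2, tolerance = 1e-10)
  expect_equal(r1$mse_loo, r2$mse_loo, tolerance = 1e-10)
})

test_that("adding a feature never decreases in-sample R-squared", {
  voidshape:::with_seed(77, {
    for (rep in 1:5) {
      fx <- generate_regression_fixture(18, c(0.5, -0.3, 0.2), 0.5,
                                        seed = 500 + rep)
      tab <- cbind(fx$X, y = fx$y)
      r1 <- voidshape:::global_fit(tab, "y", "X1", "population")$r2
      r12 <- voidshape:::global_fit(tab, "y", c("X1", "X2"), "population")$r2
      r123 <- voidshape:::global_fit(tab, "y", c("X1", "X2", "X3"),
                                     "population")$r2
      expect_gte(r12, r1 - 1e-12)
      expect_gte(r123, r12 - 1e-12)
    }
  })
})

test_that("leave-k-out ratios behave at the degenerate and k = 1 limits", {
  x <- seq_len(12)
  tab <- data.frame(x = x, y = 2 * x + 3)
  res <- leave_k_out_ratio(tab, "y", "x", k = 2, seed = 1)
  expect_true(attr(res, "degenerate"))
  expect_equal(res$ratio, c(1, 1))
  fx <- generate_regression_fixture(20, c(a = 0.7, b = -0.4), 0.1, seed = 5)
  tab2 <- cbind(fx$X, y = fx$y)
  res2 <- leave_k_out_ratio(tab2, "y", c("a", "b"), k = 3, seed = 2)
  expect_equal(res2$ratio[1], 1, tolerance = 1e-12)  # self-referential
  expect_false(attr(res2, "degenerate"))
  expect_error(leave_k_out_ratio(tab2[1:5, ], "y", c("a", "b"), k = 3),
               "insufficient")
})

test_that("chemistry-to-void fitting returns one model per void variable", {
  voidshape:::with_seed(13, {
    n <- 20
    chem <- as.data.frame(matrix(stats::rnorm(n * 4), n,
                                 dimnames = list(NULL, c("MM", "vdW", "nC",
                                                         "nPolar"))))
    coef_true <- rbind(V = c(0.9, 0, 0, 0), S = c(0, 0.8, 0, 0))
    voids <- as.data.frame(t(coef_true %*% t(as.matrix(chem)))) +
      matrix(stats::rnorm(n * 2, sd = 0.05), n)
    names(voids) <- c("V", "S")
    res <- fit_chemistry_to_void(chem, voids)
    expect_named(res$results, c("V", "S"))
    expect_true("MM" %in% res$results$V$features)
    expect_true("vdW" %in% res$results$S$features)
    expect_equal(dim(res$coefficients), c(2L, 4L))
    # a void variable independent of all chemistry earns no confidence
    # (mean validated R2 over several null draws)
    null_r2 <- vapply(1:5, function(i) {
      null_voids <- data.frame(V = stats::rnorm(n))
      fit_chemistry_to_void(chem, null_voids)$results$V$r2_loo
    }, numeric(1))
    expect_lt(mean(null_r2), 0.2)
    expect_error(fit_chemistry_to_void(chem[1:10, ], voids), "mismatch")
  })
})
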