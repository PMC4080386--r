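test_that("OLS statistics match an explicit least-squares oracle", {
  x <- c(0, 1, 2, 3)
  y <- c(0, 1, 2, 3.1)
  fit <- ols_regression(matrix(x, ncol = 1, dimnames = list(NULL, "x")), y)
  expect_equal(fit$r_squared, cor(x, y)^2)
  expect_equal(fit$r_squared, 0.9985, tolerance = 1e-3)
  # oracle via normal equations
  X1 <- cbind(1, x)
  beta_hat <- solve(t(X1) %*% X1, t(X1) %*% y)
  expect_equal(unname(fit$coefficients), c(beta_hat), tolerance = 1e-12)
  expect_equal(unname(fit$vif), 1)
})

test_that("a noiseless linear outcome gives R squared of one", {
  X <- withr::with_seed(1, matrix(rnorm(30), ncol = 2,
                                  dimnames = list(NULL, c("a", "b"))))
  y <- 2 + 3 * X[, 1] - X[, 2]
  fit <- suppressWarnings(ols_regression(X, y))
  expect_equal(fit$r_squared, 1)
  # an exactly-zero residual sum of squares degenerates the Gaussian BIC
  expect_warning(bic <- regression_bic(list(rss = 0, n = 15, k = 2)), "RSS")
  expect_identical(bic, -Inf)
})

test_that("F, t and p values agree with matrix-algebra formulas", {
  withr::with_seed(7, {
    X <- matrix(rnorm(40 * 3), ncol = 3,
                dimnames = list(NULL, c("a", "b", "c")))
    y <- 1 + X %*% c(0.5, 0, -0.3) + rnorm(40)
  })
  fit <- ols_regression(X, y)
  n <- 40; k <- 3
  X1 <- cbind(1, X)
  bh <- solve(t(X1) %*% X1, t(X1) %*% y)
  res <- y - X1 %*% bh
  rss <- sum(res^2)
  sigma2 <- rss / (n - k - 1)
  se <- sqrt(diag(solve(t(X1) %*% X1)) * sigma2)
  tv <- c(bh / se)[-1]
  expect_equal(unname(fit$t), tv, tolerance = 1e-10)
  expect_equal(unname(fit$p), 2 * pt(-abs(tv), n - k - 1), tolerance = 1e-10)
  r2 <- 1 - rss / sum((y - mean(y))^2)
  expect_equal(fit$F, (r2 / k) / ((1 - r2) / (n - k - 1)), tolerance = 1e-10)
  # standardized coefficients equal the fit on z-scored data
  fitz <- lm(scale(y) ~ scale(X))
  expect_equal(unname(fit$b), unname(coef(fitz)[-1]), tolerance = 1e-10)
})

test_that("VIF is one for orthogonal regressors and matches car::vif", {
  X <- cbind(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1))
  y <- c(0.3, 1, 2, 0.1)
  fit <- ols_regression(X, y)
  expect_equal(unname(fit$vif), c(1, 1))
  withr::with_seed(3, {
    Xr <- matrix(rnorm(25 * 3), ncol = 3,
                 dimnames = list(NULL, c("a", "b", "c")))
    Xr[, 3] <- Xr[, 1] + 0.5 * rnorm(25)
    yr <- rnorm(25)
  })
  fitr <- ols_regression(Xr, yr)
  expect_equal(unname(fitr$vif), unname(car::vif(fitr$lm)), tolerance = 1e-8)
  expect_true(all(fitr$vif >= 1))
})

test_that("rank-deficient designs are rejected naming the collinear columns", {
  X <- cbind(a = 1:6, b = 2 * (1:6))
  expect_error(ols_regression(X, rnorm(6)), "collinear.*b")
  expect_error(ols_regression(matrix(rnorm(4), ncol = 2), rnorm(2)),
               "n > k")
})

test_that("the Gaussian-form BIC penalises complexity and ignores shifts", {
  withr::with_seed(11, {
    n <- 200
    x1 <- rnorm(n)
    y <- 1 + 0.8 * x1 + rnorm(n)
    # a pure-noise regressor raises BIC in the median over replicates
    deltas <- vapply(1:50, function(i) {
      noise <- rnorm(n)
      f1 <- ols_regression(cbind(x1 = x1), y)
      f2 <- ols_regression(cbind(x1 = x1, junk = noise), y)
      regression_bic(f2) - regression_bic(f1)
    }, numeric(1))
    expect_gt(median(deltas), 0)
  })
  # identical fit quality, more parameters -> larger BIC by the penalty term
  f <- list(rss = 10, n = 50, k = 1)
  g <- list(rss = 10, n = 50, k = 3)
  expect_equal(regression_bic(g) - regression_bic(f), 2 * log(50))
  # BIC differences are invariant to adding a constant to the outcome
  withr::with_seed(12, {
    x <- rnorm(30); yy <- x + rnorm(30); z <- rnorm(30)
  })
  d1 <- regression_bic(ols_regression(cbind(x = x, z = z), yy)) -
    regression_bic(ols_regression(cbind(x = x), yy))
  d2 <- regression_bic(ols_regression(cbind(x = x, z = z), yy + 100)) -
    regression_bic(ols_regression(cbind(x = x), yy + 100))
  expect_equal(d1, d2, tolerance = 1e-8)
})

test_that("stage-2 selection ranks twelve candidate regressions by BIC", {
  # synthetic fits: 12 datasets, winner M2 everywhere, omega drives the trait
  withr::with_seed(21, {
    n <- 30
    ids <- sprintf("S%03d", 1:n)
    omega <- runif(n, -6, -2)
    theta <- runif(n, 0.01, 0.1)
    trait <- 60 + 2.5 * omega + rnorm(n, 0, 1)
    make_fits <- function(noise) {
      fits <- lapply(seq_len(n), function(i)
        list(subject = ids[i], model = "M2",
             estimates = c(omega = omega[i] + rnorm(1, 0, noise),
                           theta = theta[i] + rnorm(1, 0, noise / 100))))
      names(fits) <- ids
      fits
    }
    labels <- paste0("D", 1:12)
    fits <- lapply(setNames(labels, labels),
                   function(l) list(M2 = make_fits(noise = runif(1, 0.1, 2))))
    bms <- lapply(setNames(labels, labels),
                  function(l) list(winner = "M2"))
    cov <- data.frame(subject = ids, trait_score = trait)
  })
  s2 <- stage2_select(fits, bms, cov)
  expect_equal(nrow(s2$table), 12)
  expect_equal(s2$winner, s2$table$dataset[1])
  expect_equal(s2$table$bic, sort(s2$table$bic))
  expect_equal(s2$bonferroni_level, 0.05 / 12)
  # the least-noisy estimates should make omega significant in the winner
  expect_true(s2$table$omega_significant[1])
})

test_that("stage-2 drops subjects pairwise and skips starved datasets", {
  withr::with_seed(22, {
    ids <- sprintf("S%03d", 1:10)
    fits_full <- lapply(ids, function(id)
      list(subject = id, model = "M2",
           estimates = c(omega = rnorm(1, -4), theta = runif(1, 0.01, 0.1))))
    names(fits_full) <- ids
    cov <- data.frame(subject = ids, trait_score = rnorm(10, 60))
  })
  fits <- list(D1 = list(M2 = fits_full),
               D2 = list(M2 = fits_full[1:3]))
  bms <- list(D1 = list(winner = "M2"), D2 = list(winner = "M2"))
  expect_warning(s2 <- stage2_select(fits, bms, cov), "dropped pairwise")
  expect_equal(nrow(s2$table), 1)
  expect_match(s2$skipped$D2, "insufficient subjects")
})
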