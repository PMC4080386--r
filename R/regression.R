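#' Multiple linear regression with standardized coefficients and VIF
#'
#' Ordinary least squares with intercept (via [stats::lm()]). Reports raw
#' coefficients `B`, standardized coefficients `b` (from z-scored regressors
#' and outcome), per-coefficient t and p values, R-squared, the overall F
#' test, and the variance inflation factor of every regressor
#' (`VIF_j = 1 / (1 - R2_j)` from regressing regressor j on the others).
#'
#' @param X Subjects x regressors matrix or data frame.
#' @param y Outcome vector.
#' @return List of class `"ols_fit"`.
#' @export
ols_regression <- function(X, y) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X)
  k <- ncol(X)
  if (n <= k + 1) stop("need n > k + 1 observations")
  qrX <- qr(cbind(1, X))
  if (qrX$rank < k + 1) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, k + 1)] - 1]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }

  df <- data.frame(y = y, X)
  fit <- lm(y ~ ., data = df)
  sm <- summary(fit)
  rss <- sum(fit$residuals^2)
  r2 <- sm$r.squared
  Fstat <- (r2 / k) / ((1 - r2) / (n - k - 1))
  Fp <- pf(Fstat, k, n - k - 1, lower.tail = FALSE)

  # standardized coefficients
  b_std <- coef(fit)[-1] * apply(X, 2, sd) / sd(y)

  vif <- vapply(seq_len(k), function(j) {
    if (k == 1) return(1)
    r2j <- summary(lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared
    1 / (1 - r2j)
  }, numeric(1))
  names(vif) <- colnames(X)

  ct <- sm$coefficients
  tvals <- ct[-1, "t value"]
  pvals <- ct[-1, "Pr(>|t|)"]
  names(tvals) <- names(pvals) <- colnames(X)
  structure(list(coefficients = coef(fit),
                 B = coef(fit)[-1], b = b_std,
                 t = tvals, p = pvals,
                 r_squared = r2, F = Fstat, F_p = Fp,
                 rss = rss, vif = vif, n = n, k = k, lm = fit),
            class = "ols_fit")
}

#' Gaussian-form BIC of a fitted regression
#'
#' `BIC = n * ln(RSS / n) + (k + 1) * ln(n)`; lower is better. `RSS = 0`
#' returns `-Inf` with a warning.
#'
#' @param result An `ols_fit`.
#' @return Scalar BIC.
#' @export
regression_bic <- function(result) {
  if (result$rss <= 0) {
    warning("RSS is zero; BIC is -Inf")
    return(-Inf)
  }
  result$n * log(result$rss / result$n) + (result$k + 1) * log(result$n)
}

#' Stage-2 model selection: construct validity against a trait score
#'
#' For each dataset, regresses the trait score on the stage-1 winning model's
#' subject-wise native-space parameter estimates (omega and theta, plus beta
#' or alpha where the model has them free). The twelve candidate regressions
#' are ranked by [regression_bic()] (ties broken by fewer regressors) and
#' significance is Bonferroni-corrected across the candidates.
#'
#' @param fits All fits: nested list `dataset label -> model id -> list of
#'   subject_fits` (as produced by [fit_dataset()] per model).
#' @param bms Named list `dataset label -> bms_result` (stage 1).
#' @param covariates Data frame with columns `subject` and the trait score.
#' @param trait_col Name of the outcome column (default `"trait_score"`).
#' @param alpha_level Family significance level before correction (0.05).
#' @param n_tests Bonferroni divisor (defaults to the number of datasets).
#' @return List of class `"stage2_result"`: per-dataset `table` (winner
#'   model, BIC, R2, F, p, per-coefficient p values, Bonferroni flags),
#'   `winner` (dataset label with minimal BIC), `regressions` (the `ols_fit`
#'   objects), `skipped` (error records), and the correction level used.
#' @export
stage2_select <- function(fits, bms, covariates, trait_col = "trait_score",
                          alpha_level = 0.05, n_tests = NULL) {
  labels <- names(bms)
  if (is.null(n_tests)) n_tests <- length(labels)
  level <- alpha_level / n_tests

  rows <- list()
  regressions <- list()
  skipped <- list()
  for (lab in labels) {
    win <- bms[[lab]]$winner
    subj_fits <- fits[[lab]][[win]]
    ids <- intersect(covariates$subject, names(subj_fits))
    dropped <- setdiff(covariates$subject, ids)
    if (length(dropped))
      warning("dataset ", lab, ": subjects dropped pairwise: ",
              paste(dropped, collapse = ", "))
    pnames <- free_parameters(win)
    X <- t(vapply(ids, function(id) subj_fits[[id]]$estimates[pnames],
                  numeric(length(pnames))))
    colnames(X) <- pnames
    yv <- covariates[[trait_col]][match(ids, covariates$subject)]
    if (length(ids) < length(pnames) + 2) {
      skipped[[lab]] <- paste0("insufficient subjects (", length(ids), ")")
      next
    }
    reg <- ols_regression(X, yv)
    bic <- regression_bic(reg)
    regressions[[lab]] <- reg
    row <- data.frame(dataset = lab, model = win, k = reg$k, n = reg$n,
                      bic = bic, r_squared = reg$r_squared, F = reg$F,
                      F_p = reg$F_p,
                      F_significant = reg$F_p < level,
                      p_omega = if ("omega" %in% pnames) reg$p[["omega"]] else NA,
                      p_theta = if ("theta" %in% pnames) reg$p[["theta"]] else NA,
                      omega_significant = if ("omega" %in% pnames)
                        reg$p[["omega"]] < level else NA)
    rows[[lab]] <- row
  }
  if (!length(rows)) stop("no dataset had enough subjects for stage 2")
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  ord <- order(table$bic, table$k)
  table <- table[ord, ]
  structure(list(table = table, winner = table$dataset[1],
                 regressions = regressions, skipped = skipped,
                 bonferroni_level = level, n_tests = n_tests),
            class = "stage2_result")
}

#' @export
print.stage2_result <- function(x, ...) {
  cat("Stage-2 construct-validity comparison over", nrow(x$table),
      "datasets (Bonferroni level", signif(x$bonferroni_level, 3), ")\n")
  print(x$table, digits = 4)
  cat("winner (min BIC):", x$winner, "\n")
  if (length(x$skipped)) {
    cat("skipped:\n")
    for (lab in names(x$skipped)) cat(" ", lab, "-", x$skipped[[lab]], "\n")
  }
  invisible(x)
}
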