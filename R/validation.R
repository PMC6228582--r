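#' Leave-one-out cross-validation of the strength regression
#'
#' For each of the n instances, refits the two-feature least-squares model
#' on the other n - 1 and predicts the held-out instance. Reports per-fold
#' predictions and residuals plus the Pearson correlation between observed
#' and cross-validated predictions.
#'
#' @param table A `feature_table` with n >= 5 rows.
#' @return A data.frame of class `cv_table` with columns `fold`, `s35`,
#'   `s10`, `combined`, `observed`, `cvpred`, `cvres` (= observed - cvpred)
#'   and attribute `correlation`.
#' @examples
#' cv <- loocv(featurize(anderson_fixture()))
#' attr(cv, "correlation")
#' @export
loocv <- function(table) {
  n <- nrow(table)
  if (n < 5)
    stop("leave-one-out cross-validation needs at least 5 instances")
  cvpred <- vapply(seq_len(n), function(i) {
    fit <- tryCatch(fit_ols(table[-i, ]),
                    error = function(e)
                      stop(sprintf("fold %d: %s", i, conditionMessage(e))))
    predict_log_strength(fit, table$s35[i], table$s10[i])
  }, numeric(1))
  out <- data.frame(fold = seq_len(n), s35 = table$s35, s10 = table$s10,
                    combined = table$combined, observed = table$y,
                    cvpred = cvpred, cvres = table$y - cvpred)
  attr(out, "correlation") <- stats::cor(out$observed, out$cvpred)
  class(out) <- c("cv_table", "data.frame")
  out
}

#' Random hexamer pairs
#'
#' Generates (hex35, hex10) pairs with every base drawn i.i.d. uniformly
#' over A/C/G/T — the negative set of "promoters" with no sequence signal.
#'
#' @param n Number of pairs.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return A data.frame with columns `hex35`, `hex10`.
#' @export
random_hexamers <- function(n, seed) {
  stopifnot(n > 0)
  draw <- withr_seed(seed, function() {
    matrix(sample(BASES, 12 * n, replace = TRUE), nrow = n)
  })
  data.frame(
    hex35 = apply(draw[, 1:6, drop = FALSE], 1, paste, collapse = ""),
    hex10 = apply(draw[, 7:12, drop = FALSE], 1, paste, collapse = ""),
    stringsAsFactors = FALSE)
}

# Run fn with a local RNG seed, restoring the caller's RNG state after.
withr_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  fn()
}

#' Random-promoter strength baseline
#'
#' Scores `n_sets` sets of `set_size` random hexamer pairs with the two
#' PWMs, predicts their strengths (exp scale) under the fitted model, and
#' summarizes the sampling distribution of the per-set mean strengths. A
#' specific model should assign random sequences far lower strength than
#' any real training promoter.
#'
#' @param fit A `promoter_fit`.
#' @param pwm35,pwm10 PWMs used to score the random hexamers.
#' @param n_sets Number of sets; default 100.
#' @param set_size Pairs per set; default 100.
#' @param seed Integer seed.
#' @return A `baseline_summary` list: `set_means` (length `n_sets`),
#'   `grand_mean`, `standard_error` (= sd(set means)/sqrt(n_sets)), `seed`,
#'   `n_sets`, `set_size`.
#' @export
random_baseline <- function(fit, pwm35, pwm10, n_sets = 100, set_size = 100,
                            seed = 1) {
  stopifnot(inherits(fit, "promoter_fit"), n_sets > 0, set_size > 0)
  pairs <- random_hexamers(n_sets * set_size, seed)
  s35 <- score_hexamer(pwm35, pairs$hex35)
  s10 <- score_hexamer(pwm10, pairs$hex10)
  strengths <- predict_strength(fit, s35, s10)
  set_means <- colMeans(matrix(strengths, nrow = set_size))
  se <- if (n_sets > 1) stats::sd(set_means) / sqrt(n_sets) else 0
  structure(list(set_means = set_means, grand_mean = mean(set_means),
                 standard_error = se, seed = seed, n_sets = n_sets,
                 set_size = set_size),
            class = "baseline_summary")
}

#' @export
print.baseline_summary <- function(x, ...) {
  cat(sprintf("Random-promoter baseline: %d sets of %d (seed %d)\n",
              x$n_sets, x$set_size, x$seed))
  cat(sprintf("  mean predicted strength %.3e +/- %.3e (SE)\n",
              x$grand_mean, x$standard_error))
  invisible(x)
}

#' Write a baseline summary as JSON
#' @param baseline A `baseline_summary`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_baseline <- function(baseline, path) {
  jsonlite::write_json(unclass(baseline), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Correlation matrix of features and response variables
#'
#' Pearson correlations among the -35 score, -10 score, combined score, raw
#' strength and log strength — the table that shows each feature correlating
#' better with the log of strength than with strength itself.
#'
#' @param table A `feature_table` (its `strength` and `y` columns are the
#'   two responses).
#' @return A symmetric 5 x 5 matrix with unit diagonal, dimensions
#'   s35, s10, combined, strength, log_strength.
#' @examples
#' correlation_matrix(featurize(anderson_fixture()))
#' @export
correlation_matrix <- function(table) {
  if (nrow(table) < 3)
    stop("correlation matrix needs at least 3 instances")
  vars <- cbind(s35 = table$s35, s10 = table$s10, combined = table$combined,
                strength = table$strength, log_strength = table$y)
  stats::cor(vars)
}

#' Linear-model diagnostics datasets
#'
#' Emits, as one table, the data behind the four standard diagnostic plots:
#' residuals vs fitted, scale-location (sqrt of |standardized residual| vs
#' fitted), the normal Q-Q pairs for the standardized residuals (plotting
#' position (i - 0.5)/n), and standardized residuals vs leverage.
#' Standardized residuals are internally studentized:
#' r_i / (sigma * sqrt(1 - h_ii)) with h the hat-matrix diagonal.
#'
#' @param fit A `promoter_fit` computed on `table` by least squares.
#' @param table The `feature_table` it was fit on.
#' @return A data.frame of class `diagnostics_report` with columns `id`,
#'   `fitted`, `residual`, `std_residual`, `sqrt_abs_std_residual`,
#'   `leverage`, `theoretical_quantile` (normal quantile paired with the
#'   row's rank among standardized residuals).
#' @export
diagnostics <- function(fit, table) {
  stopifnot(inherits(fit, "promoter_fit"))
  X <- design_matrix(table)
  n <- nrow(X)
  H <- X %*% chol2inv(chol(crossprod(X))) %*% t(X)
  lev <- diag(H)
  res <- table$y - drop(X %*% fit$coefficients)
  sigma <- sqrt(sum(res^2) / (n - ncol(X)))
  std <- res / (sigma * sqrt(1 - lev))
  qq <- stats::qnorm((rank(std, ties.method = "first") - 0.5) / n)
  structure(
    data.frame(id = table$id, fitted = fit$fitted, residual = res,
               std_residual = std, sqrt_abs_std_residual = sqrt(abs(std)),
               leverage = lev, theoretical_quantile = qq,
               stringsAsFactors = FALSE),
    class = c("diagnostics_report", "data.frame"))
}

#' Write a cv table or diagnostics report as TSV
#' @param x A `cv_table` or `diagnostics_report`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
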