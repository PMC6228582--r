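#' Floored natural log of promoter strength
#'
#' Normalized strengths approach 0 for very weak promoters and ln would run
#' to -Inf, so the strength is floored at `floor` (default 1e-4) before the
#' natural log is taken.
#'
#' @param strength Non-negative strength value(s), normalized to the
#'   reference promoter.
#' @param floor Positive lower cap applied before the log; default 1e-4.
#' @return ln(max(strength, floor)).
#' @examples
#' log_strength(1)     # 0
#' log_strength(0.01)  # -4.60517
#' log_strength(0)     # ln(1e-4)
#' @export
log_strength <- function(strength, floor = 1e-4) {
  stopifnot(is.numeric(strength), floor > 0)
  if (any(strength < 0))
    stop("promoter strength cannot be negative")
  log(pmax(strength, floor))
}

#' Promoter records
#'
#' Validated table of training promoters: identifier, -35 hexamer, -10
#' hexamer and normalized strength in (0, 1] (values above 1 are tolerated
#' for promoters stronger than the reference).
#'
#' @param id Character identifiers.
#' @param hex35,hex10 6-nt hexamers.
#' @param strength Non-negative normalized strengths.
#' @return A data.frame of class `promoter_records`.
#' @export
promoter_records <- function(id, hex35, hex10, strength) {
  if (length(id) > 0) {
    hex35 <- check_hexamers(hex35, what = "-35 hexamer")
    hex10 <- check_hexamers(hex10, what = "-10 hexamer")
  } else {
    hex35 <- hex10 <- character()
  }
  stopifnot(is.numeric(strength), all(strength >= 0))
  structure(
    data.frame(id = as.character(id), hex35 = hex35, hex10 = hex10,
               strength = strength, stringsAsFactors = FALSE),
    class = c("promoter_records", "data.frame"))
}

#' Read a training table of promoters
#'
#' TSV with columns `id`, `hex35`, `hex10`, `strength`; optional
#' precomputed `s35`, `s10` columns are carried through so a feature table
#' can be built without PWMs (fixture mode).
#'
#' @param path File path.
#' @return A `promoter_records` data.frame (with `s35`/`s10` if present).
#' @export
read_training <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("id", "hex35", "hex10", "strength")
  if (!all(need %in% names(tab)))
    stop("training table needs columns id, hex35, hex10, strength")
  rec <- promoter_records(tab$id, tab$hex35, tab$hex10, tab$strength)
  for (col in c("s35", "s10"))
    if (col %in% names(tab)) rec[[col]] <- tab[[col]]
  rec
}

#' Build the regression feature table
#'
#' One row per promoter with its two PWM scores (s35, s10), their sum
#' (`combined`), and the floored log strength as the response. If the
#' records already carry `s35`/`s10` columns (e.g. the shipped training
#' fixture with its printed scores), PWMs may be omitted and those scores
#' are used verbatim.
#'
#' @param records A `promoter_records` data.frame.
#' @param pwm35,pwm10 PWMs for the -35 and -10 elements; optional when
#'   `records` has precomputed scores.
#' @param floor Strength floor for [log_strength()].
#' @return A data.frame of class `feature_table` with columns `id`, `s35`,
#'   `s10`, `combined`, `y`, plus `strength`.
#' @export
featurize <- function(records, pwm35 = NULL, pwm10 = NULL, floor = 1e-4) {
  if (nrow(records) == 0)
    return(structure(
      data.frame(id = character(), s35 = numeric(), s10 = numeric(),
                 combined = numeric(), y = numeric(), strength = numeric()),
      class = c("feature_table", "data.frame")))
  if (is.null(pwm35) || is.null(pwm10)) {
    if (is.null(records$s35) || is.null(records$s10))
      stop("either supply pwm35 and pwm10 or records with s35/s10 columns")
    s35 <- records$s35
    s10 <- records$s10
  } else {
    s35 <- tryCatch(score_hexamer(pwm35, records$hex35),
                    error = function(e) stop(sprintf(
                      "scoring -35 hexamers failed (first record '%s'): %s",
                      records$id[1], conditionMessage(e))))
    s10 <- score_hexamer(pwm10, records$hex10)
  }
  structure(
    data.frame(id = records$id, s35 = s35, s10 = s10, combined = s35 + s10,
               y = log_strength(records$strength, floor),
               strength = records$strength, stringsAsFactors = FALSE),
    class = c("feature_table", "data.frame"))
}

# Design matrix [1 | s35 | s10] for the two-feature model.
design_matrix <- function(table) {
  cbind(intercept = 1, s35 = table$s35, s10 = table$s10)
}

new_fit <- function(coefficients, table, method, ...) {
  X <- design_matrix(table)
  fitted <- drop(X %*% coefficients)
  structure(
    list(coefficients = coefficients, fitted = fitted,
         residuals = table$y - fitted, n = nrow(table), m = 2L,
         fit_method = method, ...),
    class = "promoter_fit")
}

#' Exact least-squares fit of log strength on the two PWM scores
#'
#' Solves ln(strength) = b0 + b35 * s35 + b10 * s10 by QR decomposition of
#' the design matrix — the exact minimizer of the residual sum of squares.
#'
#' @param table A `feature_table` (n >= 4, full-rank features).
#' @return A `promoter_fit`: coefficients (intercept, s35, s10), fitted
#'   values, residuals, `fit_method = "ols"`.
#' @examples
#' fit_ols(featurize(anderson_fixture()))
#' @export
fit_ols <- function(table) {
  if (nrow(table) < 4)
    stop("need at least 4 instances to fit the two-feature model")
  X <- design_matrix(table)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("collinear features: design matrix is rank-deficient")
  beta <- qr.coef(qrX, table$y)
  new_fit(beta, table, "ols")
}

#' Batch gradient-descent fit of the same regression
#'
#' Minimizes the mean-squared-error cost J(b) = (1/2n) * sum((Xb - y)^2)
#' from zero-initialized coefficients with fixed-step batch updates
#' b <- b - rate * X'(Xb - y)/n. Deterministic; on the training fixture it
#' converges to the exact least-squares solution well within the default
#' iteration budget.
#'
#' @param table A `feature_table`.
#' @param learning_rate Step size; default 0.015.
#' @param iterations Number of updates; default 1e5.
#' @param feature_scaling Standardize features to zero mean / unit sd for
#'   the updates (coefficients are mapped back to the raw scale). Off by
#'   default: the raw-score problem is well-conditioned enough at the
#'   default rate.
#' @param trace_every Record the cost every this many iterations (0 = only
#'   first/last).
#' @return A `promoter_fit` with `fit_method = "gradient_descent"`, the
#'   hyperparameters, `final_cost` and a `cost_trace`.
#' @export
fit_gradient_descent <- function(table, learning_rate = 0.015,
                                 iterations = 1e5, feature_scaling = FALSE,
                                 trace_every = 1000) {
  stopifnot(learning_rate > 0, iterations >= 1)
  X <- design_matrix(table)
  y <- table$y
  n <- nrow(X)
  ctr <- c(0, 0, 0); scl <- c(1, 1, 1)
  if (feature_scaling) {
    ctr <- c(0, mean(table$s35), mean(table$s10))
    scl <- c(1, stats::sd(table$s35), stats::sd(table$s10))
    X <- sweep(sweep(X, 2, ctr, `-`), 2, scl, `/`)
  }
  b <- c(0, 0, 0)
  cost <- function(b) sum((X %*% b - y)^2) / (2 * n)
  trace <- c(cost(b))
  prev <- trace[1]
  rising <- 0L
  for (it in seq_len(iterations)) {
    g <- crossprod(X, X %*% b - y) / n
    b <- b - learning_rate * drop(g)
    cur <- cost(b)
    rising <- if (!is.finite(cur) || cur > prev) rising + 1L else 0L
    if (rising >= 100L)
      stop("gradient descent is diverging (cost rose over 100 consecutive ",
           "steps); lower the learning rate or enable feature_scaling")
    prev <- cur
    if (trace_every > 0 && it %% trace_every == 0) trace <- c(trace, cur)
  }
  # map standardized-scale coefficients back to raw scores
  raw <- b / scl
  raw[1] <- b[1] - sum((b[-1] / scl[-1]) * ctr[-1])
  names(raw) <- c("intercept", "s35", "s10")
  new_fit(raw, table, "gradient_descent",
          learning_rate = learning_rate, iterations = iterations,
          feature_scaling = feature_scaling,
          final_cost = prev, cost_trace = c(trace, prev))
}

#' @export
print.promoter_fit <- function(x, ...) {
  cat(sprintf("Promoter strength regression (%s), n = %d\n", x$fit_method, x$n))
  cat(sprintf("  ln(strength) = %.4f + %.4f * s35 + %.4f * s10\n",
              x$coefficients[1], x$coefficients[2], x$coefficients[3]))
  if (x$fit_method == "gradient_descent")
    cat(sprintf("  rate %g, %g iterations, final cost %.6g\n",
                x$learning_rate, x$iterations, x$final_cost))
  invisible(x)
}

#' Adjusted coefficient of determination
#'
#' Adj. R2 = 1 - (1 - R2) * (n - 1) / (n - m - 1): the complexity-penalized
#' R2 for a model with m features fit to n instances.
#'
#' @param r2 Unadjusted R2.
#' @param n Number of instances.
#' @param m Number of features.
#' @return Adjusted R2.
#' @examples
#' adjusted_r2(0.69, 18, 2)
#' @export
adjusted_r2 <- function(r2, n, m) {
  if (n <= m + 1)
    stop("adjusted R2 needs n > m + 1")
  1 - (1 - r2) * (n - 1) / (n - m - 1)
}

#' Classical OLS inference for a fitted model
#'
#' Standard errors from the residual variance and the inverse Gram matrix,
#' t-statistics and p-values on n - m - 1 degrees of freedom, the overall
#' F-statistic, R2 / adjusted R2, and central confidence intervals
#' estimate +/- t_crit * SE.
#'
#' @param fit A `promoter_fit` computed on `table`.
#' @param table The `feature_table` the fit was computed on.
#' @param level Confidence level; default 0.95.
#' @return A `model_stats` list: `coefficients` (a data.frame with estimate,
#'   se, t, p, ci_lower, ci_upper), `r2`, `adj_r2`, `f_statistic`,
#'   `f_pvalue`, `sigma`, `df_residual`, `n`, `m`.
#' @examples
#' tab <- featurize(anderson_fixture())
#' model_stats(fit_ols(tab), tab)
#' @export
model_stats <- function(fit, table, level = 0.95) {
  stopifnot(inherits(fit, "promoter_fit"), level > 0, level < 1)
  X <- design_matrix(table)
  y <- table$y
  n <- nrow(X); m <- ncol(X) - 1L
  df <- n - m - 1L
  res <- y - drop(X %*% fit$coefficients)
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  sigma2 <- rss / df
  if (rss <= 1e-12 * max(1, tss))
    warning("zero residual variance: t-statistics are unbounded")
  XtXi <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * diag(XtXi))
  est <- fit$coefficients
  tval <- est / se
  pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  tcrit <- stats::qt((1 + level) / 2, df)
  r2 <- 1 - rss / tss
  fstat <- ((tss - rss) / m) / sigma2
  structure(
    list(coefficients = data.frame(
           term = c("intercept", "s35", "s10"),
           estimate = unname(est), se = unname(se), t = unname(tval),
           p = unname(pval),
           ci_lower = unname(est - tcrit * se),
           ci_upper = unname(est + tcrit * se)),
         r2 = r2, adj_r2 = adjusted_r2(r2, n, m),
         f_statistic = fstat,
         f_pvalue = stats::pf(fstat, m, df, lower.tail = FALSE),
         sigma = sqrt(sigma2), df_residual = df, n = n, m = m,
         level = level),
    class = "model_stats")
}

#' @export
print.model_stats <- function(x, ...) {
  cat(sprintf("n = %d, m = %d | R2 = %.4f, adj R2 = %.4f | F(%d, %d) = %.3f, p = %.3g\n",
              x$n, x$m, x$r2, x$adj_r2, x$m, x$df_residual,
              x$f_statistic, x$f_pvalue))
  print(x$coefficients, digits = 7, row.names = FALSE)
  invisible(x)
}

#' Predict log strength and strength for hexamer score pairs
#'
#' The linear predictor intercept + b35 * s35 + b10 * s10;
#' `predict_strength()` exponentiates it. No ceiling is applied: predicted
#' strengths above 1 simply exceed the reference promoter.
#'
#' @param fit A `promoter_fit`.
#' @param s35,s10 PWM score(s) of the -35 and -10 hexamers.
#' @return Numeric prediction(s) on the ln (resp. raw) strength scale.
#' @examples
#' fit <- fit_ols(featurize(anderson_fixture()))
#' predict_log_strength(fit, 6.5966, 2.398)
#' predict_strength(fit, 9.1308, 10.086)
#' @export
predict_log_strength <- function(fit, s35, s10) {
  stopifnot(inherits(fit, "promoter_fit"),
            all(is.finite(s35)), all(is.finite(s10)))
  b <- unname(fit$coefficients)
  b[1] + b[2] * s35 + b[3] * s10
}

#' @rdname predict_log_strength
#' @export
predict_strength <- function(fit, s35, s10) {
  exp(predict_log_strength(fit, s35, s10))
}

# Helper: adj R2 and coefficient p-values for an arbitrary design matrix,
# used by the variant-model comparison.
ols_summary <- function(X, y) {
  n <- nrow(X); m <- ncol(X) - 1L
  qrX <- qr(X)
  beta <- qr.coef(qrX, y)
  res <- y - drop(X %*% beta)
  rss <- sum(res^2); tss <- sum((y - mean(y))^2)
  df <- n - m - 1L
  sigma2 <- rss / df
  se <- sqrt(sigma2 * diag(chol2inv(chol(crossprod(X)))))
  tval <- beta / se
  list(coefficients = beta,
       p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE),
       r2 = 1 - rss / tss,
       adj_r2 = adjusted_r2(1 - rss / tss, n, m))
}

#' Compare the main model with its variants
#'
#' Fits, alongside the main two-feature model of log strength:
#' (i) the interaction model s35 + s10 + s35:s10, (ii) the univariate model
#' on the combined score s35 + s10 alone, and (iii) the two-feature model of
#' the raw (un-logged) strength. Reports adjusted R2 and coefficient
#' p-values side by side — the comparison that justifies keeping the
#' additive log-scale model.
#'
#' @param table A `feature_table`.
#' @return A `variant_models` list with elements `main`, `interaction`,
#'   `combined`, `raw_strength`, each carrying `coefficients`, `p`, `r2`,
#'   `adj_r2`; plus a `summary` data.frame.
#' @examples
#' fit_variant_models(featurize(anderson_fixture()))
#' @export
fit_variant_models <- function(table) {
  y <- table$y
  X <- design_matrix(table)
  main <- ols_summary(X, y)
  interaction <- ols_summary(cbind(X, `s35:s10` = table$s35 * table$s10), y)
  combined <- ols_summary(cbind(intercept = 1, combined = table$combined), y)
  raw <- ols_summary(X, table$strength)
  summary <- data.frame(
    model = c("main", "interaction", "combined", "raw_strength"),
    response = c("log-strength", "log-strength", "log-strength", "strength"),
    adj_r2 = c(main$adj_r2, interaction$adj_r2, combined$adj_r2, raw$adj_r2))
  structure(list(main = main, interaction = interaction, combined = combined,
                 raw_strength = raw, summary = summary),
            class = "variant_models")
}

#' @export
print.variant_models <- function(x, ...) {
  print(transform(x$summary, adj_r2 = round(adj_r2, 4)), row.names = FALSE)
  invisible(x)
}

#' Persist / load a fitted model as JSON
#'
#' @param fit A `promoter_fit`.
#' @param path File path.
#' @param stats Optional `model_stats` to embed.
#' @return `write_model` returns `path` invisibly; `read_model` a
#'   `promoter_fit`.
#' @export
write_model <- function(fit, path, stats = NULL) {
  obj <- list(coefficients = as.list(fit$coefficients),
              fit_method = fit$fit_method, n = fit$n, m = fit$m)
  if (fit$fit_method == "gradient_descent")
    obj$hyperparameters <- list(learning_rate = fit$learning_rate,
                                iterations = fit$iterations,
                                feature_scaling = fit$feature_scaling)
  if (!is.null(stats))
    obj$stats <- list(r2 = stats$r2, adj_r2 = stats$adj_r2,
                      f_statistic = stats$f_statistic,
                      f_pvalue = stats$f_pvalue,
                      coefficients = stats$coefficients)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path))
    stop(sprintf("model file not found: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  b <- unlist(obj$coefficients)[c("intercept", "s35", "s10")]
  structure(list(coefficients = b, n = obj$n, m = obj$m,
                 fit_method = obj$fit_method),
            class = "promoter_fit")
}
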