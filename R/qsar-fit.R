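# Multiple linear regression with the QSAR validation suite:
# fit statistics, VIF, p-value stepwise selection, leave-one-out Q2,
# external Q2 and y-randomization.

#' Fit a multiple linear regression QSAR model
#'
#' Ordinary least squares of a response on a table of descriptors, with the
#' fit statistics conventionally reported for MLR QSAR models. The training
#' data are stored on the result so that leave-one-out, external-validation
#' and applicability-domain routines can be applied afterwards.
#'
#' `rmse` uses the population denominator `n` (not `n - k - 1`), the
#' convention under which the published training RMSE values reproduce; set
#' `rmse_df = TRUE` for the degrees-of-freedom-corrected version.
#'
#' @param x Data frame (or matrix) of descriptor values, one row per
#'   compound. Column names may be non-syntactic (e.g. `BCUTw-1h`).
#' @param y Numeric response vector (here: adsorption energies, kcal/mol).
#' @param rmse_df Use `n - k - 1` in the RMSE denominator (default `FALSE`).
#' @return An object of class `mlr_fit`: coefficients, `r_squared`, `rmse`,
#'   overall `f_statistic` with `p_value`, per-descriptor `t_values`,
#'   `p_values`, `vif` and standardized coefficients `std_coef`
#'   (`b * sd(x) / sd(y)`), residuals and fitted values, the underlying
#'   [stats::lm] object, and the training `x`/`y`.
#' @examples
#' d <- gen_linear(n = 30, beta = c(3, -1), sigma = 0.5, seed = 1)
#' fit <- fit_mlr(d$x, d$y)
#' fit$r_squared
#' @export
fit_mlr <- function(x, y, rmse_df = FALSE) {
  x <- as.data.frame(x, check.names = FALSE)
  stopifnot(nrow(x) == length(y), is.numeric(y), !anyNA(y), !anyNA(x),
            all(vapply(x, is.numeric, logical(1))))
  n <- nrow(x); k <- ncol(x)
  if (n <= k + 1) stop("need more compounds than coefficients (n > k + 1)")
  d <- cbind(.y = y, x)
  fit <- stats::lm(.y ~ ., data = d)
  if (fit$rank < k + 1)
    stop(errorCondition("descriptor matrix is rank deficient (singular design)",
                        class = c("mpqsar_singular", "error", "condition")))
  res <- stats::residuals(fit)
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  degenerate <- sst <= 0
  r2 <- if (degenerate) 0 else 1 - sse / sst
  smry <- suppressWarnings(summary(fit))  # perfect fits warn harmlessly
  fstat <- if (degenerate) NA_real_ else unname(smry$fstatistic[1])
  pval <- if (degenerate) NA_real_ else
    stats::pf(fstat, k, n - k - 1, lower.tail = FALSE)
  coefs <- stats::coef(fit)
  names(coefs) <- c("(Intercept)", colnames(x))
  sdy <- stats::sd(y)
  std_coef <- if (degenerate) rep(NA_real_, k) else
    coefs[-1] * vapply(x, stats::sd, numeric(1)) / sdy
  structure(list(
    coefficients = coefs,
    r_squared = r2,
    rmse = sqrt(sse / if (rmse_df) n - k - 1 else n),
    sigma = sqrt(sse / (n - k - 1)),
    f_statistic = fstat,
    p_value = pval,
    t_values = stats::setNames(smry$coefficients[-1, "t value"], colnames(x)),
    p_values = stats::setNames(smry$coefficients[-1, "Pr(>|t|)"], colnames(x)),
    vif = if (k >= 2) vif(x) else stats::setNames(1, colnames(x)),
    std_coef = stats::setNames(std_coef, colnames(x)),
    fitted = unname(stats::fitted(fit)),
    residuals = unname(res),
    n = n, k = k, degenerate = degenerate,
    lm = fit, x = x, y = y
  ), class = "mlr_fit")
}

#' @export
print.mlr_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<mlr_fit> n = %d, k = %d\n", x$n, x$k))
  print(round(x$coefficients, digits))
  p_disp <- if (is.na(x$p_value)) "NA"
    else if (x$p_value < 0.001) "< 0.001"
    else format(round(x$p_value, 3))
  cat(sprintf("R2 = %.*f, RMSE = %.*f, F = %.*f, p %s\n", digits,
              x$r_squared, digits, x$rmse, digits,
              ifelse(is.na(x$f_statistic), NaN, x$f_statistic),
              ifelse(grepl("^<", p_disp), p_disp, paste("=", p_disp))))
  invisible(x)
}

#' Predict from an `mlr_fit`
#'
#' @param object An `mlr_fit`.
#' @param newdata Data frame containing the model's descriptor columns;
#'   defaults to the training data.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.mlr_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  newdata <- as.data.frame(newdata, check.names = FALSE)
  miss <- setdiff(colnames(object$x), colnames(newdata))
  if (length(miss))
    stop(sprintf("newdata is missing descriptor(s): %s",
                 paste(miss, collapse = ", ")))
  b <- object$coefficients
  m <- as.matrix(newdata[, colnames(object$x), drop = FALSE])
  unname(drop(b[1] + m %*% b[-1]))
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)`, where `R2_j` comes from regressing descriptor
#' `j` on all the others (with intercept). Perfectly collinear columns give
#' `Inf`.
#'
#' @param x Data frame or matrix of descriptor values with at least two
#'   columns.
#' @return Named numeric vector of VIFs (each `>= 1`).
#' @export
vif <- function(x) {
  x <- as.data.frame(x, check.names = FALSE)
  stopifnot(ncol(x) >= 2, all(vapply(x, is.numeric, logical(1))))
  out <- vapply(seq_along(x), function(jc) {
    fit <- stats::lm(x[[jc]] ~ ., data = x[, -jc, drop = FALSE])
    res <- stats::residuals(fit)
    sst <- sum((x[[jc]] - mean(x[[jc]]))^2)
    if (sst <= 0) return(Inf)  # constant column: undefined, flag as infinite
    r2 <- 1 - sum(res^2) / sst
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  stats::setNames(out, colnames(x))
}

#' Bidirectional stepwise descriptor selection on partial t-test p-values
#'
#' Classic p-value-driven stepwise regression: at each round the candidate
#' descriptor with the smallest addition p-value enters if it is below
#' `p_enter`; included descriptors whose p-value rises above `p_remove` are
#' then removed (worst first). Ties are broken by column order, so the
#' procedure is deterministic.
#'
#' @param x Data frame of candidate descriptors.
#' @param y Numeric response.
#' @param p_enter P-value threshold to enter (default 0.05).
#' @param p_remove P-value threshold to remove (default 0.10);
#'   must be `>= p_enter` to avoid cycling.
#' @param max_terms Upper bound on selected descriptors (default keeps
#'   `n - 2` degrees of freedom free).
#' @return List with `selected` (character vector, in order of entry) and
#'   `trace` (data frame of `step`, `action`, `term`, `p_value`).
#' @export
stepwise_select <- function(x, y, p_enter = 0.05, p_remove = 0.10,
                            max_terms = NULL) {
  x <- as.data.frame(x, check.names = FALSE)
  stopifnot(ncol(x) >= 1, nrow(x) == length(y), p_enter > 0, p_enter < 1,
            p_remove >= p_enter, p_remove < 1)
  if (is.null(max_terms)) max_terms <- max(1L, nrow(x) - 3L)
  selected <- character()
  trace <- data.frame(step = integer(), action = character(),
                      term = character(), p_value = numeric())
  step_no <- 0L
  term_p <- function(cols) {
    # p-values of each term in the model y ~ cols
    f <- fit_p_values(x[, cols, drop = FALSE], y)
    f
  }
  repeat {
    step_no <- step_no + 1L
    candidates <- setdiff(colnames(x), selected)
    added <- FALSE
    if (length(candidates) && length(selected) < max_terms) {
      pv <- vapply(candidates, function(cand) {
        p <- term_p(c(selected, cand))
        p[[cand]]
      }, numeric(1))
      best <- which.min(pv)
      if (is.finite(pv[best]) && pv[best] < p_enter) {
        selected <- c(selected, candidates[best])
        trace <- rbind(trace, data.frame(step = step_no, action = "add",
                                         term = candidates[best],
                                         p_value = unname(pv[best])))
        added <- TRUE
      }
    }
    # backward pass
    repeat {
      if (length(selected) < 1L) break
      pv <- term_p(selected)
      worst <- which.max(pv)
      if (pv[worst] > p_remove) {
        trace <- rbind(trace, data.frame(step = step_no, action = "remove",
                                         term = selected[worst],
                                         p_value = unname(pv[worst])))
        selected <- selected[-worst]
      } else break
    }
    if (!added) break
  }
  list(selected = selected, trace = trace)
}

# per-term p-values of the OLS fit y ~ x (helper for stepwise_select;
# Inf degrees of freedom or singular designs yield NA)
fit_p_values <- function(x, y) {
  d <- cbind(.y = y, x)
  fit <- stats::lm(.y ~ ., data = d)
  cf <- summary(fit)$coefficients
  out <- rep(NA_real_, ncol(x))
  names(out) <- colnames(x)
  rn <- rownames(cf)[-1]
  # lm backticks non-syntactic names in coefficient rows
  rn <- gsub("^`|`$", "", rn)
  out[rn] <- cf[-1, "Pr(>|t|)"]
  out
}

#' Leave-one-out cross-validated Q2
#'
#' `Q2_LOO = 1 - PRESS / SST`, with PRESS computed through the hat-matrix
#' shortcut `e_i / (1 - h_ii)` (algebraically identical to refitting the
#' model `n` times, each time predicting the held-out compound).
#'
#' @param fit An `mlr_fit`.
#' @return A single numeric value (`<= 1`; can be negative for models that
#'   predict worse than the training mean).
#' @export
q2_loo <- function(fit) {
  stopifnot(inherits(fit, "mlr_fit"))
  if (fit$n <= fit$k + 2) stop("need n > k + 2 for leave-one-out validation")
  h <- stats::lm.influence(fit$lm, do.coef = FALSE)$hat
  if (any(h >= 1 - 1e-10))
    stop(errorCondition(
      "leave-one-out undefined: a compound has leverage 1 (its removal makes the fit singular)",
      class = c("mpqsar_loo_undefined", "error", "condition")))
  press <- sum((fit$residuals / (1 - h))^2)
  sst <- sum((fit$y - mean(fit$y))^2)
  1 - press / sst
}

#' External validation statistics
#'
#' Evaluates a trained model on held-out compounds. `q2_ext` follows the F1
#' convention, `1 - sum((yhat - y)^2) / sum((y - mean(y_train))^2)`; the F2
#' variant (validation-set mean in the denominator) is available via
#' `variant = "F2"`. `r2_ext` is the squared Pearson correlation between
#' predicted and observed values, and `rmse_v` the root mean square
#' prediction error over the validation rows.
#'
#' @param fit An `mlr_fit`.
#' @param x Validation descriptor data frame.
#' @param y Validation response vector.
#' @param variant `"F1"` (default, training mean) or `"F2"` (validation
#'   mean).
#' @return List with `q2_ext`, `r2_ext`, `rmse_v` and `n_validation`.
#'   `r2_ext` is `NA` (with a warning) when the validation response has zero
#'   variance.
#' @export
q2_ext <- function(fit, x, y, variant = c("F1", "F2")) {
  stopifnot(inherits(fit, "mlr_fit"), length(y) >= 1, nrow(x) == length(y))
  variant <- match.arg(variant)
  pred <- stats::predict(fit, x)
  centre <- if (variant == "F1") mean(fit$y) else mean(y)
  denom <- sum((y - centre)^2)
  q2 <- if (denom <= 0) NA_real_ else 1 - sum((pred - y)^2) / denom
  r2 <- if (length(y) >= 2 && stats::sd(y) > 0 && stats::sd(pred) > 0)
    stats::cor(pred, y)^2
  else {
    warning("validation response or predictions have zero variance; r2_ext undefined")
    NA_real_
  }
  list(q2_ext = q2, r2_ext = r2,
       rmse_v = sqrt(mean((pred - y)^2)), n_validation = length(y))
}

#' y-randomization test
#'
#' Refits the model after randomly permuting the response and collects the
#' permuted-R2 distribution. A real structure-activity relationship should
#' give permuted R2 values far below the original fit; the null expectation
#' is about `k / (n - 1)`.
#'
#' @param x Descriptor data frame.
#' @param y Response vector.
#' @param n_perm Number of permutations (default 100).
#' @param seed Integer seed; the permutation stream is a pure function of it.
#' @param perms Optional list of explicit permutations (integer vectors),
#'   overriding the random ones (used for degenerate controls).
#' @return List with `r_squared` (vector of length `n_perm`), `mean`, `min`,
#'   `max`, `n_perm` and `seed`.
#' @export
y_randomize <- function(x, y, n_perm = 100, seed = 1, perms = NULL) {
  x <- as.data.frame(x, check.names = FALSE)
  stopifnot(nrow(x) == length(y), n_perm >= 1)
  if (is.null(perms))
    perms <- with_seed(seed, lapply(seq_len(n_perm),
                                    function(idx) sample.int(length(y))))
  stopifnot(length(perms) == n_perm)
  xm <- cbind(1, as.matrix(x))
  r2 <- vapply(perms, function(p) {
    yp <- y[p]
    res <- stats::residuals(stats::lm.fit(xm, yp))
    1 - sum(res^2) / sum((yp - mean(yp))^2)
  }, numeric(1))
  list(r_squared = r2, mean = mean(r2), min = min(r2), max = max(r2),
       n_perm = n_perm, seed = seed)
}
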