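# Leverage-based applicability domain: hat-matrix leverages, warning
# leverage, standardized residuals and the Williams-plot table.

#' Hat-matrix leverages
#'
#' Leverage of each compound with respect to a training design:
#' `h_i = x_i' (X'X)^-1 x_i`, with an intercept column included. Query rows
#' are evaluated against the training `X'X`, so their leverage may exceed 1.
#'
#' @param x_train Data frame or matrix of training descriptor values.
#' @param x_query Optional data frame of query rows (same columns). When
#'   supplied, the returned values are the query leverages.
#' @return Numeric vector of leverages: training values if `x_query` is
#'   `NULL`, query values otherwise.
#' @export
leverages <- function(x_train, x_query = NULL) {
  xt <- cbind(1, as.matrix(x_train))
  xtx <- crossprod(xt)
  inv <- tryCatch(solve(xtx), error = function(e)
    stop(errorCondition("training design is singular; leverages undefined",
                        class = c("mpqsar_singular", "error", "condition"))))
  xq <- if (is.null(x_query)) xt else {
    x_query <- as.data.frame(x_query, check.names = FALSE)
    cols <- colnames(as.data.frame(x_train, check.names = FALSE))
    miss <- setdiff(cols, colnames(x_query))
    if (length(miss))
      stop(sprintf("query rows are missing descriptor(s): %s",
                   paste(miss, collapse = ", ")))
    cbind(1, as.matrix(x_query[, cols, drop = FALSE]))
  }
  unname(rowSums((xq %*% inv) * xq))
}

#' Warning leverage h*
#'
#' The conventional applicability-domain threshold `3 (k + 1) / n`, where
#' `k` is the number of descriptors and `n` the number of training
#' compounds.
#'
#' @param k Number of descriptors.
#' @param n Number of training compounds.
#' @param rounded Round to two decimals for display (default `FALSE`).
#' @return A single numeric value.
#' @examples
#' warning_leverage(4, 43, rounded = TRUE)   # 0.35
#' @export
warning_leverage <- function(k, n, rounded = FALSE) {
  stopifnot(n > 0, k >= 0)
  h <- 3 * (k + 1) / n
  if (rounded) round(h, 2) else h
}

#' Standardized residuals
#'
#' Residuals divided by the training residual standard deviation
#' `sqrt(SSE / (n - k - 1))`. Validation/query compounds (supplied through
#' `x` and `y`) are standardized on the same training scale, so the
#' conventional |delta*| > 3 outlier rule applies to both sets. A perfect
#' fit (zero residual variance) returns all-zero residuals.
#'
#' @param fit An `mlr_fit`.
#' @param x,y Optional held-out descriptors and observed responses; default
#'   is the training set.
#' @return Numeric vector of standardized residuals.
#' @export
standardized_residuals <- function(fit, x = NULL, y = NULL) {
  stopifnot(inherits(fit, "mlr_fit"))
  res <- if (is.null(x)) fit$residuals else {
    stopifnot(!is.null(y), nrow(x) == length(y))
    y - stats::predict(fit, x)
  }
  # numerically perfect fits have no residual scale; return zeros
  if (fit$sigma <= 1e-8 * max(1, stats::sd(fit$y))) return(rep(0, length(res)))
  unname(res / fit$sigma)
}

#' Applicability-domain report
#'
#' Assembles, for every training, validation and query compound, the
#' leverage `h`, the standardized residual `delta_star` and the flags used
#' to read a Williams plot:
#'
#' * `outlier` - |delta*| > 3: response poorly described by the model;
#' * `high_leverage` - `h > h*`: for a training compound this marks a strong
#'   influence on the fitted model, for a validation/query compound it marks
#'   a prediction that extrapolates beyond the training domain.
#'
#' @param fit An `mlr_fit` trained on the model's training set.
#' @param x_valid,y_valid Optional validation descriptors and responses.
#' @param x_query Optional query descriptors (no response; `delta_star` is
#'   `NA` and only the leverage flag is meaningful).
#' @param ids,ids_valid,ids_query Optional compound identifiers.
#' @return An object of class `ad_report`: a data frame with columns `id`,
#'   `set`, `h`, `delta_star`, `outlier`, `high_leverage`, with the warning
#'   leverage in attribute `h_star` (raw) and `h_star_rounded`.
#' @export
ad_report <- function(fit, x_valid = NULL, y_valid = NULL, x_query = NULL,
                      ids = NULL, ids_valid = NULL, ids_query = NULL) {
  stopifnot(inherits(fit, "mlr_fit"))
  h_star <- warning_leverage(fit$k, fit$n)
  mk <- function(id, set, h, ds)
    data.frame(id = id, set = set, h = h, delta_star = ds,
               outlier = !is.na(ds) & abs(ds) > 3,
               high_leverage = h > h_star, stringsAsFactors = FALSE)
  if (is.null(ids)) ids <- paste0("train_", seq_len(fit$n))
  out <- mk(ids, "training", leverages(fit$x), standardized_residuals(fit))
  if (!is.null(x_valid)) {
    if (is.null(ids_valid)) ids_valid <- paste0("valid_", seq_len(nrow(x_valid)))
    out <- rbind(out, mk(ids_valid, "validation",
                         leverages(fit$x, x_valid),
                         standardized_residuals(fit, x_valid, y_valid)))
  }
  if (!is.null(x_query)) {
    if (is.null(ids_query)) ids_query <- paste0("query_", seq_len(nrow(x_query)))
    out <- rbind(out, mk(ids_query, "query", leverages(fit$x, x_query),
                         NA_real_))
  }
  rownames(out) <- NULL
  structure(out, h_star = h_star, h_star_rounded = round(h_star, 2),
            class = c("ad_report", "data.frame"))
}

#' Williams-plot table
#'
#' Flattens an [ad_report()] into a plain plotting table with the guide
#' values (warning leverage and the +/-3 residual band) echoed on every row,
#' so the result can be written to disk and plotted as-is.
#'
#' @param report An `ad_report`.
#' @return A plain data frame with columns `id`, `set`, `h`, `delta_star`,
#'   `outlier`, `high_leverage`, `h_star`, `delta_limit`.
#' @export
williams_data <- function(report) {
  stopifnot(inherits(report, "ad_report"))
  out <- as.data.frame(report)
  out$h_star <- attr(report, "h_star")
  out$delta_limit <- 3
  out
}
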