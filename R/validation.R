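#' Least-squares regression through the origin
#'
#' For the Golbraikh-Tropsha battery: slope `k = sum(x*y) / sum(x^2)` and
#' the through-origin determination coefficient
#' `r0^2 = 1 - sum((y - k*x)^2) / sum((y - mean(y))^2)`.
#'
#' @param x predictor vector (e.g. experimental activity).
#' @param y response vector (e.g. predicted activity).
#' @return list with `k` and `r0_sq`.
#' @export
through_origin_stats <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 points")
  sx2 <- sum(x^2)
  if (sx2 <= 0) stop("sum(x^2) must be positive")
  ssy <- sum((y - mean(y))^2)
  if (ssy <= 0) stop("y has zero variance")
  k <- sum(x * y) / sx2
  r0_sq <- 1 - sum((y - k * x)^2) / ssy
  list(k = k, r0_sq = r0_sq)
}

#' Roy's rm2 metric
#'
#' `variant = "abs"`: `r2 * (1 - |r2 - r0^2|)`.
#' `variant = "sqrt"` (Roy's published form): `r2 * (1 - sqrt(r2 - r0^2))`,
#' defined for `r0^2 <= r2`.
#'
#' @param r2 squared correlation between observed and predicted.
#' @param r0_sq through-origin determination coefficient.
#' @param variant `"sqrt"` (default) or `"abs"`.
#' @return numeric scalar.
#' @export
rm2 <- function(r2, r0_sq, variant = c("sqrt", "abs")) {
  variant <- match.arg(variant)
  if (variant == "abs") return(r2 * (1 - abs(r2 - r0_sq)))
  if (r0_sq > r2) {
    stop("sqrt variant requires r0_sq <= r2 (got r2 - r0_sq < 0)")
  }
  r2 * (1 - sqrt(r2 - r0_sq))
}

#' Flag outlier compounds by absolute residual
#'
#' @param residuals named numeric vector (experimental - predicted).
#' @param threshold absolute residual cutoff in log units (default 0.4).
#' @return character vector of flagged ids (empty when none).
#' @export
flag_outliers <- function(residuals, threshold = 0.4) {
  stopifnot(threshold > 0)
  names(residuals)[abs(residuals) > threshold]
}

#' Golbraikh-Tropsha external validation battery
#'
#' Computes every quantity of the standard external-validation test on a
#' test set: squared Pearson correlation `r2`; through-origin determination
#' coefficients and slopes in both orientations (`r0_sq`/`k`: predicted
#' regressed on experimental; `r0_prime_sq`/`k_prime`: experimental on
#' predicted); the condition verdicts (`q2 > 0.5` when supplied, `r2 > 0.6`,
#' `(r2 - r0^2)/r2 < 0.1` in either orientation, `0.85 <= k <= 1.15` in
#' either orientation, `|r0^2 - r0'^2| < 0.3`); both rm2 variants; residuals
#' and outlier flags. A PRESS-based predictive r2
#' (`1 - sum((obs - pred)^2) / sum((obs - ybar_train)^2)`) is reported as
#' `r2_pred` when a training mean is supplied.
#'
#' @param y_exp experimental activities (named by compound id if available).
#' @param y_pred predicted activities, parallel to `y_exp`.
#' @param q2 optional LOO q2 of the underlying model (condition 1).
#' @param outlier_threshold absolute-residual flag level (default 0.4).
#' @param training_mean optional training-set mean activity for `r2_pred`.
#' @return object of class `external_validation`.
#' @export
external_metrics <- function(y_exp, y_pred, q2 = NA_real_,
                             outlier_threshold = 0.4,
                             training_mean = NULL) {
  stopifnot(length(y_exp) == length(y_pred))
  if (length(y_exp) < 3L) stop("need at least 3 test compounds")
  if (stats::sd(y_exp) == 0 || stats::sd(y_pred) == 0) {
    stop("zero variance in observed or predicted activities")
  }
  ids <- names(y_exp)
  if (is.null(ids)) ids <- as.character(seq_along(y_exp))
  r2 <- stats::cor(y_exp, y_pred)^2
  fwd <- through_origin_stats(y_exp, y_pred)   # predicted on experimental
  rev <- through_origin_stats(y_pred, y_exp)   # experimental on predicted
  res <- setNames(y_exp - y_pred, ids)
  rm_abs <- rm2(r2, fwd$r0_sq, "abs")
  rm_sqrt <- if (fwd$r0_sq <= r2) rm2(r2, fwd$r0_sq, "sqrt") else NA_real_
  conditions <- data.frame(
    condition = c("q2 > 0.5", "r2 > 0.6",
                  "(r2-r0^2)/r2 < 0.1", "(r2-r0'^2)/r2 < 0.1",
                  "0.85 <= k <= 1.15", "0.85 <= k' <= 1.15",
                  "|r0^2 - r0'^2| < 0.3"),
    value = c(q2, r2,
              (r2 - fwd$r0_sq) / r2, (r2 - rev$r0_sq) / r2,
              fwd$k, rev$k,
              abs(fwd$r0_sq - rev$r0_sq)),
    pass = c(isTRUE(q2 > 0.5), r2 > 0.6,
             (r2 - fwd$r0_sq) / r2 < 0.1, (r2 - rev$r0_sq) / r2 < 0.1,
             fwd$k >= 0.85 && fwd$k <= 1.15, rev$k >= 0.85 && rev$k <= 1.15,
             abs(fwd$r0_sq - rev$r0_sq) < 0.3),
    stringsAsFactors = FALSE)
  out <- list(r2 = r2, r0_sq = fwd$r0_sq, r0_prime_sq = rev$r0_sq,
              k = fwd$k, k_prime = rev$k,
              rm_sq_abs = rm_abs, rm_sq_sqrt = rm_sqrt,
              q2 = q2, conditions = conditions,
              residuals = res,
              outlier_ids = flag_outliers(res, outlier_threshold),
              n = length(y_exp))
  if (!is.null(training_mean)) {
    out$r2_pred <- 1 - sum((y_exp - y_pred)^2) /
      sum((y_exp - training_mean)^2)
  }
  class(out) <- "external_validation"
  out
}

#' @export
print.external_validation <- function(x, ...) {
  cat("<external_validation> n =", x$n, "\n")
  cat(sprintf("  r2 = %.3f  r0^2 = %.3f  r0'^2 = %.3f  k = %.3f  k' = %.3f\n",
              x$r2, x$r0_sq, x$r0_prime_sq, x$k, x$k_prime))
  cat(sprintf("  rm2(sqrt) = %.3f  rm2(abs) = %.3f\n",
              x$rm_sq_sqrt, x$rm_sq_abs))
  cat("  conditions passed:", sum(x$conditions$pass), "/",
      nrow(x$conditions), "\n")
  if (length(x$outlier_ids)) {
    cat("  outliers:", paste(x$outlier_ids, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Validate a fitted model on its test set
#'
#' Runs [external_metrics()] on a `qsar_model`'s test predictions, both with
#' all test compounds and with flagged outliers excluded (the conventional
#' reporting for condition tables), and labels which is which.
#'
#' @param model a fitted `qsar_model` with a test set.
#' @param outlier_threshold absolute residual cutoff (default 0.4 log units).
#' @return list: `all` and `without_outliers` (`external_validation`
#'   objects; identical when no outlier is flagged), `outlier_ids`.
#' @export
validate_model <- function(model, outlier_threshold = 0.4) {
  if (is.null(model$test_predictions)) stop("model has no test set")
  obs <- model$test_observed
  pred <- model$test_predictions
  full <- external_metrics(obs, pred, q2 = model$q2,
                           outlier_threshold = outlier_threshold,
                           training_mean = model$summary$training_mean)
  keep <- setdiff(names(obs), full$outlier_ids)
  trimmed <- if (length(keep) < length(obs)) {
    external_metrics(obs[keep], pred[keep], q2 = model$q2,
                     outlier_threshold = outlier_threshold,
                     training_mean = model$summary$training_mean)
  } else full
  list(all = full, without_outliers = trimmed,
       outlier_ids = full$outlier_ids)
}

#' Condition-table report for one or more validated models
#'
#' @param ... named `external_validation` objects (one column per model).
#' @return data.frame: condition id, parameter, threshold, one value column
#'   and one verdict column per model.
#' @export
validation_report <- function(...) {
  reports <- list(...)
  stopifnot(length(reports) >= 1)
  if (is.null(names(reports)) || any(!nzchar(names(reports)))) {
    names(reports) <- paste0("model_", seq_along(reports))
  }
  base <- data.frame(
    condition = c("1", "2", "3a", "3b", "4a", "4b", "5a", "5b", "6",
                  "7", "7b"),
    parameter = c("q2", "r2", "r0^2", "r0'^2", "k", "k'",
                  "(r2-r0^2)/r2", "(r2-r0'^2)/r2", "|r0^2-r0'^2|",
                  "rm2 (sqrt)", "rm2 (abs)"),
    threshold = c("> 0.5", "> 0.6", "close to r2", "close to r2",
                  "0.85 - 1.15", "0.85 - 1.15", "< 0.1", "< 0.1", "< 0.3",
                  "> 0.5", "> 0.5"),
    stringsAsFactors = FALSE)
  for (nm in names(reports)) {
    v <- reports[[nm]]
    base[[nm]] <- c(v$q2, v$r2, v$r0_sq, v$r0_prime_sq, v$k, v$k_prime,
                    (v$r2 - v$r0_sq) / v$r2, (v$r2 - v$r0_prime_sq) / v$r2,
                    abs(v$r0_sq - v$r0_prime_sq),
                    v$rm_sq_sqrt, v$rm_sq_abs)
  }
  base
}
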