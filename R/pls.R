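# fast column standard deviations (denominator n - 1)
.col_sds <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  sqrt(pmax(colSums(x^2) - n * mu^2, 0) / (n - 1))
}

#' Drop low-variance descriptor columns
#'
#' Removes columns whose standard deviation over the training rows (in the
#' column's native units) falls below `threshold`. This is the CoMFA/CoMSIA
#' "column filter" used to reduce noise before PLS; the conventional value
#' is 2.0 kcal/mol.
#'
#' @param dm a `descriptor_matrix`.
#' @param threshold non-negative standard-deviation cutoff.
#' @param train_idx indices of training rows used to measure the sd.
#' @return list: `matrix` (the filtered `descriptor_matrix`) and
#'   `dropped` (integer indices of removed columns).
#' @export
filter_columns <- function(dm, threshold = 2.0,
                           train_idx = seq_len(nrow(dm$x))) {
  stopifnot(threshold >= 0)
  sds <- .col_sds(dm$x[train_idx, , drop = FALSE])
  drop <- unname(which(sds < threshold))
  if (length(drop) == ncol(dm$x)) {
    stop("column filter removed every column; lower the threshold")
  }
  keep <- setdiff(seq_len(ncol(dm$x)), drop)
  out <- dm
  out$x <- dm$x[, keep, drop = FALSE]
  out$column_meta <- dm$column_meta[keep, , drop = FALSE]
  rownames(out$column_meta) <- NULL
  list(matrix = out, dropped = drop)
}

#' Block-scale a descriptor matrix (CoMFA-STD)
#'
#' Each field block is divided by the standard deviation of all its training
#' entries, equalizing the a-priori influence of the blocks on the PLS fit.
#'
#' @param dm a `descriptor_matrix`.
#' @param scaling `"comfa_std"` or `"none"`.
#' @param train_idx training rows used to measure block sds.
#' @return the scaled `descriptor_matrix`; block sds kept in
#'   attribute `"block_sd"`.
#' @export
scale_blocks <- function(dm, scaling = c("comfa_std", "none"),
                         train_idx = seq_len(nrow(dm$x))) {
  scaling <- match.arg(scaling)
  if (scaling == "none") return(dm)
  types <- unique(dm$column_meta$field_type)
  bsd <- setNames(numeric(length(types)), types)
  for (ft in types) {
    cols <- which(dm$column_meta$field_type == ft)
    s <- stats::sd(as.vector(dm$x[train_idx, cols, drop = FALSE]))
    if (!is.finite(s) || s == 0) s <- 1
    bsd[ft] <- s
    dm$x[, cols] <- dm$x[, cols, drop = FALSE] / s
  }
  attr(dm, "block_sd") <- bsd
  dm
}

#' Fit a PLS1 regression (NIPALS)
#'
#' Latent-variable regression of a single response on a (typically wide,
#' collinear) descriptor matrix. Columns are mean-centred; no per-column
#' scaling is applied (block scaling, if any, happens upstream). The
#' deflation loop is the classical NIPALS PLS1 and is fully deterministic.
#'
#' @param X numeric matrix (n x p).
#' @param y numeric response vector, length n.
#' @param ncomp number of latent components; at most `min(n - 1, p)`.
#' @return object of class `pls_fit` with `coefficients` (length p, original
#'   column space), `intercept`, `ncomp`, `fitted`, `x_mean`, `y_mean`,
#'   scores/loadings.
#' @export
pls_fit <- function(X, y, ncomp) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n)
  if (ncomp < 1 || ncomp > min(n - 1, p)) {
    stop("ncomp must be between 1 and min(n - 1, p) = ", min(n - 1, p))
  }
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  E <- sweep(X, 2, x_mean)
  f <- y - y_mean
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); q <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {         # residual X carries no covariance with y
      ncomp <- a - 1L
      if (ncomp == 0L) stop("X has no covariance with y; cannot fit")
      W <- W[, seq_len(ncomp), drop = FALSE]
      P <- P[, seq_len(ncomp), drop = FALSE]
      Tm <- Tm[, seq_len(ncomp), drop = FALSE]
      q <- q[seq_len(ncomp)]
      break
    }
    w <- w / nw
    t <- as.vector(E %*% w)
    tt <- sum(t^2)
    pvec <- as.vector(crossprod(E, t)) / tt
    qa <- sum(f * t) / tt
    E <- E - tcrossprod(t, pvec)
    f <- f - qa * t
    W[, a] <- w; P[, a] <- pvec; Tm[, a] <- t; q[a] <- qa
  }
  beta <- W %*% solve(crossprod(P, W), q)
  intercept <- y_mean - sum(x_mean * beta)
  fitted <- as.vector(X %*% beta) + intercept
  structure(list(coefficients = as.vector(beta), intercept = intercept,
                 ncomp = ncomp, fitted = fitted,
                 x_mean = x_mean, y_mean = y_mean,
                 scores = Tm, loadings = P, weights = W, q = q),
            class = "pls_fit")
}

# coefficient vector (original column space) truncated to the first a
# components of a fitted pls_fit; NIPALS components are nested, so this
# equals refitting with ncomp = a.
.pls_coef_at <- function(fit, a) {
  W <- fit$weights[, seq_len(a), drop = FALSE]
  P <- fit$loadings[, seq_len(a), drop = FALSE]
  beta <- W %*% solve(crossprod(P, W), fit$q[seq_len(a)])
  intercept <- fit$y_mean - sum(fit$x_mean * beta)
  list(beta = as.vector(beta), intercept = intercept)
}

#' Predict from a PLS fit
#' @param object a `pls_fit`.
#' @param newdata matrix with the same columns the model was fitted on.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.pls_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$coefficients)) {
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         length(object$coefficients))
  }
  as.vector(newdata %*% object$coefficients) + object$intercept
}

# one preprocessing + fit + predict round used by the LOO loop:
# filtering and block scaling are recomputed on the fold's training rows.
.fit_fold <- function(dm, y, train_rows, ncomp, filter_threshold, scaling) {
  flt <- filter_columns(dm, filter_threshold, train_idx = train_rows)
  scl <- scale_blocks(flt$matrix, scaling, train_idx = train_rows)
  ncomp_eff <- min(ncomp, length(train_rows) - 1L, ncol(scl$x))
  fit <- pls_fit(scl$x[train_rows, , drop = FALSE], y[train_rows], ncomp_eff)
  list(fit = fit, x = scl$x, filtered = flt, scaled = scl)
}

#' Leave-one-out cross-validation q2 and SEP
#'
#' For each candidate component count N, every compound is predicted by a
#' model refitted on the remaining training compounds, with column filtering
#' and block scaling recomputed inside each fold. Then
#' `q2 = 1 - PRESS / sum((y - ybar)^2)` with `ybar` the full training-set
#' mean, and `SEP = sqrt(PRESS / (n - N - 1))`. The optimal N maximizes q2
#' (ties to the smaller N), restricted to N <= floor(n/3) so that components
#' stay well below one-third of the number of compounds.
#'
#' @param dm a `descriptor_matrix` of the training set.
#' @param y training activities (pEC50).
#' @param max_components largest N to scan; must be < n - 1.
#' @param filter_threshold column filter sd cutoff (default 2.0).
#' @param scaling `"comfa_std"` (default) or `"none"`.
#' @return list: `per_component` (data.frame N, q2, sep), `optimal_n`,
#'   `q2` and `sep` at the optimum, and `loo_predictions` at the optimum.
#' @export
loo_q2 <- function(dm, y, max_components = 10, filter_threshold = 2.0,
                   scaling = c("comfa_std", "none")) {
  scaling <- match.arg(scaling)
  n <- nrow(dm$x)
  if (n < 3L) stop("need at least 3 rows for leave-one-out")
  if (max_components >= n - 1) {
    stop("max_components must be smaller than n - 1 = ", n - 1)
  }
  ybar <- mean(y)
  ss_tot <- sum((y - ybar)^2)
  preds <- matrix(NA_real_, n, max_components)
  for (i in seq_len(n)) {
    train <- setdiff(seq_len(n), i)
    fold <- .fit_fold(dm, y, train, max_components, filter_threshold, scaling)
    xi <- fold$x[i, , drop = FALSE]
    for (N in seq_len(max_components)) {
      if (N > fold$fit$ncomp) {   # fold ran out of usable components
        preds[i, N] <- preds[i, fold$fit$ncomp]
        next
      }
      cf <- .pls_coef_at(fold$fit, N)
      preds[i, N] <- as.vector(xi %*% cf$beta) + cf$intercept
    }
  }
  press <- colSums((y - preds)^2)
  q2 <- 1 - press / ss_tot
  sep <- sqrt(press / (n - seq_len(max_components) - 1))
  per <- data.frame(N = seq_len(max_components), q2 = q2, sep = sep)
  n_cap <- min(max_components, floor(n / 3))
  if (n_cap < 1L) n_cap <- 1L
  opt <- which.max(q2[seq_len(n_cap)])   # which.max takes the first maximum
  list(per_component = per, optimal_n = opt,
       q2 = q2[opt], sep = sep[opt], loo_predictions = preds[, opt])
}

#' Internal (non-cross-validated) model statistics
#'
#' Fits the final PLS model at N components on the full training set and
#' reports the conventional internal statistics: `SEE = sqrt(RSS/(n-N-1))`,
#' `r2_ncv = 1 - RSS/TSS`, `F = (r2_ncv/N) / ((1-r2_ncv)/(n-N-1))`, and the
#' per-field contribution percentages (sum over each block of
#' |coefficient| * column sd, normalized across blocks).
#'
#' @param dm training `descriptor_matrix` (unfiltered, unscaled).
#' @param y training activities.
#' @param n_components N, e.g. the optimum from [loo_q2()].
#' @param filter_threshold,scaling as in [loo_q2()].
#' @return object of class `pls_summary`: `n_components`, `see`, `r2_ncv`,
#'   `f_stat`, `field_contributions`, `coefficients`, `intercept`,
#'   `training_mean`, plus the fitted objects needed for prediction
#'   (`fit`, `kept_columns`, `block_sd`, `column_meta`).
#' @export
summarize_model <- function(dm, y, n_components, filter_threshold = 2.0,
                            scaling = c("comfa_std", "none")) {
  scaling <- match.arg(scaling)
  n <- nrow(dm$x)
  if (n - n_components - 1 <= 0) stop("n - N - 1 must be positive")
  fold <- .fit_fold(dm, y, seq_len(n), n_components, filter_threshold, scaling)
  fit <- fold$fit
  rss <- sum((y - fit$fitted)^2)
  tss <- sum((y - mean(y))^2)
  r2_ncv <- 1 - rss / tss
  see <- sqrt(rss / (n - fit$ncomp - 1))
  f_stat <- (r2_ncv / fit$ncomp) / ((1 - r2_ncv) / (n - fit$ncomp - 1))
  meta <- fold$scaled$column_meta
  sds <- apply(fold$x, 2, stats::sd)
  contrib_raw <- tapply(abs(fit$coefficients) * sds, meta$field_type, sum)
  contrib <- contrib_raw / sum(contrib_raw)
  structure(list(n_components = fit$ncomp, see = see, r2_ncv = r2_ncv,
                 f_stat = f_stat,
                 field_contributions = contrib[unique(meta$field_type)],
                 coefficients = fit$coefficients, intercept = fit$intercept,
                 training_mean = mean(y), fit = fit,
                 kept_columns = setdiff(seq_len(ncol(dm$x)), fold$filtered$dropped),
                 block_sd = attr(fold$scaled, "block_sd"),
                 column_meta = meta, fitted = fit$fitted),
            class = "pls_summary")
}

#' @export
print.pls_summary <- function(x, ...) {
  cat("<pls_summary> N =", x$n_components,
      " r2_ncv =", round(x$r2_ncv, 3),
      " SEE =", round(x$see, 3),
      " F =", round(x$f_stat, 1), "\n")
  fc <- round(100 * x$field_contributions, 1)
  cat("  field contributions (%):",
      paste(names(fc), fc, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Predict activities for new descriptor rows
#'
#' Applies the stored column filter and block scaling of a fitted model
#' summary, then scores the PLS regression.
#'
#' @param summary a `pls_summary` from [summarize_model()].
#' @param dm_new `descriptor_matrix` of query compounds, built on the same
#'   grid and fields (full column set, pre-filtering).
#' @return numeric vector of predicted activities.
#' @export
predict_activity <- function(summary, dm_new) {
  X <- dm_new$x
  if (ncol(X) < max(summary$kept_columns)) {
    stop("query descriptor matrix does not contain the model's columns")
  }
  X <- X[, summary$kept_columns, drop = FALSE]
  if (!is.null(summary$block_sd)) {
    for (ft in names(summary$block_sd)) {
      cols <- which(summary$column_meta$field_type == ft)
      X[, cols] <- X[, cols, drop = FALSE] / summary$block_sd[ft]
    }
  }
  predict(summary$fit, X)
}
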