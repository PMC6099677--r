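#' Standardize query descriptors against training statistics
#'
#' The standardization-approach applicability domain works on
#' `S_ik = |x_ik - mean_i(train)| / sd_i(train)` for descriptor i and
#' compound k. Columns with zero training standard deviation are dropped
#' with a warning.
#'
#' @param x_train training descriptor matrix (>= 2 rows).
#' @param x_query query descriptor matrix with the same columns.
#' @return matrix of standardized absolute deviations (rows = query
#'   compounds).
#' @export
standardize_descriptors <- function(x_train, x_query) {
  x_train <- as.matrix(x_train)
  x_query <- as.matrix(x_query)
  if (nrow(x_train) < 2L) stop("need at least 2 training rows")
  if (ncol(x_train) != ncol(x_query)) {
    stop("training and query matrices must share columns")
  }
  mu <- colMeans(x_train)
  sds <- .col_sds(x_train)
  zero <- sds == 0
  if (any(zero)) {
    warning(sum(zero), " descriptor(s) with zero training sd dropped")
    x_query <- x_query[, !zero, drop = FALSE]
    mu <- mu[!zero]
    sds <- sds[!zero]
  }
  if (!length(mu)) stop("no descriptor with positive training sd")
  S <- abs(sweep(x_query, 2, mu)) / rep(sds, each = nrow(x_query))
  rownames(S) <- rownames(x_query)
  S
}

#' Classify compounds as inside/outside the applicability domain
#'
#' Standardization-approach decision rule per compound k:
#' if `max(S_k) <= 3` the compound is inside; if additionally `min(S_k) >= 3`
#' it is outside; otherwise `S_new = mean(S_k) + 1.28 * sd(S_k)` decides
#' (inside iff `S_new <= 3`). The sample (n-1) standard deviation is the
#' default; set `sd_type = "population"` for the n-denominator variant.
#'
#' @param S matrix from [standardize_descriptors()] (or a single numeric
#'   vector for one compound).
#' @param sd_type `"sample"` (default) or `"population"` sd for `S_new`.
#' @return data.frame: `compound_id`, `s_max`, `s_min`, `s_new` (NA when the
#'   S_new branch is not taken), `status` (`"inside"`/`"outside"`).
#' @export
classify_ad <- function(S, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (is.vector(S)) S <- matrix(S, nrow = 1)
  if (!ncol(S)) stop("empty descriptor vector")
  ids <- rownames(S)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(S)))
  out <- lapply(seq_len(nrow(S)), function(k) {
    s <- S[k, ]
    s_max <- max(s); s_min <- min(s)
    s_new <- NA_real_
    if (s_max <= 3) {
      status <- "inside"
    } else if (s_min >= 3) {
      status <- "outside"
    } else {
      sdev <- stats::sd(s)
      if (sd_type == "population") sdev <- sdev * sqrt((length(s) - 1) / length(s))
      s_new <- mean(s) + 1.28 * sdev
      status <- if (s_new <= 3) "inside" else "outside"
    }
    data.frame(compound_id = ids[k], s_max = s_max, s_min = s_min,
               s_new = s_new, status = status, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Applicability-domain report for a fitted model
#'
#' Standardizes the query compounds' retained descriptors against the
#' model's training rows and classifies each query compound.
#'
#' @param model a `qsar_model`.
#' @param query_idx row indices of the model's descriptor matrix to
#'   classify (default: the test rows).
#' @param sd_type passed to [classify_ad()].
#' @return data.frame as from [classify_ad()].
#' @export
ad_report <- function(model, query_idx = model$test_idx,
                      sd_type = "sample") {
  keep <- model$summary$kept_columns
  x_train <- model$descriptors$x[model$train_idx, keep, drop = FALSE]
  x_query <- model$descriptors$x[query_idx, keep, drop = FALSE]
  S <- suppressWarnings(standardize_descriptors(x_train, x_query))
  classify_ad(S, sd_type = sd_type)
}
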