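#' Enumerate field combinations for a method
#'
#' All non-empty subsets of the field universe, in deterministic order
#' (increasing subset size, then lexicographic in the canonical S, E, H, D,
#' A letter order). CoMFA draws from \{S, E\} (3 combinations), CoMSIA from
#' \{S, E, H, D, A\} (31 combinations).
#'
#' @param method `"comfa"` or `"comsia"`.
#' @param fields_universe override of the field universe (letter vector).
#' @return list of character vectors of field letters.
#' @export
enumerate_models <- function(method = c("comfa", "comsia"),
                             fields_universe = NULL) {
  method <- match.arg(method)
  if (is.null(fields_universe)) {
    fields_universe <- if (method == "comfa") c("S", "E") else
      c("S", "E", "H", "D", "A")
  }
  if (!length(fields_universe)) stop("field universe must be non-empty")
  canon <- c("S", "E", "H", "D", "A")
  u <- canon[canon %in% fields_universe]
  out <- list()
  for (k in seq_along(u)) {
    combos <- utils::combn(u, k, simplify = FALSE)
    out <- c(out, combos)
  }
  out
}

#' Rank fitted models by the selection rule
#'
#' Models with `q2 <= threshold` (default 0.5) are flagged ineligible.
#' Eligible models are ordered by test-set r2 (descending), ties broken by
#' q2 (descending); ineligible models follow, in the same ordering.
#'
#' @param summaries data.frame with columns `model`, `q2`, `r2_test` (e.g.
#'   rbind-ed [model_report()] rows).
#' @param q2_threshold eligibility cutoff on q2 (default 0.5, exclusive).
#' @return the data.frame re-ordered, with logical column `eligible` and
#'   integer column `rank` (NA for ineligible models).
#' @export
rank_models <- function(summaries, q2_threshold = 0.5) {
  stopifnot(is.data.frame(summaries), nrow(summaries) >= 1,
            all(c("model", "q2", "r2_test") %in% names(summaries)))
  eligible <- summaries$q2 > q2_threshold
  ord <- order(!eligible, -summaries$r2_test, -summaries$q2,
               summaries$model)
  out <- summaries[ord, , drop = FALSE]
  out$eligible <- eligible[ord]
  out$rank <- NA_integer_
  out$rank[out$eligible] <- seq_len(sum(out$eligible))
  rownames(out) <- NULL
  out
}

#' Fit every field combination and rank the models
#'
#' Exhaustive model search: fits [qsar_model()] for each combination from
#' [enumerate_models()] on a shared grid, collects the one-row reports and
#' ranks them with [rank_models()].
#'
#' @param dataset an [aligned_dataset()].
#' @param method `"comfa"` or `"comsia"`.
#' @param combinations optional list of field-letter vectors (defaults to
#'   the full enumeration).
#' @param ... passed to [qsar_model()].
#' @return list: `table` (ranked report data.frame), `models` (named list of
#'   `qsar_model` objects).
#' @export
select_models <- function(dataset, method = c("comfa", "comsia"),
                          combinations = NULL, ...) {
  method <- match.arg(method)
  if (is.null(combinations)) combinations <- enumerate_models(method)
  grid <- build_grid(dataset$molecules)
  models <- lapply(combinations, function(fl) {
    qsar_model(dataset, method = method, fields = fl, grid = grid, ...)
  })
  names(models) <- vapply(combinations, paste, character(1), collapse = "")
  tab <- do.call(rbind, lapply(models, model_report))
  list(table = rank_models(tab), models = models)
}
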