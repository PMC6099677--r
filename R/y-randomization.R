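#' Y-randomization (response permutation) robustness test
#'
#' Shuffles the activity vector, refits the PLS model (including the full
#' leave-one-out cross-validation) on the original descriptor matrix, and
#' records per-iteration q2 and r2_ncv. A genuine structure-activity model
#' must collapse under permutation: the verdict is `pass` when every
#' randomized iteration has q2 < 0.5 and r2_ncv < 0.6.
#'
#' The component count defaults to the un-randomized model's N (re-selecting
#' N per iteration is available via `reselect_n = TRUE`).
#'
#' @param dm training `descriptor_matrix`.
#' @param y training activities.
#' @param n_components component count of the reference model.
#' @param n_iterations number of permutations (default 10).
#' @param seed master seed; per-iteration seeds are derived from it.
#' @param filter_threshold,scaling preprocessing, as in [loo_q2()].
#' @param reselect_n if `TRUE`, re-select N by LOO inside each iteration.
#' @param permutations optional list of explicit permutation index vectors
#'   (overrides the RNG; used for testing).
#' @return list: `results` (data.frame iteration, seed, q2, r2_ncv),
#'   `verdict` (`"pass"`/`"fail"`), `q2_limit`, `r2_limit`.
#' @export
y_randomize <- function(dm, y, n_components, n_iterations = 10, seed = 1L,
                        filter_threshold = 2.0,
                        scaling = c("comfa_std", "none"),
                        reselect_n = FALSE, permutations = NULL) {
  scaling <- match.arg(scaling)
  if (n_iterations < 1) stop("n_iterations must be at least 1")
  n <- nrow(dm$x)
  set.seed(as.integer(seed))
  iter_seeds <- sample.int(.Machine$integer.max, n_iterations)
  if (is.null(permutations)) {
    permutations <- lapply(iter_seeds, function(s) {
      set.seed(s)
      sample.int(n)
    })
  } else if (length(permutations) != n_iterations) {
    stop("need one permutation per iteration")
  }
  rows <- lapply(seq_len(n_iterations), function(it) {
    perm <- permutations[[it]]
    y_perm <- y[perm]
    maxc <- if (reselect_n) min(10, n - 2L) else n_components
    loo <- loo_q2(dm, y_perm, max_components = maxc,
                  filter_threshold = filter_threshold, scaling = scaling)
    N <- if (reselect_n) loo$optimal_n else n_components
    q2 <- loo$per_component$q2[N]
    summ <- summarize_model(dm, y_perm, N,
                            filter_threshold = filter_threshold,
                            scaling = scaling)
    data.frame(iteration = it, seed = iter_seeds[it],
               q2 = q2, r2_ncv = summ$r2_ncv)
  })
  results <- do.call(rbind, rows)
  verdict <- if (all(results$q2 < 0.5) && all(results$r2_ncv < 0.6)) {
    "pass"
  } else "fail"
  list(results = results, verdict = verdict,
       q2_limit = 0.5, r2_limit = 0.6)
}
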