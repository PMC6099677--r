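#' Fit a CoMFA or CoMSIA QSAR model on an aligned dataset
#'
#' End-to-end pipeline for one field combination: build the lattice over all
#' molecules, compute the requested field blocks, assemble descriptors,
#' impute masked electrostatic entries from the training rows, run
#' leave-one-out cross-validation on the training set to pick the component
#' count, fit the final model, and predict the test set.
#'
#' @param dataset an [aligned_dataset()]; atoms must carry properties
#'   (see [assign_atom_properties()]).
#' @param method `"comfa"` or `"comsia"`.
#' @param fields field letters to include: subset of `"S","E"` for CoMFA,
#'   of `"S","E","H","D","A"` for CoMSIA.
#' @param spacing,padding lattice geometry (Angstrom; defaults 2 and 4).
#' @param cutoff CoMFA truncation (kcal/mol, default 30).
#' @param alpha CoMSIA attenuation factor (default 0.3).
#' @param filter_threshold column filter sd cutoff, in the field's native
#'   units. The default (`NULL`) resolves to 2.0 for CoMFA (kcal/mol, the
#'   conventional energy-scale filter) and 0.05 for CoMSIA, whose
#'   dimensionless similarity indices are orders of magnitude smaller than
#'   field energies, so the same numeric cutoff would discard every column;
#'   0.05 prunes effectively constant lattice points.
#' @param scaling `"comfa_std"` or `"none"`.
#' @param max_components LOO scan limit (default 10, reduced when the
#'   training set is small).
#' @param grid optionally, a pre-built `grid_spec` shared across models.
#' @return object of class `qsar_model`: the `pls_summary` (`summary`), LOO
#'   results (`loo`), internal q2/SEP, test-set predictions and r2_test,
#'   plus the grid, descriptor matrix and configuration.
#' @export
qsar_model <- function(dataset, method = c("comfa", "comsia"),
                       fields = NULL, spacing = 2, padding = 4,
                       cutoff = 30, alpha = 0.3,
                       filter_threshold = NULL,
                       scaling = c("comfa_std", "none"),
                       max_components = 10, grid = NULL) {
  method <- match.arg(method)
  scaling <- match.arg(scaling)
  if (is.null(filter_threshold)) {
    filter_threshold <- if (method == "comfa") 2.0 else 0.05
  }
  universe <- if (method == "comfa") c("S", "E") else c("S", "E", "H", "D", "A")
  if (is.null(fields)) fields <- universe
  fields <- match.arg(fields, universe, several.ok = TRUE)
  if (is.null(grid)) grid <- build_grid(dataset$molecules, spacing, padding)
  train_idx <- which(dataset$roles == "train")
  test_idx <- which(dataset$roles == "test")

  blocks <- .compute_blocks(dataset$molecules, grid, method, fields,
                            cutoff, alpha)
  blocks <- lapply(blocks, impute_masked, train_idx = train_idx)
  dm <- assemble_descriptors(blocks)

  y <- dataset$activities$pec50
  dm_train <- dm
  dm_train$x <- dm$x[train_idx, , drop = FALSE]
  dm_train$row_ids <- dm$row_ids[train_idx]
  y_train <- y[train_idx]

  maxc <- min(max_components, length(train_idx) - 2L)
  loo <- loo_q2(dm_train, y_train, max_components = maxc,
                filter_threshold = filter_threshold, scaling = scaling)
  summ <- summarize_model(dm_train, y_train, loo$optimal_n,
                          filter_threshold = filter_threshold,
                          scaling = scaling)
  out <- list(method = method, fields = fields, grid = grid,
              descriptors = dm, train_idx = train_idx, test_idx = test_idx,
              loo = loo, q2 = loo$q2, sep = loo$sep,
              summary = summ,
              config = list(spacing = spacing, padding = padding,
                            cutoff = cutoff, alpha = alpha,
                            filter_threshold = filter_threshold,
                            scaling = scaling))
  if (length(test_idx)) {
    dm_test <- dm
    dm_test$x <- dm$x[test_idx, , drop = FALSE]
    pred <- predict_activity(summ, dm_test)
    out$test_predictions <- setNames(pred, dm$row_ids[test_idx])
    out$test_observed <- setNames(y[test_idx], dm$row_ids[test_idx])
    out$r2_test <- stats::cor(y[test_idx], pred)^2
  }
  class(out) <- "qsar_model"
  out
}

.field_letter_map <- c(S = "steric", E = "electrostatic", H = "hydrophobic",
                       D = "donor", A = "acceptor")

.compute_blocks <- function(molecules, grid, method, fields, cutoff, alpha) {
  if (method == "comfa") {
    blocks <- comfa_fields(molecules, grid, cutoff = cutoff)
    keep <- paste0("comfa_", .field_letter_map[fields])
    blocks[vapply(blocks, function(b) b$field_type %in% keep, logical(1))]
  } else {
    comsia_fields(molecules, grid, alpha = alpha,
                  properties = unname(.field_letter_map[fields]))
  }
}

#' @export
print.qsar_model <- function(x, ...) {
  cat("<qsar_model>", toupper(x$method), "-",
      paste(x$fields, collapse = ""), "\n")
  cat("  q2 =", round(x$q2, 3), " N =", x$summary$n_components,
      " SEP =", round(x$sep, 3), " SEE =", round(x$summary$see, 3),
      " r2_ncv =", round(x$summary$r2_ncv, 3),
      " F =", round(x$summary$f_stat, 1), "\n")
  if (!is.null(x$r2_test)) cat("  r2_test =", round(x$r2_test, 3), "\n")
  invisible(x)
}

#' One-row internal-statistics report for a fitted model
#'
#' @param model a `qsar_model`.
#' @return data.frame mirroring the conventional model-statistics table:
#'   model name, q2, N, SEP, SEE, r2_ncv, F, r2_test and field
#'   contribution fractions.
#' @export
model_report <- function(model) {
  fc <- model$summary$field_contributions
  letters_ <- names(.field_letter_map)[match(
    sub("^(comfa|comsia)_", "", names(fc)), .field_letter_map)]
  row <- data.frame(
    model = paste0(toupper(model$method), "-", paste(model$fields, collapse = "")),
    q2 = model$q2, N = model$summary$n_components,
    SEP = model$sep, SEE = model$summary$see,
    r2_ncv = model$summary$r2_ncv, F = model$summary$f_stat,
    r2_test = if (is.null(model$r2_test)) NA_real_ else model$r2_test,
    stringsAsFactors = FALSE)
  for (L in c("S", "E", "H", "D", "A")) {
    row[[L]] <- if (L %in% letters_) unname(fc[which(letters_ == L)]) else NA_real_
  }
  row
}
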