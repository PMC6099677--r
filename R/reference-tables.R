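# md5 checksums protecting the shipped reference CSVs against silent edits
.reference_md5 <- c(
  activity    = "757ae2038d5addc5680cd46237bd15e7",
  predictions = "5720d4266fd6c25d0113e12297e3c88b",
  validation  = "01324120afeb1c0e055679e4eed1446c",
  models      = "07476914ac670d677726b2eff62ca184"
)

.reference_files <- c(
  activity    = "activity_reference.csv",
  predictions = "predictions_reference.csv",
  validation  = "validation_reference.csv",
  models      = "models_reference.csv"
)

#' Load the shipped reference tables
#'
#' The package ships, as plain CSV, the printed tables of a published
#' CoMFA/CoMSIA study of 41 aryloxypropanolamine beta3-adrenergic agonists:
#'
#' * `activity`: compound id, EC50 (micromolar) and printed pEC50 for all
#'   41 compounds. (In the source, the printed pEC50 column for compounds
#'   25-28 was mis-paired with the EC50 column by one row; the shipped table
#'   carries the corrected pairing, cross-checked against the predictions
#'   table and against 6 - log10(EC50).)
#' * `predictions`: experimental and CoMFA/CoMSIA-predicted pEC50 per
#'   compound, with test-set and per-model outlier flags (12 test
#'   compounds; CoMFA outliers 18 and 23, CoMSIA outliers 40 and 41).
#' * `validation`: the printed external-validation condition table for both
#'   models.
#' * `models`: the printed internal statistics (q2, N, SEP, SEE, r2_ncv, F,
#'   test r2, field contributions) across the named field combinations.
#'
#' File integrity is verified by md5 checksum on every load.
#'
#' @return named list of data.frames: `activity`, `predictions`,
#'   `validation`, `models`.
#' @export
#' @examples
#' ref <- load_reference_tables()
#' subset(ref$activity, compound == 16)
load_reference_tables <- function() {
  dir <- system.file("extdata", package = "fieldqsar")
  out <- lapply(names(.reference_files), function(key) {
    path <- file.path(dir, .reference_files[[key]])
    if (!file.exists(path)) stop("missing reference table: ", path)
    md5 <- unname(tools::md5sum(path))
    if (!identical(md5, unname(.reference_md5[[key]]))) {
      stop("reference table '", key, "' is corrupted (checksum mismatch)")
    }
    utils::read.csv(path, stringsAsFactors = FALSE)
  })
  names(out) <- names(.reference_files)
  out
}
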