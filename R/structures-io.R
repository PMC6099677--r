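#' Read aligned structures from SDF or MOL2
#'
#' SDF (V2000) files are parsed with ChemmineR; MOL2 (TRIPOS) files with
#' bio3d (multi-record files are split on `@<TRIPOS>MOLECULE` and parsed
#' record-wise). MOL2 partial charges, when present, are retained on the
#' atoms. Coordinates are taken as Angstrom.
#'
#' @param path file path.
#' @param format `"sdf"` or `"mol2"`; defaults from the file extension.
#' @return list of [molecule()] objects, ids taken from the record titles.
#' @export
read_structures <- function(path, format = c("sdf", "mol2")) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (missing(format)) {
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("sdf", "mol2")) format <- ext
  }
  format <- match.arg(format)
  if (format == "sdf") .read_sdf(path) else .read_mol2(path)
}

.read_sdf <- function(path) {
  set <- tryCatch(
    suppressWarnings(ChemmineR::read.SDFset(path)),
    error = function(e) stop("failed to parse SDF file: ", conditionMessage(e))
  )
  if (length(set) == 0L) stop("empty SDF file: ", path)
  # bond-free records are legal V2000; require atoms with finite coordinates
  valid <- vapply(seq_along(set), function(k) {
    ab <- ChemmineR::atomblock(set[[k]])
    is.matrix(ab) && nrow(ab) > 0 && all(is.finite(ab[, 1:3]))
  }, logical(1))
  if (!all(valid)) {
    stop("unparseable SDF record(s) at index: ",
         paste(which(!valid), collapse = ", "))
  }
  lapply(seq_along(set), function(k) {
    sdf <- set[[k]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    el <- sub("_.*$", "", rownames(ab))
    atoms <- data.frame(element = el,
                        x = ab[, 1], y = ab[, 2], z = ab[, 3],
                        stringsAsFactors = FALSE)
    rownames(atoms) <- NULL
    bonds <- NULL
    if (is.matrix(bb) && nrow(bb) && ncol(bb) >= 3) {
      bonds <- data.frame(from = as.integer(bb[, 1]),
                          to = as.integer(bb[, 2]),
                          order = as.integer(bb[, 3]))
    }
    id <- ChemmineR::header(sdf)[["Molecule_Name"]]
    if (is.null(id) || !nzchar(id)) id <- paste0("mol_", k)
    molecule(id, atoms, bonds = bonds)
  })
}

.read_mol2 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^@<TRIPOS>MOLECULE", lines)
  if (!length(starts)) stop("no @<TRIPOS>MOLECULE record in: ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  lapply(seq_along(starts), function(k) {
    chunk <- lines[starts[k]:ends[k]]
    tmp <- tempfile(fileext = ".mol2")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(chunk, tmp)
    rec <- tryCatch(
      suppressWarnings(bio3d::read.mol2(tmp)),   # bondless records are fine
      error = function(e) stop("unparseable MOL2 record at index ", k, ": ",
                               conditionMessage(e))
    )
    at <- rec$atom
    el <- sub("\\..*$", "", at$elety)   # SYBYL type, e.g. "C.3" -> "C"
    atoms <- data.frame(element = el, x = at$x, y = at$y, z = at$z,
                        stringsAsFactors = FALSE)
    if (!is.null(at$charge)) atoms$charge <- as.numeric(at$charge)
    bonds <- NULL
    if (!is.null(rec$bond) && nrow(rec$bond)) {
      bd <- rec$bond
      ord <- suppressWarnings(as.integer(bd$type))
      ord[is.na(ord)] <- 1L
      bonds <- data.frame(from = as.integer(bd$origin),
                          to = as.integer(bd$target),
                          order = ord)
    }
    id <- trimws(chunk[2])
    if (!nzchar(id)) id <- paste0("mol_", k)
    molecule(id, atoms, bonds = bonds)
  })
}

#' Write molecules to SDF or MOL2
#'
#' Writes standard V2000 SDF or TRIPOS MOL2 records readable by
#' [read_structures()] (and by ChemmineR / bio3d / OpenBabel). MOL2 carries
#' partial charges; SDF carries only elements, coordinates and bonds.
#'
#' @param molecules list of [molecule()] objects.
#' @param path output file path.
#' @param format `"sdf"` or `"mol2"`.
#' @return `path`, invisibly.
#' @export
write_structures <- function(molecules, path, format = c("sdf", "mol2")) {
  format <- match.arg(format)
  if (!length(molecules)) stop("no molecules to write")
  txt <- unlist(lapply(molecules,
                       if (format == "sdf") .format_sdf else .format_mol2))
  ok <- tryCatch({writeLines(txt, path); TRUE},
                 error = function(e) FALSE)
  if (!ok) stop("cannot write to path: ", path)
  invisible(path)
}

.format_sdf <- function(mol) {
  a <- mol$atoms
  b <- mol$bonds
  nb <- if (is.null(b)) 0L else nrow(b)
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(a), nb)
  atom_lines <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                        a$x, a$y, a$z, a$element)
  bond_lines <- if (nb) sprintf("%3d%3d%3d  0", b$from, b$to, b$order) else character(0)
  c(mol$id, "  fieldqsar", "", counts, atom_lines, bond_lines, "M  END", "$$$$")
}

.format_mol2 <- function(mol) {
  a <- mol$atoms
  b <- mol$bonds
  nb <- if (is.null(b)) 0L else nrow(b)
  chg <- a$charge
  has_chg <- !all(is.na(chg))
  if (!has_chg) chg <- rep(0, nrow(a))
  atom_lines <- sprintf("%7d %-8s %9.4f %9.4f %9.4f %-5s %5d %-8s %9.4f",
                        seq_len(nrow(a)), a$element, a$x, a$y, a$z,
                        a$element, 1L, "MOL1", chg)
  bond_lines <- if (nb) {
    sprintf("%6d %5d %5d %s", seq_len(nb), b$from, b$to, as.character(b$order))
  } else character(0)
  c("@<TRIPOS>MOLECULE", mol$id,
    sprintf("%5d %5d %5d %5d %5d", nrow(a), nb, 1L, 0L, 0L),
    "SMALL",
    if (has_chg) "USER_CHARGES" else "NO_CHARGES",
    "",
    "@<TRIPOS>ATOM", atom_lines,
    if (nb) c("@<TRIPOS>BOND", bond_lines) else character(0))
}

#' Convert EC50 (micromolar) to pEC50
#'
#' pEC50 = -log10(EC50 in mol/L) = 6 - log10(EC50 in uM).
#'
#' @param ec50 numeric vector of EC50 values in micromolar; must be positive.
#' @return numeric vector of pEC50 values (mol/L scale).
#' @export
#' @examples
#' ec50_to_pec50(1)     # 6
#' ec50_to_pec50(0.062) # 7.208
ec50_to_pec50 <- function(ec50) {
  if (!is.numeric(ec50) || any(!is.finite(ec50)) || any(ec50 <= 0)) {
    stop("ec50 must be positive and finite (micromolar)")
  }
  6 - log10(ec50)
}

#' Rigid (Kabsch) superposition on matched atom pairs
#'
#' Finds the rotation + translation of `mobile` minimizing the RMSD over the
#' mapped atom pairs (singular value decomposition of the covariance of the
#' centred mapped coordinates, with reflection correction).
#'
#' @param mobile,reference `molecule` objects.
#' @param atom_map two-column integer matrix (or data.frame) of index pairs:
#'   column 1 indexes atoms of `mobile`, column 2 atoms of `reference`.
#' @return list with `molecule` (transformed copy of `mobile`), `rmsd`
#'   (Angstrom, over mapped pairs), `rotation` (3x3) and `translation`.
#' @export
kabsch_align <- function(mobile, reference, atom_map) {
  atom_map <- as.matrix(atom_map)
  if (nrow(atom_map) < 3L) stop("need at least 3 mapped atom pairs")
  P <- coords(mobile)[atom_map[, 1], , drop = FALSE]
  Q <- coords(reference)[atom_map[, 2], , drop = FALSE]
  # collinearity check: rank of centred reference points must be >= 2
  Qc <- sweep(Q, 2, colMeans(Q))
  Pc <- sweep(P, 2, colMeans(P))
  if (sum(svd(Qc)$d > 1e-8) < 2L || sum(svd(Pc)$d > 1e-8) < 2L) {
    stop("mapped atom pairs are collinear")
  }
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- colMeans(Q) - as.vector(R %*% colMeans(P))
  X <- coords(mobile)
  Xnew <- t(R %*% t(X)) + matrix(trans, nrow(X), 3, byrow = TRUE)
  out <- mobile
  out$atoms$x <- Xnew[, 1]
  out$atoms$y <- Xnew[, 2]
  out$atoms$z <- Xnew[, 3]
  Pt <- Xnew[atom_map[, 1], , drop = FALSE]
  rmsd <- sqrt(mean(rowSums((Pt - Q)^2)))
  list(molecule = out, rmsd = rmsd, rotation = R, translation = trans)
}

#' Split compounds into training and test sets
#'
#' `strategy = "manual"` takes an explicit list of test ids.
#' `strategy = "stratified_random"` bins pEC50 into \[4,6) and \[6,8) log-unit
#' activity bins and samples test compounds proportionally from each bin with
#' a fixed seed, mirroring selection of structurally/activity-diverse test
#' compounds across low and high potency ranges.
#'
#' @param ids character vector of compound ids.
#' @param pec50 numeric vector of activities, parallel to `ids`.
#' @param train_fraction proportion of compounds assigned to training
#'   (0 < f < 1).
#' @param strategy `"stratified_random"` or `"manual"`.
#' @param seed integer seed for the random strategy.
#' @param test_ids explicit test-set ids (manual strategy).
#' @return named character vector: `"train"`/`"test"` per id.
#' @export
split_train_test <- function(ids, pec50, train_fraction = 0.7,
                             strategy = c("stratified_random", "manual"),
                             seed = 1L, test_ids = NULL) {
  strategy <- match.arg(strategy)
  n <- length(ids)
  stopifnot(length(pec50) == n)
  if (n < 4L) stop("need at least 4 compounds to split")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)")
  }
  roles <- setNames(rep("train", n), ids)
  if (strategy == "manual") {
    if (is.null(test_ids)) stop("manual strategy requires test_ids")
    unknown <- setdiff(test_ids, ids)
    if (length(unknown)) stop("unknown id(s) in test list: ",
                              paste(unknown, collapse = ", "))
    roles[test_ids] <- "test"
    return(roles)
  }
  n_test <- n - round(train_fraction * n)
  bins <- cut(pec50, breaks = c(-Inf, 4, 6, 8, Inf), right = FALSE)
  set.seed(as.integer(seed))
  # proportional allocation across activity bins, largest-remainder rounding
  tab <- table(bins)
  quota <- as.numeric(tab) * n_test / n
  take <- floor(quota)
  rem <- n_test - sum(take)
  if (rem > 0) {
    ord <- order(quota - take, decreasing = TRUE)
    take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1L
  }
  test_sel <- character(0)
  for (b in seq_along(tab)) {
    members <- ids[as.integer(bins) == b]
    k <- min(take[b], length(members))
    if (k > 0) test_sel <- c(test_sel, sample(members, k))
  }
  # top up if small bins could not fill their quota
  short <- n_test - length(test_sel)
  if (short > 0) {
    pool <- setdiff(ids, test_sel)
    test_sel <- c(test_sel, sample(pool, short))
  }
  roles[test_sel] <- "test"
  roles
}

#' Bundle molecules, activities and roles into an aligned dataset
#'
#' @param molecules list of `molecule` objects sharing one alignment frame.
#' @param activities data.frame with columns `id`, `pec50` and optionally
#'   `ec50_uM`; one row per molecule. If both `ec50_uM` and `pec50` are given
#'   they must agree (pEC50 = 6 - log10(EC50 uM)) to within 0.001.
#' @param roles named character vector (`"train"`/`"test"`) per molecule id.
#' @return object of class `aligned_dataset`.
#' @export
aligned_dataset <- function(molecules, activities, roles) {
  ids <- vapply(molecules, function(m) m$id, character(1))
  if (anyDuplicated(ids)) stop("molecule ids must be unique")
  stopifnot(all(c("id", "pec50") %in% names(activities)))
  if (!setequal(ids, activities$id)) {
    stop("activities must cover exactly the molecule ids")
  }
  if (!setequal(ids, names(roles)) || !all(roles %in% c("train", "test"))) {
    stop("roles must label every molecule as train or test")
  }
  if (!is.null(activities$ec50_uM)) {
    both <- !is.na(activities$ec50_uM) & !is.na(activities$pec50)
    if (any(both)) {
      diff <- abs(ec50_to_pec50(activities$ec50_uM[both]) - activities$pec50[both])
      if (any(diff > 1e-3 + 1e-9)) {
        stop("ec50_uM and pec50 disagree beyond printing precision for id(s): ",
             paste(activities$id[both][diff > 1e-3 + 1e-9], collapse = ", "))
      }
    }
  }
  activities <- activities[match(ids, activities$id), , drop = FALSE]
  rownames(activities) <- NULL
  structure(list(molecules = molecules, activities = activities,
                 roles = roles[ids]),
            class = "aligned_dataset")
}

#' @export
print.aligned_dataset <- function(x, ...) {
  cat("<aligned_dataset>", length(x$molecules), "molecules (",
      sum(x$roles == "train"), "train /", sum(x$roles == "test"), "test )\n")
  invisible(x)
}

#' Write a normalized dataset manifest
#'
#' Echoes compound ids, pEC50 and train/test roles to CSV.
#'
#' @param dataset an `aligned_dataset`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(dataset, path) {
  df <- data.frame(id = dataset$activities$id,
                   pec50 = dataset$activities$pec50,
                   role = unname(dataset$roles))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
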