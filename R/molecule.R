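#' Construct a molecule
#'
#' A molecule is an aligned 3D structure: an ordered atom table (element,
#' Cartesian coordinates in Angstrom, and optional per-atom physicochemical
#' properties) plus an optional bond list. Coordinates are assumed to live in
#' the dataset's shared alignment frame.
#'
#' @param id unique identifier (coerced to character).
#' @param atoms data.frame with at least columns `element`, `x`, `y`, `z`;
#'   optional columns `charge`, `vdw_radius`, `hydrophobicity`, `is_donor`,
#'   `is_acceptor`. Missing property columns are filled with `NA`.
#' @param bonds optional data.frame with columns `from`, `to` (1-based atom
#'   indices) and optionally `order`.
#' @param name optional human-readable name.
#' @return object of class `molecule`.
#' @export
#' @examples
#' m <- molecule("m1", data.frame(element = "C", x = 0, y = 0, z = 0))
#' n_atoms(m)
molecule <- function(id, atoms, bonds = NULL, name = NULL) {
  stopifnot(is.data.frame(atoms))
  req <- c("element", "x", "y", "z")
  if (!all(req %in% names(atoms))) {
    stop("atoms must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(atoms) < 1L) stop("molecule must have at least one atom")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("atom coordinates must be finite")
  for (col in c("charge", "vdw_radius", "hydrophobicity")) {
    if (is.null(atoms[[col]])) atoms[[col]] <- NA_real_
  }
  for (col in c("is_donor", "is_acceptor")) {
    if (is.null(atoms[[col]])) atoms[[col]] <- NA
  }
  if (!is.null(atoms$vdw_radius) && any(!is.na(atoms$vdw_radius) & atoms$vdw_radius <= 0)) {
    stop("vdw_radius must be positive")
  }
  if (!is.null(bonds)) {
    stopifnot(is.data.frame(bonds), all(c("from", "to") %in% names(bonds)))
    if (nrow(bonds) && (max(bonds$from, bonds$to) > nrow(atoms) ||
                        min(bonds$from, bonds$to) < 1)) {
      stop("bond indices out of range")
    }
    if (is.null(bonds$order)) bonds$order <- 1L
  }
  structure(
    list(id = as.character(id), name = name,
         atoms = atoms, bonds = bonds),
    class = "molecule"
  )
}

#' @export
print.molecule <- function(x, ...) {
  cat("<molecule>", x$id, if (!is.null(x$name)) paste0("(", x$name, ")"),
      "-", nrow(x$atoms), "atoms\n")
  invisible(x)
}

#' Number of atoms in a molecule
#' @param mol a `molecule`.
#' @return integer.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

#' Atom coordinates as a matrix
#' @param mol a `molecule`.
#' @return numeric matrix, one row per atom, columns x/y/z (Angstrom).
#' @export
coords <- function(mol) {
  unname(as.matrix(mol$atoms[, c("x", "y", "z")]))
}

# indices of atoms bonded to atom i
.neighbours <- function(mol, i) {
  b <- mol$bonds
  if (is.null(b) || !nrow(b)) return(integer(0))
  c(b$to[b$from == i], b$from[b$to == i])
}

#' Assign per-atom physicochemical properties
#'
#' Populates van der Waals radius (Bondi), hydrophobicity (element-level
#' atomic logP contribution), hydrogen-bond donor/acceptor flags, and partial
#' charges. Donor flags follow the rule: an H bonded to N, O or S is a donor,
#' and the flag is also carried on that heavy atom. Acceptors are N or O
#' bearing a lone pair; quaternary nitrogen (four connections) and nitro
#' nitrogen are excluded.
#'
#' @param mol a `molecule`. For `charge_method = "gasteiger"` and for the
#'   H-bond rules, bonds must be present.
#' @param charge_method `"input"` keeps charges already on the atoms (e.g.
#'   read from a MOL2 file); `"gasteiger"` computes Gasteiger-Marsili charges
#'   through OpenBabel.
#' @return the molecule with all property columns populated.
#' @export
assign_atom_properties <- function(mol, charge_method = c("input", "gasteiger")) {
  charge_method <- match.arg(charge_method)
  el <- mol$atoms$element
  pars <- .element_row(el)
  mol$atoms$vdw_radius <- pars$vdw_radius
  mol$atoms$hydrophobicity <- pars$hydrophobicity

  if (charge_method == "gasteiger") {
    if (is.null(mol$bonds) || !nrow(mol$bonds)) {
      stop("gasteiger charges require bond information")
    }
    mol$atoms$charge <- .gasteiger_charges(mol)
  } else if (all(is.na(mol$atoms$charge))) {
    mol$atoms$charge <- 0
  }

  n <- n_atoms(mol)
  donor <- logical(n)
  acceptor <- logical(n)
  for (i in seq_len(n)) {
    nb <- .neighbours(mol, i)
    nb_el <- el[nb]
    if (el[i] == "H" && any(nb_el %in% c("N", "O", "S"))) donor[i] <- TRUE
    if (el[i] %in% c("N", "O", "S") && any(nb_el == "H")) donor[i] <- TRUE
    if (el[i] == "O") acceptor[i] <- TRUE
    if (el[i] == "N") {
      quaternary <- length(nb) >= 4L
      # nitro: N bonded to two terminal oxygens
      term_o <- sum(vapply(nb, function(j) {
        el[j] == "O" && length(.neighbours(mol, j)) == 1L
      }, logical(1)))
      nitro <- term_o >= 2L
      if (!quaternary && !nitro) acceptor[i] <- TRUE
    }
  }
  mol$atoms$is_donor <- donor
  mol$atoms$is_acceptor <- acceptor
  mol
}

# Gasteiger-Marsili partial charges via the OpenBabel command-line tool.
.gasteiger_charges <- function(mol) {
  if (!nzchar(Sys.which("obabel"))) {
    stop("obabel executable not found; gasteiger charges unavailable")
  }
  tmp_in <- tempfile(fileext = ".sdf")
  tmp_out <- tempfile(fileext = ".mol2")
  on.exit(unlink(c(tmp_in, tmp_out)), add = TRUE)
  write_structures(list(mol), tmp_in, format = "sdf")
  status <- suppressWarnings(system2(
    "obabel", c(tmp_in, "-O", tmp_out, "--partialcharge", "gasteiger"),
    stdout = FALSE, stderr = FALSE
  ))
  if (status != 0 || !file.exists(tmp_out)) {
    stop("obabel failed to compute gasteiger charges")
  }
  out <- read_structures(tmp_out, format = "mol2")[[1]]
  if (n_atoms(out) != n_atoms(mol)) {
    stop("atom count changed during charge assignment")
  }
  out$atoms$charge
}
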