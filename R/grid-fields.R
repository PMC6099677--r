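# Coulomb constant in kcal*A/(mol*e^2)
.coulomb_k <- 332.0636
# minimum distance guard for the Coulomb kernel (A)
.r_min_guard <- 1e-6

#' Build a cubic lattice enclosing a set of aligned molecules
#'
#' The grid extends at least `padding` Angstrom beyond the union bounding box
#' of all atoms on every face. The origin is snapped down to integer
#' multiples of `spacing` in the shared coordinate frame, so translating a
#' dataset by a multiple of the spacing reproduces the same columns.
#'
#' @param molecules list of `molecule` objects (non-empty).
#' @param spacing lattice spacing in Angstrom (default 2).
#' @param padding extension beyond the bounding box in Angstrom (default 4).
#' @return object of class `grid_spec`: `origin`, `spacing`, `dims`.
#' @export
build_grid <- function(molecules, spacing = 2, padding = 4) {
  if (!length(molecules)) stop("empty molecule list")
  stopifnot(spacing > 0, padding >= 0)
  xyz <- do.call(rbind, lapply(molecules, coords))
  lo <- apply(xyz, 2, min) - padding
  hi <- apply(xyz, 2, max) + padding
  origin <- floor(lo / spacing) * spacing
  dims <- pmax(2L, as.integer(ceiling((hi - origin) / spacing)) + 1L)
  structure(list(origin = origin, spacing = spacing, dims = dims),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat("<grid_spec>", paste(x$dims, collapse = " x "), "points, spacing",
      x$spacing, "A, origin (", paste(signif(x$origin, 6), collapse = ", "), ")\n")
  invisible(x)
}

#' Lattice point coordinates
#'
#' @param grid a `grid_spec`.
#' @return matrix (n_points x 3); x varies fastest, then y, then z.
#' @export
grid_points <- function(grid) {
  ax <- lapply(1:3, function(k) grid$origin[k] + grid$spacing * (seq_len(grid$dims[k]) - 1))
  pts <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                     KEEP.OUT.ATTRS = FALSE)
  unname(as.matrix(pts))
}

#' CoMFA probe specification
#'
#' The default is an sp3 carbon probe: van der Waals radius 1.52 A, charge
#' +1.0 e, Lennard-Jones well depth 0.107 kcal/mol.
#' @param vdw_radius,charge,epsilon probe parameters.
#' @return list of probe parameters.
#' @export
probe_comfa <- function(vdw_radius = 1.52, charge = 1.0, epsilon = 0.107) {
  list(vdw_radius = vdw_radius, charge = charge, epsilon = epsilon)
}

#' CoMSIA probe specification
#'
#' Standard settings: radius 1.0 A and unit weight (+1.0) for every
#' property (charge, hydrophobicity, H-bond donor, H-bond acceptor).
#' @param vdw_radius,charge,hydrophobicity,donor_weight,acceptor_weight
#'   probe property weights.
#' @return list of probe parameters.
#' @export
probe_comsia <- function(vdw_radius = 1.0, charge = 1.0, hydrophobicity = 1.0,
                         donor_weight = 1.0, acceptor_weight = 1.0) {
  list(vdw_radius = vdw_radius, charge = charge,
       hydrophobicity = hydrophobicity,
       donor_weight = donor_weight, acceptor_weight = acceptor_weight)
}

.field_block <- function(field_type, values, units, row_ids) {
  rownames(values) <- row_ids
  structure(list(field_type = field_type, values = values, units = units),
            class = "field_block")
}

#' @export
print.field_block <- function(x, ...) {
  cat("<field_block>", x$field_type, ":", nrow(x$values), "molecules x",
      ncol(x$values), "grid points (", x$units, ")\n")
  invisible(x)
}

# squared distances from every atom (rows) to every grid point (cols)
.dist2 <- function(xyz, pts) {
  outer(rowSums(xyz^2), rep(1, nrow(pts))) +
    outer(rep(1, nrow(xyz)), rowSums(pts^2)) -
    2 * xyz %*% t(pts)
}

#' CoMFA steric and electrostatic fields
#'
#' Steric: Lennard-Jones 6-12 probe-atom energy summed over atoms,
#' `eps_ij * ((rm/r)^12 - 2 (rm/r)^6)` with `rm = r_atom + r_probe` and
#' `eps_ij = sqrt(eps_atom * eps_probe)` (Lorentz-Berthelot). Electrostatic:
#' Coulomb energy with distance-dependent dielectric `eps(r) = r`, i.e.
#' `332.0636 * q_atom * q_probe / r^2`. Both are clipped to `[-cutoff,
#' +cutoff]` kcal/mol. At lattice points where the (unclipped) steric energy
#' reaches the cutoff, the electrostatic entry is masked (`NA`); impute with
#' [impute_masked()] using training-column means before modelling.
#'
#' @param molecules list of molecules with charges and radii assigned.
#' @param grid a `grid_spec`.
#' @param probe a [probe_comfa()] specification.
#' @param cutoff truncation level in kcal/mol (default 30).
#' @return list of two `field_block`s: `comfa_steric`, `comfa_electrostatic`.
#' @export
comfa_fields <- function(molecules, grid, probe = probe_comfa(), cutoff = 30) {
  pts <- grid_points(grid)
  ids <- vapply(molecules, function(m) m$id, character(1))
  n <- length(molecules)
  ster <- matrix(0, n, nrow(pts))
  elec <- matrix(0, n, nrow(pts))
  for (m in seq_len(n)) {
    mol <- molecules[[m]]
    if (all(is.na(mol$atoms$charge))) stop("molecule ", mol$id, " has no charges")
    pars <- .element_row(mol$atoms$element)
    r2 <- .dist2(coords(mol), pts)
    r2[r2 < .r_min_guard^2] <- .r_min_guard^2
    rm_ij <- mol$atoms$vdw_radius + probe$vdw_radius
    eps_ij <- sqrt(pars$lj_epsilon * probe$epsilon)
    s6 <- sweep((1 / r2)^3, 1, rm_ij^6, `*`)   # (rm/r)^6 per atom x point
    lj <- sweep(s6^2 - 2 * s6, 1, eps_ij, `*`)
    ster[m, ] <- colSums(lj)
    q <- mol$atoms$charge
    q[is.na(q)] <- 0
    cou <- sweep(1 / r2, 1, .coulomb_k * q * probe$charge, `*`)
    elec[m, ] <- colSums(cou)
  }
  masked <- ster >= cutoff
  ster <- pmin(pmax(ster, -cutoff), cutoff)
  elec <- pmin(pmax(elec, -cutoff), cutoff)
  elec[masked] <- NA_real_
  list(.field_block("comfa_steric", ster, "kcal/mol", ids),
       .field_block("comfa_electrostatic", elec, "kcal/mol", ids))
}

#' Replace masked (NA) field entries by training-column means
#'
#' Sybyl-style convention for electrostatic values inside the steric
#' envelope: masked entries take the mean of the unmasked training-set
#' entries of their column (0 if the whole training column is masked).
#'
#' @param block a `field_block` (possibly containing `NA`).
#' @param train_idx indices (or logical mask) of training rows.
#' @return the block with `NA`s imputed.
#' @export
impute_masked <- function(block, train_idx = seq_len(nrow(block$values))) {
  v <- block$values
  if (!anyNA(v)) return(block)
  tr <- v[train_idx, , drop = FALSE]
  mu <- colMeans(tr, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(is.na(v), arr.ind = TRUE)
  v[idx] <- mu[idx[, 2]]
  block$values <- v
  block
}

# CoMSIA atomic weights for one property
.comsia_weights <- function(mol, property) {
  a <- mol$atoms
  switch(property,
    steric = a$vdw_radius^3,
    electrostatic = {q <- a$charge; q[is.na(q)] <- 0; q},
    hydrophobic = a$hydrophobicity,
    donor = as.numeric(a$is_donor & a$element != "H"),
    acceptor = as.numeric(a$is_acceptor),
    stop("unknown CoMSIA property: ", property))
}

#' CoMSIA similarity-index fields
#'
#' Gaussian-attenuated similarity index of Klebe: the value of property `k`
#' at lattice point `q` is `-sum_i w_probe_k * w_ik * exp(-alpha * r_iq^2)`
#' with distances in Angstrom. Atomic weights: steric = vdW radius cubed,
#' electrostatic = partial charge, hydrophobic = atomic logP contribution,
#' donor/acceptor = binary flags on heavy atoms. No cutoff is applied; the
#' Gaussian makes the fields smooth everywhere.
#'
#' @param molecules list of molecules with all properties assigned.
#' @param grid a `grid_spec`.
#' @param probe a [probe_comsia()] specification.
#' @param alpha attenuation factor (default 0.3), must be positive.
#' @param properties which of the five fields to compute.
#' @return list of `field_block`s (`comsia_steric`, ..., `comsia_acceptor`).
#' @export
comsia_fields <- function(molecules, grid, probe = probe_comsia(), alpha = 0.3,
                          properties = c("steric", "electrostatic",
                                         "hydrophobic", "donor", "acceptor")) {
  if (!is.numeric(alpha) || alpha <= 0) stop("alpha must be positive")
  properties <- match.arg(properties, several.ok = TRUE)
  pts <- grid_points(grid)
  ids <- vapply(molecules, function(m) m$id, character(1))
  n <- length(molecules)
  probe_w <- c(steric = probe$vdw_radius^3, electrostatic = probe$charge,
               hydrophobic = probe$hydrophobicity,
               donor = probe$donor_weight, acceptor = probe$acceptor_weight)
  vals <- lapply(properties, function(p) matrix(0, n, nrow(pts)))
  names(vals) <- properties
  for (m in seq_len(n)) {
    mol <- molecules[[m]]
    g <- exp(-alpha * .dist2(coords(mol), pts))
    for (p in properties) {
      w <- .comsia_weights(mol, p)
      if (anyNA(w)) stop("molecule ", mol$id, " lacks property: ", p)
      vals[[p]][m, ] <- -probe_w[[p]] * colSums(sweep(g, 1, w, `*`))
    }
  }
  lapply(properties, function(p) {
    .field_block(paste0("comsia_", p), vals[[p]], "similarity", ids)
  })
}

#' Concatenate field blocks into a descriptor matrix
#'
#' @param blocks list of `field_block`s sharing row count and order.
#' @param row_ids molecule ids (defaults to the first block's rownames).
#' @return object of class `descriptor_matrix`: `x` (molecules x columns),
#'   `column_meta` (data.frame: `field_type`, `grid_index`), `row_ids`.
#' @export
assemble_descriptors <- function(blocks, row_ids = NULL) {
  if (!length(blocks)) stop("no field blocks supplied")
  nr <- vapply(blocks, function(b) nrow(b$values), integer(1))
  if (length(unique(nr)) != 1L) stop("field blocks have mismatched row counts")
  rid <- lapply(blocks, function(b) rownames(b$values))
  if (!all(vapply(rid, identical, logical(1), rid[[1]]))) {
    stop("field blocks have mismatched row order")
  }
  if (is.null(row_ids)) row_ids <- rid[[1]]
  x <- do.call(cbind, lapply(blocks, function(b) b$values))
  meta <- do.call(rbind, lapply(blocks, function(b) {
    data.frame(field_type = b$field_type,
               grid_index = seq_len(ncol(b$values)),
               stringsAsFactors = FALSE)
  }))
  colnames(x) <- paste0(meta$field_type, "_", meta$grid_index)
  rownames(x) <- row_ids
  structure(list(x = x, column_meta = meta, row_ids = row_ids),
            class = "descriptor_matrix")
}

#' @export
print.descriptor_matrix <- function(x, ...) {
  cat("<descriptor_matrix>", nrow(x$x), "molecules x", ncol(x$x), "columns (",
      paste(unique(x$column_meta$field_type), collapse = ", "), ")\n")
  invisible(x)
}
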