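# 1 Angstrom in bohr (CODATA)
.ang_to_bohr <- 1 / 0.529177210903

#' StDev*Coeff contour field for one field type
#'
#' The conventional CoMFA/CoMSIA display statistic: for each lattice point,
#' the PLS coefficient of the corresponding column times that column's
#' training standard deviation. Columns removed by the column filter carry
#' the value 0, so the field covers the full lattice.
#'
#' @param model a fitted `qsar_model`.
#' @param field_type one of the model's block types (e.g. `"comsia_steric"`).
#' @return object of class `contour_field`: `field_type`, `values` (one
#'   scalar per lattice point, in lattice order), `grid`.
#' @export
stdev_coeff_field <- function(model, field_type) {
  all_meta <- model$descriptors$column_meta
  if (!field_type %in% all_meta$field_type) {
    stop("unknown field_type: ", field_type, " (model has: ",
         paste(unique(all_meta$field_type), collapse = ", "), ")")
  }
  summ <- model$summary
  n_pts <- prod(model$grid$dims)
  values <- numeric(n_pts)
  # coefficients live on the retained (filtered) columns; map back through
  # the kept-column index into the full lattice of this field
  kept_meta <- summ$column_meta
  in_field <- kept_meta$field_type == field_type
  # coefficient x sd in the scaled space equals coefficient x sd in the
  # original space (the block factor cancels), computed on training rows
  x_train <- model$descriptors$x[model$train_idx,
                                 summ$kept_columns, drop = FALSE]
  sds <- .col_sds(x_train)
  contrib <- summ$coefficients * sds
  values[kept_meta$grid_index[in_field]] <- contrib[in_field]
  structure(list(field_type = field_type, values = values,
                 grid = model$grid),
            class = "contour_field")
}

#' @export
print.contour_field <- function(x, ...) {
  nz <- sum(x$values != 0)
  cat("<contour_field>", x$field_type, ":", length(x$values),
      "lattice points,", nz, "non-zero\n")
  invisible(x)
}

#' Favored / disfavored contour levels
#'
#' Percentiles of the non-zero value distribution (linear interpolation
#' between order statistics, i.e. `quantile(type = 7)`); the defaults 80/20
#' follow the conventional favored/disfavored display levels.
#'
#' @param field a `contour_field`.
#' @param favored_pct,disfavored_pct percentiles in \[0, 100\] with
#'   `disfavored_pct < favored_pct`.
#' @return named numeric vector `c(favored = , disfavored = )`.
#' @export
threshold_levels <- function(field, favored_pct = 80, disfavored_pct = 20) {
  stopifnot(disfavored_pct >= 0, favored_pct <= 100,
            disfavored_pct < favored_pct)
  nz <- field$values[field$values != 0]
  if (!length(nz)) stop("all-zero contour field; no levels to compute")
  q <- stats::quantile(nz, c(favored_pct, disfavored_pct) / 100,
                       type = 7, names = FALSE)
  c(favored = q[1], disfavored = q[2])
}

#' Export a contour field as an OpenDX or Gaussian cube file
#'
#' OpenDX: regular positions/connections grid in Angstrom. Gaussian cube:
#' origin and voxel vectors converted to bohr per the format convention;
#' `molecule` supplies the atom records (a cube without atoms writes an
#' empty atom list). Values are written with 6 significant digits, so a
#' round trip through [read_volumetric()] reproduces them to at least 5.
#'
#' @param field a `contour_field` (or any numeric vector of lattice values
#'   matching the grid).
#' @param grid the `grid_spec` (defaults to the field's own grid).
#' @param path output file path.
#' @param format `"dx"` or `"cube"`.
#' @param molecule optional `molecule` written into the cube atom block.
#' @return `path`, invisibly.
#' @export
export_volumetric <- function(field, path, format = c("dx", "cube"),
                              grid = NULL, molecule = NULL) {
  format <- match.arg(format)
  if (inherits(field, "contour_field")) {
    if (is.null(grid)) grid <- field$grid
    values <- field$values
  } else {
    values <- as.numeric(field)
    if (is.null(grid)) stop("grid must be supplied for raw value vectors")
  }
  if (length(values) != prod(grid$dims)) {
    stop("value count ", length(values), " does not match grid dims ",
         paste(grid$dims, collapse = "x"))
  }
  txt <- if (format == "dx") .format_dx(values, grid) else
    .format_cube(values, grid, molecule)
  writeLines(txt, path)
  invisible(path)
}

# OpenDX expects z to vary fastest; lattice order here is x-fastest
.xfast_to_zfast <- function(values, dims) {
  a <- array(values, dim = dims)                 # [x, y, z], x fastest
  as.vector(aperm(a, c(3, 2, 1)))                # z fastest
}

.zfast_to_xfast <- function(values, dims) {
  a <- array(values, dim = rev(dims))            # [z, y, x]
  as.vector(aperm(a, c(3, 2, 1)))
}

.format_dx <- function(values, grid) {
  d <- grid$dims
  v <- .xfast_to_zfast(values, d)
  pad <- c(v, rep(NA_real_, (3 - length(v) %% 3) %% 3))
  rows <- matrix(pad, ncol = 3, byrow = TRUE)
  data_lines <- apply(rows, 1, function(r) {
    paste(sprintf("%.6g", r[!is.na(r)]), collapse = " ")
  })
  c(sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6f %.6f %.6f",
            grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.6f 0.000000 0.000000", grid$spacing),
    sprintf("delta 0.000000 %.6f 0.000000", grid$spacing),
    sprintf("delta 0.000000 0.000000 %.6f", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf(paste0("object 3 class array type double rank 0 items %d",
                   " data follows"), prod(d)),
    data_lines,
    "attribute \"dep\" string \"positions\"",
    "object \"regular positions regular connections\" class field",
    "component \"positions\" value 1",
    "component \"connections\" value 2",
    "component \"data\" value 3")
}

.format_cube <- function(values, grid, molecule) {
  d <- grid$dims
  b <- .ang_to_bohr
  natoms <- if (is.null(molecule)) 0L else n_atoms(molecule)
  atom_lines <- character(0)
  if (natoms > 0) {
    z_num <- c(H = 1, C = 6, N = 7, O = 8, F = 9, P = 15, S = 16,
               Cl = 17, Br = 35, I = 53)
    xyz <- coords(molecule) * b
    zs <- z_num[molecule$atoms$element]
    zs[is.na(zs)] <- 0
    atom_lines <- sprintf("%5d %11.6f %11.6f %11.6f %11.6f",
                          as.integer(zs), 0, xyz[, 1], xyz[, 2], xyz[, 3])
  }
  v <- .xfast_to_zfast(values, d)
  # cube bodies conventionally wrap at 6 values per line
  pad <- c(v, rep(NA_real_, (6 - length(v) %% 6) %% 6))
  rows <- matrix(pad, ncol = 6, byrow = TRUE)
  data_lines <- apply(rows, 1, function(r) {
    paste(sprintf("%12.5e", r[!is.na(r)]), collapse = " ")
  })
  c("fieldqsar contour field",
    "StDev*Coeff lattice values",
    sprintf("%5d %11.6f %11.6f %11.6f", natoms,
            grid$origin[1] * b, grid$origin[2] * b, grid$origin[3] * b),
    sprintf("%5d %11.6f %11.6f %11.6f", d[1], grid$spacing * b, 0, 0),
    sprintf("%5d %11.6f %11.6f %11.6f", d[2], 0, grid$spacing * b, 0),
    sprintf("%5d %11.6f %11.6f %11.6f", d[3], 0, 0, grid$spacing * b),
    atom_lines,
    data_lines)
}

#' Read back a volumetric file written by [export_volumetric()]
#'
#' @param path file path.
#' @param format `"dx"` or `"cube"`; defaults from the extension.
#' @return list: `values` (lattice order, x fastest), `grid` (`grid_spec`,
#'   Angstrom).
#' @export
read_volumetric <- function(path, format = c("dx", "cube")) {
  if (missing(format)) {
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("dx", "cube")) format <- ext
  }
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  if (format == "dx") .parse_dx(lines) else .parse_cube(lines)
}

.parse_dx <- function(lines) {
  nums <- function(s) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(s), "\\s+")[[1]]))
    v[!is.na(v)]
  }
  cl <- grep("gridpositions counts", lines, value = TRUE)[1]
  dims <- as.integer(utils::tail(nums(gsub("[^0-9. -]", " ", cl)), 3))
  origin <- utils::tail(nums(grep("^origin", lines, value = TRUE)[1]), 3)
  deltas <- vapply(grep("^delta", lines, value = TRUE), function(s)
    max(utils::tail(nums(s), 3)), numeric(1))
  spacing <- deltas[1]
  i0 <- grep("data follows", lines)[1]
  body <- lines[(i0 + 1):length(lines)]
  body <- body[!grepl("^(attribute|object|component)", body)]
  v <- as.numeric(unlist(strsplit(trimws(body[nzchar(trimws(body))]), "\\s+")))
  grid <- structure(list(origin = origin, spacing = spacing, dims = dims),
                    class = "grid_spec")
  list(values = .zfast_to_xfast(v, dims), grid = grid)
}

.parse_cube <- function(lines) {
  nums <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  h3 <- nums(lines[3])
  natoms <- as.integer(h3[1])
  origin <- h3[2:4] / .ang_to_bohr
  ax <- lapply(4:6, function(i) nums(lines[i]))
  dims <- vapply(ax, function(a) as.integer(a[1]), integer(1))
  spacing <- ax[[1]][2] / .ang_to_bohr
  body <- lines[(7 + natoms):length(lines)]
  v <- as.numeric(unlist(strsplit(trimws(body[nzchar(trimws(body))]), "\\s+")))
  grid <- structure(list(origin = origin, spacing = spacing, dims = dims),
                    class = "grid_spec")
  list(values = .zfast_to_xfast(v, dims), grid = grid)
}
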