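# toy molecules with explicit bonding, built in code

make_water <- function() {
  molecule("water",
           data.frame(element = c("O", "H", "H"),
                      x = c(0, 0.96, -0.24), y = c(0, 0, 0.93),
                      z = c(0, 0, 0)),
           bonds = data.frame(from = c(1, 1), to = c(2, 3)))
}

make_benzene <- function() {
  theta <- 2 * pi * (0:5) / 6
  rc <- 1.39; rh <- 2.48
  atoms <- data.frame(
    element = c(rep("C", 6), rep("H", 6)),
    x = c(rc * cos(theta), rh * cos(theta)),
    y = c(rc * sin(theta), rh * sin(theta)),
    z = 0)
  bonds <- data.frame(from = c(1:6, 1:6),
                      to = c(c(2:6, 1), 7:12),
                      order = c(rep(c(2L, 1L), 3), rep(1L, 6)))
  molecule("benzene", atoms, bonds = bonds)
}

make_ethanol <- function() {
  atoms <- data.frame(
    element = c("C", "C", "O", "H", "H", "H", "H", "H", "H"),
    x = c(1.2304, 0, -1.1457, 1.2766, 1.2766, 2.1059, -0.0492, -0.0492, -1.8782),
    y = c(-0.2164, 0.4519, -0.3741, -0.8471, -0.8471, 0.4421, 1.0902, 1.0902, 0.2355),
    z = c(0, 0, 0, 0.89, -0.89, 0, 0.89, -0.89, 0))
  bonds <- data.frame(from = c(1, 2, 1, 1, 1, 2, 2, 3),
                      to = c(2, 3, 4, 5, 6, 7, 8, 9))
  molecule("ethanol", atoms, bonds = bonds)
}

# single point atom with controllable properties, for field kernels
make_point_atom <- function(id = "pt", element = "C", pos = c(0, 0, 0),
                            charge = 1, donor = FALSE, acceptor = FALSE) {
  m <- molecule(id, data.frame(element = element,
                               x = pos[1], y = pos[2], z = pos[3],
                               charge = charge))
  m <- assign_atom_properties(m, "input")
  m$atoms$is_donor <- donor
  m$atoms$is_acceptor <- acceptor
  m
}

# index of the lattice point closest to `p`; errors if not a lattice point
lattice_index <- function(grid, p, exact = TRUE) {
  pts <- grid_points(grid)
  d2 <- rowSums(sweep(pts, 2, p)^2)
  i <- which.min(d2)
  if (exact) stopifnot(d2[i] < 1e-18)
  i
}

# small random descriptor matrix with block structure, for PLS tests
make_dm <- function(n, p_per_block, types = c("blockA", "blockB"), seed = 1) {
  set.seed(seed)
  blocks <- lapply(types, function(ft) {
    v <- matrix(rnorm(n * p_per_block), n, p_per_block)
    rownames(v) <- paste0("m", seq_len(n))
    structure(list(field_type = ft, values = v, units = "a.u."),
              class = "field_block")
  })
  assemble_descriptors(blocks)
}
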