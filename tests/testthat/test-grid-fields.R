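test_that("grid construction covers the bounding box with snapping", {
  m <- make_point_atom(pos = c(0, 0, 0))
  g <- build_grid(list(m), spacing = 2, padding = 4)
  expect_true(all(g$origin <= -4))
  far <- g$origin + (g$dims - 1) * g$spacing
  expect_true(all(far >= 4))
  expect_true(all(g$dims >= 5))
  expect_equal(g$origin %% 2, c(0, 0, 0))

  g0 <- build_grid(list(m), spacing = 2, padding = 0)
  expect_true(all(g0$dims >= 2))
  expect_error(build_grid(list()), "empty")

  # doubling the spacing roughly halves the per-axis point count
  mols <- generate_dataset(generator_spec(seed = 4))$dataset$molecules
  g1 <- build_grid(mols, spacing = 1, padding = 4)
  g2 <- build_grid(mols, spacing = 2, padding = 4)
  expect_true(all(abs(g2$dims - (ceiling((g1$dims - 1) / 2) + 1)) <= 1))
})

test_that("joint translation of molecules and grid leaves fields bit-identical", {
  gen <- generate_dataset(generator_spec(seed = 5))
  mols <- gen$dataset$molecules[1:6]
  g <- build_grid(mols, 2, 4)
  shift <- c(2, 0, 0)   # a lattice-vector shift; snapping reproduces columns
  mols_t <- lapply(mols, function(m) {
    m$atoms$x <- m$atoms$x + shift[1]
    m$atoms$y <- m$atoms$y + shift[2]
    m$atoms$z <- m$atoms$z + shift[3]
    m
  })
  g_t <- build_grid(mols_t, 2, 4)
  expect_equal(g_t$dims, g$dims)
  expect_identical(unname(g_t$origin - g$origin), shift)

  f1 <- comfa_fields(mols, g)
  f2 <- comfa_fields(mols_t, g_t)
  expect_identical(f1[[1]]$values, f2[[1]]$values)
  expect_identical(f1[[2]]$values, f2[[2]]$values)
  c1 <- comsia_fields(mols, g)
  c2 <- comsia_fields(mols_t, g_t)
  for (b in seq_along(c1)) expect_identical(c1[[b]]$values, c2[[b]]$values)

  # non-lattice joint translation with an explicitly shifted grid
  g_arb <- g; g_arb$origin <- g$origin + 0.737
  mols_a <- lapply(mols, function(m) { m$atoms$x <- m$atoms$x + 0.737
    m$atoms$y <- m$atoms$y + 0.737; m$atoms$z <- m$atoms$z + 0.737; m })
  g_arb2 <- g; g_arb2$origin <- g$origin   # reference frame
  f3 <- comfa_fields(mols, g_arb2)
  g_arb3 <- g; g_arb3$origin <- g$origin + 0.737
  f4 <- comfa_fields(mols_a, g_arb3)
  expect_equal(f3[[1]]$values, f4[[1]]$values, tolerance = 1e-12)
})

test_that("CoMFA kernels match closed-form Lennard-Jones and Coulomb", {
  q_atom <- 0.37
  mol <- make_point_atom(element = "O", pos = c(0, 0, 0), charge = q_atom)
  g <- build_grid(list(mol), spacing = 2, padding = 8)
  probe <- probe_comfa()
  f <- comfa_fields(list(mol), g, probe)
  ster <- f[[1]]$values[1, ]; elec <- f[[2]]$values[1, ]

  pars <- element_parameters("O")
  rm_ <- pars$vdw_radius + probe$vdw_radius
  eps <- sqrt(pars$lj_epsilon * probe$epsilon)
  for (p in list(c(2, 0, 0), c(0, 4, 0), c(2, 2, 0), c(0, 2, 2), c(4, 4, 2))) {
    i <- lattice_index(g, p)
    r <- sqrt(sum(p^2))
    lj <- eps * ((rm_ / r)^12 - 2 * (rm_ / r)^6)
    expect_equal(unname(ster[i]), min(max(lj, -30), 30), tolerance = 1e-10)
    cou <- 332.0636 * q_atom * probe$charge / r^2
    expect_equal(unname(elec[i]), min(max(cou, -30), 30), tolerance = 1e-10)
  }

  # at the atom center the steric energy is the clipped cutoff exactly,
  # and the electrostatic entry is masked
  i0 <- lattice_index(g, c(0, 0, 0))
  expect_identical(unname(ster[i0]), 30)
  expect_true(is.na(elec[i0]))

  # 12 A away the LJ contribution has decayed below 0.01 kcal/mol
  far <- lattice_index(g, c(0, 0, 6))
  expect_lt(abs(unname(f[[1]]$values[1, lattice_index(g, c(6, 6, 6))])), 0.01)

  expect_error(comfa_fields(list(molecule("nc", data.frame(
    element = "C", x = 0, y = 0, z = 0, vdw_radius = 1.7))), g),
    "no charges")
})

test_that("masked electrostatic entries are imputed with training means", {
  mols <- lapply(1:4, function(k)
    make_point_atom(paste0("m", k), pos = c(0.1 * k, 0, 0), charge = 0.2 * k))
  g <- build_grid(mols, 2, 4)
  f <- comfa_fields(mols, g)
  elec <- f[[2]]
  expect_true(anyNA(elec$values))
  imp <- impute_masked(elec, train_idx = 1:3)
  expect_false(anyNA(imp$values))
  na_cols <- which(apply(is.na(elec$values), 2, any))
  j <- na_cols[1]
  mu <- mean(elec$values[1:3, j], na.rm = TRUE)
  if (is.nan(mu)) mu <- 0
  i <- which(is.na(elec$values[, j]))[1]
  expect_equal(unname(imp$values[i, j]), mu)
})

test_that("CoMSIA kernel matches its closed form and is additive", {
  # electrostatic similarity with unit charge isolates the Gaussian kernel
  mol <- make_point_atom(pos = c(0, 0, 0), charge = 1)
  g <- build_grid(list(mol), spacing = 1, padding = 4)
  f <- comsia_fields(list(mol), g, alpha = 0.3,
                     properties = "electrostatic")[[1]]
  expect_equal(unname(f$values[1, lattice_index(g, c(0, 0, 0))]), -1.0,
               tolerance = 1e-12)
  expect_equal(unname(f$values[1, lattice_index(g, c(1, 0, 0))]), -exp(-0.3),
               tolerance = 1e-10)
  expect_equal(round(unname(f$values[1, lattice_index(g, c(1, 0, 0))]), 5), -0.74082)

  two <- molecule("two", data.frame(element = c("C", "C"),
                                    x = c(1, -1), y = 0, z = 0, charge = 1))
  two <- assign_atom_properties(two, "input")
  f2 <- comsia_fields(list(two), g, alpha = 0.3,
                      properties = "electrostatic")[[1]]
  expect_equal(unname(f2$values[1, lattice_index(g, c(0, 0, 0))]),
               2 * -exp(-0.3), tolerance = 1e-12)

  expect_error(comsia_fields(list(mol), g, alpha = 0), "positive")
  expect_error(comsia_fields(list(mol), g, alpha = -1), "positive")
})

test_that("CoMSIA agrees with a brute-force double loop on random molecules", {
  set.seed(42)
  for (rep in 1:3) {
    atoms <- data.frame(
      element = sample(c("C", "N", "O", "S", "F"), 5, replace = TRUE),
      x = runif(5, -2, 2), y = runif(5, -2, 2), z = runif(5, -2, 2),
      charge = runif(5, -0.5, 0.5))
    mol <- assign_atom_properties(molecule(paste0("r", rep), atoms), "input")
    mol$atoms$is_donor <- sample(c(TRUE, FALSE), 5, replace = TRUE)
    mol$atoms$is_acceptor <- sample(c(TRUE, FALSE), 5, replace = TRUE)
    g <- build_grid(list(mol), spacing = 2, padding = 2)
    pts <- grid_points(g)
    blocks <- comsia_fields(list(mol), g, alpha = 0.3)
    weights <- list(
      comsia_steric = mol$atoms$vdw_radius^3,
      comsia_electrostatic = mol$atoms$charge,
      comsia_hydrophobic = mol$atoms$hydrophobicity,
      comsia_donor = as.numeric(mol$atoms$is_donor & mol$atoms$element != "H"),
      comsia_acceptor = as.numeric(mol$atoms$is_acceptor))
    xyz <- coords(mol)
    for (b in blocks) {
      w <- weights[[b$field_type]]
      oracle <- vapply(seq_len(nrow(pts)), function(j) {
        s <- 0
        for (i in 1:5) {
          r2 <- sum((xyz[i, ] - pts[j, ])^2)
          s <- s + w[i] * exp(-0.3 * r2)
        }
        -s
      }, numeric(1))
      expect_equal(unname(b$values[1, ]), oracle, tolerance = 1e-10)
    }
  }
})

test_that("field values respect their theoretical ranges", {
  gen <- generate_dataset(generator_spec(seed = 6))
  mols <- gen$dataset$molecules[1:8]
  g <- build_grid(mols, 2, 4)
  f <- comfa_fields(mols, g)
  expect_true(all(f[[1]]$values >= -30 & f[[1]]$values <= 30))
  expect_true(all(is.na(f[[2]]$values) |
                  (f[[2]]$values >= -30 & f[[2]]$values <= 30)))
  # all-positive weights: similarity in [-sum(w), 0]
  ster <- comsia_fields(mols, g, properties = "steric")[[1]]
  for (m in 1:8) {
    wsum <- sum(mols[[m]]$atoms$vdw_radius^3)
    expect_true(all(ster$values[m, ] <= 0 & ster$values[m, ] >= -wsum))
  }
})

test_that("descriptor assembly concatenates blocks and validates rows", {
  dm <- make_dm(3, 4)
  expect_equal(dim(dm$x), c(3, 8))
  expect_equal(nrow(dm$column_meta), 8)
  expect_error(assemble_descriptors(list()), "no field blocks")
  b1 <- structure(list(field_type = "a",
                       values = matrix(0, 3, 2,
                                       dimnames = list(paste0("m", 1:3), NULL)),
                       units = "u"), class = "field_block")
  b2 <- structure(list(field_type = "b",
                       values = matrix(0, 4, 2,
                                       dimnames = list(paste0("m", 1:4), NULL)),
                       units = "u"), class = "field_block")
  expect_error(assemble_descriptors(list(b1, b2)), "mismatched row")
})
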