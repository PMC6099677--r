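test_that("EC50 to pEC50 conversion matches the definition and its algebra", {
  expect_equal(ec50_to_pec50(1), 6)
  expect_equal(round(ec50_to_pec50(0.062), 3), 7.208)
  expect_equal(round(ec50_to_pec50(130), 3), 3.886)
  expect_error(ec50_to_pec50(0), "positive")
  expect_error(ec50_to_pec50(-2), "positive")
  # strictly decreasing; one decade = exactly one log unit
  x <- c(0.01, 0.3, 5, 120)
  expect_true(all(diff(ec50_to_pec50(x)) < 0))
  expect_equal(ec50_to_pec50(10 * x), ec50_to_pec50(x) - 1)
})

test_that("every reference activity row converts to its printed pEC50", {
  ref <- load_reference_tables()$activity
  expect_equal(nrow(ref), 41)
  expect_true(all(abs(round(ec50_to_pec50(ref$ec50_uM), 3) - ref$pec50) <= 0.001))
})

test_that("SDF and MOL2 writers round-trip through the readers", {
  mols <- generate_dataset(generator_spec(seed = 3))$dataset$molecules
  ids <- vapply(mols, function(m) m$id, character(1))

  sdf <- tempfile(fileext = ".sdf")
  write_structures(mols, sdf, format = "sdf")
  back <- read_structures(sdf, format = "sdf")
  expect_length(back, 41)
  expect_identical(vapply(back, function(m) m$id, character(1)), ids)
  for (k in c(1, 20, 41)) {
    expect_equal(coords(back[[k]]), coords(mols[[k]]), tolerance = 1e-4)
    expect_identical(back[[k]]$atoms$element, mols[[k]]$atoms$element)
  }

  mol2 <- tempfile(fileext = ".mol2")
  write_structures(mols, mol2, format = "mol2")
  back2 <- read_structures(mol2, format = "mol2")
  expect_length(back2, 41)
  expect_identical(vapply(back2, function(m) m$id, character(1)), ids)
  # MOL2 carries partial charges verbatim (to the written precision)
  expect_equal(back2[[5]]$atoms$charge, mols[[5]]$atoms$charge,
               tolerance = 1e-4)
  expect_equal(coords(back2[[41]]), coords(mols[[41]]), tolerance = 1e-4)
})

test_that("written files parse in an independent third-party reader", {
  mols <- generate_dataset(generator_spec(seed = 3))$dataset$molecules[1:5]
  sdf <- tempfile(fileext = ".sdf")
  out <- tempfile(fileext = ".smi")
  write_structures(mols, sdf, format = "sdf")
  status <- suppressWarnings(system2("obabel", c(sdf, "-osmi", "-O", out),
                                     stdout = FALSE, stderr = FALSE))
  expect_identical(status, 0L)
  expect_length(readLines(out), 5)
})

test_that("reader errors are informative", {
  empty <- tempfile(fileext = ".sdf")
  file.create(empty)
  expect_error(read_structures(empty, "sdf"))
  expect_error(read_structures(tempfile(), "sdf"), "not found")
})

test_that("atom property assignment applies the H-bond and charge rules", {
  w <- assign_atom_properties(make_water(), "input")
  expect_true(w$atoms$is_donor[1])        # O carries the O-H donor flag
  expect_true(w$atoms$is_acceptor[1])
  expect_true(all(w$atoms$is_donor[2:3])) # H on O are donors
  expect_false(any(w$atoms$is_acceptor[2:3]))

  b <- assign_atom_properties(make_benzene(), "input")
  expect_false(any(b$atoms$is_donor[1:6]))
  expect_false(any(b$atoms$is_acceptor[1:6]))
  expect_equal(b$atoms$vdw_radius[1], 1.70)   # Bondi carbon

  e <- assign_atom_properties(make_ethanol(), "gasteiger")
  expect_lt(abs(sum(e$atoms$charge)), 0.01)   # neutral molecule
  expect_lt(e$atoms$charge[3], 0)             # O is negative
  expect_error(assign_atom_properties(
    molecule("x", data.frame(element = "Xx", x = 0, y = 0, z = 0)), "input"),
    "unknown element")
})

test_that("Kabsch alignment recovers rigid transforms and minimizes RMSD", {
  ref <- assign_atom_properties(make_ethanol(), "input")
  id_map <- cbind(1:9, 1:9)

  same <- kabsch_align(ref, ref, id_map)
  expect_lt(same$rmsd, 1e-6)
  expect_equal(same$rotation, diag(3), tolerance = 1e-8)

  # rotate 90 degrees about z and translate; alignment must undo it
  R90 <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  mob <- ref
  xyz <- t(R90 %*% t(coords(ref))) + matrix(c(5, -2, 1), 9, 3, byrow = TRUE)
  mob$atoms$x <- xyz[, 1]; mob$atoms$y <- xyz[, 2]; mob$atoms$z <- xyz[, 3]
  fit <- kabsch_align(mob, ref, id_map)
  expect_lt(fit$rmsd, 1e-8)
  expect_equal(coords(fit$molecule), coords(ref), tolerance = 1e-8)

  # perturb one atom: optimum must match an independent search over
  # rotations (Nelder-Mead on Euler angles, centroid-matched translation)
  mob2 <- ref
  mob2$atoms$x[1] <- mob2$atoms$x[1] + 0.1
  fit2 <- kabsch_align(mob2, ref, id_map)
  euler <- function(a) {
    cz <- cos(a[3]); sz <- sin(a[3]); cy <- cos(a[2]); sy <- sin(a[2])
    cx <- cos(a[1]); sx <- sin(a[1])
    matrix(c(cy * cz, cz * sx * sy - cx * sz, cx * cz * sy + sx * sz,
             cy * sz, cx * cz + sx * sy * sz, -cz * sx + cx * sy * sz,
             -sy, cy * sx, cx * cy), 3, 3, byrow = TRUE)
  }
  P <- coords(mob2); Q <- coords(ref)
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  obj <- function(a) sqrt(mean(rowSums((Pc %*% t(euler(a)) - Qc)^2)))
  best <- min(vapply(1:20, function(s) {
    set.seed(s)
    stats::optim(runif(3, -pi, pi), obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))$value
  }, numeric(1)))
  expect_equal(round(fit2$rmsd, 2), round(best, 2))
  expect_lte(fit2$rmsd, best + 1e-6)   # never worse than the search

  expect_error(kabsch_align(ref, ref, id_map[1:2, ]), "at least 3")
  line <- molecule("line", data.frame(element = rep("C", 3),
                                      x = 0:2, y = 0, z = 0))
  expect_error(kabsch_align(line, line, cbind(1:3, 1:3)), "collinear")
})

test_that("train/test splitting honours counts, seeds and manual lists", {
  ids <- paste0("c", 1:10)
  act <- seq(4.2, 7.6, length.out = 10)
  r1 <- split_train_test(ids, act, 0.7, "stratified_random", seed = 5)
  expect_equal(sum(r1 == "train"), 7)
  expect_equal(sum(r1 == "test"), 3)
  expect_identical(r1, split_train_test(ids, act, 0.7, "stratified_random",
                                        seed = 5))
  expect_error(split_train_test(ids, act, 0.7, "manual",
                                test_ids = c("c1", "zz")), "unknown id")

  # the published split: 12 flagged test compounds out of 41
  ref <- load_reference_tables()$predictions
  roles <- split_train_test(as.character(ref$compound), ref$experimental,
                            29 / 41, "manual",
                            test_ids = as.character(ref$compound[ref$test_set]))
  expect_equal(sum(roles == "test"), 12)
  expect_setequal(names(roles)[roles == "test"],
                  as.character(c(1, 6, 8, 10, 11, 14, 18, 23, 34, 37, 40, 41)))
})

test_that("aligned_dataset enforces consistency between ids and activities", {
  mols <- generate_dataset(generator_spec(seed = 2))$dataset$molecules[1:4]
  ids <- vapply(mols, function(m) m$id, character(1))
  act <- data.frame(id = ids, pec50 = c(5, 6, 7, 6.5))
  roles <- setNames(c("train", "train", "train", "test"), ids)
  expect_s3_class(aligned_dataset(mols, act, roles), "aligned_dataset")
  bad <- act; bad$id[1] <- "nope"
  expect_error(aligned_dataset(mols, bad, roles), "cover exactly")
  act2 <- act; act2$ec50_uM <- 10^(6 - act2$pec50) * c(1, 1, 1, 2)
  expect_error(aligned_dataset(mols, act2, roles), "disagree")
})
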