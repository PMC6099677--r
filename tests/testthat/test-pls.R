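test_that("column filter drops exactly the low-variance columns", {
  # columns with known sds 0.5, 1.5, 2.5, ..., 9.5 (constructed exactly)
  n <- 9
  base <- scale(seq_len(n))[, 1]          # sd exactly 1
  sds <- seq(0.5, 9.5, by = 1)
  v <- sapply(sds, function(s) base * s)
  rownames(v) <- paste0("m", 1:n)
  dm <- assemble_descriptors(list(structure(
    list(field_type = "f", values = v, units = "u"), class = "field_block")))
  out <- filter_columns(dm, threshold = 2.0)
  expect_identical(out$dropped, which(sds < 2.0))
  expect_equal(ncol(out$matrix$x), sum(sds >= 2.0))

  cst <- dm; cst$x[, 1] <- 5
  expect_true(1L %in% filter_columns(cst, 0.1)$dropped)
  expect_identical(filter_columns(dm, 0)$dropped, integer(0))
  expect_error(filter_columns(dm, 100), "lower the threshold")
})

test_that("PLS recovers exact linear signal and hits the OLS limit", {
  set.seed(10)
  n <- 12; p <- 4
  X <- matrix(rnorm(n * p), n, p)
  beta <- c(2, -1, 0.5, 3)
  y <- drop(X %*% beta) + 1.5
  fit <- pls_fit(X, y, ncomp = p)
  expect_lt(max(abs(fit$fitted - y)), 1e-8)

  # at full component count PLS equals ordinary least squares
  y2 <- y + rnorm(n, 0, 0.3)
  fit2 <- pls_fit(X, y2, ncomp = p)
  ols <- stats::lm(y2 ~ X)
  expect_equal(unname(fit2$fitted), unname(stats::fitted(ols)),
               tolerance = 1e-6)

  # duplicated columns leave predictions unchanged
  fit3 <- pls_fit(cbind(X, X), y2, ncomp = p)
  expect_equal(fit3$fitted, fit2$fitted, tolerance = 1e-8)

  expect_error(pls_fit(X, y, ncomp = 50), "ncomp")
  expect_error(predict(fit, X[, 1:2]), "columns")
})

test_that("PLS predictions match the mixOmics implementation", {
  set.seed(21)
  n <- 15; p <- 8
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("v", 1:p)))
  y <- rnorm(n)
  for (A in c(1, 3, 5)) {
    ours <- pls_fit(X, y, A)
    ref <- mixOmics::pls(X, y, ncomp = A, mode = "regression",
                         scale = FALSE)
    pref <- predict(ref, X)$predict[, 1, A]
    expect_equal(unname(ours$fitted), unname(pref), tolerance = 1e-8)
  }
})

test_that("leave-one-out q2 equals a from-scratch refit loop", {
  dm <- make_dm(8, 3, seed = 31)
  set.seed(31)
  y <- rnorm(8, 6, 1)
  res <- loo_q2(dm, y, max_components = 3, filter_threshold = 0.2,
                scaling = "comfa_std")
  for (N in 1:3) {
    preds <- vapply(1:8, function(i) {
      train <- setdiff(1:8, i)
      flt <- filter_columns(dm, 0.2, train_idx = train)
      scl <- scale_blocks(flt$matrix, "comfa_std", train_idx = train)
      f <- pls_fit(scl$x[train, , drop = FALSE], y[train], N)
      predict(f, scl$x[i, , drop = FALSE])
    }, numeric(1))
    q2_oracle <- 1 - sum((y - preds)^2) / sum((y - mean(y))^2)
    expect_equal(res$per_component$q2[N], q2_oracle, tolerance = 1e-10)
    expect_equal(res$per_component$sep[N],
                 sqrt(sum((y - preds)^2) / (8 - N - 1)), tolerance = 1e-10)
  }
  expect_error(loo_q2(dm, y, max_components = 7), "max_components")
})

test_that("q2 definition behaves at its fixed points", {
  # predictions equal to the observations give q2 = 1; predictions equal to
  # the training mean give q2 = 0 (checked through the same formula path
  # loo_q2 uses)
  y <- c(4.2, 5.1, 6.3, 7.0, 5.5)
  press_perfect <- sum((y - y)^2)
  press_mean <- sum((y - mean(y))^2)
  ss <- sum((y - mean(y))^2)
  expect_equal(1 - press_perfect / ss, 1)
  expect_equal(1 - press_mean / ss, 0)
})

test_that("model summary reports SEE, F and field contributions correctly", {
  set.seed(41)
  n <- 14
  base <- matrix(rnorm(n * 5), n, 5)
  rownames(base) <- paste0("m", 1:n)
  mk <- function(ft, v) structure(list(field_type = ft, values = v,
                                       units = "u"), class = "field_block")
  # two identical blocks share the signal symmetrically
  dm_sym <- assemble_descriptors(list(mk("A", base), mk("B", base)))
  y <- drop(base %*% c(1, -2, 0.5, 0, 1)) + rnorm(n, 0, 0.05) + 6
  s <- summarize_model(dm_sym, y, 3, filter_threshold = 0, scaling = "none")
  expect_equal(unname(s$field_contributions["A"]), 0.5, tolerance = 1e-6)
  expect_equal(sum(s$field_contributions), 1, tolerance = 1e-9)

  # perfect fit: r2_ncv = 1, SEE = 0
  y_exact <- drop(base %*% c(1, -2, 0.5, 0, 1))
  dm_one <- assemble_descriptors(list(mk("A", base)))
  s2 <- summarize_model(dm_one, y_exact, 5, filter_threshold = 0,
                        scaling = "none")
  expect_equal(s2$r2_ncv, 1, tolerance = 1e-9)
  expect_lt(s2$see, 1e-6)

  # signal planted only in block A: its contribution dominates
  noise <- matrix(rnorm(n * 5, 0, 0.05), n, 5)
  rownames(noise) <- rownames(base)
  dm_ab <- assemble_descriptors(list(mk("A", base), mk("B", noise)))
  s3 <- summarize_model(dm_ab, y, 3, filter_threshold = 0, scaling = "none")
  expect_gt(s3$field_contributions["A"], s3$field_contributions["B"])

  # F consistency with its r2-based definition
  expect_equal(s3$f_stat,
               (s3$r2_ncv / s3$n_components) /
                 ((1 - s3$r2_ncv) / (n - s3$n_components - 1)))
  expect_error(summarize_model(dm_one, y_exact, n - 1), "positive")
})

test_that("activity rescaling scales errors but not dimensionless statistics", {
  dm <- make_dm(10, 4, seed = 51)
  set.seed(51)
  y <- rnorm(10, 6, 1)
  a <- loo_q2(dm, y, 3, filter_threshold = 0, scaling = "none")
  b <- loo_q2(dm, 3 * y, 3, filter_threshold = 0, scaling = "none")
  expect_equal(b$per_component$q2, a$per_component$q2, tolerance = 1e-10)
  expect_equal(b$per_component$sep, 3 * a$per_component$sep, tolerance = 1e-10)
  sa <- summarize_model(dm, y, 2, filter_threshold = 0, scaling = "none")
  sb <- summarize_model(dm, 3 * y, 2, filter_threshold = 0, scaling = "none")
  expect_equal(sb$r2_ncv, sa$r2_ncv, tolerance = 1e-10)
  expect_equal(sb$f_stat, sa$f_stat, tolerance = 1e-10)
  expect_equal(sb$see, 3 * sa$see, tolerance = 1e-10)
})

test_that("leave-one-out is invariant to row order", {
  dm <- make_dm(9, 4, seed = 61)
  set.seed(61)
  y <- rnorm(9, 6, 1)
  perm <- sample(9)
  dmp <- dm
  dmp$x <- dm$x[perm, , drop = FALSE]
  dmp$row_ids <- dm$row_ids[perm]
  a <- loo_q2(dm, y, 3, filter_threshold = 0, scaling = "none")
  b <- loo_q2(dmp, y[perm], 3, filter_threshold = 0, scaling = "none")
  expect_equal(b$per_component$q2, a$per_component$q2, tolerance = 1e-10)
})

test_that("block order does not change the fitted model", {
  set.seed(71)
  n <- 12
  v1 <- matrix(rnorm(n * 3), n, 3); v2 <- matrix(rnorm(n * 3), n, 3)
  rownames(v1) <- rownames(v2) <- paste0("m", 1:n)
  mk <- function(ft, v) structure(list(field_type = ft, values = v,
                                       units = "u"), class = "field_block")
  y <- rnorm(n, 6, 1)
  s12 <- summarize_model(assemble_descriptors(list(mk("A", v1), mk("B", v2))),
                         y, 2, filter_threshold = 0)
  s21 <- summarize_model(assemble_descriptors(list(mk("B", v2), mk("A", v1))),
                         y, 2, filter_threshold = 0)
  expect_equal(s12$r2_ncv, s21$r2_ncv, tolerance = 1e-10)
  expect_equal(s12$field_contributions[c("A", "B")],
               s21$field_contributions[c("A", "B")], tolerance = 1e-10)
})
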