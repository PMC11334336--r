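euclid_d <- function(Y) {
  rn <- rownames(Y)
  if (is.null(rn)) rn <- sprintf("s%02d", seq_len(nrow(Y)))
  dist_matrix(as.matrix(dist(Y)), rn, "euclidean")
}

test_that("vif pruning removes collinear predictors", {
  set.seed(2)
  x1 <- rnorm(30); x2 <- rnorm(30)
  dup <- cbind(a = x1, b = x1, c = x2)
  pr <- vif_prune(dup)
  expect_identical(length(pr$removed), 1L)
  expect_true(all(pr$vif < 10))

  # orthogonal to each other and to the intercept
  orth <- qr.Q(qr(cbind(1, matrix(rnorm(30 * 3), 30))))[, 2:4]
  colnames(orth) <- c("u", "v", "w")
  pr2 <- vif_prune(orth)
  expect_identical(pr2$removed, character(0))
  expect_equal(unname(pr2$vif), rep(1, 3), tolerance = 1e-9)

  # x3 = x1 + x2 + tiny noise: exactly one of the triad goes
  x3 <- x1 + x2 + rnorm(30, 0, 1e-4)
  pr3 <- vif_prune(cbind(x1 = x1, x2 = x2, x3 = x3))
  expect_identical(length(pr3$removed), 1L)
  expect_true(all(pr3$vif < 10))
})

test_that("dbrda matches the direct least-squares oracle on Euclidean data", {
  set.seed(5)
  n <- 25
  X <- matrix(rnorm(n * 3), n, dimnames = list(sprintf("s%02d", 1:n),
                                               c("a", "b", "c")))
  Y <- cbind(X %*% c(1, -2, 0.5) + rnorm(n, 0, 0.7),
             rnorm(n), X[, 2] + rnorm(n))
  rownames(Y) <- rownames(X)
  res <- dbrda(euclid_d(Y), X, n_perm = 99, seed = 1)
  # oracle: classical RDA R2 from raw responses by least squares
  Yc <- scale(Y, scale = FALSE)
  H <- qr.fitted(qr(cbind(1, X)), Yc)
  expect_equal(res$R2, sum(H^2) / sum(Yc^2), tolerance = 1e-10)
  expect_equal(res$adj_R2, 1 - (1 - res$R2) * (n - 1) / (n - 3 - 1),
               tolerance = 1e-12)

  # perfect fit: response exactly linear in X
  Yp <- X %*% c(2, 1, -1)
  resp <- dbrda(euclid_d(cbind(Yp)), X, n_perm = 99, seed = 1)
  expect_equal(resp$R2, 1, tolerance = 1e-9)
  expect_error(dbrda(euclid_d(Y), matrix(rnorm(n * 24), n), 99, 1),
               "saturated")
})

test_that("hierarchical partitioning sums to the full-model adjusted R2", {
  set.seed(11)
  for (rep in 1:10) {
    n <- 30
    groups <- list(g1 = matrix(rnorm(n * 2), n), g2 = matrix(rnorm(n), n),
                   g3 = matrix(rnorm(n * 2), n))
    y <- groups$g1 %*% c(1, 0.5) + groups$g2 * 0.8 + rnorm(n)
    Y <- cbind(y, rnorm(n))
    rownames(Y) <- sprintf("s%02d", 1:n)
    groups <- lapply(groups, function(g) { rownames(g) <- rownames(Y); g })
    hp <- hierarchical_partition(euclid_d(Y), groups)
    expect_equal(sum(hp$effects), hp$total_adj_R2, tolerance = 1e-9)
  }
})

test_that("orthogonal groups get their marginal adjusted R2", {
  set.seed(21)
  n <- 200  # large n keeps the Ezekiel penalty asymmetry negligible
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 4), n))))[, 2:5]
  groups <- list(a = Q[, 1:2, drop = FALSE], b = Q[, 3:4, drop = FALSE])
  y <- Q %*% c(2, 1, -1, 0.5) + rnorm(n, 0, 0.3)
  Y <- cbind(y)
  rownames(Y) <- sprintf("s%02d", 1:n)
  groups <- lapply(groups, function(g) { rownames(g) <- rownames(Y); g })
  d <- euclid_d(Y)
  hp <- hierarchical_partition(d, groups)
  # centered orthonormal columns: joint fit decomposes additively, so the
  # independent effect matches each group's own adjusted R2 closely
  for (g in names(groups)) {
    marg <- trophgrad:::ezekiel_adj(
      trophgrad:::coords_r2(trophgrad:::pcoa_coords(d)$coords, groups[[g]]),
      n, 2)
    expect_lt(abs(hp$effects[[g]] - marg), 0.01)
  }
  # single group: effect equals the full-model adjusted R2
  hp1 <- hierarchical_partition(d, groups["a"])
  expect_equal(unname(hp1$effects), hp1$total_adj_R2, tolerance = 1e-12)
  # permutation invariance of group labels
  hp_rev <- hierarchical_partition(d, rev(groups))
  expect_equal(hp_rev$effects[names(hp$effects)], hp$effects,
               tolerance = 1e-12)
})

test_that("variation partitioning isolates shared structure", {
  set.seed(31)
  n <- 40
  shared <- matrix(rnorm(n), n)
  uniq <- matrix(rnorm(n), n)
  y <- shared * 2 + uniq + rnorm(n, 0, 0.4)
  Y <- cbind(y); rownames(Y) <- sprintf("s%02d", 1:n)
  mk <- function(m) { rownames(m) <- rownames(Y); m }
  # biotic signal duplicated into the climatic group
  vp <- variation_partition(euclid_d(Y), list(
    climatic = mk(cbind(shared, rnorm(n))), edaphic = mk(cbind(uniq)),
    biotic = mk(cbind(shared + rnorm(n, 0, 0.01)))))
  expect_gt(vp["shared_climatic_biotic", "fraction"], 0.2)
  expect_lt(abs(vp["unique_biotic", "fraction"]), 0.05)

  # orthogonal groups share nothing
  Q <- qr.Q(qr(matrix(rnorm(n * 3), n)))
  y2 <- Q %*% c(1, 1, 1) + rnorm(n, 0, 0.3)
  Y2 <- cbind(y2); rownames(Y2) <- rownames(Y)
  vp2 <- variation_partition(euclid_d(Y2), list(
    climatic = mk(Q[, 1, drop = FALSE]), edaphic = mk(Q[, 2, drop = FALSE]),
    biotic = mk(Q[, 3, drop = FALSE])))
  shared_rows <- grepl("^shared", rownames(vp2))
  expect_true(all(abs(vp2$fraction[shared_rows]) < 0.05))
  expect_error(variation_partition(euclid_d(Y2), list(
    a = mk(cbind(rep(0, n))), b = mk(Q[, 2, drop = FALSE]),
    c = mk(Q[, 3, drop = FALSE]))), "constant")
})

test_that("moving windows tile the gradient contiguously", {
  set.seed(41)
  n <- 10; S <- 30
  pres <- rand_presence(n, S, seed = 7)
  grad <- seq_len(n) + runif(n, 0, 0.1)
  Y <- matrix(rnorm(n * 2), n); rownames(Y) <- rownames(pres)
  g1 <- matrix(rnorm(n), n, dimnames = list(rownames(pres), "v1"))
  d <- euclid_d(Y)
  mw <- moving_window(pres, d, list(env = g1), grad, w = 8,
                      nst_config = null_config(n_null = 20, seed = 1))
  expect_identical(nrow(mw), 3L)  # n - w + 1
  expect_identical(strsplit(mw$members[2], ";")[[1]],
                   rownames(pres)[order(grad)][2:9])
  expect_true(all(diff(mw$center) > 0))
  one <- moving_window(pres, d, list(env = g1), grad, w = 10,
                       nst_config = null_config(n_null = 20, seed = 1))
  expect_identical(nrow(one), 1L)
  expect_error(moving_window(pres, d, list(env = g1), grad, w = 11),
               "larger")
})
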