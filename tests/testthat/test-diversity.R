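test_that("community distances match hand-computed values", {
  m <- rbind(s1 = c(2L, 1L, 0L), s2 = c(1L, 1L, 1L))
  colnames(m) <- c("a", "b", "c")
  tab <- asv_table(m, "bacteria")
  d <- community_distance(tab, "bray_curtis")
  # on relative abundances: x=(2/3,1/3,0), y=(1/3,1/3,1/3) -> BC = 1/3
  expect_equal(d["s1", "s2"], 1 / 3, tolerance = 1e-12)

  disjoint <- asv_table(rbind(s1 = c(1L, 0L), s2 = c(0L, 1L)) |>
                          (\(x) { colnames(x) <- c("a", "b"); x })(),
                        "bacteria")
  expect_equal(unclass(community_distance(disjoint, "bray_curtis"))["s1", "s2"], 1)
  expect_equal(unclass(community_distance(disjoint, "jaccard"))["s1", "s2"], 1)

  same <- asv_table(rbind(s1 = c(3L, 1L), s2 = c(3L, 1L)) |>
                      (\(x) { colnames(x) <- c("a", "b"); x })(), "bacteria")
  expect_equal(unclass(community_distance(same, "bray_curtis"))["s1", "s2"], 0)
  expect_equal(unclass(community_distance(same, "jaccard"))["s1", "s2"], 0)

  # Hellinger rows have unit sum of squares
  h <- hellinger(make_counts(4, 6, seed = 2))
  expect_equal(unname(rowSums(h^2)), rep(1, 4), tolerance = 1e-12)
})

test_that("nmds recovers embeddable configurations and centers output", {
  eu <- make_euclidean(12, seed = 3)
  ord <- nmds(eu$d, k = 2, n_starts = 5, seed = 1)
  expect_lt(ord$stress, 0.01)
  expect_equal(unname(colMeans(ord$coordinates)), c(0, 0), tolerance = 1e-9)

  # stress is non-increasing in k (nested models)
  for (s in 1:5) {
    dd <- make_euclidean(10, seed = s + 40, k = 4)$d
    s2 <- nmds(dd, k = 2, n_starts = 5, seed = 1)$stress
    s3 <- nmds(dd, k = 3, n_starts = 5, seed = 1)$stress
    expect_lte(s3, s2 + 1e-6)
  }
})

test_that("anosim separates groups and matches the enumeration oracle", {
  # two groups, all between-distances larger than all within-distances: R = 1
  pts <- rbind(matrix(rnorm(8, 0, 0.01), 4), matrix(rnorm(8, 10, 0.01), 4))
  rownames(pts) <- sprintf("s%d", 1:8)
  d <- dist_matrix(as.matrix(dist(pts)), rownames(pts), "euclidean")
  g <- rep(c("a", "b"), each = 4)
  expect_equal(anosim_test(d, g, n_perm = 99, seed = 1)$R, 1)
  expect_error(anosim_test(d, c("a", rep("b", 7)), 99, 1), "singleton")

  # exhaustive p on n = 6 equals a brute-force oracle over all 20 splits
  eu <- make_euclidean(6, seed = 9)
  g6 <- rep(c("a", "b"), each = 3)
  res <- anosim_test(eu$d, g6, exhaustive = TRUE)
  oracle_R <- function(groups) {
    m <- unclass(eu$d)
    rk <- matrix(0, 6, 6)
    rk[lower.tri(rk)] <- rank(m[lower.tri(m)])
    rk <- rk + t(rk)
    w <- c(); b <- c()
    for (i in 1:5) for (j in (i + 1):6) {
      if (groups[i] == groups[j]) w <- c(w, rk[i, j]) else b <- c(b, rk[i, j])
    }
    (mean(b) - mean(w)) / (15 / 2)
  }
  splits <- combn(6, 3)
  oracle_stats <- apply(splits, 2, function(idx) {
    gg <- rep("b", 6); gg[idx] <- "a"; oracle_R(gg)
  })
  expect_equal(res$p, mean(oracle_stats >= oracle_R(g6) - 1e-12))
  expect_equal(res$R, oracle_R(g6), tolerance = 1e-12)
})

test_that("mantel matches enumeration and is invariant to positive scaling", {
  eu <- make_euclidean(5, seed = 12)
  d2 <- dist_matrix(unclass(eu$d) * 3.7, rownames(unclass(eu$d)), "scaled")
  expect_equal(mantel_test(eu$d, d2, n_perm = 99, seed = 1)$r, 1,
               tolerance = 1e-12)

  other <- make_euclidean(5, seed = 13)$d
  res <- mantel_test(eu$d, other, exhaustive = TRUE)
  m1 <- unclass(eu$d); m2 <- unclass(other)
  v1 <- m1[lower.tri(m1)]
  rs <- vapply(oracle_perms(5), function(p) {
    mp <- m2[p, p]
    cor(v1, mp[lower.tri(mp)])
  }, 0)
  expect_equal(res$n_perm, 120L)
  expect_equal(res$p, mean(rs >= res$r - 1e-12))
  con <- dist_matrix(matrix(1, 5, 5) - diag(5), rownames(m1), "constant")
  expect_error(mantel_test(eu$d, con, 99, 1), "zero variance")
})

test_that("geographic distance matches the haversine closed form", {
  md <- data.frame(site_id = c("a", "b", "c"),
                   latitude = c(0, 1, 0), longitude = c(0, 0, 180))
  d <- geographic_distance(md)
  expect_equal(d["a", "a"], 0)
  expect_equal(d["a", "b"], 111.1949, tolerance = 1e-4)
  expect_equal(d["a", "c"], pi * 6371, tolerance = 1e-6)
  expect_error(geographic_distance(data.frame(site_id = "a",
                                              latitude = NA_real_,
                                              longitude = 1)), "missing")
})

test_that("distance decay recovers planted slopes per group", {
  set.seed(3)
  md <- data.frame(site_id = sprintf("s%02d", 1:12),
                   latitude = runif(12, 20, 45),
                   longitude = runif(12, 100, 120))
  geo <- geographic_distance(md)
  sim <- 1 - 0.001 * unclass(geo)
  diag(sim) <- 1
  comm <- dist_matrix(1 - sim, md$site_id, "bray_curtis")
  fit <- distance_decay(comm, geo)
  expect_equal(fit$groups$all$slope, -0.001, tolerance = 1e-10)

  const <- dist_matrix((1 - diag(12)) * 0.4, md$site_id, "bray_curtis")
  expect_equal(distance_decay(const, geo)$groups$all$slope, 0,
               tolerance = 1e-12)
})

test_that("distance-decay interaction test detects differing slopes", {
  hits <- vapply(1:50, function(s) {
    set.seed(s)
    n <- 30
    md <- data.frame(site_id = sprintf("s%02d", 1:(2 * n)),
                     latitude = c(runif(n, 20, 30), runif(n, 34, 45)),
                     longitude = runif(2 * n, 100, 120))
    geo <- geographic_distance(md)
    groups <- rep(c("low", "high"), each = n)
    g <- unclass(geo)
    slope <- ifelse(outer(groups, groups, function(a, b) a == "low" & b == "low"),
                    -0.002, -0.0005)
    sim <- 1 + slope * g + matrix(rnorm(length(g), 0, 0.05), nrow(g))
    sim <- (sim + t(sim)) / 2
    dmat <- 1 - sim; diag(dmat) <- 0
    dmat <- pmax(dmat, 0)
    comm <- dist_matrix(dmat, md$site_id, "bray_curtis")
    distance_decay(comm, geo, groups)$slope_difference_p < 0.05
  }, NA)
  expect_gte(mean(hits), 0.9)
})
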