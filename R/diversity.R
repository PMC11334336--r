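#' Community dissimilarity matrix
#'
#' Bray-Curtis on (optionally Hellinger-transformed) relative-abundance
#' profiles, or Jaccard on presence/absence. Bray-Curtis is
#' `sum|x_i - y_i| / sum(x_i + y_i)`; Jaccard is `1 - |intersection|/|union|`.
#' The Hellinger transform takes the square root of relative abundances, so
#' transformed rows have unit sum of squares.
#'
#' @param x an `asv_table`.
#' @param metric `"bray_curtis"` or `"jaccard"`.
#' @param transform `"none"` or `"hellinger"` (Bray-Curtis only).
#' @return a [dist_matrix()].
#' @export
community_distance <- function(x, metric = c("bray_curtis", "jaccard"),
                               transform = c("none", "hellinger")) {
  metric <- match.arg(metric)
  transform <- match.arg(transform)
  if (nrow(x$counts) < 2L) stop("need at least 2 samples")
  if (any(rowSums(x$counts) == 0)) stop("all-zero sample: distance undefined")
  n <- nrow(x$counts)
  if (metric == "bray_curtis") {
    p <- relative_abundance(x)
    if (transform == "hellinger") p <- sqrt(p)
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) {
      xi <- p[i, ]
      for (j in (i + 1L):n) {
        d[i, j] <- d[j, i] <- sum(abs(xi - p[j, ])) / sum(xi + p[j, ])
      }
    }
  } else {
    z <- x$counts > 0L
    inter <- tcrossprod(z * 1)          # |A intersect B|
    tot <- rowSums(z)
    uni <- outer(tot, tot, "+") - inter # |A union B|
    d <- 1 - inter / uni
    diag(d) <- 0
  }
  dist_matrix(d, sample_ids(x), metric)
}

#' Hellinger transform
#' @param counts count or abundance matrix (samples in rows).
#' @return matrix of square roots of relative abundances.
#' @export
hellinger <- function(counts) sqrt(counts / rowSums(counts))

#' Nonmetric multidimensional scaling
#'
#' Kruskal stress-1 NMDS via pool-adjacent-violators monotone regression
#' (`vegan::monoMDS`), taking the best of a metric (principal-coordinate)
#' start plus `n_starts` random starts.
#'
#' @param d a [dist_matrix()].
#' @param k target dimensionality (default 2).
#' @param n_starts random starts in addition to the metric start.
#' @param seed integer seed.
#' @param maxit maximum iterations per start.
#' @return an `ordination_result`: `coordinates` (centered samples x k),
#'   `stress` (Kruskal stress-1), `converged`, `n_starts_used`.
#' @export
nmds <- function(d, k = 2L, n_starts = 20L, seed = 1L, maxit = 300L) {
  stopifnot(k >= 1L)
  dd <- stats::as.dist(unclass(d))
  best <- NULL
  with_seed(seed, {
    starts <- vector("list", n_starts + 1L)
    # metric start: PCoA coordinates (padded if rank-deficient)
    pc <- suppressWarnings(stats::cmdscale(dd, k = k))
    if (ncol(pc) < k) pc <- cbind(pc, matrix(0, nrow(pc), k - ncol(pc)))
    starts[[1L]] <- pc
    for (s in seq_len(n_starts)) {
      starts[[s + 1L]] <- matrix(stats::rnorm(attr(dd, "Size") * k), ncol = k)
    }
    for (st in starts) {
      fit <- vegan::monoMDS(dd, y = st, k = k, model = "global",
                            maxit = maxit, smin = 1e-7, sfgrmin = 1e-7)
      if (is.null(best) || fit$stress < best$stress) best <- fit
    }
  })
  coords <- scale(best$points, scale = FALSE)
  dimnames(coords) <- list(rownames(as.matrix(d)), paste0("NMDS", seq_len(k)))
  structure(list(coordinates = coords, stress = best$stress,
                 converged = best$maxits < maxit || best$stress < 1e-6,
                 n_starts_used = n_starts + 1L),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf("<ordination> %d points, k = %d, stress = %.4f\n",
              nrow(x$coordinates), ncol(x$coordinates), x$stress))
  invisible(x)
}

# ANOSIM R for a ranked distance matrix and grouping.
anosim_stat <- function(rank_d, groups) {
  n <- nrow(rank_d)
  same <- outer(groups, groups, "==")
  lt <- lower.tri(rank_d)
  rw <- rank_d[lt & same]
  rb <- rank_d[lt & !same]
  m <- n * (n - 1) / 2
  (mean(rb) - mean(rw)) / (m / 2)
}

#' Analysis of similarity (ANOSIM)
#'
#' Tests whether between-group dissimilarities exceed within-group ones on
#' ranked distances: `R = (mean rank between - mean rank within) / (M/2)`
#' with `M = n(n-1)/2`. The p-value comes from label permutations
#' (add-one corrected), or from exhaustive enumeration of all distinct label
#' arrangements when `exhaustive = TRUE`.
#'
#' @param d a [dist_matrix()].
#' @param groups group labels, one per sample; every group needs >= 2
#'   members.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param exhaustive enumerate all label arrangements (small n only).
#' @return list with `R`, `p`, `n_perm`.
#' @export
anosim_test <- function(d, groups, n_perm = 999L, seed = 1L,
                        exhaustive = FALSE) {
  groups <- as.character(groups)
  if (length(unique(groups)) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("singleton group")
  m <- unclass(d)
  rank_d <- m
  rank_d[lower.tri(m)] <- rank(lower_tri(m))
  rank_d[upper.tri(m)] <- t(rank_d)[upper.tri(m)]
  obs <- anosim_stat(rank_d, groups)
  if (exhaustive) {
    perms <- label_arrangements(groups)
    stats_all <- vapply(perms, function(g) anosim_stat(rank_d, g), 0)
    p <- mean(stats_all >= obs - 1e-12)
    n_used <- length(perms)
  } else {
    hits <- with_seed(seed, {
      sum(vapply(seq_len(n_perm), function(i) {
        anosim_stat(rank_d, sample(groups)) >= obs - 1e-12
      }, NA))
    })
    p <- (hits + 1) / (n_perm + 1)
    n_used <- n_perm
  }
  list(R = obs, p = p, n_perm = n_used)
}

#' Mantel test
#'
#' Pearson correlation between the lower triangles of two distance matrices;
#' significance by permuting the row/column order of the second matrix
#' (one-sided upper, add-one corrected), or by exhaustive enumeration of all
#' `n!` orders when `exhaustive = TRUE`.
#'
#' @param d1,d2 [dist_matrix()] objects over the same ids.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param exhaustive enumerate all permutations (n <= 8).
#' @return list with `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999L, seed = 1L,
                        exhaustive = FALSE) {
  m1 <- unclass(d1); m2 <- unclass(d2)
  if (!identical(dim(m1), dim(m2))) stop("dimension mismatch")
  if (!is.null(rownames(m1)) && !is.null(rownames(m2)) &&
      !identical(rownames(m1), rownames(m2))) stop("id mismatch")
  v1 <- lower_tri(m1)
  if (stats::sd(v1) == 0 || stats::sd(lower_tri(m2)) == 0) {
    stop("zero variance in distances")
  }
  r_for <- function(perm) stats::cor(v1, lower_tri(m2[perm, perm]))
  obs <- r_for(seq_len(nrow(m1)))
  if (exhaustive) {
    perms <- all_permutations(nrow(m1))
    rs <- apply(perms, 1L, r_for)
    p <- mean(rs >= obs - 1e-12)
    n_used <- nrow(perms)
  } else {
    hits <- with_seed(seed, {
      sum(vapply(seq_len(n_perm), function(i) {
        r_for(sample.int(nrow(m1))) >= obs - 1e-12
      }, NA))
    })
    p <- (hits + 1) / (n_perm + 1)
    n_used <- n_perm
  }
  list(r = obs, p = p, n_perm = n_used)
}

#' Great-circle distances between sites
#'
#' Haversine distance in kilometers (Earth radius 6371 km) from latitude and
#' longitude in decimal degrees.
#'
#' @param metadata data.frame with `site_id`, `latitude`, `longitude`.
#' @return a [dist_matrix()] in km.
#' @export
geographic_distance <- function(metadata) {
  if (anyNA(metadata$latitude) || anyNA(metadata$longitude)) {
    stop("missing coordinates")
  }
  lat <- metadata$latitude * pi / 180
  lon <- metadata$longitude * pi / 180
  n <- length(lat)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    a <- sin((lat - lat[i]) / 2)^2 +
      cos(lat[i]) * cos(lat) * sin((lon - lon[i]) / 2)^2
    d[i, ] <- 2 * 6371 * asin(pmin(1, sqrt(a)))
  }
  diag(d) <- 0
  dist_matrix(d, metadata$site_id, "haversine_km")
}

#' Distance-decay relationship
#'
#' OLS of community similarity (1 - dissimilarity) on geographic distance,
#' using within-group site pairs only. When two groups are supplied, the
#' difference between their slopes is tested through the distance x group
#' interaction term of a pooled OLS over within-group pairs.
#'
#' @param community_d community [dist_matrix()].
#' @param geo_d geographic [dist_matrix()] over the same ids.
#' @param groups optional per-site labels defining groups.
#' @return list of per-group fits (`slope`, `intercept`, `p`, `n_pairs`)
#'   plus `slope_difference_p` when exactly two groups are given.
#' @export
distance_decay <- function(community_d, geo_d, groups = NULL) {
  m <- unclass(community_d); g <- unclass(geo_d)
  if (!identical(dim(m), dim(g))) stop("dimension mismatch")
  n <- nrow(m)
  if (is.null(groups)) groups <- rep("all", n)
  groups <- as.character(groups)
  pair_rows <- which(lower.tri(m), arr.ind = TRUE)
  same <- groups[pair_rows[, 1L]] == groups[pair_rows[, 2L]]
  df <- data.frame(similarity = 1 - m[lower.tri(m)],
                   distance = g[lower.tri(g)],
                   group = groups[pair_rows[, 1L]])[same, ]
  fits <- lapply(split(df, df$group), function(sub) {
    if (nrow(sub) < 3L) stop("group with fewer than 3 within-group pairs")
    fit <- stats::lm(similarity ~ distance, data = sub)
    co <- summary(fit)$coefficients
    list(slope = unname(co["distance", 1L]),
         intercept = unname(co["(Intercept)", 1L]),
         p = unname(co["distance", 4L]), n_pairs = nrow(sub))
  })
  out <- list(groups = fits)
  if (length(unique(df$group)) == 2L) {
    inter <- stats::lm(similarity ~ distance * group, data = df)
    co <- summary(inter)$coefficients
    out$slope_difference_p <- unname(co[4L, 4L])
  }
  out
}
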