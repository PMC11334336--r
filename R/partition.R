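#' Variance-inflation-factor pruning
#'
#' Iteratively removes the predictor with the largest VIF
#' (`1 / (1 - R^2)` of that column regressed on the others) until all VIFs
#' are below the limit.
#'
#' @param X numeric site x predictor matrix with column names.
#' @param limit VIF ceiling (default 10, the conventional cutoff).
#' @return list with the pruned matrix `X`, `removed` (names, in removal
#'   order) and `vif` (final values).
#' @export
vif_prune <- function(X, limit = 10) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  removed <- character(0)
  const <- apply(X, 2L, stats::sd) == 0
  if (any(const)) {  # constant columns carry no information and break VIF
    removed <- colnames(X)[const]
    X <- X[, !const, drop = FALSE]
  }
  vifs_of <- function(M) {
    vapply(seq_len(ncol(M)), function(j) {
      r2 <- suppressWarnings(
        summary(stats::lm(M[, j] ~ M[, -j, drop = FALSE]))$r.squared)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, 0)
  }
  while (ncol(X) > 1L) {
    v <- vifs_of(X)
    if (all(v < limit)) break
    worst <- which.max(v)
    removed <- c(removed, colnames(X)[worst])
    X <- X[, -worst, drop = FALSE]
  }
  if (ncol(X) == 0L) stop("collinearity unresolvable: all predictors removed")
  final <- if (ncol(X) > 1L) vifs_of(X) else 1
  list(X = X, removed = removed,
       vif = stats::setNames(final, colnames(X)))
}

# Principal-coordinate decomposition of a distance matrix. Negative
# eigenvalues are dropped; the discarded inertia fraction is returned.
pcoa_coords <- function(d, tol = 1e-9) {
  m <- unclass(d)
  n <- nrow(m)
  G <- -0.5 * m^2
  G <- sweep(G, 1L, rowMeans(G))
  G <- sweep(G, 2L, colMeans(G))  # sequential sweeps == -0.5 * J m^2 J
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  pos <- e$values > tol * max(abs(e$values))
  neg_mass <- sum(abs(e$values[e$values < 0]))
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  rownames(coords) <- rownames(m)
  list(coords = coords, eig = e$values[pos],
       discarded_inertia = neg_mass / (sum(e$values[pos]) + neg_mass))
}

# Constrained fraction of inertia: R^2 of regressing PCoA coordinates on X.
coords_r2 <- function(Y, X) {
  Yc <- scale(Y, scale = FALSE)
  fit <- qr.fitted(qr(cbind(1, X)), Yc)
  sum(fit^2) / sum(Yc^2)
}

ezekiel_adj <- function(r2, n, p) 1 - (1 - r2) * (n - 1) / (n - p - 1)

#' Distance-based redundancy analysis
#'
#' Principal coordinates of the dissimilarity matrix (negative eigenvalues
#' dropped, discarded inertia logged) are regressed on the predictors. R^2 is
#' the constrained fraction of retained inertia; adjusted R^2 uses Ezekiel's
#' formula; significance comes from unrestricted row permutations of the
#' predictors.
#'
#' @param d a [dist_matrix()].
#' @param X numeric site x predictor matrix (VIF-pruned).
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return list: `R2`, `adj_R2`, `F`, `p`, `n_perm`, `discarded_inertia`.
#' @export
dbrda <- function(d, X, n_perm = 999L, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (!is.null(rownames(X)) && !identical(rownames(X), rownames(unclass(d)))) {
    stop("id mismatch between distances and predictors")
  }
  if (p >= n - 1L) stop("saturated model")
  pc <- pcoa_coords(d)
  r2 <- coords_r2(pc$coords, X)
  Fstat <- (r2 / p) / ((1 - r2) / (n - p - 1))
  hits <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      coords_r2(pc$coords, X[sample.int(n), , drop = FALSE]) >= r2 - 1e-12
    }, NA))
  })
  list(R2 = r2, adj_R2 = ezekiel_adj(r2, n, p), F = Fstat,
       p = (hits + 1) / (n_perm + 1), n_perm = n_perm,
       discarded_inertia = pc$discarded_inertia)
}

# Adjusted R^2 of every non-empty subset of predictor groups, on shared
# PCoA coordinates. `groups` is a named list of site x variable matrices.
subset_adj_r2 <- function(d, groups) {
  k <- length(groups)
  if (k > 8L) stop("at most 8 predictor groups (2^k - 1 subset models)")
  for (g in groups) {
    if (any(apply(g, 2L, stats::sd) == 0)) stop("constant predictor column")
  }
  pc <- pcoa_coords(d)
  n <- nrow(pc$coords)
  subsets <- lapply(seq_len(2^k - 1L), function(code) {
    which(bitwAnd(code, 2^(seq_len(k) - 1L)) > 0L)
  })
  vals <- vapply(subsets, function(idx) {
    X <- do.call(cbind, groups[idx])
    if (ncol(X) >= n - 1L) stop("saturated subset model")
    ezekiel_adj(coords_r2(pc$coords, X), n, ncol(X))
  }, 0)
  list(subsets = subsets, adj_r2 = vals, k = k)
}

#' Hierarchical partitioning of community variation over predictor groups
#'
#' Fits the adjusted R^2 of every non-empty subset of groups and assigns
#' each group its independent effect: the average over hierarchy levels of
#' its mean incremental adjusted R^2 (the Shapley decomposition). Effects
#' sum exactly to the full-model adjusted R^2.
#'
#' @param d a [dist_matrix()].
#' @param groups named list of site x variable matrices (<= 8 groups).
#' @return list: `effects` (named, summing to `total_adj_R2`),
#'   `total_adj_R2`, `subset_adj_r2` (all-subsets table).
#' @export
hierarchical_partition <- function(d, groups) {
  sub <- subset_adj_r2(d, groups)
  k <- sub$k
  codes <- vapply(sub$subsets, function(s) sum(2^(s - 1L)), 0)
  r2_of <- function(idx) {
    if (length(idx) == 0L) return(0)
    sub$adj_r2[match(sum(2^(idx - 1L)), codes)]
  }
  effects <- numeric(k)
  others <- function(g) setdiff(seq_len(k), g)
  for (g in seq_len(k)) {
    oth <- others(g)
    # Shapley weights over subsets S of the other groups
    for (code in 0:(2^(k - 1L) - 1L)) {
      S <- oth[which(bitwAnd(code, 2^(seq_along(oth) - 1L)) > 0L)]
      h <- length(S)
      w <- factorial(h) * factorial(k - h - 1L) / factorial(k)
      effects[g] <- effects[g] + w * (r2_of(c(S, g)) - r2_of(S))
    }
  }
  names(effects) <- names(groups)
  list(effects = effects, total_adj_R2 = r2_of(seq_len(k)),
       subset_adj_r2 = data.frame(
       subset = vapply(sub$subsets, function(s)
         paste(names(groups)[s], collapse = "+"), ""),
       adj_R2 = sub$adj_r2))
}

#' Variation partitioning over three predictor groups
#'
#' Inclusion-exclusion over the seven subset adjusted R^2 values, yielding
#' unique, pairwise-shared and fully-shared fractions (slightly negative
#' fractions are reported as-is) plus the residual.
#'
#' @param d a [dist_matrix()].
#' @param groups named list of exactly 3 site x variable matrices.
#' @return data.frame of fractions with rownames naming each component.
#' @export
variation_partition <- function(d, groups) {
  if (length(groups) != 3L) stop("variation partitioning needs exactly 3 groups")
  sub <- subset_adj_r2(d, groups)
  codes <- vapply(sub$subsets, function(s) sum(2^(s - 1L)), 0)
  f <- function(...) sub$adj_r2[match(sum(2^(c(...) - 1L)), codes)]
  g3 <- f(1) + f(2) + f(3) - f(1, 2) - f(1, 3) - f(2, 3) + f(1, 2, 3)
  nm <- names(groups)
  out <- data.frame(fraction = c(
    f(1, 2, 3) - f(2, 3),
    f(1, 2, 3) - f(1, 3),
    f(1, 2, 3) - f(1, 2),
    f(1) + f(2) - f(1, 2) - g3,
    f(1) + f(3) - f(1, 3) - g3,
    f(2) + f(3) - f(2, 3) - g3,
    g3,
    1 - f(1, 2, 3)))
  rownames(out) <- c(paste0("unique_", nm),
                     paste0("shared_", c(paste(nm[1], nm[2], sep = "_"),
                                         paste(nm[1], nm[3], sep = "_"),
                                         paste(nm[2], nm[3], sep = "_"))),
                     "shared_all", "residual")
  out
}

#' Assemble predictor groups from metadata and per-site network metrics
#'
#' Builds the four canonical groups: climatic (MAT, MAP, MTCM, PSCV),
#' edaphic (pH, SWC, C_N), P-B associations (edges, connectance) and V-B
#' associations (edges, connectance).
#'
#' @param metadata site metadata `data.frame`.
#' @param pb_metrics,vb_metrics [site_subnetworks()] outputs aligned to the
#'   metadata sites (may be `NULL` to omit a group).
#' @return named list of matrices with site ids as rownames.
#' @export
predictor_groups <- function(metadata, pb_metrics = NULL, vb_metrics = NULL) {
  rn <- metadata$site_id
  grab <- function(cols) {
    m <- as.matrix(metadata[, cols, drop = FALSE]); rownames(m) <- rn; m
  }
  groups <- list(climatic = grab(c("MAT", "MAP", "MTCM", "PSCV")),
                 edaphic = grab(c("pH", "SWC", "C_N")))
  net_group <- function(metrics, prefix) {
    metrics <- metrics[match(rn, metrics$site_id), ]
    m <- cbind(metrics$E, metrics$C)
    dimnames(m) <- list(rn, paste0(prefix, c("_edges", "_connectance")))
    m
  }
  if (!is.null(pb_metrics)) groups$PB <- net_group(pb_metrics, "PB")
  if (!is.null(vb_metrics)) groups$VB <- net_group(vb_metrics, "VB")
  # constant predictors (e.g. covariates held fixed in a microcosm arm)
  # carry no variance and would inflate the parameter count
  groups <- lapply(groups, function(m) {
    m[, apply(m, 2L, stats::sd) > 0, drop = FALSE]
  })
  groups[vapply(groups, ncol, 0L) > 0L]
}

#' Moving-window scan along a gradient
#'
#' Sites are sorted by the gradient; windows are contiguous runs of `w`
#' sites stepping one site at a time (`n - w + 1` windows), so the
#' low-gradient group transitions smoothly into the high-gradient group.
#' Each window carries the deterministic fraction (1 - NST) of the focal
#' community and the hierarchical-partitioning independent effects of the
#' predictor groups.
#'
#' @param presence binary samples x taxa matrix of the focal (bacterial)
#'   community, rows named by site.
#' @param d community [dist_matrix()] over the same sites.
#' @param groups named list of predictor matrices (rownames = site ids).
#' @param gradient per-site gradient values, aligned with `presence` rows.
#' @param w window size; defaults to the size of the initial low-gradient
#'   group under `split` (the survey's latitude-32 split).
#' @param split gradient split point used only for the default `w`.
#' @param nst_config a [null_config()] for the per-window NST.
#' @return data.frame: window_index, center (median gradient), n_sites,
#'   determinism, one `effect_*` column per group, total_adj_R2.
#' @export
moving_window <- function(presence, d, groups, gradient, w = NULL,
                          split = 32, nst_config = null_config(n_null = 100L)) {
  n <- nrow(presence)
  min_w <- sum(vapply(groups, ncol, 0L)) + 5L
  if (is.null(w)) w <- min(n, max(sum(gradient < split), min_w))
  if (w > n) stop("window larger than the number of sites")
  if (w < min_w) stop(sprintf("window size %d below minimum viable %d", w, min_w))
  ord <- order(gradient)
  dm <- unclass(d)
  out <- lapply(seq_len(n - w + 1L), function(i) {
    idx <- ord[i:(i + w - 1L)]
    cfg <- nst_config
    cfg$seed <- child_seed(nst_config$seed, paste0("window", i))
    det <- nst(presence[idx, , drop = FALSE], cfg)$determinism
    dw <- dist_matrix(dm[idx, idx], rownames(dm)[idx], attr(d, "metric"))
    gw <- lapply(groups, function(m) m[idx, , drop = FALSE])
    hp <- hierarchical_partition(dw, gw)
    eff <- as.data.frame(t(hp$effects))
    names(eff) <- paste0("effect_", names(groups))
    cbind(data.frame(window_index = i,
                     center = stats::median(gradient[ord][i:(i + w - 1L)]),
                     members = paste(rownames(presence)[idx], collapse = ";"),
                     n_sites = w, determinism = det,
                     stringsAsFactors = FALSE),
          eff, total_adj_R2 = hp$total_adj_R2)
  })
  do.call(rbind, out)
}
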