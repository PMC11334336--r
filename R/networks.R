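#' Spearman correlation block between predator and prey tables
#'
#' Pairwise Spearman rank correlations (average ranks for ties) between every
#' predator ASV and every prey ASV across the shared samples, computed on
#' relative abundances. Constant vectors yield an undefined correlation,
#' recorded as 0 with a warning.
#'
#' @param prey an `asv_table` (bacteria).
#' @param predator an `asv_table` (protist or virus).
#' @return a `correlation_block`: list with `predator_ids`, `prey_ids` and
#'   `rho` (predators x prey matrix).
#' @export
spearman_block <- function(prey, predator) {
  if (!identical(sample_ids(prey), sample_ids(predator))) {
    stop("prey and predator tables must share samples in the same order")
  }
  # per-sample fractions; a sample emptied by column filtering contributes
  # zero abundance for every ASV rather than failing normalization
  rel_safe <- function(tab) {
    tot <- rowSums(tab$counts)
    sweep(tab$counts, 1L, pmax(tot, 1L), "/")
  }
  rp <- rel_safe(predator)
  rb <- rel_safe(prey)
  rho <- suppressWarnings(stats::cor(rp, rb, method = "spearman"))
  if (anyNA(rho)) {
    warning("constant ASV vector(s): undefined correlations recorded as 0")
    rho[is.na(rho)] <- 0
  }
  structure(list(predator_ids = asv_ids(predator), prey_ids = asv_ids(prey),
                 rho = rho), class = "correlation_block")
}

# Spectrum of the symmetric bipartite embedding [[0, A], [A', 0]] restricted
# to the active subnetwork (rows/columns with at least one surviving entry):
# the +/- singular values of the restricted block plus its explicit zero
# modes (odd components such as predator stars contribute exact zeros, a
# level-clustering signature the spacing test must see).
embedded_spectrum <- function(A, tol = 1e-10) {
  act_r <- rowSums(A != 0) > 0
  act_c <- colSums(A != 0) > 0
  A <- A[act_r, act_c, drop = FALSE]
  if (!all(dim(A) > 0)) return(numeric(0))
  sv <- svd(A, nu = 0, nv = 0)$d
  sv <- sv[sv > tol]
  n_zero <- nrow(A) + ncol(A) - 2L * length(sv)
  sort(c(-sv, rep(0, n_zero), sv))
}

# Unfold a spectrum with a cubic smoothing spline on the empirical CDF and
# return nearest-neighbour spacings normalized to unit mean.
unfold_spacings <- function(ev, nknots = 10L) {
  n <- length(ev)
  Fhat <- (seq_len(n) - 0.5) / n
  if (length(unique(ev)) < 10L || stats::IQR(ev) <= 0) {
    # spline unfolding undefined on (near-)degenerate spectra; unfold by
    # average ranks so repeated levels still yield zero spacings
    xi <- rank(ev, ties.method = "average")
  } else {
    fit <- suppressWarnings(
      stats::smooth.spline(ev, Fhat,
                           nknots = min(nknots, length(unique(ev)) - 1L)))
    xi <- n * stats::predict(fit, ev)$y
  }
  s <- pmax(diff(xi), 0)
  if (mean(s) <= 0) return(rep(1, n - 1L))
  s / mean(s)
}

# Chi-square goodness of fit of spacings to a reference spacing law over
# fixed bins on [0, smax] plus an overflow bin (large unfolded gaps carry
# real evidence); sparse bins are pooled until expected counts are >= 5.
spacing_gof <- function(s, cdf, bins = 40L, smax = 3) {
  if (length(s) < 10L) return(list(chi2 = NA_real_, p = NA_real_))
  edges <- seq(0, smax, length.out = bins + 1L)
  obs <- c(tabulate(findInterval(pmin(s, smax - 1e-12), edges,
                                 rightmost.closed = TRUE), nbins = bins),
           sum(s > smax))
  exp_k <- length(s) * c(diff(cdf(edges)), 1 - cdf(smax))
  while (length(exp_k) > 2L && min(exp_k) < 5) {
    k <- which.min(exp_k)
    j <- if (k == length(exp_k)) k - 1L else k + 1L
    exp_k[j] <- exp_k[j] + exp_k[k]; obs[j] <- obs[j] + obs[k]
    exp_k <- exp_k[-k]; obs <- obs[-k]
  }
  chi2 <- sum((obs - exp_k)^2 / exp_k)
  df <- length(exp_k) - 1L
  list(chi2 = chi2, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

poisson_cdf <- function(u) 1 - exp(-u)
wigner_cdf <- function(u) 1 - exp(-pi * u^2 / 4)

#' Random-matrix-theory correlation threshold
#'
#' Scans candidate cutoffs: at each threshold the correlation block is
#' hard-thresholded (entries with `|rho|` below the cutoff zeroed), embedded
#' as the off-diagonal blocks of a symmetric matrix, and the nearest-
#' neighbour spacing distribution (NNSD) of the unfolded nonzero spectrum is
#' scored against the Poisson law `exp(-u)` (uncorrelated signal) and the
#' Wigner-Dyson surmise `(pi u/2) exp(-pi u^2/4)` (correlated noise). The
#' chosen threshold St is the smallest cutoff whose NNSD is
#' Poisson-consistent (chi-square p > 0.05).
#'
#' @param block a [spearman_block()] result.
#' @param scan threshold grid (default 0.30-0.98 by 0.01).
#' @param min_eigen minimum spectrum size needed to score a threshold
#'   (default 30; the scan stops once the active spectrum shrinks below it).
#' @param bins NNSD histogram bins on `[0, 3]`.
#' @param p_cut Poisson-consistency level.
#' @return an `rmt_scan`: data.frame `scan` (threshold, n_eigenvalues,
#'   chi2_poisson, p_poisson, chi2_wigner, p_wigner) plus `chosen_threshold`.
#'   Errors (attaching the scan table) if no threshold is Poisson-consistent.
#' @export
rmt_threshold <- function(block, scan = seq(0.30, 0.98, by = 0.01),
                          min_eigen = 30L, bins = 40L, p_cut = 0.05) {
  rho <- block$rho
  rows <- list()
  for (s in scan) {
    A <- rho * (abs(rho) >= s)
    ev <- embedded_spectrum(A)
    if (length(ev) < min_eigen) {
      rows[[length(rows) + 1L]] <- data.frame(
        threshold = s, n_eigenvalues = length(ev), chi2_poisson = NA,
        p_poisson = NA, chi2_wigner = NA, p_wigner = NA)
      break  # spectra only shrink as the threshold rises
    }
    sp <- unfold_spacings(ev)
    gp <- spacing_gof(sp, poisson_cdf, bins)
    gw <- spacing_gof(sp, wigner_cdf, bins)
    rows[[length(rows) + 1L]] <- data.frame(
      threshold = s, n_eigenvalues = length(ev),
      chi2_poisson = gp$chi2, p_poisson = gp$p,
      chi2_wigner = gw$chi2, p_wigner = gw$p)
  }
  tab <- do.call(rbind, rows)
  # Prefer the stable Poisson region: the smallest consistent threshold with
  # no rejection above it (transient acceptances inside the noise regime are
  # spurious). Sporadic late rejections on very small spectra can leave no
  # stable region; fall back to the first consistent threshold then.
  ok <- !is.na(tab$p_poisson) & tab$p_poisson > p_cut
  evaluable <- !is.na(tab$p_poisson)
  chosen <- NA_real_
  stable <- NA
  if (any(ok)) {
    rejected <- which(evaluable & !ok)
    lo <- if (length(rejected)) max(rejected) + 1L else 1L
    cand <- which(ok)
    stable_cand <- cand[cand >= lo]
    if (length(stable_cand)) {
      chosen <- tab$threshold[min(stable_cand)]
      stable <- TRUE
    } else {
      chosen <- tab$threshold[min(cand)]
      stable <- FALSE
    }
  }
  if (is.na(chosen)) {
    cond <- simpleError("no threshold reaches Poisson consistency")
    cond$scan <- tab
    stop(cond)
  }
  structure(list(scan = tab, chosen_threshold = chosen, stable = stable),
            class = "rmt_scan")
}

#' @export
print.rmt_scan <- function(x, ...) {
  cat(sprintf("<rmt_scan> %d thresholds scanned, St = %.2f\n",
              nrow(x$scan), x$chosen_threshold))
  invisible(x)
}

#' Build the binary bipartite meta-network
#'
#' An edge links a predator and a prey ASV when `|rho|` (or `rho` with
#' `positive_only = TRUE`) reaches the threshold. Isolated ASVs are excluded
#' from the node count; connectance is `C = E / N^2`.
#'
#' @param block a [spearman_block()] result.
#' @param threshold correlation cutoff in `[0, 1]` (e.g. the RMT-chosen St).
#' @param positive_only admit only positive correlations as edges.
#' @return a `bipartite_network`: `adjacency` (0/1, predators x prey),
#'   `threshold`, `E`, `N`, `C`, plus the id vectors.
#' @export
build_meta_network <- function(block, threshold, positive_only = FALSE) {
  stopifnot(threshold >= 0, threshold <= 1)
  adj <- if (positive_only) (block$rho >= threshold) else
    (abs(block$rho) >= threshold)
  adj <- adj * 1L
  E <- sum(adj)
  N <- sum(rowSums(adj) > 0) + sum(colSums(adj) > 0)
  structure(list(predator_ids = block$predator_ids,
                 prey_ids = block$prey_ids, adjacency = adj,
                 rho = block$rho, threshold = threshold,
                 E = E, N = N, C = if (N > 0) E / N^2 else 0),
            class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("<bipartite_network> threshold %.2f: E = %d, N = %d, C = %.4f\n",
              x$threshold, x$E, x$N, x$C))
  invisible(x)
}

#' Per-site induced subnetwork metrics
#'
#' For each sample, induces the meta-network on the ASVs present (count > 0)
#' at that site and reports edge count E, node count N (degree >= 1 in the
#' induced graph), and connectance `C = E/N^2` (0 when N = 0).
#'
#' @param meta a [build_meta_network()] result.
#' @param prey,predator the (rarefied) `asv_table`s the meta-network was
#'   built from.
#' @return data.frame: site_id, pair ("P-B" or "V-B"), E, N, C.
#' @export
site_subnetworks <- function(meta, prey, predator) {
  if (!identical(sample_ids(prey), sample_ids(predator))) {
    stop("sample id mismatch between prey and predator tables")
  }
  pred_m <- predator$counts[, meta$predator_ids, drop = FALSE] > 0L
  prey_m <- prey$counts[, meta$prey_ids, drop = FALSE] > 0L
  pair <- if (predator$kingdom == "virus") "V-B" else "P-B"
  out <- lapply(seq_len(nrow(pred_m)), function(i) {
    sub <- meta$adjacency[pred_m[i, ], prey_m[i, ], drop = FALSE]
    E <- sum(sub)
    N <- sum(rowSums(sub) > 0) + sum(colSums(sub) > 0)
    data.frame(site_id = sample_ids(prey)[i], pair = pair, E = E, N = N,
               C = if (N > 0) E / N^2 else 0, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Sensitivity of per-site network metrics to the prevalence threshold
#'
#' Rebuilds the predator-prey network at each prevalence-filter level and
#' correlates (Spearman) the per-site metric series between levels.
#'
#' @param prey an `asv_table` (unfiltered).
#' @param predator an `asv_table` (unfiltered).
#' @param prevalence_levels two or more occupancy fractions.
#' @param threshold `"rmt"` to rechoose St per level, or a fixed numeric.
#' @param ... passed to [rmt_threshold()].
#' @return data.frame: pair, metric (E or C), level_a, level_b, rho
#'   (NA when a metric series is constant).
#' @export
threshold_sensitivity <- function(prey, predator,
                                  prevalence_levels = c(0.2, 0.3, 0.4),
                                  threshold = "rmt", ...) {
  if (length(prevalence_levels) < 2L) stop("need at least 2 prevalence levels")
  per_level <- lapply(prevalence_levels, function(lv) {
    pf <- prevalence_filter(prey, lv)
    df <- prevalence_filter(predator, lv)
    blk <- spearman_block(pf, df)
    thr <- if (identical(threshold, "rmt")) {
      rmt_threshold(blk, ...)$chosen_threshold
    } else threshold
    site_subnetworks(build_meta_network(blk, thr), pf, df)
  })
  pair <- per_level[[1L]]$pair[1L]
  combos <- utils::combn(seq_along(prevalence_levels), 2L)
  out <- list()
  for (metric in c("E", "C")) {
    for (k in seq_len(ncol(combos))) {
      a <- combos[1L, k]; b <- combos[2L, k]
      va <- per_level[[a]][[metric]]; vb <- per_level[[b]][[metric]]
      rho <- if (stats::sd(va) == 0 || stats::sd(vb) == 0) NA_real_ else
        stats::cor(va, vb, method = "spearman")
      out[[length(out) + 1L]] <- data.frame(
        pair = pair, metric = metric,
        level_a = prevalence_levels[a], level_b = prevalence_levels[b],
        rho = rho, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Export a bipartite network as an edge list and GraphML
#'
#' Writes `<prefix>_edges.tsv` (predator_id, prey_id, rho, sign) and
#' `<prefix>.graphml` for external viewers.
#'
#' @param net a [build_meta_network()] result.
#' @param prefix output path prefix.
#' @return the edge-list path, invisibly.
#' @export
write_network <- function(net, prefix) {
  idx <- which(net$adjacency == 1L, arr.ind = TRUE)
  edges <- data.frame(
    predator_id = net$predator_ids[idx[, 1L]],
    prey_id = net$prey_ids[idx[, 2L]],
    rho = net$rho[idx],
    sign = ifelse(net$rho[idx] >= 0, "positive", "negative"),
    stringsAsFactors = FALSE)
  write_tsv(edges, paste0(prefix, "_edges.tsv"))
  nodes <- unique(c(edges$predator_id, edges$prey_id))
  xml <- c('<?xml version="1.0" encoding="UTF-8"?>',
           '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
           '<graph id="bipartite" edgedefault="undirected">',
           sprintf('<node id="%s"/>', nodes),
           sprintf('<edge source="%s" target="%s"/>',
                   edges$predator_id, edges$prey_id),
           '</graph>', '</graphml>')
  writeLines(xml, paste0(prefix, ".graphml"))
  invisible(paste0(prefix, "_edges.tsv"))
}
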