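#' Null-model configuration for stochasticity estimation
#'
#' @param algorithm null algorithm; `"proportional_fixed"` keeps each
#'   sample's richness fixed and draws taxa with probability proportional to
#'   their observed occupancy frequency.
#' @param n_null number of null matrices (default 1000).
#' @param seed integer seed.
#' @return a `null_config` list.
#' @export
null_config <- function(algorithm = "proportional_fixed", n_null = 1000L,
                        seed = 1L) {
  algorithm <- match.arg(algorithm, "proportional_fixed")
  stopifnot(n_null >= 2L)
  structure(list(algorithm = algorithm, n_null = as.integer(n_null),
                 seed = as.integer(seed)), class = "null_config")
}

#' Occupancy-proportional fixed-richness null matrices
#'
#' Each null matrix preserves every sample's richness exactly; the taxa
#' filling a sample are drawn without replacement with probability
#' proportional to their occupancy frequency across the observed matrix
#' (taxa never observed can never appear).
#'
#' @param presence binary samples x taxa matrix with no empty rows.
#' @param config a [null_config()].
#' @return list of `n_null` binary matrices.
#' @export
null_randomize <- function(presence, config = null_config()) {
  presence <- (presence > 0) * 1L
  if (any(rowSums(presence) == 0)) stop("empty sample row")
  occ <- colSums(presence)
  pool <- which(occ > 0)
  rich <- rowSums(presence)
  if (any(rich > length(pool))) {
    stop("sample richness exceeds the occupied taxon pool")
  }
  n <- nrow(presence); S <- ncol(presence)
  with_seed(config$seed, {
    lapply(seq_len(config$n_null), function(b) {
      m <- matrix(0L, n, S, dimnames = dimnames(presence))
      for (i in seq_len(n)) {
        m[i, sample(pool, rich[i], prob = occ[pool])] <- 1L
      }
      m
    })
  })
}

jaccard_dist <- function(presence) {
  z <- (presence > 0) * 1
  inter <- tcrossprod(z)
  tot <- rowSums(z)
  uni <- outer(tot, tot, "+") - inter
  d <- 1 - inter / uni
  d[uni == 0] <- 0
  diag(d) <- 0
  d
}

#' Normalized stochasticity ratio (NST)
#'
#' Compares observed pairwise Jaccard dissimilarity `D_ij` with its null
#' expectation `E_ij` (mean over null matrices). Per pair,
#' `ST_ij = E/D` if `D >= E` else `D/E` (1 when both are 0), and, using the
#' maximum dissimilarity `D_max = 1` as normalizer,
#' `NST_ij = (1 - D)/(1 - E)` when `D >= E` (capped at 1) else `D/E`.
#' `ST` and `NST` are pairwise means; the deterministic fraction is
#' `1 - NST`, with 0.5 the stochastic/deterministic boundary.
#'
#' @param presence binary samples x taxa matrix (>= 3 samples).
#' @param config a [null_config()].
#' @return an `assembly_result`: `ST`, `NST`, `determinism` (= 1 - NST),
#'   `pairwise` (data.frame i, j, D, E), `n_null`, `seed`.
#' @export
nst <- function(presence, config = null_config()) {
  presence <- (presence > 0) * 1L
  if (nrow(presence) < 3L) stop("need at least 3 samples")
  D <- jaccard_dist(presence)
  nulls <- null_randomize(presence, config)
  Em <- Reduce(`+`, lapply(nulls, jaccard_dist)) / length(nulls)
  lt <- lower.tri(D)
  Dv <- D[lt]; Ev <- Em[lt]
  st_ij <- ifelse(Dv >= Ev,
                  ifelse(Dv > 0, Ev / Dv, 1),
                  Dv / Ev)
  nst_ij <- ifelse(Dv >= Ev,
                   ifelse(Ev < 1, pmin(1, (1 - Dv) / (1 - Ev)), 1),
                   Dv / Ev)
  if (all(Dv == 0) && all(Ev == 0)) {
    warning("all samples identical and nulls degenerate; ST = 0")
    st_ij <- nst_ij <- rep(0, length(Dv))
  }
  idx <- which(lt, arr.ind = TRUE)
  structure(list(ST = mean(st_ij), NST = mean(nst_ij),
                 determinism = 1 - mean(nst_ij),
                 pairwise = data.frame(i = idx[, 2L], j = idx[, 1L],
                                       D = Dv, E = Ev),
                 n_null = config$n_null, seed = config$seed),
            class = "assembly_result")
}

#' @export
print.assembly_result <- function(x, ...) {
  cat(sprintf("<assembly> ST = %.3f, NST = %.3f, determinism = %.3f (%d nulls)\n",
              x$ST, x$NST, x$determinism, x$n_null))
  invisible(x)
}
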