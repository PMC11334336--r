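#' Derive a reproducible child seed from a master seed and a stage name
#'
#' Every stochastic stage of the pipeline draws from its own seed computed
#' deterministically from the master seed and the stage label, so that a stage
#' can be re-run in isolation and reproduce the pipeline's result.
#'
#' @param master integer master seed.
#' @param stage character stage label.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(master) * 7919 + h * 104729) %% (2^31 - 1))
}

# Run expr with a local RNG state seeded by `seed`; caller's RNG untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Construct a validated distance matrix
#'
#' A thin container for a symmetric, zero-diagonal, non-negative dissimilarity
#' matrix with sample identifiers, used by all distance-based analyses.
#'
#' @param values square numeric matrix.
#' @param ids character identifiers (defaults to rownames of `values`).
#' @param metric label describing the metric.
#' @return a `dist_matrix`: the matrix with `metric` attribute and class set.
#' @export
dist_matrix <- function(values, ids = rownames(values), metric = "unknown") {
  values <- as.matrix(values)
  if (is.null(ids)) stop("distance matrix requires ids")
  if (nrow(values) != ncol(values)) stop("distance matrix must be square")
  if (anyNA(values)) stop("distance matrix contains NA")
  if (max(abs(values - t(values))) > 1e-8) stop("distance matrix not symmetric")
  if (any(diag(values) != 0)) stop("distance matrix diagonal must be zero")
  if (any(values < 0)) stop("distances must be non-negative")
  values <- (values + t(values)) / 2
  dimnames(values) <- list(ids, ids)
  structure(values, metric = metric, class = c("dist_matrix", "matrix", "array"))
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("<dist_matrix> %d ids, metric = %s\n", nrow(x),
              attr(x, "metric")))
  invisible(x)
}

# Lower-triangle vector of a square matrix.
lower_tri <- function(m) m[lower.tri(m)]

# Write a data.frame as the package's TSV dialect.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Multiset permutations of a label vector (used by exhaustive ANOSIM).
# Returns a list of label vectors; feasible only for small n.
label_arrangements <- function(labels) {
  labels <- as.character(labels)
  rec <- function(remaining) {
    if (length(remaining) == 1L) return(list(remaining))
    out <- list()
    for (u in unique(remaining)) {
      i <- match(u, remaining)
      for (tail in rec(remaining[-i])) {
        out[[length(out) + 1L]] <- c(u, tail)
      }
    }
    out
  }
  rec(labels)
}

# All permutations of 1..n (n <= 8), as a matrix with one permutation per row.
all_permutations <- function(n) {
  if (n > 8L) stop("exhaustive enumeration limited to n <= 8")
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(sub, n)
    if (pos < n) {
      block <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], n,
                     sub[, pos:(n - 1L), drop = FALSE])
    }
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}
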