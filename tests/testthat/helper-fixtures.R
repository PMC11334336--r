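# Small in-code fixtures shared across test files.

make_counts <- function(n, m, seed = 1L, lambda = 20) {
  set.seed(seed)
  x <- matrix(rpois(n * m, lambda), n, m,
              dimnames = list(sprintf("s%02d", seq_len(n)),
                              sprintf("a%02d", seq_len(m))))
  storage.mode(x) <- "integer"
  x
}

make_table <- function(n = 6, m = 8, seed = 1L, kingdom = "bacteria",
                       lambda = 20) {
  asv_table(make_counts(n, m, seed, lambda), kingdom)
}

# Random embeddable 2-D point configuration and its Euclidean distances.
make_euclidean <- function(n, seed = 1L, k = 2L) {
  set.seed(seed)
  pts <- matrix(rnorm(n * k), n, k)
  rownames(pts) <- sprintf("s%02d", seq_len(n))
  list(points = pts,
       d = dist_matrix(as.matrix(dist(pts)), rownames(pts), "euclidean"))
}

# Independent recursive permutation enumerator (oracle-side, not the
# package's all_permutations).
oracle_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in oracle_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# A small simulated survey at reduced scale for pipeline-level tests.
small_config <- function(seed = 1L, ...) {
  sim_config(n_sites = 24L,
             n_asv_pool = c(bacteria = 60L, protist = 30L, virus = 20L),
             depth = 2000L, n_true_links = c(PB = 5L, VB = 5L),
             seed = seed, ...)
}

rand_presence <- function(n, S, p = 0.5, seed = 1L) {
  set.seed(seed)
  m <- matrix(rbinom(n * S, 1L, p), n, S,
              dimnames = list(sprintf("s%02d", seq_len(n)),
                              sprintf("t%03d", seq_len(S))))
  m[rowSums(m) == 0, 1L] <- 1L
  m
}
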