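# Center a configuration and scale it to unit sum of squares.
unit_configuration <- function(A) {
  A <- as.matrix(A)
  A <- scale(A, scale = FALSE)
  ss <- sum(A^2)
  if (ss <= 0) stop("zero-variance configuration")
  A / sqrt(ss)
}

#' Symmetric Procrustes superimposition
#'
#' Centers and unit-scales both configurations, finds the optimal orthogonal
#' rotation (reflections allowed) from the singular decomposition of the
#' cross-product, and reports the badness of fit `m2 = 1 - (sum of singular
#' values)^2`, the Procrustes correlation `R2 = 1 - m2`, and pointwise
#' residuals (Euclidean distance between matched rows after transformation).
#'
#' @param A,B site x k coordinate matrices over the same sites, same row
#'   order (k = 2 for the first two NMDS axes in the pipeline).
#' @return a `procrustes_result`: `m2`, `R2`, `residuals`, `rotation`,
#'   `scale`.
#' @export
procrustes_fit <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) != nrow(B) || ncol(A) != ncol(B)) stop("dimension mismatch")
  if (nrow(A) < 3L) stop("need at least 3 sites")
  X <- unit_configuration(A)
  Y <- unit_configuration(B)
  sv <- svd(crossprod(X, Y))
  rot <- sv$v %*% t(sv$u)
  c_scale <- sum(sv$d)
  Yrot <- c_scale * Y %*% rot
  resid <- sqrt(rowSums((X - Yrot)^2))
  names(resid) <- rownames(A)
  m2 <- 1 - c_scale^2
  structure(list(m2 = m2, R2 = 1 - m2, residuals = resid,
                 rotation = rot, scale = c_scale),
            class = "procrustes_result")
}

#' @export
print.procrustes_result <- function(x, ...) {
  cat(sprintf("<procrustes> m2 = %.4f, R2 = %.4f", x$m2, x$R2))
  if (!is.null(x$p)) cat(sprintf(", p = %.4g (%d perms)", x$p, x$n_perm))
  cat("\n")
  invisible(x)
}

#' PROTEST permutation test of Procrustes concordance
#'
#' Permutes the row order of the second configuration and compares permuted
#' `m2` values with the observed one (one-sided, add-one corrected), or
#' enumerates all `n!` row orders when `exhaustive = TRUE`.
#'
#' @param A,B coordinate matrices as in [procrustes_fit()].
#' @param n_perm number of permutations (default 999; the survey pipeline
#'   uses 1000).
#' @param seed integer seed.
#' @param exhaustive enumerate all row permutations (n <= 8).
#' @return a `procrustes_result` with `p` and `n_perm` added.
#' @export
protest <- function(A, B, n_perm = 999L, seed = 1L, exhaustive = FALSE) {
  if (nrow(as.matrix(A)) < 5L) {
    warning("fewer than 5 sites: permutation p has little resolution")
  }
  fit <- procrustes_fit(A, B)
  B <- as.matrix(B)
  m2_for <- function(perm) procrustes_fit(A, B[perm, , drop = FALSE])$m2
  if (exhaustive) {
    perms <- all_permutations(nrow(B))
    m2s <- apply(perms, 1L, m2_for)
    fit$p <- mean(m2s <= fit$m2 + 1e-12)
    fit$n_perm <- nrow(perms)
  } else {
    hits <- with_seed(seed, {
      sum(vapply(seq_len(n_perm), function(i) {
        m2_for(sample.int(nrow(B))) <= fit$m2 + 1e-12
      }, NA))
    })
    fit$p <- (hits + 1) / (n_perm + 1)
    fit$n_perm <- n_perm
  }
  fit
}

#' Trend of Procrustes residuals along a gradient
#'
#' Fits linear and quadratic OLS of the pointwise residuals on the gradient
#' and keeps the lower-AIC model; low residuals mean congruent predator and
#' prey community structure at that site.
#'
#' @param result a [procrustes_fit()]/[protest()] result.
#' @param gradient per-site gradient values aligned with the residuals.
#' @return a `trend_fit` (see [fit_gradient_trend()]).
#' @export
residual_gradient <- function(result, gradient) {
  r <- result$residuals
  if (length(r) != length(gradient)) stop("residuals and gradient misaligned")
  if (stats::sd(r) == 0) {
    warning("constant residuals: returning flat fit")
    return(structure(list(model = "linear",
                          coefficients = c(`(Intercept)` = unname(r[1L]),
                                           g = 0),
                          R2 = 0, AIC = NA_real_, p_overall = NA_real_,
                          fitted = rep(unname(r[1L]), length(r))),
                     class = "trend_fit"))
  }
  fit_gradient_trend(r, gradient)
}
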