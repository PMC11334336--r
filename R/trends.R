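#' Linear-versus-quadratic gradient trend, AIC selected
#'
#' Fits `y ~ g` and `y ~ g + g^2` by OLS and keeps the model with the lower
#' AIC (full Gaussian convention, `n log(2 pi) + n log(RSS/n) + n + 2k` with
#' k counting the coefficients plus the error variance — the same constant
#' throughout the package, so only differences matter). Nonsignificant
#' trends (overall F-test p > .05) are flagged, mirroring dotted-line
#' plotting conventions.
#'
#' @param y per-site response values (n >= 5).
#' @param g gradient values (latitude, temperature, ...).
#' @return a `trend_fit`: `model` ("linear"/"quadratic"), `coefficients`,
#'   `R2`, `AIC` (both candidates in `aic_candidates`), `p_overall`,
#'   `significant`, `fitted`, and `predict(newg)` giving fit and 95%
#'   prediction interval.
#' @export
fit_gradient_trend <- function(y, g) {
  if (length(y) < 5L) stop("need at least 5 observations")
  if (stats::sd(g) == 0) stop("constant gradient")
  df <- data.frame(y = y, g = g)
  lin <- stats::lm(y ~ g, data = df)
  quad <- stats::lm(y ~ g + I(g^2), data = df)
  aics <- c(linear = stats::AIC(lin), quadratic = stats::AIC(quad))
  model <- if (aics[["quadratic"]] < aics[["linear"]]) "quadratic" else "linear"
  best <- if (model == "quadratic") quad else lin
  sm <- summary(best)
  p_overall <- if (is.null(sm$fstatistic)) NA_real_ else
    stats::pf(sm$fstatistic[1L], sm$fstatistic[2L], sm$fstatistic[3L],
              lower.tail = FALSE)
  structure(list(model = model, coefficients = stats::coef(best),
                 R2 = sm$r.squared, AIC = min(aics), aic_candidates = aics,
                 p_overall = unname(p_overall),
                 significant = !is.na(p_overall) && p_overall <= 0.05,
                 fitted = unname(stats::fitted(best)),
                 predict = function(newg) {
                   as.data.frame(stats::predict(
                     best, newdata = data.frame(g = newg),
                     interval = "prediction", level = 0.95))
                 }),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> %s model, R2 = %.3f, AIC = %.2f, p = %.3g%s\n",
              x$model, x$R2, x$AIC, x$p_overall,
              if (isTRUE(x$significant)) "" else " (nonsignificant)"))
  invisible(x)
}

#' Standardized multiple OLS with AIC-based subset selection
#'
#' Standardizes the response and all candidate predictors to mean 0, SD 1,
#' then searches for the lowest-AIC model: exhaustively over all subsets
#' (including the intercept-only model) when the number of candidates is at
#' most `max_exhaustive`, otherwise by backward elimination. Coefficients of
#' the selected model are standardized beta weights.
#'
#' @param y response vector.
#' @param X site x candidate-predictor matrix with column names.
#' @param max_exhaustive largest p for exhaustive search (default 10).
#' @return a `regression_fit`: `terms`, `beta` (standardized), `R2`, `AIC`,
#'   `p_terms`, `method`.
#' @export
ols_best_subset <- function(y, X, max_exhaustive = 10L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  X <- X[, apply(X, 2L, stats::sd) > 0, drop = FALSE]
  n <- length(y); p <- ncol(X)
  if (n <= p + 2L) stop("too few observations for the candidate set")
  if (kappa(cbind(1, scale(X)), exact = TRUE) > 1e10) {
    stop("collinear candidates: apply vif_prune first")
  }
  ys <- as.numeric(scale(y))
  Xs <- scale(X)
  fit_subset <- function(idx) {
    dat <- data.frame(y = ys, Xs[, idx, drop = FALSE])
    stats::lm(y ~ ., data = dat)
  }
  if (p <= max_exhaustive) {
    method <- "exhaustive"
    best <- NULL; best_idx <- integer(0)
    best_aic <- stats::AIC(stats::lm(ys ~ 1))
    for (code in seq_len(2^p - 1L)) {
      idx <- which(bitwAnd(code, 2^(seq_len(p) - 1L)) > 0L)
      fit <- fit_subset(idx)
      a <- stats::AIC(fit)
      if (a < best_aic) { best_aic <- a; best <- fit; best_idx <- idx }
    }
  } else {
    method <- "backward"
    idx <- seq_len(p)
    best <- fit_subset(idx)
    best_aic <- stats::AIC(best)
    repeat {
      improved <- FALSE
      for (drop in idx) {
        cand <- setdiff(idx, drop)
        fit <- if (length(cand)) fit_subset(cand) else stats::lm(ys ~ 1)
        if (stats::AIC(fit) < best_aic) {
          best_aic <- stats::AIC(fit); best <- fit; idx <- cand
          improved <- TRUE
          break
        }
      }
      if (!improved || length(idx) == 0L) break
    }
    best_idx <- idx
  }
  if (length(best_idx) == 0L) {
    return(structure(list(terms = character(0), beta = numeric(0),
                          R2 = 0, AIC = best_aic, p_terms = numeric(0),
                          method = method), class = "regression_fit"))
  }
  sm <- summary(best)
  co <- sm$coefficients[-1L, , drop = FALSE]
  structure(list(terms = colnames(X)[best_idx],
                 beta = stats::setNames(co[, 1L], colnames(X)[best_idx]),
                 R2 = sm$r.squared, AIC = best_aic,
                 p_terms = stats::setNames(co[, 4L], colnames(X)[best_idx]),
                 method = method),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit> %s: {%s}, R2 = %.3f, AIC = %.2f\n",
              x$method, paste(x$terms, collapse = ", "), x$R2, x$AIC))
  invisible(x)
}
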