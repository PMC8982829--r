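#' Residualize a variable on nuisance covariates
#'
#' Least-squares residuals of `y` on an intercept plus the given covariates
#' (numeric columns as-is, character/factor columns expanded to indicators).
#' Constant columns are dropped; genuine rank deficiency is an error naming
#' the collinear column. Residuals are exactly orthogonal to every retained
#' design column.
#'
#' @param y numeric vector with no missing values (impute upstream).
#' @param covariates data.frame of covariate columns aligned with `y`.
#' @return numeric residual vector.
#' @export
residualize <- function(y, covariates) {
  stopifnot(is.numeric(y), nrow(covariates) == length(y))
  if (anyNA(y) || anyNA(covariates)) {
    stop_validation("residualize requires complete data; impute first")
  }
  X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (is.numeric(v)) {
      if (sd(v) > 0) {
        X <- cbind(X, matrix(v, dimnames = list(NULL, nm)))
      }
    } else {
      f <- factor(v)
      if (nlevels(f) > 1L) {
        d <- stats::model.matrix(~f)[, -1, drop = FALSE]
        colnames(d) <- paste0(nm, levels(f)[-1])
        X <- cbind(X, d)
      }
    }
  }
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1L):ncol(X)]]
    stop_validation(sprintf("collinear covariate column(s): %s",
                            paste(bad, collapse = ", ")))
  }
  as.numeric(qr.resid(q, y))
}

#' Drop rows with listed outlier decoding scores
#'
#' Removes participants whose decoding score equals any value in
#' `scores_to_drop` exactly; the removed ids are attached as an attribute.
#'
#' @param table cohort table with a `decoding` column.
#' @param scores_to_drop numeric scores to exclude (may be empty).
#' @return the filtered table with attribute `excluded_ids`.
#' @export
exclude_outliers <- function(table, scores_to_drop = numeric(0)) {
  stopifnot(all(is.finite(scores_to_drop)))
  drop <- !is.na(table$decoding) & table$decoding %in% scores_to_drop
  out <- table[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded_ids") <- table$id[drop]
  out
}

#' Add bounded uniform jitter to a vector
#'
#' Adds an independent draw from Uniform(-bound, bound) to each entry; used
#' on landscape values to avoid degenerate quantile-regression fits when many
#' values are exactly zero. Drawn once per analysis, not per bootstrap draw.
#'
#' @param x finite numeric vector (or matrix).
#' @param seed integer seed.
#' @param bound jitter half-width (default 1e-5).
#' @return `x` plus jitter, same shape.
#' @export
jitter_values <- function(x, seed, bound = 1e-5) {
  stopifnot(all(is.finite(x)))
  with_seed(seed, x + runif(length(x), -bound, bound))
}

#' Convert a t statistic to Cohen's d
#'
#' The conversion `d = 2 t / sqrt(df)` used for reporting regression effect
#' sizes.
#'
#' @param t t statistic.
#' @param df degrees of freedom, > 0.
#' @return Cohen's d.
#' @examples
#' cohen_d_from_t(3.40, 420)  # 0.332 to three decimals
#' @export
cohen_d_from_t <- function(t, df) {
  if (any(df <= 0)) stop_validation("df must be positive")
  2 * t / sqrt(df)
}

#' Simple linear regression of residualized behavior on landscape values
#'
#' Ordinary least squares of `y_resid` on `x` with intercept. The slope's t
#' statistic has `df = n - 2`; Cohen's d is `2 t / sqrt(df)`.
#'
#' @param y_resid residualized behavioral score.
#' @param x landscape values at one position.
#' @return list: `estimate`, `se`, `t`, `df`, `p`, `ci` (95%), `d`, `n`.
#' @export
fit_linear <- function(y_resid, x) {
  n <- length(x)
  stopifnot(length(y_resid) == n)
  if (n < 10L) stop_validation("fit_linear requires n >= 10")
  if (sd(x) == 0) {
    stop(structure(class = c("asymtopo_degenerate_predictor", "error", "condition"),
                   list(message = "degenerate predictor: x is constant",
                        call = sys.call(-1))))
  }
  xc <- x - mean(x)
  yc <- y_resid - mean(y_resid)
  sxx <- sum(xc^2)
  slope <- sum(xc * yc) / sxx
  res <- yc - slope * xc
  df <- n - 2L
  se <- sqrt(sum(res^2) / df / sxx)
  tval <- if (se == 0) 0 else slope / se
  crit <- qt(0.975, df)
  list(estimate = slope, se = se, t = tval, df = df,
       p = 2 * pt(-abs(tval), df),
       ci = c(slope - crit * se, slope + crit * se),
       d = cohen_d_from_t(tval, df), n = n)
}

#' Quadratic quantile regression for the sandpile (canalization) envelope
#'
#' Regresses the (jittered) landscape values on an orthonormal degree-2
#' polynomial basis of the residualized behavioral score, minimizing the
#' tau-check loss `sum rho_tau(a - X beta)` (99th conditional percentile by
#' default). A negative quadratic term is the inverted-U envelope predicted
#' by canalization: large asymmetries co-occur only with average behavior.
#'
#' @param a landscape values (response), jittered upstream.
#' @param y_resid residualized behavioral score (predictor).
#' @param tau quantile level in (0, 1), default 0.99.
#' @return list: `intercept`, `linear`, `quadratic`, `tau`, `n`.
#' @export
fit_quantile_sandpile <- function(a, y_resid, tau = 0.99) {
  n <- length(a)
  stopifnot(length(y_resid) == n, tau > 0, tau < 1)
  if (sd(y_resid) == 0) {
    stop(structure(class = c("asymtopo_degenerate_predictor", "error", "condition"),
                   list(message = "degenerate predictor: y_resid is constant",
                        call = sys.call(-1))))
  }
  P <- poly(y_resid, 2)   # centered, orthonormal (Gram-Schmidt)
  X <- cbind(1, P[, 1], P[, 2])
  fit <- quantreg::rq.fit.br(X, a, tau = tau)
  if (any(!is.finite(fit$coefficients))) {
    stop("quantile solver returned non-finite coefficients")
  }
  list(intercept = unname(fit$coefficients[1]),
       linear = unname(fit$coefficients[2]),
       quadratic = unname(fit$coefficients[3]),
       tau = tau, n = n)
}

#' Bootstrap resampling of a fit over participants
#'
#' Draws `B` resamples of rows with replacement, applies `fit_fn` and
#' collects its named numeric results. Failed draws are excluded with a
#' count. Reproducible from `seed`.
#'
#' @param fit_fn function of `(data, idx)` returning a named numeric vector.
#' @param data data.frame (or list with `$n` rows) passed to `fit_fn`.
#' @param B number of bootstrap draws, >= 1.
#' @param seed integer seed.
#' @param resample if `FALSE`, every "draw" is the identity sample (used to
#'   recover the plain fit).
#' @return list: `draws` (B_ok x k matrix), `pooled` (column means),
#'   `n_failed`, `B`, `seed`.
#' @export
bootstrap_pool <- function(fit_fn, data, B, seed, resample = TRUE) {
  stopifnot(B >= 1L)
  n <- if (is.data.frame(data)) nrow(data) else data$n
  idx_mat <- if (resample) {
    with_seed(seed, matrix(sample.int(n, n * B, replace = TRUE), nrow = n))
  } else {
    matrix(rep(seq_len(n), B), nrow = n)
  }
  rows <- vector("list", B)
  n_failed <- 0L
  for (b in seq_len(B)) {
    rows[[b]] <- tryCatch(fit_fn(data, idx_mat[, b]), error = function(e) NULL)
    if (is.null(rows[[b]])) n_failed <- n_failed + 1L
  }
  draws <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(draws)) stop("every bootstrap draw failed")
  list(draws = draws, pooled = colMeans(draws), n_failed = n_failed,
       B = as.integer(B), seed = seed)
}

#' Pool fits over imputations and bootstrap draws
#'
#' Averages estimates over all `m x B` fits and derives two-sided bootstrap
#' p-values per term as the doubled fraction of draws on the opposite side of
#' zero from the pooled estimate, floored at `1/B`.
#'
#' @param results list (length m) of `draws` matrices (B x k) from
#'   [bootstrap_pool()], sharing column names.
#' @return list: `pooled` (named means), `p_bootstrap` (named), `count`
#'   (total contributing fits), `draws` (stacked matrix).
#' @export
pool_over_imputations <- function(results) {
  if (length(results) == 0L) stop_validation("no results to pool")
  draws <- do.call(rbind, results)
  pooled <- colMeans(draws)
  B <- nrow(results[[1]])
  p <- vapply(seq_along(pooled), function(j) {
    cross <- mean(draws[, j] * sign(pooled[j]) < 0)
    max(1 / B, min(1, 2 * cross))
  }, numeric(1))
  names(p) <- names(pooled)
  list(pooled = pooled, p_bootstrap = p, count = nrow(draws), draws = draws)
}
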