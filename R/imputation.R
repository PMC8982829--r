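#' Multiple imputation by chained equations with predictive-mean matching
#'
#' Iterative conditional modeling: missing entries are initialised by random
#' draws from the observed values of their column, then refined over
#' `cycles` sweeps in which each incomplete column is regressed on all other
#' columns and each missing cell receives the observed value of one of the
#' `donors` nearest neighbours in predicted value (predictive-mean matching,
#' so every imputed value is an observed value of its column). Produces `m`
#' completed tables; ids and observed cells are never changed. Reproducible
#' from `seed`.
#'
#' @param table data.frame; an `id` column is carried through untouched.
#' @param m number of completed tables (default 10).
#' @param seed integer seed.
#' @param cycles sweeps of the chained equations (default 10).
#' @param donors nearest-prediction donors to sample from (default 5).
#' @return list of `m` completed data.frames.
#' @export
chained_imputation <- function(table, m = 10L, seed = 1L, cycles = 10L,
                               donors = 5L) {
  stopifnot(m >= 1L, cycles >= 1L, donors >= 1L)
  vars <- setdiff(names(table), "id")
  miss <- vapply(table[vars], function(v) mean(is.na(v)), numeric(1))
  if (any(miss >= 1)) {
    stop_validation(sprintf("column '%s' is entirely missing",
                            vars[which(miss >= 1)[1]]))
  }
  if (any(miss > 0.5)) {
    stop_validation(sprintf("column '%s' has fewer than 50%% observed values",
                            vars[which(miss > 0.5)[1]]))
  }
  if (!any(miss == 0)) {
    stop_validation("at least one fully observed column is required")
  }
  impute_cols <- vars[miss > 0]
  if (length(impute_cols) == 0L) {
    return(replicate(m, table, simplify = FALSE))
  }
  for (cl in impute_cols) {
    if (!is.numeric(table[[cl]])) {
      stop_validation(sprintf("can only impute numeric columns ('%s')", cl))
    }
  }

  design <- function(dat, target) {
    X <- matrix(1, nrow(dat), 1)
    for (nm in setdiff(vars, target)) {
      v <- dat[[nm]]
      if (is.numeric(v)) {
        if (sd(v) > 0) X <- cbind(X, v)
      } else {
        f <- factor(v)
        if (nlevels(f) > 1L) X <- cbind(X, stats::model.matrix(~f)[, -1])
      }
    }
    X
  }

  lapply(seq_len(m), function(k) {
    with_seed(seed + k, {
      dat <- table
      na_idx <- lapply(impute_cols, function(cl) which(is.na(table[[cl]])))
      names(na_idx) <- impute_cols
      for (cl in impute_cols) {
        obs <- table[[cl]][!is.na(table[[cl]])]
        dat[[cl]][na_idx[[cl]]] <- sample(obs, length(na_idx[[cl]]),
                                          replace = TRUE)
      }
      for (cyc in seq_len(cycles)) {
        for (cl in impute_cols) {
          mis <- na_idx[[cl]]
          obs <- setdiff(seq_len(nrow(dat)), mis)
          X <- design(dat, cl)
          fit <- lm.fit(X[obs, , drop = FALSE], table[[cl]][obs])
          beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
          pred <- as.numeric(X %*% beta)
          for (i in mis) {
            d <- abs(pred[obs] - pred[i])
            don <- obs[order(d, obs)[seq_len(min(donors, length(obs)))]]
            dat[[cl]][i] <- table[[cl]][don[sample.int(length(don), 1L)]]
          }
        }
      }
      dat
    })
  })
}
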