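#' Analysis configuration
#'
#' Bundles the tunable statistical parameters of the position-wise analyses.
#' Defaults are desk-scale: `B = 1000` bootstrap draws and `m = 10`
#' imputations (the full-scale analysis uses `B = 10000`).
#'
#' @param alpha two-tailed uncorrected significance level.
#' @param B bootstrap draws per imputation (>= 1).
#' @param m number of imputations (>= 1).
#' @param tau quantile level for the canalization model.
#' @param jitter_bound half-width of the uniform jitter added once per
#'   analysis to the landscape values.
#' @param outlier_scores decoding scores excluded exactly (e.g. `c(47, 55)`).
#' @param covariates nuisance covariates regressed out of decoding; `site`
#'   is treated as categorical.
#' @param scopes which analysis scopes to run: `"hemisphere"`, `"roi"` or
#'   both.
#' @param hemisphere_model,roi_model `"linear"` or `"quantile"`; hemisphere
#'   aggregates are approximately normal and use the linear model by
#'   default, while skewed ROI landscape data use the quantile model.
#' @param G landscape grid size (analyses use positions `2..G-1`).
#' @param n_perm permutations for the extent-based correction.
#' @param extent_pool `"family"` (default) estimates each direction's
#'   run-length null from the significance indicators counted across all
#'   analyzed landscapes, so mostly-null landscapes set the chance level;
#'   `"scope"` resamples each landscape's own indicators instead, which is
#'   conservative to the point of self-defeat when one landscape carries a
#'   dense run of true effects.
#' @param birth_lo,birth_hi,death_min optional persistence-pair filters
#'   (strict bounds; infinite bounds disable).
#' @param seed master seed; all sub-seeds are small deterministic offsets.
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(alpha = 0.05, B = 1000L, m = 10L, tau = 0.99,
                            jitter_bound = 1e-5, outlier_scores = numeric(0),
                            covariates = c("age", "sex", "site"),
                            scopes = "hemisphere",
                            hemisphere_model = "linear",
                            roi_model = "quantile",
                            G = 15L, n_perm = 10000L,
                            extent_pool = c("family", "scope"),
                            birth_lo = -Inf, birth_hi = Inf, death_min = -Inf,
                            seed = 1L) {
  extent_pool <- match.arg(extent_pool)
  stopifnot(alpha > 0, alpha < 1, B >= 1L, m >= 1L, tau > 0, tau < 1,
            all(scopes %in% c("hemisphere", "roi")),
            hemisphere_model %in% c("linear", "quantile"),
            roi_model %in% c("linear", "quantile"))
  structure(list(alpha = alpha, B = as.integer(B), m = as.integer(m),
                 tau = tau, jitter_bound = jitter_bound,
                 outlier_scores = outlier_scores, covariates = covariates,
                 scopes = scopes, hemisphere_model = hemisphere_model,
                 roi_model = roi_model, G = as.integer(G),
                 n_perm = as.integer(n_perm), extent_pool = extent_pool,
                 birth_lo = birth_lo,
                 birth_hi = birth_hi, death_min = death_min,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

# covariate design for residualization; site is categorical
covariate_frame <- function(table, covariates) {
  cov <- table[, covariates, drop = FALSE]
  if ("site" %in% names(cov)) cov$site <- factor(cov$site)
  cov
}

# vectorised per-position OLS over the columns of a landscape matrix
ols_positions <- function(Y, y) {
  n <- length(y)
  Sx <- colSums(Y)
  sxx <- colSums(Y^2) - Sx^2 / n
  sxy <- colSums(Y * y) - Sx * sum(y) / n
  syy <- sum(y^2) - sum(y)^2 / n
  slope <- sxy / sxx
  sse <- pmax(syy - slope * sxy, 0)
  df <- n - 2L
  se <- sqrt(sse / df / sxx)
  t <- ifelse(se > 0, slope / se, 0)
  list(slope = slope, t = t, df = df)
}

#' Position-wise association analysis of one scope
#'
#' Runs the full bootstrap-within-imputation analysis of one landscape
#' matrix: jitter the landscape values once, impute the behavioral table `m`
#' times, residualize decoding on the nuisance covariates, fit the linear
#' (lateralization) or tau-quantile sandpile (canalization) model at every
#' analyzed position in each of `B` bootstrap resamples per imputation, and
#' pool the `m x B` fits.
#'
#' @param Y landscape matrix from [build_matrix()] (participants x
#'   positions), rows aligned with `table`.
#' @param table cohort table (outliers already excluded), rows aligned
#'   with `Y`.
#' @param config an [analysis_config()].
#' @param scope scope label for the output.
#' @param model `"linear"` or `"quantile"`.
#' @param seed_base seed offset for this scope's jitter/imputation/bootstrap
#'   streams.
#' @return data.frame, one row per analyzed position: estimates, pooled t,
#'   df, `p_pooled_t`, `p_bootstrap`, `p_primary`, `estimate_primary`,
#'   Cohen's d, counts.
#' @export
analyze_scope <- function(Y, table, config, scope, model = "linear",
                          seed_base = 0L) {
  stopifnot(nrow(Y) == nrow(table), model %in% c("linear", "quantile"))
  n <- nrow(Y)
  P <- ncol(Y)
  positions <- 2:(P + 1L)
  Yj <- jitter_values(Y, seed = config$seed + seed_base + 11L,
                      bound = config$jitter_bound)
  imps <- chained_imputation(table, m = config$m,
                             seed = config$seed + seed_base + 23L)
  df <- n - 2L

  draws_by_imp <- lapply(seq_along(imps), function(k) {
    imp <- imps[[k]]
    y_resid <- residualize(imp$decoding,
                           covariate_frame(imp, config$covariates))
    dat <- list(n = n, Y = Yj, y = y_resid)
    fit_fn <- if (model == "linear") {
      function(d, idx) {
        f <- ols_positions(d$Y[idx, , drop = FALSE], d$y[idx])
        stats::setNames(c(f$slope, f$t),
                        c(paste0("est_", positions), paste0("t_", positions)))
      }
    } else {
      function(d, idx) {
        yb <- d$y[idx]
        co <- vapply(seq_len(P), function(j) {
          ft <- fit_quantile_sandpile(d$Y[idx, j], yb, tau = config$tau)
          c(ft$linear, ft$quadratic)
        }, numeric(2))
        stats::setNames(c(co[1, ], co[2, ]),
                        c(paste0("lin_", positions), paste0("quad_", positions)))
      }
    }
    bootstrap_pool(fit_fn, dat, B = config$B,
                   seed = config$seed + seed_base + 100L + k)$draws
  })

  pooled <- pool_over_imputations(draws_by_imp)
  if (model == "linear") {
    est <- pooled$pooled[paste0("est_", positions)]
    tbar <- pooled$pooled[paste0("t_", positions)]
    out <- data.frame(
      scope = scope, position = positions, model = model, tau = NA_real_,
      estimate_linear = unname(est), estimate_quadratic = NA_real_,
      t = unname(tbar), df = df,
      p_pooled_t = 2 * pt(-abs(unname(tbar)), df),
      p_bootstrap = unname(pooled$p_bootstrap[paste0("est_", positions)]),
      cohen_d = cohen_d_from_t(unname(tbar), df),
      stringsAsFactors = FALSE
    )
    out$estimate_primary <- out$estimate_linear
    out$p_primary <- out$p_pooled_t
  } else {
    lin <- pooled$pooled[paste0("lin_", positions)]
    quad <- pooled$pooled[paste0("quad_", positions)]
    out <- data.frame(
      scope = scope, position = positions, model = model, tau = config$tau,
      estimate_linear = unname(lin), estimate_quadratic = unname(quad),
      t = NA_real_, df = df, p_pooled_t = NA_real_,
      p_bootstrap = unname(pooled$p_bootstrap[paste0("quad_", positions)]),
      cohen_d = NA_real_, stringsAsFactors = FALSE
    )
    out$estimate_primary <- out$estimate_quadratic
    out$p_primary <- out$p_bootstrap
  }
  out$n_used <- n
  out$B <- config$B
  out$m <- config$m
  out$count <- pooled$count
  out$seed <- config$seed
  out
}

# persistence + scoping + landscape matrices for one cohort
cohort_features <- function(cohort, config) {
  tab <- exclude_outliers(cohort$table, config$outlier_scores)
  vols <- cohort$volumes[tab$id]
  lookup <- cohort$atlas$lookup
  pairs_list <- lapply(vols, function(v) {
    p <- assign_pairs(sublevel_2cycles(v), cohort$atlas, dim(v))
    filter_pairs(p, config$birth_lo, config$birth_hi, config$death_min)
  })
  sides <- c(left = "left", right = "right")
  hemi_pairs <- lapply(sides, function(s) {
    lapply(pairs_list, hemisphere_diagram, hemisphere = s, lookup = lookup)
  })
  grids <- lapply(hemi_pairs, make_grid, G = config$G)

  scopes <- list()
  if ("hemisphere" %in% config$scopes) {
    for (s in sides) {
      scopes[[paste0("hemisphere_", s)]] <- list(
        pairs = hemi_pairs[[s]], grid = grids[[s]],
        model = config$hemisphere_model)
    }
  }
  if ("roi" %in% config$scopes) {
    for (r in seq_len(nrow(lookup))) {
      lab <- lookup$label[r]
      side <- lookup$hemisphere[r]
      scopes[[paste0("roi_", lookup$name[r])]] <- list(
        pairs = lapply(pairs_list, function(p) {
          out <- p[!is.na(p$roi) & p$roi == lab, , drop = FALSE]
          rownames(out) <- NULL
          out
        }),
        grid = grids[[side]], model = config$roi_model)
    }
  }
  mats <- lapply(scopes, function(sc) {
    build_matrix(lapply(sc$pairs, landscape_first, grid = sc$grid))
  })
  list(table = tab, scopes = scopes, matrices = mats, grids = grids,
       excluded = attr(tab, "excluded_ids"))
}

# analyze + correct one cohort; seed_base separates the two samples' streams
process_cohort <- function(cohort, config, seed_base) {
  feats <- cohort_features(cohort, config)
  results <- list()
  raws <- list()
  for (i in seq_along(feats$scopes)) {
    nm <- names(feats$scopes)[i]
    res <- analyze_scope(feats$matrices[[nm]], feats$table, config,
                         scope = nm, model = feats$scopes[[nm]]$model,
                         seed_base = seed_base + 1000L * i)
    results[[nm]] <- res
    raws[[nm]] <- threshold_mask(res$estimate_primary, res$p_primary,
                                 config$alpha)
  }
  # run-length null per direction, estimated from the indicators of the
  # whole scope family (counted across landscapes) so one landscape's own
  # significance density does not set its own cutoff
  masks <- list()
  for (i in seq_along(raws)) {
    nm <- names(raws)[i]
    corrected <- list()
    for (dir in c("positive", "negative")) {
      pool <- if (config$extent_pool == "family") {
        unlist(lapply(raws, `[[`, dir), use.names = FALSE)
      } else {
        raws[[nm]][[dir]]
      }
      ex <- extent_null(raws[[nm]][[dir]], n_perm = config$n_perm,
                        seed = config$seed + seed_base + 1000L * i +
                          ifelse(dir == "positive", 7L, 8L),
                        pool = pool)
      corrected[[dir]] <- apply_extent(raws[[nm]][[dir]], ex$k_star)
      corrected[[paste0("k_star_", dir)]] <- ex$k_star
    }
    corrected$uncorrected <- raws[[nm]]
    masks[[nm]] <- corrected
  }
  list(results = do.call(rbind, results), masks = masks,
       grids = feats$grids, excluded = feats$excluded)
}

#' Run the full two-sample analysis pipeline
#'
#' Executes, per cohort: outlier exclusion, persistence, ROI assignment and
#' optional diagram filtering, pooled-grid landscapes, jitter, chained
#' imputation, bootstrap position-wise models, pooling, uncorrected
#' thresholding, permutation extent correction; then gates significance on
#' replication across the two cohorts at the same position and direction.
#' Fully determined by the configuration seed.
#'
#' @param cohort_a,cohort_b lists with `volumes` (named list of 3D arrays),
#'   `table`, and `atlas` (as produced by [simulate_cohort()]).
#' @param config an [analysis_config()].
#' @param out_dir optional directory; when given, per-cohort results TSVs
#'   and the replication report JSON are written there.
#' @return list: `results_a`, `results_b` (position-wise tables), `masks_a`,
#'   `masks_b`, `report` (per scope: surviving positions per sample and
#'   intersection per direction, plus the overall `headline` flag).
#' @export
run_pipeline <- function(cohort_a, cohort_b, config = analysis_config(),
                         out_dir = NULL) {
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", what,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  a <- stage("sample_a", process_cohort(cohort_a, config, seed_base = 0L))
  b <- stage("sample_b", process_cohort(cohort_b, config, seed_base = 500000L))
  report <- list()
  headline <- FALSE
  for (nm in names(a$masks)) {
    if (!nm %in% names(b$masks)) next
    gate <- replication_gate(a$masks[[nm]], b$masks[[nm]])
    # report landscape position numbers (2..G-1), not mask indices
    for (dir in c("positive", "negative")) {
      gate[[dir]] <- lapply(gate[[dir]], function(ix) ix + 1L)
    }
    gate$k_star_a <- list(positive = a$masks[[nm]]$k_star_positive,
                          negative = a$masks[[nm]]$k_star_negative)
    gate$k_star_b <- list(positive = b$masks[[nm]]$k_star_positive,
                          negative = b$masks[[nm]]$k_star_negative)
    report[[nm]] <- gate
    headline <- headline || gate$headline
  }
  out <- list(results_a = a$results, results_b = b$results,
              masks_a = a$masks, masks_b = b$masks,
              report = report, headline = headline,
              config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_results_tsv(a$results, file.path(out_dir, "results_a.tsv"))
    write_results_tsv(b$results, file.path(out_dir, "results_b.tsv"))
    write_report_json(out, file.path(out_dir, "report.json"))
  }
  out
}
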