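test_that("threshold_mask splits by sign with a strict alpha", {
  est <- c(1, -2, 3, 0.5, -1)
  m <- threshold_mask(est, rep(0.5, 5))
  expect_false(any(m$positive) || any(m$negative))

  p <- c(0.5, 0.5, 0.5, 0.01, 0.5)
  m2 <- threshold_mask(est, p)
  expect_equal(which(m2$positive), 4L)
  expect_equal(which(m2$negative), integer(0))

  # boundary: p exactly alpha is not significant
  m3 <- threshold_mask(est, c(0.05, 0.04999, 0.05, 0.05, 0.05))
  expect_equal(which(m3$negative), 2L)
  expect_false(any(m3$positive))
  expect_error(threshold_mask(est, c(0.1, NA, 0.1, 0.1, 0.1)),
               class = "asymtopo_validation_error")
})

test_that("extent_null matches exhaustive enumeration and is monotone", {
  # all-FALSE mask: nothing can ever survive
  ex0 <- extent_null(rep(FALSE, 13), n_perm = 500, seed = 1)
  expect_equal(ex0$k_star, 1L)
  expect_equal(ex0$null_tail[1], 0)

  # length-5 mask with one TRUE: resampling is i.i.d. Bernoulli(0.2)
  mask <- c(TRUE, FALSE, FALSE, FALSE, FALSE)
  ex <- extent_null(mask, n_perm = 10000, seed = 5)
  exact <- oracle_maxrun_tail(5, 2, 0.2)
  mcse <- sqrt(exact * (1 - exact) / 10000)
  expect_lt(abs(ex$null_tail[2] - exact), 3 * mcse)

  expect_identical(extent_null(mask, n_perm = 10000, seed = 5)$k_star,
                   ex$k_star)
  expect_error(extent_null(mask, n_perm = 50, seed = 1),
               class = "asymtopo_validation_error")

  # k* never decreases as the observed mask gains TRUE positions
  ks <- vapply(1:9, function(k) {
    extent_null(c(rep(TRUE, k), rep(FALSE, 13 - k)), n_perm = 2000,
                seed = 9)$k_star
  }, integer(1))
  expect_true(all(diff(ks) >= 0))
})

test_that("apply_extent keeps only runs of at least k_star", {
  mask <- c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE)
  expect_equal(apply_extent(mask, 2), c(FALSE, FALSE, TRUE, TRUE, TRUE,
                                        FALSE, FALSE))
  expect_equal(apply_extent(mask, 1), mask)
  expect_false(any(apply_extent(rep(FALSE, 13), 2)))
  expect_false(any(apply_extent(mask, 4)))
})

test_that("replication_gate intersects surviving positions by direction", {
  mk <- function(pos, neg, L = 13) {
    list(positive = seq_len(L) %in% pos, negative = seq_len(L) %in% neg)
  }
  g <- replication_gate(mk(6:8, integer(0)), mk(7:9, integer(0)))
  expect_equal(g$positive$intersection, 7:8)
  expect_true(g$headline)
  expect_true(all(g$positive$intersection %in% g$positive$a))
  expect_true(all(g$positive$intersection %in% g$positive$b))

  g2 <- replication_gate(mk(6:8, integer(0)), mk(integer(0), integer(0)))
  expect_equal(g2$positive$intersection, integer(0))
  expect_equal(g2$positive$a, 6:8)
  expect_false(g2$headline)

  # opposite directions at the same position never intersect
  g3 <- replication_gate(mk(5, integer(0)), mk(integer(0), 5))
  expect_false(g3$headline)

  expect_error(replication_gate(mk(1, 2, L = 13), mk(1, 2, L = 12)),
               class = "asymtopo_validation_error")
})

test_that("run_pipeline is deterministic end to end", {
  a <- simulate_cohort(cohort_spec(n = 24, coupling = "linear",
                                   target_r = 0.8, seed = 101))
  b <- simulate_cohort(cohort_spec(n = 24, coupling = "linear",
                                   target_r = 0.8, seed = 102))
  cfg <- analysis_config(B = 25, m = 2, n_perm = 300, seed = 5)
  out1 <- run_pipeline(a, b, cfg)
  out2 <- run_pipeline(a, b, cfg)
  expect_identical(out1, out2)
  expect_equal(nrow(out1$results_a), 26L)  # two hemispheres x 13 positions
  expect_true(all(c("hemisphere_left", "hemisphere_right") %in%
                    names(out1$report)))

  # archives written to disk are byte-identical across reruns
  d1 <- tempfile(); d2 <- tempfile()
  run_pipeline(a, b, cfg, out_dir = d1)
  run_pipeline(a, b, cfg, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
})

test_that("pipeline covers ROI scopes with the quantile model", {
  a <- simulate_cohort(cohort_spec(n = 40, rois_per_hemisphere = 2,
                                   coupling = "canalized", seed = 201))
  b <- simulate_cohort(cohort_spec(n = 40, rois_per_hemisphere = 2,
                                   coupling = "canalized", seed = 202))
  cfg <- analysis_config(B = 10, m = 1, n_perm = 200, scopes = "roi",
                         seed = 3)
  out <- run_pipeline(a, b, cfg)
  expect_equal(sort(unique(out$results_a$scope)),
               sort(paste0("roi_", a$atlas$lookup$name)))
  expect_true(all(out$results_a$model == "quantile"))
  expect_true(all(out$results_a$tau == 0.99))
  expect_true(all(out$results_a$count == 10))
})
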