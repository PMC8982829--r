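test_that("analytic cavity cases give the hand-derived pairs", {
  # constant volume: no cavities
  expect_equal(nrow(sublevel_2cycles(array(1, c(5, 5, 5)))), 0L)

  # single interior peak: one cavity born at the zero background
  v <- single_peak_volume()
  p <- sublevel_2cycles(v)
  expect_equal(nrow(p), 1L)
  expect_equal(c(p$birth, p$death), c(0, 5))
  expect_equal(c(p$peak_i, p$peak_j, p$peak_k), c(4, 4, 4))

  # two peaks joined by a ridge: the younger cavity dies at the ridge level
  w <- two_peak_ridge_volume()
  pw <- sublevel_2cycles(w)
  expect_equal(pw[order(pw$birth), c("birth", "death")],
               data.frame(birth = c(0, 2), death = c(5, 3)),
               ignore_attr = TRUE)

  # strictly monotone ramp: bright phase always touches the boundary
  r <- array(rep(seq_len(8), 8 * 8), c(8, 8, 8))
  expect_equal(nrow(sublevel_2cycles(r)), 0L)

  expect_error(sublevel_2cycles(array(1, c(2, 5, 5))),
               class = "asymtopo_validation_error")
})

test_that("merge-tree, direct reduction, and the independent oracle agree", {
  set.seed(7)
  for (i in 1:40) {
    dims <- sample(5:8, 3, replace = TRUE)
    v <- random_int_volume(dims)
    fast <- sublevel_2cycles(v)
    slow <- sublevel_2cycles(v, method = "reduction")
    orc <- oracle_h2_pairs(v)
    expect_equal(fast[, c("birth", "death")], slow[, c("birth", "death")],
                 ignore_attr = TRUE)
    expect_equal(fast[, c("birth", "death")],
                 orc[order(orc$birth, orc$death), ], ignore_attr = TRUE)
  }
})

test_that("every pair's death value is anchored at its peak voxel", {
  set.seed(11)
  for (i in 1:10) {
    v <- array(rnorm(10^3), c(10, 10, 10))
    p <- sublevel_2cycles(v)
    expect_true(all(v[cbind(p$peak_i, p$peak_j, p$peak_k)] == p$death))
    expect_true(all(p$death > p$birth))
  }
})

test_that("small value perturbations move births and deaths by at most eps", {
  set.seed(13)
  for (i in 1:10) {
    v <- array(sample(seq(0, 50, by = 2), 8^3, replace = TRUE), c(8, 8, 8))
    p0 <- sublevel_2cycles(v)   # every pair persists by >= 2 (the value gap)
    eps <- 0.4
    dv <- array(runif(length(v), -eps, eps), dim(v))
    # perturbation can promote former zero-persistence (tied) features into
    # pairs of persistence <= 2 eps; those match the diagonal, not p0
    p1 <- sublevel_2cycles(v + dv)
    p1 <- p1[p1$death - p1$birth > 2 * eps, , drop = FALSE]
    expect_equal(nrow(p0), nrow(p1))
    # greedy sup-norm matching of the two diagrams
    left <- seq_len(nrow(p1))
    worst <- 0
    for (q in seq_len(nrow(p0))) {
      dist <- pmax(abs(p1$birth[left] - p0$birth[q]),
                   abs(p1$death[left] - p0$death[q]))
      j <- which.min(dist)
      worst <- max(worst, dist[j])
      left <- left[-j]
    }
    expect_lte(worst, eps + 1e-12)
  }
})

test_that("assign_pairs uses the peak voxel only", {
  atlas <- make_atlas(c(8, 8, 8), 2)
  v <- array(0, c(8, 8, 8))
  # a blob straddling two left ROIs with its peak inside one of them
  v <- place_blob(v, c(3, 3, 4), sigma = 2, peak = 4)
  p <- assign_pairs(sublevel_2cycles(v), atlas, c(8, 8, 8))
  expect_equal(nrow(p), 1L)
  expect_equal(p$roi, atlas$labels[p$peak_i, p$peak_j, p$peak_k])

  # background peaks stay unassigned
  atlas2 <- make_atlas(c(8, 8, 8), 2, margin = 2L)
  v2 <- place_blob(array(0, c(8, 8, 8)), c(4, 4, 2), sigma = 2, peak = 4)
  expect_identical(atlas2$labels[4, 4, 2], 0L)
  p2 <- assign_pairs(sublevel_2cycles(v2), atlas2, c(8, 8, 8))
  expect_true(is.na(p2$roi))
  expect_equal(nrow(hemisphere_diagram(p2, "left", atlas2$lookup)), 0L)

  expect_error(assign_pairs(p, atlas, c(9, 8, 8)),
               class = "asymtopo_validation_error")
})

test_that("filter_pairs applies strict birth/death bounds", {
  d <- data.frame(birth = c(0.1, 0.3, 0.05), death = c(1.5, 2.0, 0.8),
                  peak_i = 1L, peak_j = 1L, peak_k = 1L, roi = NA_integer_)
  kept <- filter_pairs(d, birth_lo = 0, birth_hi = 0.2, death_min = 1)
  expect_equal(kept$birth, 0.1)
  expect_equal(kept$death, 1.5)
  expect_identical(filter_pairs(d), d)
  expect_equal(nrow(filter_pairs(d[0, ], 0, 1)), 0L)
  expect_error(filter_pairs(d, birth_lo = 1, birth_hi = 0),
               class = "asymtopo_validation_error")
})

test_that("hemisphere diagrams partition the assigned pairs", {
  co <- simulate_cohort(cohort_spec(n = 6, seed = 3))
  p <- assign_pairs(sublevel_2cycles(co$volumes[[1]]), co$atlas)
  left <- hemisphere_diagram(p, "left", co$atlas$lookup)
  right <- hemisphere_diagram(p, "right", co$atlas$lookup)
  per_roi <- sum(vapply(co$atlas$lookup$label, function(l) {
    sum(!is.na(p$roi) & p$roi == l)
  }, numeric(1)))
  expect_equal(nrow(left) + nrow(right), per_roi)
  expect_error(hemisphere_diagram(p, "dorsal", co$atlas$lookup),
               class = "asymtopo_validation_error")
})
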