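#' Add a Gaussian blob to a volume
#'
#' Adds `peak * exp(-||x - center||^2 / (2 sigma^2))` at every voxel `x`.
#' Blobs are additive, so placement order never matters.
#'
#' @param vol 3D numeric array.
#' @param center voxel triple (1-based), inside the volume.
#' @param sigma blob width in voxels, > 0.
#' @param peak amplitude added at the center.
#' @return the volume with the blob added.
#' @export
place_blob <- function(vol, center, sigma, peak) {
  validate_volume(vol)
  stopifnot(length(center) == 3L, sigma > 0, is.finite(peak))
  d <- dim(vol)
  if (any(center < 1L) || any(center > d)) {
    stop_validation("blob center lies outside the volume")
  }
  d2 <- outer(outer((seq_len(d[1]) - center[1])^2,
                    (seq_len(d[2]) - center[2])^2, `+`),
              (seq_len(d[3]) - center[3])^2, `+`)
  vol + peak * exp(-d2 / (2 * sigma^2))
}

# all ordered factor triples (a, b, c) with a * b * c == r
factor_triples <- function(r) {
  out <- list()
  for (a in seq_len(r)) {
    if (r %% a != 0L) next
    for (b in seq_len(r %/% a)) {
      if ((r %/% a) %% b != 0L) next
      out[[length(out) + 1L]] <- c(a, b, r %/% (a * b))
    }
  }
  out
}

# split 1..n into k contiguous near-equal intervals; NULL if k > n
split_extent <- function(n, k) {
  if (k > n) return(NULL)
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  ends <- cumsum(sizes)
  cbind(start = c(1L, head(ends, -1L) + 1L), end = ends)
}

#' Build a synthetic left/right box parcellation
#'
#' Splits each hemisphere (the two halves of the flip axis) into
#' `rois_per_hemisphere` contiguous boxes, choosing the most isotropic box
#' grid that fits. Label 0 is background-free here (every voxel is labelled)
#' unless `margin > 0`, in which case a background shell of that thickness is
#' left unlabelled along each axis. The right-hemisphere layout mirrors the
#' left so labels `r` and `rois_per_hemisphere + r` are homologous.
#'
#' @param shape integer triple; the flip axis (first) must be even.
#' @param rois_per_hemisphere number of ROIs per hemisphere, >= 1.
#' @param margin unlabelled background margin in voxels (default 0).
#' @param split_flip if `FALSE`, ROI boxes are never split along the flip
#'   axis (each box spans the hemisphere's full depth), which keeps ROI
#'   interiors away from both the midline and the lateral image face.
#' @return list with `labels` (integer 3D array) and `lookup`
#'   (data.frame: label, name, hemisphere).
#' @export
make_atlas <- function(shape, rois_per_hemisphere, margin = 0L,
                       split_flip = TRUE) {
  stopifnot(length(shape) == 3L, all(shape >= 1L), rois_per_hemisphere >= 1L)
  if (shape[1] %% 2L != 0L) {
    stop_validation("flip axis extent must be even so no ROI straddles the midline")
  }
  half <- shape[1] %/% 2L
  ext <- c(half, shape[2], shape[3]) - c(margin, 2L * margin, 2L * margin)
  if (any(ext < 1L)) stop_validation("shape too small for the requested margin")

  # most isotropic factorisation of the ROI count that fits the hemisphere
  triples <- factor_triples(as.integer(rois_per_hemisphere))
  if (!split_flip) triples <- Filter(function(tr) tr[1] == 1L, triples)
  score <- vapply(triples, function(tr) {
    if (any(tr > ext)) return(Inf)
    max(ext / tr) / min(ext / tr)
  }, numeric(1))
  if (all(!is.finite(score))) {
    stop_validation("shape too small to host the requested ROI count")
  }
  tr <- triples[[which.min(score)]]

  labels <- array(0L, dim = shape)
  s1 <- split_extent(ext[1], tr[1])
  s2 <- split_extent(ext[2], tr[2])
  s3 <- split_extent(ext[3], tr[3])
  lab <- 0L
  for (k in seq_len(tr[3])) for (j in seq_len(tr[2])) for (i in seq_len(tr[1])) {
    lab <- lab + 1L
    i1 <- (s1[i, 1]:s1[i, 2]) + margin
    j1 <- (s2[j, 1]:s2[j, 2]) + margin
    k1 <- (s3[k, 1]:s3[k, 2]) + margin
    labels[i1, j1, k1] <- lab
    # mirrored right-hemisphere box
    labels[shape[1] + 1L - i1, j1, k1] <- lab + as.integer(rois_per_hemisphere)
  }
  r <- as.integer(rois_per_hemisphere)
  lookup <- data.frame(
    label = seq_len(2L * r),
    name = c(paste0("L_", seq_len(r)), paste0("R_", seq_len(r))),
    hemisphere = rep(c("left", "right"), each = r),
    stringsAsFactors = FALSE
  )
  list(labels = labels, lookup = lookup)
}

#' Specify a synthetic cohort
#'
#' Bundles the study conditions for [simulate_cohort()]: cohort size, volume
#' geometry, blob amplitude distribution, the behavior-asymmetry coupling, and
#' covariate/missingness settings.
#'
#' Each participant's Jacobian volume carries i.i.d. Gaussian background noise
#' plus one smooth blob per hemisphere, each placed in a uniformly drawn ROI of
#' that hemisphere (the right blob avoids the mirror of the left blob's ROI so
#' each hemisphere's ground-truth magnitude is unambiguous after
#' flip-subtraction). Blob amplitudes are uniform on `amp_range`, bounded away
#' from zero so every participant carries one well-defined bright structure.
#'
#' Couplings between phonological decoding (standard-score scale, mean 100,
#' sd 15) and the left-hemisphere blob amplitude `a`:
#' \describe{
#'   \item{null}{decoding independent of `a`.}
#'   \item{linear}{`decoding = 100 + 15 * (r z + sqrt(1 - r^2) e)` with
#'     `z` the population-standardised amplitude, `e` standard normal, and
#'     `r = target_r`.}
#'   \item{canalized}{decoding is drawn first; then
#'     `a = strength * max(0, 1 - ((decoding - 100) / 30)^2) * u`, `u` uniform
#'     on (0, 1): peak asymmetry can occur only near average decoding
#'     (sandpile envelope spanning +/- 2 sd).}
#' }
#'
#' @param n number of participants (>= 4).
#' @param shape volume shape; first axis is the flip axis and must be even.
#' @param rois_per_hemisphere ROIs per hemisphere.
#' @param coupling one of "null", "linear", "canalized".
#' @param target_r population correlation for the linear coupling.
#' @param strength amplitude scale of the canalization envelope.
#' @param amp_range uniform blob-amplitude bounds.
#' @param noise_sd Jacobian background noise sd (the asymmetry image noise sd
#'   is `sqrt(2)` times this).
#' @param blob_sigma blob width in voxels.
#' @param smooth_sigma Gaussian smoothing of the Jacobian before subtraction;
#'   0 by default because the synthetic blobs are already smooth.
#' @param n_sites number of research sites.
#' @param age_range uniform age bounds in years.
#' @param covariate_effects named numeric vector of decoding effects for
#'   `age`, `sex`, `site` (per-site sd); all zero by default so recovery tests
#'   isolate the coupling.
#' @param missing_rate MCAR missingness rate applied to behavioral columns.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n, shape = c(12L, 12L, 12L), rois_per_hemisphere = 8L,
                        coupling = c("null", "linear", "canalized"),
                        target_r = 0.3, strength = 2, amp_range = c(1, 2),
                        noise_sd = 0.02, blob_sigma = 0.8, smooth_sigma = 0,
                        n_sites = 4L, age_range = c(6, 17),
                        covariate_effects = c(age = 0, sex = 0, site = 0),
                        missing_rate = 0, seed = 1L) {
  coupling <- match.arg(coupling)
  stopifnot(n >= 4L, target_r >= -1, target_r <= 1, strength >= 0,
            missing_rate >= 0, missing_rate < 1, noise_sd >= 0,
            amp_range[1] > 0, amp_range[2] >= amp_range[1])
  structure(list(n = as.integer(n), shape = as.integer(shape),
                 rois_per_hemisphere = as.integer(rois_per_hemisphere),
                 coupling = coupling, target_r = target_r, strength = strength,
                 amp_range = amp_range, noise_sd = noise_sd,
                 blob_sigma = blob_sigma, smooth_sigma = smooth_sigma,
                 n_sites = as.integer(n_sites), age_range = age_range,
                 covariate_effects = covariate_effects,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "cohort_spec")
}

# center of an ROI box, jittered by at most 1 voxel, kept inside the box and
# inside the optional safe range (away from image faces and midline so blob
# tails stay well below the enclosure level)
roi_center <- function(labels, label, jit, safe_lo = NULL, safe_hi = NULL) {
  idx <- which(labels == label, arr.ind = TRUE)
  ctr <- round(colMeans(idx))
  lo <- apply(idx, 2, min)
  hi <- apply(idx, 2, max)
  if (!is.null(safe_lo)) {
    ok <- safe_lo <= hi & safe_hi >= lo   # only tighten where feasible
    lo <- ifelse(ok, pmax(lo, safe_lo), lo)
    hi <- ifelse(ok, pmin(hi, safe_hi), hi)
  }
  pmin(pmax(ctr + jit, lo), hi)
}

#' Simulate a cohort of asymmetry volumes with behavioral ground truth
#'
#' Generates, per participant, a Jacobian volume (noise + one blob per
#' hemisphere), flip-subtracts it into an asymmetry volume, and draws the
#' behavioral table under the requested coupling (see [cohort_spec()]).
#' Fully reproducible from `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return list with `volumes` (named list of 3D arrays), `table`
#'   (data.frame: id, decoding, word_id, comprehension, rapid_naming,
#'   verbal_comp, age, sex, site, total_brain_volume), `atlas`, and `truth`
#'   (per-participant blob amplitudes and ROI placements, plus the
#'   n x n_labels ROI amplitude matrix and n x 2 hemisphere amplitude matrix).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  atlas <- make_atlas(spec$shape, spec$rois_per_hemisphere, margin = 1L,
                      split_flip = FALSE)
  R <- spec$rois_per_hemisphere
  n <- spec$n
  d <- spec$shape
  half <- d[1] %/% 2L
  # blob centers stay >= 2 voxels from image faces and from the midline
  safe <- list(
    left = list(lo = c(3L, 3L, 3L), hi = c(half - 2L, d[2] - 2L, d[3] - 2L)),
    right = list(lo = c(half + 3L, 3L, 3L), hi = d - 2L)
  )

  with_seed(spec$seed, {
    # design draws, in fixed order for reproducibility
    roi_left <- sample.int(R, n, replace = TRUE)
    # the right blob's ROI is chosen so that its mirrored box is well
    # separated from the left blob's ROI: overlapping mirrored structures
    # would cancel under flip-subtraction and blur the ground truth
    rng <- lapply(seq_len(R), function(lab) {
      idx <- which(atlas$labels == lab, arr.ind = TRUE)
      rbind(apply(idx, 2, min), apply(idx, 2, max))
    })
    box_gap <- function(l1, l2) {
      max(rng[[l2]][1, ] - rng[[l1]][2, ] - 1L,
          rng[[l1]][1, ] - rng[[l2]][2, ] - 1L)
    }
    gaps <- outer(seq_len(R), seq_len(R), Vectorize(box_gap))
    roi_right <- vapply(roi_left, function(rl) {
      for (min_gap in c(2L, 1L)) {
        cand <- which(gaps[rl, ] >= min_gap)
        if (length(cand) > 0L) {
          return(cand[sample.int(length(cand), 1L)])
        }
      }
      cand <- setdiff(seq_len(R), rl)
      if (length(cand) == 0L) rl else cand[sample.int(length(cand), 1L)]
    }, integer(1)) + R
    jit_l <- matrix(sample(-1:1, 3L * n, replace = TRUE), ncol = 3L)
    jit_r <- matrix(sample(-1:1, 3L * n, replace = TRUE), ncol = 3L)
    amp_right <- runif(n, spec$amp_range[1], spec$amp_range[2])

    age <- runif(n, spec$age_range[1], spec$age_range[2])
    sex <- rbinom(n, 1L, 0.5)
    site <- sample.int(spec$n_sites, n, replace = TRUE)
    tbv <- rnorm(n, 1000, 100)
    ce <- spec$covariate_effects
    cov_shift <- ce[["age"]] * (age - mean(spec$age_range)) +
      ce[["sex"]] * (sex - 0.5) +
      ce[["site"]] * rnorm(spec$n_sites)[site]

    if (spec$coupling == "null") {
      amp_left <- runif(n, spec$amp_range[1], spec$amp_range[2])
      decoding <- 100 + 15 * rnorm(n) + cov_shift
    } else if (spec$coupling == "linear") {
      amp_left <- runif(n, spec$amp_range[1], spec$amp_range[2])
      z <- (amp_left - mean(spec$amp_range)) / (diff(spec$amp_range) / sqrt(12))
      r <- spec$target_r
      decoding <- 100 + 15 * (r * z + sqrt(1 - r^2) * rnorm(n)) + cov_shift
    } else { # canalized: sandpile envelope, peak asymmetry at average decoding
      decoding <- 100 + 15 * rnorm(n) + cov_shift
      env <- pmax(0, 1 - ((decoding - 100) / 30)^2)
      amp_left <- spec$strength * env * runif(n)
    }

    zdec <- (decoding - 100) / 15
    extra <- function() 100 + 15 * (0.6 * zdec + 0.8 * rnorm(n))
    table <- data.frame(
      id = sprintf("P%04d", seq_len(n)),
      decoding = decoding, word_id = extra(), comprehension = extra(),
      rapid_naming = extra(), verbal_comp = extra(),
      age = age, sex = sex, site = site, total_brain_volume = tbv,
      stringsAsFactors = FALSE
    )

    volumes <- vector("list", n)
    for (i in seq_len(n)) {
      jac <- array(rnorm(prod(spec$shape), sd = spec$noise_sd), dim = spec$shape)
      if (amp_left[i] > 0) {
        jac <- place_blob(jac, roi_center(atlas$labels, roi_left[i], jit_l[i, ],
                                          safe$left$lo, safe$left$hi),
                          spec$blob_sigma, amp_left[i])
      }
      jac <- place_blob(jac, roi_center(atlas$labels, roi_right[i], jit_r[i, ],
                                        safe$right$lo, safe$right$hi),
                        spec$blob_sigma, amp_right[i])
      volumes[[i]] <- asymmetry_from_jacobian(jac, spec$smooth_sigma)
    }
    names(volumes) <- table$id

    roi_amp <- matrix(0, n, 2L * R,
                      dimnames = list(table$id, atlas$lookup$name))
    roi_amp[cbind(seq_len(n), roi_left)] <- amp_left
    roi_amp[cbind(seq_len(n), roi_right)] <- amp_right
    truth <- list(
      amp_left = amp_left, amp_right = amp_right,
      roi_left = roi_left, roi_right = roi_right,
      roi_amplitude = roi_amp,
      hemi_amplitude = cbind(left = amp_left, right = amp_right)
    )

    if (spec$missing_rate > 0) {
      table <- inject_missingness(table, spec$missing_rate,
                                  seed = spec$seed + 1L)
    }
    list(volumes = volumes, table = table, atlas = atlas, truth = truth,
         spec = spec)
  })
}

#' Behavioral columns of a cohort table
#' @keywords internal
behavioral_columns <- function() {
  c("decoding", "word_id", "comprehension", "rapid_naming", "verbal_comp")
}

#' Inject completely-at-random missingness into behavioral columns
#'
#' @param table cohort table.
#' @param rate missingness probability per behavioral cell, in `[0, 1)`.
#' @param seed integer seed.
#' @param columns columns to affect; defaults to the behavioral scores.
#' @return the table with `NA`s injected; id and covariates untouched.
#' @export
inject_missingness <- function(table, rate, seed,
                               columns = intersect(behavioral_columns(),
                                                   names(table))) {
  if (!is.numeric(rate) || rate < 0 || rate >= 1) {
    stop_validation("missingness rate must lie in [0, 1)")
  }
  if (rate == 0) return(table)
  with_seed(seed, {
    for (cl in columns) {
      table[[cl]][runif(nrow(table)) < rate] <- NA_real_
    }
    table
  })
}
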