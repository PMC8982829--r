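#' Threshold pooled position-wise results into signed significance masks
#'
#' A position enters the mask matching the sign of its estimate when its
#' (uncorrected, two-tailed) p-value is strictly below `alpha`.
#'
#' @param estimate numeric vector of position estimates.
#' @param p numeric vector of p-values in `[0, 1]`, same length, no missing.
#' @param alpha significance level (default 0.05), strict inequality.
#' @return list of logical masks `positive` and `negative`.
#' @export
threshold_mask <- function(estimate, p, alpha = 0.05) {
  stopifnot(length(estimate) == length(p))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop_validation("p-values must be present and within [0, 1]")
  }
  sig <- p < alpha
  list(positive = sig & estimate > 0, negative = sig & estimate < 0)
}

# longest run of TRUE in a logical vector
max_run <- function(mask) {
  if (!any(mask)) return(0L)
  r <- rle(mask)
  max(r$lengths[r$values])
}

#' Permutation run-length null and extent cutoff for a significance mask
#'
#' Resamples the observed position indicators i.i.d. with replacement
#' `n_perm` times, records the maximum run of consecutive significant
#' positions in each resample, and returns the smallest run length `k*`
#' whose null probability of occurring is below 0.05. Effects must span at
#' least `k*` adjacent positions to survive. An all-FALSE mask yields the
#' vacuous `k* = 1` (nothing can survive since no position is significant).
#'
#' @param mask logical vector of uncorrected significance calls (length >= 2).
#' @param n_perm number of permutations (>= 100; default 10000).
#' @param seed integer seed.
#' @param pool indicators to resample from; defaults to the observed mask
#'   itself. When many landscapes are corrected together, passing their
#'   concatenated indicators estimates the chance run length from the whole
#'   family (most of which is null) rather than from one landscape's own
#'   significance density.
#' @return list: `k_star`, `null_tail` (P(max run >= k) for k = 1..L),
#'   `n_perm`, `seed`.
#' @export
extent_null <- function(mask, n_perm = 10000L, seed = 1L, pool = mask) {
  L <- length(mask)
  stopifnot(is.logical(mask), is.logical(pool), L >= 2L, length(pool) >= 1L)
  if (n_perm < 100L) stop_validation("n_perm < 100 is underpowered")
  runs <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      max_run(sample(pool, L, replace = TRUE))
    }, integer(1))
  })
  tail_p <- vapply(seq_len(L), function(k) mean(runs >= k), numeric(1))
  k_star <- which(tail_p < 0.05)
  k_star <- if (length(k_star) == 0L) L + 1L else min(k_star)
  k_star <- max(1L, k_star)
  list(k_star = as.integer(k_star), null_tail = tail_p,
       n_perm = as.integer(n_perm), seed = seed)
}

#' Apply an extent threshold to a significance mask
#'
#' Retains only maximal runs of consecutive significant positions with
#' length at least `k_star`.
#'
#' @param mask logical vector.
#' @param k_star minimum surviving run length (>= 1).
#' @return logical vector of the same length.
#' @export
apply_extent <- function(mask, k_star) {
  stopifnot(k_star >= 1L)
  r <- rle(mask)
  r$values <- r$values & r$lengths >= k_star
  inverse.rle(r)
}

#' Two-sample replication gate
#'
#' Declares positions significant only when they survive extent correction
#' in both samples at the same position and direction; single-sample
#' survivors are reported separately.
#'
#' @param corrected_a,corrected_b lists with logical `positive` and
#'   `negative` masks of equal length.
#' @return list per direction: `a`, `b` (surviving position indices per
#'   sample), `intersection`; plus `headline`, TRUE when any intersection is
#'   nonempty.
#' @export
replication_gate <- function(corrected_a, corrected_b) {
  if (length(corrected_a$positive) != length(corrected_b$positive)) {
    stop_validation("samples use different position indexing")
  }
  out <- lapply(c(positive = "positive", negative = "negative"), function(dir) {
    list(a = which(corrected_a[[dir]]),
         b = which(corrected_b[[dir]]),
         intersection = which(corrected_a[[dir]] & corrected_b[[dir]]))
  })
  out$headline <- length(out$positive$intersection) > 0L ||
    length(out$negative$intersection) > 0L
  out
}
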