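#' @useDynLib asymtopo, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats lm.fit pt qt rnorm runif rbinom sd complete.cases poly
#' @importFrom utils head read.csv write.csv read.delim write.table
NULL

#' Validate a 3D scalar volume
#'
#' Volumes are plain 3D numeric arrays. The left-right flip axis is the first
#' array dimension by default; voxel indices are 1-based in R.
#'
#' @param vol object to validate.
#' @param min_extent minimum number of voxels required along every axis.
#' @return `vol`, invisibly, if valid; otherwise an error of class
#'   `asymtopo_validation_error`.
#' @keywords internal
validate_volume <- function(vol, min_extent = 1L) {
  if (!is.array(vol) || length(dim(vol)) != 3L || !is.numeric(vol)) {
    stop_validation("volume must be a 3D numeric array")
  }
  if (any(dim(vol) < min_extent)) {
    stop_validation(sprintf("volume must have at least %d voxels per axis", min_extent))
  }
  if (!all(is.finite(vol))) {
    stop_validation("volume contains non-finite values")
  }
  invisible(vol)
}

stop_validation <- function(msg) {
  stop(structure(class = c("asymtopo_validation_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Mirror a volume across its flip axis
#'
#' The mirror of voxel index i along an axis of length N is N + 1 - i
#' (1-based), so an even-length axis has no fixed voxels while the midplane of
#' an odd-length axis maps to itself.
#'
#' @param vol 3D numeric array.
#' @param flip_axis axis index (1, 2 or 3) across which to mirror.
#' @return the mirrored array.
#' @export
mirror_volume <- function(vol, flip_axis = 1L) {
  stopifnot(flip_axis %in% 1:3)
  idx <- rep(list(quote(expr = )), 3L)
  idx[[flip_axis]] <- rev(seq_len(dim(vol)[flip_axis]))
  do.call(`[`, c(list(vol), idx, list(drop = FALSE)))
}

#' Flip-subtract a Jacobian volume into an asymmetry volume
#'
#' Subtracts each voxel's homologous (mirrored) value, producing an exactly
#' antisymmetric volume: positive values on one side indicate that this side's
#' structure is larger than its contralateral homologue.
#'
#' @param jacobian 3D numeric array of log-Jacobian (or any scalar) values.
#' @param flip_axis the left-right axis (default first).
#' @return 3D array `A` with `A == -mirror_volume(A, flip_axis)` exactly.
#' @examples
#' j <- array(0, c(4, 3, 3)); j[1, 2, 2] <- 2
#' a <- flip_subtract(j)
#' a[1, 2, 2]  # 2
#' a[4, 2, 2]  # -2
#' @export
flip_subtract <- function(jacobian, flip_axis = 1L) {
  validate_volume(jacobian, min_extent = 1L)
  if (dim(jacobian)[flip_axis] < 2L) {
    stop_validation("flip axis must have length >= 2")
  }
  jacobian - mirror_volume(jacobian, flip_axis)
}

#' Separable Gaussian smoothing of a 3D volume
#'
#' Truncated (radius `ceiling(3 * sigma)`) separable kernel; near the edges the
#' kernel is renormalised over the in-bounds support so a constant volume is
#' preserved exactly.
#'
#' @param vol 3D numeric array.
#' @param sigma kernel standard deviation in voxel units; 0 is a no-op.
#' @return the smoothed array.
#' @export
smooth_gaussian <- function(vol, sigma) {
  validate_volume(vol)
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma >= 0)
  if (sigma == 0) return(vol)
  r <- as.integer(ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  out <- vol
  for (ax in 1:3) {
    n <- dim(out)[ax]
    # banded smoothing matrix with edge renormalisation
    sm <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- max(1L, i - r):min(n, i + r)
      w <- k[j - i + r + 1L]
      sm[i, j] <- w / sum(w)
    }
    out <- apply_along(out, ax, sm)
  }
  out
}

# multiply matrix `sm` along axis `ax` of a 3D array
apply_along <- function(x, ax, sm) {
  d <- dim(x)
  perm <- c(ax, setdiff(1:3, ax))
  y <- aperm(x, perm)
  y <- sm %*% matrix(y, nrow = d[ax])
  y <- array(y, dim = d[perm])
  aperm(y, order(perm))
}

#' Asymmetry image from a Jacobian volume
#'
#' Smooths the Jacobian volume (default on) and then flip-subtracts it, the
#' order used when constructing deformation-based asymmetry images.
#'
#' @param jacobian 3D numeric array.
#' @param smooth_sigma Gaussian kernel sd in voxels applied before
#'   subtraction; set to 0 to disable.
#' @param flip_axis the left-right axis.
#' @return antisymmetric 3D array.
#' @export
asymmetry_from_jacobian <- function(jacobian, smooth_sigma = 1, flip_axis = 1L) {
  flip_subtract(smooth_gaussian(jacobian, smooth_sigma), flip_axis)
}

#' Mean asymmetry within a region of interest
#'
#' The voxel-averaging baseline: the arithmetic mean of the volume over the
#' voxels carrying a given atlas label.
#'
#' @param vol 3D numeric array.
#' @param atlas a [make_atlas()]-style atlas (list with `labels` and `lookup`).
#' @param label integer ROI label present in the atlas.
#' @return scalar mean.
#' @export
roi_mean_asymmetry <- function(vol, atlas, label) {
  validate_volume(vol)
  if (!identical(dim(vol), dim(atlas$labels))) {
    stop_validation("volume and atlas shapes differ")
  }
  sel <- atlas$labels == label
  if (!any(sel)) stop_validation(sprintf("ROI label %s is empty or absent", label))
  mean(vol[sel])
}

# evaluate expr under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
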