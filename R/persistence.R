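#' 2-cycle persistence pairs of the sublevel filtration of a 3D volume
#'
#' Computes the finite (birth, death) pairs of degree-2 homology (cavities:
#' bright 3D structures enclosed by relatively dark voxels) of the sublevel-set
#' cubical filtration. `birth` is the enclosing boundary level, `death` the
#' peak value of the structure; zero-persistence pairs are discarded. The
#' image is treated as a solid block with no padding, so a structure must be
#' enclosed by in-image voxels to count. Bright components are 26-connected
#' (equivalently, the dark phase is 6-connected).
#'
#' Two routes are provided: the fast merge-tree route on superlevel-set
#' components (`"superlevel"`, the default, implemented in C++) and a direct
#' boundary-matrix reduction of the sublevel cubical complex
#' (`"reduction"`). They return identical (birth, death) multisets.
#'
#' @param vol 3D numeric array with at least 3 voxels per axis, all finite.
#' @param method `"superlevel"` or `"reduction"`.
#' @param death_min optional noise floor; pairs with `death <= death_min`
#'   are dropped (default `-Inf`, keep all).
#' @return data.frame with columns `birth`, `death`, `peak_i`, `peak_j`,
#'   `peak_k` (1-based voxel attaining the death value, ties broken by
#'   smallest lexicographic index) and `roi` (`NA` until [assign_pairs()]),
#'   sorted by (birth, death, peak index).
#' @examples
#' v <- array(0, c(7, 7, 7)); v[4, 4, 4] <- 5
#' sublevel_2cycles(v)  # one pair: birth 0, death 5
#' @export
sublevel_2cycles <- function(vol, method = c("superlevel", "reduction"),
                             death_min = -Inf) {
  method <- match.arg(method)
  validate_volume(vol, min_extent = 3L)
  pairs <- if (method == "superlevel") {
    .cpp_sublevel_2cycles(as.numeric(vol), as.integer(dim(vol)))
  } else {
    reduce_sublevel_h2(vol)
  }
  pairs <- pairs[pairs$death > death_min, , drop = FALSE]
  pairs$roi <- rep(NA_integer_, nrow(pairs))
  o <- order(pairs$birth, pairs$death, pairs$peak_i, pairs$peak_j, pairs$peak_k)
  pairs <- pairs[o, , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Assign persistence pairs to ROIs by their peak voxel
#'
#' A pair belongs to the ROI in which its peak voxel (the death location)
#' lies; background (label 0) leaves it unassigned (`NA`). A pair is never
#' duplicated across ROIs even when its spatial extent straddles several.
#'
#' @param pairs data.frame from [sublevel_2cycles()].
#' @param atlas list with `labels` (integer array of the volume's shape) and
#'   `lookup`.
#' @param vol_dim the shape of the volume the pairs came from, used to check
#'   against the atlas shape (optional).
#' @return `pairs` with the `roi` column filled in.
#' @export
assign_pairs <- function(pairs, atlas, vol_dim = NULL) {
  if (!is.null(vol_dim) && !identical(as.integer(vol_dim), dim(atlas$labels))) {
    stop_validation("atlas shape does not match volume shape")
  }
  if (nrow(pairs) == 0L) {
    pairs$roi <- integer(0)
    return(pairs)
  }
  lab <- atlas$labels[cbind(pairs$peak_i, pairs$peak_j, pairs$peak_k)]
  pairs$roi <- ifelse(lab == 0L, NA_integer_, as.integer(lab))
  pairs
}

#' Filter a persistence diagram by birth and death ranges
#'
#' Keeps pairs with `birth` strictly inside `(birth_lo, birth_hi)` and
#' `death` strictly greater than `death_min`; any bound may be disabled by
#' leaving it infinite.
#'
#' @param pairs persistence pairs data.frame.
#' @param birth_lo,birth_hi open birth interval (defaults disable).
#' @param death_min strict lower death bound (default disables).
#' @return the filtered data.frame.
#' @export
filter_pairs <- function(pairs, birth_lo = -Inf, birth_hi = Inf,
                         death_min = -Inf) {
  if (birth_lo >= birth_hi) stop_validation("inverted birth bounds")
  keep <- pairs$birth > birth_lo & pairs$birth < birth_hi &
    pairs$death > death_min
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pool the assigned pairs of one hemisphere
#'
#' The union of all pairs assigned to any ROI of the requested hemisphere;
#' unassigned pairs are excluded.
#'
#' @param pairs assigned pairs (from [assign_pairs()]).
#' @param hemisphere `"left"` or `"right"`.
#' @param lookup the atlas lookup (label, name, hemisphere).
#' @return the hemisphere's pairs data.frame.
#' @export
hemisphere_diagram <- function(pairs, hemisphere, lookup) {
  if (!hemisphere %in% c("left", "right")) {
    stop_validation(sprintf("unknown hemisphere '%s'", hemisphere))
  }
  labs <- lookup$label[lookup$hemisphere == hemisphere]
  out <- pairs[!is.na(pairs$roi) & pairs$roi %in% labs, , drop = FALSE]
  rownames(out) <- NULL
  out
}
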