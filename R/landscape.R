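#' Fixed landscape position grid
#'
#' Equally spaced positions `t_g = lo + (g - 1) (hi - lo) / (G - 1)`,
#' `g = 1..G`. The grid is computed once from the pooled diagrams of a sample
#' and scope family and reused for every participant so that positions are
#' comparable across participants.
#'
#' @param lo,hi real bounds, `hi > lo`.
#' @param G number of positions (default 15, >= 3).
#' @return a `landscape_grid` list with `lo`, `hi`, `G` and `positions`.
#' @export
landscape_grid <- function(lo, hi, G = 15L) {
  stopifnot(is.finite(lo), is.finite(hi), G >= 3L)
  if (hi <= lo) stop_validation("grid requires hi > lo")
  structure(list(lo = lo, hi = hi, G = as.integer(G),
                 positions = seq(lo, hi, length.out = G)),
            class = "landscape_grid")
}

#' Grid spanning the pooled diagrams of a sample
#'
#' `lo` is the minimum birth and `hi` the maximum death over all pooled
#' pairs, so the grid spans the full range of asymmetry values seen in the
#' sample and the first and last positions carry no data.
#'
#' @param pairs a persistence-pairs data.frame, or a list of them, pooled
#'   over the sample and scope family.
#' @param G number of positions (default 15).
#' @return a [landscape_grid()].
#' @export
make_grid <- function(pairs, G = 15L) {
  if (is.data.frame(pairs)) pairs <- list(pairs)
  births <- unlist(lapply(pairs, `[[`, "birth"))
  deaths <- unlist(lapply(pairs, `[[`, "death"))
  if (length(births) == 0L) {
    stop_validation("cannot build a grid from empty pooled diagrams")
  }
  landscape_grid(min(births), max(deaths), G)
}

#' First persistence landscape sampled on a grid
#'
#' `lambda(t) = max over pairs (b, d) of max(0, min(t - b, d - t))`: the
#' life span of the most persistent structure whose tent covers `t`. An empty
#' diagram yields zeros everywhere.
#'
#' @param pairs persistence pairs data.frame (columns `birth`, `death`).
#' @param grid a [landscape_grid()].
#' @return numeric vector of length `grid$G` with the grid attached as an
#'   attribute.
#' @export
landscape_first <- function(pairs, grid) {
  stopifnot(inherits(grid, "landscape_grid"))
  t <- grid$positions
  if (nrow(pairs) == 0L) {
    lam <- numeric(grid$G)
  } else {
    rise <- outer(t, pairs$birth, `-`)                    # t - b
    fall <- outer(t, pairs$death, function(tt, dd) dd - tt) # d - t
    lam <- apply(pmax(pmin(rise, fall), 0), 1, max)
  }
  attr(lam, "grid") <- grid
  lam
}

#' Assemble per-participant landscapes into an analysis matrix
#'
#' Rows are participants, columns the analyzed positions `2..G-1` (13 by
#' default): the endpoint positions are computed but excluded because the
#' grid spans the pooled range and they carry no data.
#'
#' @param landscapes named list of [landscape_first()] vectors sharing one
#'   grid; participants with no pairs contribute zero rows.
#' @return numeric matrix (participants x G-2) with `pos_<g>` column names.
#' @export
build_matrix <- function(landscapes) {
  stopifnot(length(landscapes) >= 1L)
  grids <- lapply(landscapes, attr, "grid")
  g0 <- grids[[1]]
  same <- vapply(grids, function(g) {
    isTRUE(all.equal(c(g$lo, g$hi, g$G), c(g0$lo, g0$hi, g0$G)))
  }, logical(1))
  if (!all(same)) stop_validation("landscapes do not share a common grid")
  G <- g0$G
  m <- do.call(rbind, lapply(landscapes, function(l) l[2:(G - 1L)]))
  rownames(m) <- names(landscapes)
  colnames(m) <- paste0("pos_", 2:(G - 1L))
  attr(m, "grid") <- g0
  m
}
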