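# Direct sublevel-set computation of degree-2 persistence by boundary-matrix
# reduction over GF(2).
#
# The volume's voxels are the vertices of a cubical complex filling a solid
# block; every cell takes the maximum value of its vertices (so the dark,
# sublevel phase is 6-connected and the bright complement 26-connected, the
# dual of the superlevel merge-tree route). Degree-2 pairs are exactly the
# pivot pairs of the reduced 3-boundary matrix, with columns (3-cells) and
# rows (2-cells) ordered by (value, index).

# symmetric difference of two sorted integer vectors (GF(2) column addition)
xor_cols <- function(a, b) {
  u <- sort(c(a, b))
  u[!(duplicated(u) | duplicated(u, fromLast = TRUE))]
}

reduce_sublevel_h2 <- function(vol) {
  d <- dim(vol)
  n1 <- d[1]; n2 <- d[2]; n3 <- d[3]
  c1 <- n1 - 1L; c2 <- n2 - 1L; c3 <- n3 - 1L

  # face values per orientation (max over the face's 4 vertices)
  f1 <- pmax(vol[, 1:c2, 1:c3, drop = FALSE], vol[, 2:n2, 1:c3, drop = FALSE],
             vol[, 1:c2, 2:n3, drop = FALSE], vol[, 2:n2, 2:n3, drop = FALSE])
  f2 <- pmax(vol[1:c1, , 1:c3, drop = FALSE], vol[2:n1, , 1:c3, drop = FALSE],
             vol[1:c1, , 2:n3, drop = FALSE], vol[2:n1, , 2:n3, drop = FALSE])
  f3 <- pmax(vol[1:c1, 1:c2, , drop = FALSE], vol[2:n1, 1:c2, , drop = FALSE],
             vol[1:c1, 2:n2, , drop = FALSE], vol[2:n1, 2:n2, , drop = FALSE])
  fvals <- c(as.numeric(f1), as.numeric(f2), as.numeric(f3))
  off2 <- length(f1)
  off3 <- off2 + length(f2)

  # cube values (max over 8 vertices)
  cvals <- pmax(f1[1:c1, , , drop = FALSE], f1[2:n1, , , drop = FALSE])
  ncubes <- length(cvals)
  cvals <- as.numeric(cvals)

  # rows: faces ordered by (value, id)
  ford <- order(fvals, seq_along(fvals))
  frank <- integer(length(fvals))
  frank[ford] <- seq_along(fvals)
  fval_by_rank <- fvals[ford]

  # the 6 face ids of cube (i, j, k), vectorised over all cubes
  ci <- rep.int(seq_len(c1), c2 * c3)
  cj <- rep.int(rep(seq_len(c2), each = c1), c3)
  ck <- rep(seq_len(c3), each = c1 * c2)
  id1 <- function(i, j, k) i + n1 * ((j - 1L) + c2 * (k - 1L))
  id2 <- function(i, j, k) off2 + i + c1 * ((j - 1L) + n2 * (k - 1L))
  id3 <- function(i, j, k) off3 + i + c1 * ((j - 1L) + c2 * (k - 1L))
  faces <- cbind(id1(ci, cj, ck), id1(ci + 1L, cj, ck),
                 id2(ci, cj, ck), id2(ci, cj + 1L, ck),
                 id3(ci, cj, ck), id3(ci, cj, ck + 1L))

  cord <- order(cvals, seq_len(ncubes))
  pivot <- integer(length(fvals))
  cols <- vector("list", ncubes)
  pair_row <- integer(0)
  pair_cube <- integer(0)

  for (j in cord) {
    col <- sort(frank[faces[j, ]])
    repeat {
      if (length(col) == 0L) break
      l <- col[length(col)]
      if (pivot[l] == 0L) {
        pivot[l] <- j
        cols[[j]] <- col
        pair_row <- c(pair_row, l)
        pair_cube <- c(pair_cube, j)
        break
      }
      col <- xor_cols(col, cols[[pivot[l]]])
    }
  }

  birth <- fval_by_rank[pair_row]
  death <- cvals[pair_cube]
  keep <- death > birth
  birth <- birth[keep]
  death <- death[keep]
  pair_cube <- pair_cube[keep]

  # peak voxel: the killing cube's maximal corner, lexicographically smallest
  m <- length(pair_cube)
  pi <- pj <- pk <- integer(m)
  for (q in seq_len(m)) {
    j <- pair_cube[q]
    i0 <- ci[j]; j0 <- cj[j]; k0 <- ck[j]
    corners <- as.matrix(expand.grid(i = i0 + 0:1, j = j0 + 0:1, k = k0 + 0:1))
    vals <- vol[corners]
    best <- corners[vals == max(vals), , drop = FALSE]
    best <- best[order(best[, 1], best[, 2], best[, 3])[1], ]
    pi[q] <- best[1]; pj[q] <- best[2]; pk[q] <- best[3]
  }
  data.frame(birth = birth, death = death, peak_i = pi, peak_j = pj,
             peak_k = pk, stringsAsFactors = FALSE)
}
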