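# Independent oracles used to cross-check the package implementations.
# These are deliberately written with different data structures and
# conventions than the package code paths they validate.

# --- degree-2 persistence via dense GF(2) boundary reduction ----------------
# Vertices are voxels; every square (2-cell) and cube (3-cell) takes the max
# of its vertices. The full 3-boundary matrix is reduced with the textbook
# column algorithm on a dense logical matrix; pivot pairs (square, cube) with
# positive persistence are the finite degree-2 pairs.
oracle_h2_pairs <- function(vol) {
  d <- dim(vol)
  vid <- function(i, j, k) i + d[1] * (j - 1L) + d[1] * d[2] * (k - 1L)

  # enumerate squares by their 4 vertex ids (keyed), and cubes by corners
  face_key <- character(0)
  face_val <- numeric(0)
  face_env <- new.env(hash = TRUE)
  add_face <- function(verts) {
    key <- paste(sort(verts), collapse = "-")
    if (is.null(face_env[[key]])) {
      face_key[[length(face_key) + 1L]] <<- key
      face_val[[length(face_val) + 1L]] <<- max(vol[verts])
      face_env[[key]] <- length(face_key)
    }
    face_env[[key]]
  }

  nc <- (d[1] - 1L) * (d[2] - 1L) * (d[3] - 1L)
  cube_val <- numeric(nc)
  cube_faces <- vector("list", nc)
  q <- 0L
  for (k in seq_len(d[3] - 1L)) for (j in seq_len(d[2] - 1L)) {
    for (i in seq_len(d[1] - 1L)) {
      q <- q + 1L
      corners <- as.vector(outer(outer(vid(i + 0:1, j, k) - vid(i, j, k),
                                       vid(i, j + 0:1, k) - vid(i, j, k), `+`),
                                 vid(i, j, k + 0:1), `+`))
      cube_val[q] <- max(vol[corners])
      cs <- array(corners, c(2, 2, 2))
      cube_faces[[q]] <- c(
        add_face(as.vector(cs[1, , ])), add_face(as.vector(cs[2, , ])),
        add_face(as.vector(cs[, 1, ])), add_face(as.vector(cs[, 2, ])),
        add_face(as.vector(cs[, , 1])), add_face(as.vector(cs[, , 2])))
    }
  }

  nf <- length(face_val)
  ford <- order(face_val, face_key)       # row order: (value, vertex key)
  frank <- integer(nf)
  frank[ford] <- seq_len(nf)

  M <- matrix(FALSE, nf, nc)
  for (q2 in seq_len(nc)) M[frank[cube_faces[[q2]]], q2] <- TRUE

  pivot <- integer(nf)
  births <- numeric(0)
  deaths <- numeric(0)
  for (j2 in order(cube_val, seq_len(nc))) {
    repeat {
      nz <- which(M[, j2])
      if (length(nz) == 0L) break
      low <- nz[length(nz)]
      if (pivot[low] == 0L) {
        pivot[low] <- j2
        births <- c(births, face_val[ford[low]])
        deaths <- c(deaths, cube_val[j2])
        break
      }
      M[, j2] <- xor(M[, j2], M[, pivot[low]])
    }
  }
  keep <- deaths > births
  out <- data.frame(birth = births[keep], death = deaths[keep])
  out[order(out$birth, out$death), , drop = FALSE]
}

# --- exact tau-quantile regression by basic-solution enumeration ------------
# The check-loss minimum over beta is attained at a basic solution that
# interpolates p observations; enumerate all invertible p-subsets and keep
# the best. Exact for small n.
oracle_quantile <- function(X, y, tau) {
  n <- nrow(X)
  p <- ncol(X)
  rho <- function(r) sum(r * (tau - (r < 0)))
  best <- NULL
  best_loss <- Inf
  for (S in utils::combn(n, p, simplify = FALSE)) {
    XS <- X[S, , drop = FALSE]
    if (abs(det(XS)) < 1e-10) next
    beta <- solve(XS, y[S])
    loss <- rho(y - X %*% beta)
    if (loss < best_loss - 1e-12) {
      best_loss <- loss
      best <- beta
    }
  }
  list(coefficients = as.numeric(best), loss = best_loss)
}

# --- exact tail probability of the maximum run of an i.i.d. binary vector ---
oracle_maxrun_tail <- function(L, k, prob) {
  total <- 0
  for (code in 0:(2^L - 1)) {
    bits <- as.integer(intToBits(code))[seq_len(L)] == 1L
    r <- rle(bits)
    mx <- if (any(bits)) max(r$lengths[r$values]) else 0L
    if (mx >= k) {
      total <- total + prod(ifelse(bits, prob, 1 - prob))
    }
  }
  total
}

# --- closed-form simple-regression slope via the normal equations -----------
oracle_ols_slope <- function(y, x) {
  X <- cbind(1, x)
  as.numeric(solve(t(X) %*% X, t(X) %*% y))[2]
}
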