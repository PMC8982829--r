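# Small fixture builders shared across test files; everything is generated
# in code under fixed seeds.

# random integer-valued volume, the tie-heavy stress case for persistence
random_int_volume <- function(dims, vmax = 6L) {
  array(sample(0:vmax, prod(dims), replace = TRUE), dim = dims)
}

# a volume with one off-center interior peak on a zero background
single_peak_volume <- function(dims = c(7L, 7L, 7L), at = c(4L, 4L, 4L),
                               value = 5) {
  v <- array(0, dim = dims)
  v[at[1], at[2], at[3]] <- value
  v
}

# two interior peaks (5 and 3) joined by a ridge of value 2 on background 0
two_peak_ridge_volume <- function() {
  w <- array(0, c(9L, 9L, 9L))
  w[3, 5, 5] <- 5
  w[7, 5, 5] <- 3
  w[4:6, 5, 5] <- 2
  w
}

# random persistence diagram as a pairs data.frame
random_diagram <- function(n_pairs, lo = 0, hi = 1) {
  b <- runif(n_pairs, lo, hi)
  d <- b + runif(n_pairs, 0, hi - b)
  data.frame(birth = b, death = d,
             peak_i = 1L, peak_j = 1L, peak_k = 1L, roi = NA_integer_)
}

# small cohort table with optional missingness for imputation tests
tiny_table <- function(n, seed = 1, miss = 0) {
  asymtopo::inject_missingness(
    with_seed_local(seed, data.frame(
      id = sprintf("S%03d", seq_len(n)),
      decoding = rnorm(n, 100, 15),
      word_id = rnorm(n, 100, 15),
      age = runif(n, 6, 17),
      sex = rbinom(n, 1, 0.5),
      site = sample.int(3, n, replace = TRUE),
      total_brain_volume = rnorm(n, 1000, 100),
      stringsAsFactors = FALSE
    )),
    rate = miss, seed = seed + 1, columns = c("decoding", "word_id"))
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
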