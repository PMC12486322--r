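# Independent brute-force oracles, written as plain triple loops so they
# share no code path with the package implementation.

brute_com <- function(arr) {
  s <- c(0, 0, 0); n <- 0
  d <- dim(arr)
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3]))
    if (arr[z, y, x]) { s <- s + c(z, y, x); n <- n + 1 }
  s / n
}

brute_projection <- function(arr, collapse) {
  d <- dim(arr)
  keep <- setdiff(1:3, collapse)
  out <- matrix(0L, d[keep[1]], d[keep[2]])
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3]))
    if (arr[z, y, x]) {
      i <- c(z, y, x)[keep[1]]; j <- c(z, y, x)[keep[2]]
      out[i, j] <- out[i, j] + 1L
    }
  out
}

brute_sd_pop <- function(v) {
  m <- sum(v) / length(v)
  sqrt(sum((v - m)^2) / length(v))
}

# spans via the mean + k*SD projection threshold and bounding rectangles
brute_spans <- function(arr, voxel_size, k = 1) {
  span_of <- function(p, sizes) {
    thr <- sum(p) / length(p) + k * brute_sd_pop(as.vector(p))
    rows <- integer(0); cols <- integer(0)
    for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p)))
      if (p[i, j] > thr) { rows <- c(rows, i); cols <- c(cols, j) }
    if (length(rows) == 0) return(c(0, 0))
    c((max(rows) - min(rows) + 1) * sizes[1],
      (max(cols) - min(cols) + 1) * sizes[2])
  }
  dv <- span_of(brute_projection(arr, 1), voxel_size[2:3])  # (RC, ML)
  rc <- span_of(brute_projection(arr, 2), voxel_size[c(1, 3)])  # (DV, ML)
  c(ML = dv[2], RC = dv[1], DV = rc[1])
}

brute_density <- function(arr, voxel_size, collapse) {
  p <- brute_projection(arr, collapse)
  keep <- setdiff(1:3, collapse)
  occupied <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p)))
    if (p[i, j] > 0) occupied <- occupied + 1
  sum(arr) / (occupied * voxel_size[keep[1]] * voxel_size[keep[2]])
}

# two-sided Fisher by full enumeration with log-factorial probabilities
brute_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2]); N <- sum(tab)
  logp <- function(a) {
    b <- r1 - a; cc <- c1 - a; dd <- r2 - cc
    if (b < 0 || cc < 0 || dd < 0) return(-Inf)
    lfactorial(r1) + lfactorial(r2) + lfactorial(c1) + lfactorial(c2) -
      lfactorial(N) - lfactorial(a) - lfactorial(b) - lfactorial(cc) -
      lfactorial(dd)
  }
  p_obs <- exp(logp(tab[1, 1]))
  tot <- 0
  for (a in 0:min(r1, c1)) {
    p <- exp(logp(a))
    if (p <= p_obs * (1 + 1e-7)) tot <- tot + p
  }
  min(1, tot)
}

# random binary mask with given fill probability
random_mask <- function(shape, p = 0.3, voxel_size = c(2, 1, 1),
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  binary_mask(array(runif(prod(shape)) < p, dim = shape), voxel_size)
}

# small cohort parameters used by unit tests (fast geometry)
small_cohort <- function(...) {
  args <- list(n_per_group = 3, shape = c(16L, 60L, 40L),
               semi_axes_um = c(ML = 8, RC = 18, DV = 8),
               focus_shift_um = c(ML = 6, DV = 1))
  args <- utils::modifyList(args, list(...))
  do.call(cohort_params, args)
}
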