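# Independent brute-force oracles and shared fixtures.

# Tie-corrected pairwise concordance: P(pos > neg) + 0.5 P(pos = neg).
brute_auc <- function(pos, neg) {
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Dilation by a closed world-unit ball, voxel centre to voxel centre,
# by direct distance minimization over all set voxels.
brute_dilate <- function(mask, voxel_dims, radius) {
  dm <- dim(mask)
  set <- which(mask, arr.ind = TRUE)
  out <- array(FALSE, dm)
  if (nrow(set) == 0) return(out)
  sw <- sweep(set, 2, voxel_dims, `*`)
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    p <- c(i, j, k) * voxel_dims
    d2 <- (sw[, 1] - p[1])^2 + (sw[, 2] - p[2])^2 + (sw[, 3] - p[3])^2
    if (min(d2) <= radius^2 + 1e-9) out[i, j, k] <- TRUE
  }
  out
}

# Exact two-sided signed-rank p by full enumeration of all 2^n sign vectors,
# applied after the same zero-removal / average-rank preprocessing.
brute_signed_rank_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.numeric(signs %*% r)
  tol <- 1e-9
  min(1, 2 * min(mean(ws <= w + tol), mean(ws >= w - tol)))
}

# Two-pass textbook computation of the four first-order statistics.
brute_stats <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  list(mean = mu, sd = sqrt(sum((x - mu)^2) / (n - 1)),
       skewness = m3 / m2^1.5, kurtosis = m4 / m2^2)
}

# Small fast cohort shared across tests (memoized per session).
small_cohort_config <- function(seed = 42) {
  cohort_config(grid_shape = c(32, 32, 16), voxel_dims = c(2.5, 2.5, 3),
                lesion_radius_range = c(7, 9),
                core_fraction_range = c(0.25, 0.35), seed = seed)
}

.fixture_env <- new.env(parent = emptyenv())
small_cohort <- function() {
  if (is.null(.fixture_env$cohort))
    .fixture_env$cohort <- generate_cohort(small_cohort_config())
  .fixture_env$cohort
}

# A tiny flat patient: uniform grid geometry with known masks, for I/O tests.
toy_volumes <- function(n = 12, seed = 1) {
  set.seed(seed)
  dm <- c(n, n, n)
  t1 <- array(stats::runif(prod(dm), 800, 1800), dm)
  t2 <- array(stats::runif(prod(dm), 60, 250), dm)
  pd <- array(stats::runif(prod(dm), 50, 90), dm)
  wm <- array(FALSE, dm); wm[2:(n - 1), 2:(n - 1), 2:(n - 1)] <- TRUE
  t2h <- array(FALSE, dm); t2h[4:6, 4:6, 4:6] <- TRUE
  t1e <- array(FALSE, dm); t1e[5, 5, 5] <- TRUE
  list(t1 = t1, t2 = t2, pd = pd, wm = wm, t2h = t2h, t1e = t1e,
       affine = diag(c(2, 2, 2.5, 1)))
}

write_toy_patient <- function(vols, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(t1 = file.path(dir, "t1.nii.gz"),
                t2 = file.path(dir, "t2.nii.gz"),
                pd = file.path(dir, "pd.nii.gz"),
                t2h = file.path(dir, "t2h.nii.gz"),
                t1e = file.path(dir, "t1e.nii.gz"),
                wm = file.path(dir, "wm.nii.gz"))
  save_map(vols$t1, vols$affine, paths$t1)
  save_map(vols$t2, vols$affine, paths$t2)
  save_map(vols$pd, vols$affine, paths$pd)
  save_mask(vols$t2h, vols$affine, paths$t2h)
  save_mask(vols$t1e, vols$affine, paths$t1e)
  save_mask(vols$wm, vols$affine, paths$wm)
  paths
}
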