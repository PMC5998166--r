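# Shared fixtures and independent oracles. Everything is generated in code;
# no stored data.

make_cube_mask <- function(n = 10L, spacing = c(1, 1, 1), pad = 0L) {
  d <- n + 2L * pad
  arr <- array(0L, dim = c(d, d, d))
  arr[(pad + 1):(pad + n), (pad + 1):(pad + n), (pad + 1):(pad + n)] <- 1L
  voi_mask(arr, spacing = spacing, node_id = sprintf("cube%d", n))
}

digitize_sphere <- function(r, pad = 2) {
  n <- 2L * ceiling(r + pad) + 1L
  c0 <- (n - 1) / 2
  ax <- (0:(n - 1)) - c0
  g <- expand.grid(x = ax, y = ax, z = ax)
  arr <- array(g$x^2 + g$y^2 + g$z^2 <= r^2, dim = c(n, n, n))
  voi_mask(arr, node_id = sprintf("sphere%g", r))
}

digitize_ellipsoid <- function(a, b, c, pad = 2) {
  n <- 2L * ceiling(max(a, b, c) + pad) + 1L
  c0 <- (n - 1) / 2
  ax <- (0:(n - 1)) - c0
  g <- expand.grid(x = ax, y = ax, z = ax)
  arr <- array((g$x / a)^2 + (g$y / b)^2 + (g$z / c)^2 <= 1, dim = c(n, n, n))
  voi_mask(arr, node_id = "ellipsoid")
}

# dense analytically parametrized circle as a slice_contour
analytic_circle_contour <- function(r, n = 720L, centre = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  structure(list(points = cbind(centre[1] + r * cos(th),
                                centre[2] + r * sin(th)),
                 slice = 0L, centroid = centre),
            class = "slice_contour")
}

# independent exhaustive 6-neighbour boundary scan (triple loop, no shifts)
brute_boundary_count <- function(vox) {
  d <- dim(vox)
  cnt <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!vox[i, j, k]) next
    nb <- c(
      if (i > 1) vox[i - 1, j, k] else FALSE,
      if (i < d[1]) vox[i + 1, j, k] else FALSE,
      if (j > 1) vox[i, j - 1, k] else FALSE,
      if (j < d[2]) vox[i, j + 1, k] else FALSE,
      if (k > 1) vox[i, j, k - 1] else FALSE,
      if (k < d[3]) vox[i, j, k + 1] else FALSE)
    if (any(!nb)) cnt <- cnt + 1L
  }
  cnt
}

# independent exhaustive exposed-face count
brute_face_count <- function(vox) {
  d <- dim(vox)
  cnt <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!vox[i, j, k]) next
    cnt <- cnt +
      (i == 1 || !vox[i - 1, j, k]) + (i == d[1] || !vox[i + 1, j, k]) +
      (j == 1 || !vox[i, j - 1, k]) + (j == d[2] || !vox[i, j + 1, k]) +
      (k == 1 || !vox[i, j, k - 1]) + (k == d[3] || !vox[i, j, k + 1])
  }
  cnt
}

# brute-force AUROC: pairwise comparisons with half credit for ties
brute_auroc <- function(scores, labels, positive = "metastatic") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  s <- 0
  for (p in pos) for (q in neg) {
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  s / (length(pos) * length(neg))
}

# random single-component blob mask for property tests
random_blob_mask <- function(seed, r = 6) {
  set.seed(seed)
  shp <- list(base_radius_mean = r, base_radius_sd = 0,
              axis_ratios = c(1, runif(1, 0.7, 1), runif(1, 0.7, 1)),
              perturbation_amplitude = runif(1, 0, 0.12),
              perturbation_smoothness = 4L)
  generate_mask(shp, seed = seed, min_extent_mm = 0)
}
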