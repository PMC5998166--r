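# Seventeen morphological descriptors of a lymph-node VOI mask.
#
# All features are computed on the 1 mm isotropic grid. Two notions of
# "surface" coexist deliberately: the *surface feature* is the boundary voxel
# count, while the *surface area* entering compactness and irregularity is
# the exposed voxel-face count (x 1 mm^2), because the two are defined
# separately. Radial quantities use the whole-VOI radial profile: distances
# of boundary voxel centres from the barycentre.

#' Radial profile of a boundary set
#'
#' @param boundary A `boundary_set` from [extract_boundary()].
#' @return List of class `radial_profile` with `radii` (mm), `mu` (mean
#'   radius) and `scope = "voi"`.
#' @export
radial_profile <- function(boundary) {
  stopifnot(inherits(boundary, "boundary_set"))
  rel <- sweep(boundary$coordinates, 2, boundary$barycentre)
  radii <- sqrt(rowSums(rel^2))
  if (length(radii) < 4L) stop("radial profile needs at least 4 boundary points")
  structure(list(radii = radii, mu = mean(radii), scope = "voi"),
            class = "radial_profile")
}

#' Volume, surface (boundary-voxel count) and equivalent-sphere diameter
#'
#' Volume = foreground voxel count x 1 mm^3; surface = number of boundary
#' voxels; diameter = diameter of the sphere with the node's volume,
#' 2 (3V / 4 pi)^(1/3).
#'
#' @param mask Isotropic [voi_mask()].
#' @param boundary Optional precomputed [extract_boundary()] result.
#' @return Named list `volume`, `surface`, `diameter`.
#' @export
volume_surface_diameter <- function(mask, boundary = extract_boundary(mask)) {
  v <- boundary$n_foreground * prod(mask$spacing)
  list(volume = v,
       surface = boundary$n_boundary,
       diameter = 2 * (3 * v / (4 * pi))^(1 / 3))
}

#' Sphere-ratio features: circularity, compactness, irregularity
#'
#' Circularity = (volume of the sphere with the node's mean radius) / V;
#' compactness = A / V; irregularity = 1 - (area of the sphere with the
#' node's mean radius) / A, where A is the exposed voxel-face area and the
#' mean radius is the whole-VOI radial-profile mean.
#'
#' @param mask Isotropic [voi_mask()].
#' @param boundary,profile Optional precomputed intermediates.
#' @return Named list `circularity`, `compactness`, `irregularity`.
#' @export
sphere_ratios <- function(mask, boundary = extract_boundary(mask),
                          profile = radial_profile(boundary)) {
  v <- boundary$n_foreground * prod(mask$spacing)
  area <- boundary$exposed_faces * 1  # mm^2 on the 1 mm grid
  mu <- profile$mu
  list(circularity = (4 / 3) * pi * mu^3 / v,
       compactness = area / v,
       irregularity = 1 - 4 * pi * mu^2 / area)
}

#' Radial-profile features
#'
#' radial_length = mu / max(R) (normalized; the raw mm mean is returned as
#' `radial_length_mm`); spiculation = population SD of the radii (mm);
#' sphericity = mu / SD; roughness = (m4^(1/4) - m2^(1/2)) / mu with m_k the
#' k-th central moment; entropy = -sum p log p over an equal-width histogram
#' of the radii spanning [min, max].
#'
#' @param profile A [radial_profile()].
#' @param bins Histogram bin count for entropy (default 128).
#' @return Named list `radial_length`, `radial_length_mm`, `sphericity`,
#'   `spiculation`, `entropy`, `roughness`, plus `flags` (character vector of
#'   degeneracy notes).
#' @export
radial_features <- function(profile, bins = 128L) {
  r <- profile$radii
  n <- length(r)
  mu <- mean(r)
  m2 <- mean((r - mu)^2)
  m4 <- mean((r - mu)^4)
  sdev <- sqrt(m2)
  flags <- character(0)
  if (sdev == 0) {
    sphericity <- Inf
    flags <- c(flags, "zero radial SD: sphericity infinite, excluded from stats")
  } else {
    sphericity <- mu / sdev
  }
  rng <- range(r)
  if (rng[1] == rng[2]) {
    entropy <- 0
  } else {
    cuts <- seq(rng[1], rng[2], length.out = bins + 1L)
    h <- tabulate(pmin(findInterval(r, cuts, rightmost.closed = TRUE), bins),
                  nbins = bins)
    p <- h[h > 0] / n
    entropy <- -sum(p * log(p))
  }
  list(radial_length = mu / max(r),
       radial_length_mm = mu,
       sphericity = sphericity,
       spiculation = sdev,
       entropy = entropy,
       roughness = (m4^(1 / 4) - sqrt(m2)) / mu,
       flags = flags)
}

# Resample a closed polyline to (approximately) unit arc-length spacing and
# return the new points. The curve is treated as periodic.
.resample_closed <- function(pts, spacing = 1) {
  closed <- rbind(pts, pts[1, , drop = FALSE])
  seg <- sqrt(rowSums(diff(closed)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  m <- max(8L, round(total / spacing))
  su <- seq(0, total, length.out = m + 1L)[- (m + 1L)]
  cbind(stats::approx(s, closed[, 1], xout = su)$y,
        stats::approx(s, closed[, 2], xout = su)$y)
}

# Circular moving average smoothing of the rows of a closed polyline.
.smooth_closed <- function(pts, window = 5L) {
  if (window <= 1L) return(pts)
  n <- nrow(pts)
  if (n <= window) return(pts)
  half <- window %/% 2L
  out <- pts
  for (col in 1:2) {
    v <- pts[, col]
    acc <- v
    for (k in seq_len(half)) {
      acc <- acc + v[((seq_len(n) - 1 + k) %% n) + 1] +
        v[((seq_len(n) - 1 - k) %% n) + 1]
    }
    out[, col] <- acc / (2 * half + 1)
  }
  out
}

#' Per-contour curvature
#'
#' Mean over contour points of |x'y'' - y'x''| / (x'^2 + y'^2)^(3/2), with
#' cyclic central-difference derivatives taken after re-parametrizing the
#' contour to unit arc-length spacing and light circular moving-average
#' smoothing (digitized contours are staircases; the unsmoothed second
#' difference measures the staircase, not the shape).
#'
#' @param contour A `slice_contour` (or any closed n x 2 point matrix).
#' @param smooth_window Circular moving-average window (odd; default 5).
#' @param step Central-difference step in samples (default 2; a wider stencil
#'   suppresses residual staircase noise at the cost of O(step^2/r^2) bias).
#' @return Mean absolute curvature (1/mm).
#' @export
contour_curvature <- function(contour, smooth_window = 5L, step = 2L) {
  pts <- if (inherits(contour, "slice_contour")) contour$points else contour
  pts <- .resample_closed(pts, spacing = 1)
  pts <- .smooth_closed(pts, smooth_window)
  n <- nrow(pts)
  h <- min(as.integer(step), max(1L, (n - 1L) %/% 2L))
  ip <- ((seq_len(n) - 1L + h) %% n) + 1L
  im <- ((seq_len(n) - 1L - h) %% n) + 1L
  x1 <- (pts[ip, 1] - pts[im, 1]) / (2 * h)
  y1 <- (pts[ip, 2] - pts[im, 2]) / (2 * h)
  x2 <- (pts[ip, 1] - 2 * pts[, 1] + pts[im, 1]) / h^2
  y2 <- (pts[ip, 2] - 2 * pts[, 2] + pts[im, 2]) / h^2
  denom <- (x1^2 + y1^2)^(3 / 2)
  ok <- denom > 0
  mean(abs(x1[ok] * y2[ok] - y1[ok] * x2[ok]) / denom[ok])
}

#' Per-contour smoothness
#'
#' (1/N) sum_n | R_n - (R_{n-1} + R_{n+1})/2 | over the contour-ordered
#' radial profile (distances of contour points to the slice centroid). The
#' absolute value is used (the literal signed sum telescopes to ~0 on any
#' closed contour), and the contour is first re-parametrized to unit
#' arc-length spacing: on the raw pixel chain the alternating axial/diagonal
#' steps dominate the local deviation and mask real margin irregularity.
#'
#' @param contour A `slice_contour`.
#' @return Mean absolute local radial deviation (mm).
#' @export
contour_smoothness <- function(contour) {
  pts <- .resample_closed(contour$points, spacing = 1)
  cen <- contour$centroid
  r <- sqrt((pts[, 1] - cen[1])^2 + (pts[, 2] - cen[2])^2)
  n <- length(r)
  ip <- c(2:n, 1); im <- c(n, 1:(n - 1))
  mean(abs(r - (r[im] + r[ip]) / 2))
}

#' Contour features aggregated over slices
#'
#' VOI curvature and smoothness = mean of the per-slice values.
#'
#' @param contours List of `slice_contour` objects from [slice_contours()].
#' @param smooth_window Passed to [contour_curvature()].
#' @return Named list `curvature`, `smoothness` (both `NA` with a flag when
#'   no usable contour exists).
#' @export
contour_features <- function(contours, smooth_window = 5L) {
  if (!length(contours)) {
    return(list(curvature = NA_real_, smoothness = NA_real_,
                flags = "no usable slice contour (all below minimum size)"))
  }
  curv <- vapply(contours, contour_curvature, numeric(1),
                 smooth_window = smooth_window)
  smo <- vapply(contours, contour_smoothness, numeric(1))
  list(curvature = mean(curv), smoothness = mean(smo), flags = character(0))
}

# In-slice axis-aligned bounding-rectangle elongation along one axis of the
# 3D array: mean over slices of (longer side)/(shorter side), in voxels.
.elongation_along <- function(vox, axis) {
  d <- dim(vox)
  ratios <- numeric(0)
  for (k in seq_len(d[axis])) {
    sl <- switch(axis,
                 vox[k, , , drop = TRUE],
                 vox[, k, , drop = TRUE],
                 vox[, , k, drop = TRUE])
    if (is.null(dim(sl)) || length(dim(sl)) != 2L) next  # 1-voxel-thick direction
    if (!any(sl)) next
    idx <- which(sl, arr.ind = TRUE)
    ext <- c(diff(range(idx[, 1])) + 1, diff(range(idx[, 2])) + 1)
    ratios <- c(ratios, max(ext) / min(ext))
  }
  ratios
}

#' Bounding-box, eccentricity, elongation and convexity features
#'
#' Rectangularity = V / (axis-aligned bounding-box volume). Eccentricity =
#' longest boundary chord / longest chord perpendicular to it (within a 1
#' degree window, widened if the window is empty on coarse masks; the chord
#' search runs over convex-hull vertices of the boundary voxel centres, where
#' the maxima are attained). Elongation = mean over slices, taken along each
#' of the three axes, of the in-slice bounding-rectangle side ratio.
#' Convexity = convex-hull volume / V, with the hull built on boundary voxel
#' corners so that a digitized convex solid scores exactly 1.
#'
#' @param mask Isotropic [voi_mask()].
#' @param boundary Optional precomputed [extract_boundary()].
#' @return Named list `rectangularity`, `eccentricity`, `elongation`,
#'   `convexity`, plus `eccentricity_window_deg` (the perpendicular window
#'   actually used).
#' @export
bbox_features <- function(mask, boundary = extract_boundary(mask)) {
  vox <- mask$voxels
  fg <- which(vox, arr.ind = TRUE)
  ext <- apply(fg, 2, function(x) diff(range(x)) + 1)
  v <- boundary$n_foreground * prod(mask$spacing)
  rectangularity <- v / prod(ext * mask$spacing)

  elong <- unlist(lapply(1:3, function(ax) .elongation_along(vox, ax)))
  elongation <- if (length(elong)) mean(elong) else NA_real_

  # hull on boundary voxel centres: chords
  bc <- boundary$coordinates
  ecc <- NA_real_; window_used <- NA_real_
  if (nrow(unique(bc)) >= 4L) {
    hv <- tryCatch(bc[convex_hull3(bc)$vertices, , drop = FALSE],
                   error = function(e) bc)
    dmat <- as.matrix(stats::dist(hv))
    far <- which(dmat == max(dmat), arr.ind = TRUE)[1, ]
    main_dir <- hv[far[2], ] - hv[far[1], ]
    main_dir <- main_dir / sqrt(sum(main_dir^2))
    # all hull-vertex chords and their angle to the main chord
    idx <- which(upper.tri(dmat), arr.ind = TRUE)
    vecs <- hv[idx[, 2], , drop = FALSE] - hv[idx[, 1], , drop = FALSE]
    lens <- sqrt(rowSums(vecs^2))
    cosang <- abs(as.numeric(vecs %*% main_dir)) / pmax(lens, 1e-12)
    window <- 1
    repeat {
      perp <- lens[cosang <= sin(window * pi / 180)]
      if (length(perp) || window > 90) break
      window <- window * 2
    }
    if (length(perp)) {
      ecc <- max(dmat) / max(perp)
      window_used <- window
    }
  }

  # hull on boundary voxel corners for convexity
  corners <- .voxel_corners(bc, mask$spacing)
  convexity <- tryCatch(convex_hull3(corners)$volume / v,
                        error = function(e) NA_real_)
  list(rectangularity = rectangularity, eccentricity = ecc,
       elongation = elongation, convexity = convexity,
       eccentricity_window_deg = window_used)
}

# The 8 corners of each voxel (centres given), deduplicated.
.voxel_corners <- function(centres, spacing = c(1, 1, 1)) {
  offs <- as.matrix(expand.grid(c(-0.5, 0.5), c(-0.5, 0.5), c(-0.5, 0.5)))
  offs <- sweep(offs, 2, spacing, `*`)
  out <- do.call(rbind, lapply(seq_len(nrow(offs)), function(i) {
    sweep(centres, 2, offs[i, ], `+`)
  }))
  unique(out)
}

#' All seventeen morphological features of one mask
#'
#' Resamples to 1 mm isotropic voxels if needed, then composes
#' [volume_surface_diameter()], [sphere_ratios()], [radial_features()],
#' [contour_features()] and [bbox_features()].
#'
#' @param mask A [voi_mask()] (any spacing).
#' @param bins Entropy histogram bins (default 128).
#' @param smooth_window Contour smoothing window for curvature (default 5).
#' @return One-row data.frame with `node_id`, `reader_id`, the 17 canonical
#'   feature columns (`circularity`, `compactness`, `convexity`, `curvature`,
#'   `elongation`, `diameter`, `eccentricity`, `irregularity`,
#'   `radial_length`, `entropy`, `rectangularity`, `roughness`, `smoothness`,
#'   `sphericity`, `spiculation`, `surface`, `volume`) and the auxiliary
#'   `radial_length_mm`; degeneracy notes in `attr(, "flags")`.
#' @export
all_morph_features <- function(mask, bins = 128L, smooth_window = 5L) {
  stopifnot(inherits(mask, "voi_mask"))
  if (!all(mask$spacing == 1)) mask <- resample_isotropic(mask)
  boundary <- extract_boundary(mask)
  profile <- radial_profile(boundary)
  vsd <- volume_surface_diameter(mask, boundary)
  sph <- sphere_ratios(mask, boundary, profile)
  rad <- radial_features(profile, bins = bins)
  con <- contour_features(slice_contours(mask), smooth_window = smooth_window)
  box <- bbox_features(mask, boundary)
  out <- data.frame(
    node_id = mask$node_id, reader_id = mask$reader_id,
    circularity = sph$circularity, compactness = sph$compactness,
    convexity = box$convexity, curvature = con$curvature,
    elongation = box$elongation, diameter = vsd$diameter,
    eccentricity = box$eccentricity, irregularity = sph$irregularity,
    radial_length = rad$radial_length, entropy = rad$entropy,
    rectangularity = box$rectangularity, roughness = rad$roughness,
    smoothness = con$smoothness, sphericity = rad$sphericity,
    spiculation = rad$spiculation, surface = vsd$surface,
    volume = vsd$volume, radial_length_mm = rad$radial_length_mm,
    stringsAsFactors = FALSE)
  attr(out, "flags") <- c(rad$flags, con$flags)
  out
}

#' Morphological features for a list of masks
#'
#' @param masks List of [voi_mask()] objects.
#' @param ... Passed to [all_morph_features()].
#' @return data.frame, one row per mask, sorted by (node_id, reader_id).
#' @export
batch_morph <- function(masks, ...) {
  rows <- lapply(masks, all_morph_features, ...)
  out <- do.call(rbind, rows)
  out[order(out$node_id, out$reader_id), , drop = FALSE]
}

#' Canonical morphological feature names
#' @return Character vector of the 17 feature column names.
#' @export
morph_feature_names <- function() {
  c("circularity", "compactness", "convexity", "curvature", "elongation",
    "diameter", "eccentricity", "irregularity", "radial_length", "entropy",
    "rectangularity", "roughness", "smoothness", "sphericity", "spiculation",
    "surface", "volume")
}
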