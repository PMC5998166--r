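# Data model and shared geometry for lymph-node volumes of interest.
#
# Conventions (fixed across the package):
#   * voxel-centre coordinates, 0-based indices, mm world units;
#     voxel (i,j,k) (0-based) has its centre at (i*dx, j*dy, k*dz) + origin
#   * 6-connectivity for 3D components and boundary, 8-connectivity for
#     in-slice contour tracing
#   * masks are resampled to 1 mm isotropic voxels before feature extraction

#' Construct a VOI mask
#'
#' @param voxels 3D array (logical or 0/1) with at least one foreground voxel.
#' @param spacing Voxel spacing in mm per axis, strictly positive, length 3.
#' @param origin World-mm offset of voxel (0,0,0); default zero.
#' @param node_id,reader_id Identifiers carried through the pipeline.
#' @return An object of class `voi_mask`.
#' @export
voi_mask <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     node_id = "node", reader_id = "reader1") {
  if (is.null(dim(voxels)) || length(dim(voxels)) != 3L) {
    stop("'voxels' must be a 3D array")
  }
  vox <- array(as.logical(voxels != 0), dim = dim(voxels))
  if (!any(vox)) stop("empty mask: no foreground voxels")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("'spacing' must be three strictly positive numbers")
  }
  structure(
    list(voxels = vox, spacing = spacing, origin = as.numeric(origin),
         node_id = as.character(node_id), reader_id = as.character(reader_id)),
    class = "voi_mask")
}

#' @export
print.voi_mask <- function(x, ...) {
  cat(sprintf("voi_mask '%s' (%s): %d x %d x %d grid, %g x %g x %g mm, %d foreground voxels\n",
              x$node_id, x$reader_id, dim(x$voxels)[1], dim(x$voxels)[2],
              dim(x$voxels)[3], x$spacing[1], x$spacing[2], x$spacing[3],
              sum(x$voxels)))
  invisible(x)
}

#' Read a VOI mask from NIfTI
#'
#' Binarizes at `value > 0` and records the header spacing.
#'
#' @param path NIfTI file path.
#' @param node_id,reader_id Identifiers.
#' @return A [voi_mask()].
#' @export
read_mask <- function(path, node_id = sub("\\.nii(\\.gz)?$", "", basename(path)),
                      reader_id = "reader1") {
  img <- read_nifti(path)
  if (length(img$dim) != 3L) stop("mask must be a 3D volume: ", path)
  if (!any(img$data > 0)) stop("empty mask (no voxel > 0): ", path)
  voi_mask(img$data > 0, spacing = img$spacing,
           node_id = node_id, reader_id = reader_id)
}

#' Write a VOI mask to NIfTI
#'
#' @param mask A [voi_mask()].
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "voi_mask"))
  write_nifti(mask$voxels * 1L, path, spacing = mask$spacing)
}

# Shifted copies of a 3D logical array along one axis; outside-volume counts
# as FALSE (background), which makes array faces background for boundaries.
.shift3 <- function(a, axis, by) {
  d <- dim(a)
  out <- array(FALSE, dim = d)
  idx_src <- lapply(d, seq_len)
  idx_dst <- idx_src
  n <- d[axis]
  if (abs(by) >= n) return(out)
  if (by > 0) {
    idx_dst[[axis]] <- (1 + by):n
    idx_src[[axis]] <- 1:(n - by)
  } else if (by < 0) {
    idx_dst[[axis]] <- 1:(n + by)
    idx_src[[axis]] <- (1 - by):n
  }
  do.call(`[<-`, c(list(out), idx_dst, list(do.call(`[`, c(list(a), idx_src)))))
}

# Number of background 6-neighbours per voxel (array border = background).
.background_neighbour_count <- function(vox) {
  d <- dim(vox)
  cnt <- array(0L, dim = d)
  for (axis in 1:3) for (by in c(-1L, 1L)) {
    cnt <- cnt + !.shift3(vox, axis, by)
  }
  cnt
}

# Label 6-connected foreground components by vectorized frontier expansion.
# Returns integer array, 0 = background.
.label_components6 <- function(vox) {
  d <- dim(vox)
  labels <- array(0L, dim = d)
  remaining <- which(vox)
  lab <- 0L
  nxyz <- d
  while (length(remaining) > 0) {
    lab <- lab + 1L
    frontier <- remaining[1]
    labels[frontier] <- lab
    while (length(frontier) > 0) {
      # linear index -> (i,j,k), 1-based
      i0 <- frontier - 1L
      i <- i0 %% nxyz[1]
      j <- (i0 %/% nxyz[1]) %% nxyz[2]
      k <- i0 %/% (nxyz[1] * nxyz[2])
      cand <- c(
        frontier[i > 0] - 1L, frontier[i < nxyz[1] - 1L] + 1L,
        frontier[j > 0] - nxyz[1], frontier[j < nxyz[2] - 1L] + nxyz[1],
        frontier[k > 0] - nxyz[1] * nxyz[2],
        frontier[k < nxyz[3] - 1L] + nxyz[1] * nxyz[2])
      cand <- unique(cand)
      cand <- cand[vox[cand] & labels[cand] == 0L]
      labels[cand] <- lab
      frontier <- cand
    }
    remaining <- remaining[labels[remaining] == 0L]
  }
  labels
}

# Keep only the largest 6-connected component (ties: lowest label, i.e. the
# component containing the first foreground voxel in array order).
.largest_component6 <- function(vox) {
  labels <- .label_components6(vox)
  if (max(labels) <= 1L) return(vox)
  sizes <- tabulate(labels[labels > 0L])
  keep <- which.max(sizes)
  array(labels == keep, dim = dim(vox))
}

#' Resample a VOI mask to 1 mm isotropic voxels
#'
#' Nearest-neighbour interpolation on the binary mask (deterministic), then
#' retention of the largest 6-connected foreground component.
#'
#' @param mask A [voi_mask()].
#' @return A [voi_mask()] with spacing `c(1,1,1)`.
#' @export
resample_isotropic <- function(mask) {
  stopifnot(inherits(mask, "voi_mask"))
  d <- dim(mask$voxels)
  sp <- mask$spacing
  if (all(sp == 1)) {
    out <- mask
    out$voxels <- .largest_component6(mask$voxels)
    if (!any(out$voxels)) stop("resampling annihilated all foreground")
    return(out)
  }
  nd <- pmax(1L, as.integer(round(d * sp)))
  # output voxel j (0-based) centre at j mm; nearest input voxel index
  map <- lapply(1:3, function(ax) {
    # floor(x + 0.5), not round(): banker's rounding would sample input
    # voxels unevenly on exact half-grid positions
    idx <- floor((seq_len(nd[ax]) - 1) / sp[ax] + 0.5) + 1
    pmin(pmax(as.integer(idx), 1L), d[ax])
  })
  vox <- mask$voxels[map[[1]], map[[2]], map[[3]], drop = FALSE]
  vox <- array(vox, dim = nd)
  if (!any(vox)) stop("resampling annihilated all foreground")
  vox <- .largest_component6(vox)
  out <- mask
  out$voxels <- vox
  out$spacing <- c(1, 1, 1)
  out
}

#' Extract the boundary voxel set and barycentre
#'
#' Boundary voxels are foreground voxels with at least one background
#' 6-neighbour (voxels beyond the array border count as background). The
#' barycentre is the mean of all foreground voxel centres.
#'
#' @param mask An isotropic [voi_mask()].
#' @return A list of class `boundary_set` with `coordinates` (n x 3 matrix of
#'   voxel centres in mm), `barycentre`, `n_boundary`, `n_foreground` and
#'   `exposed_faces` (count of foreground faces adjacent to background, the
#'   voxelized surface area in mm^2 at 1 mm spacing).
#' @export
extract_boundary <- function(mask) {
  stopifnot(inherits(mask, "voi_mask"))
  vox <- mask$voxels
  sp <- mask$spacing
  bg_cnt <- .background_neighbour_count(vox)
  on_boundary <- vox & bg_cnt > 0L
  idx <- which(on_boundary, arr.ind = TRUE) - 1L
  coords <- sweep(idx, 2, sp, `*`)
  coords <- sweep(coords, 2, mask$origin, `+`)
  fg <- which(vox, arr.ind = TRUE) - 1L
  bary <- colMeans(sweep(fg, 2, sp, `*`)) + mask$origin
  structure(list(
    coordinates = unname(coords),
    barycentre = unname(bary),
    n_boundary = nrow(coords),
    n_foreground = nrow(fg),
    exposed_faces = sum(bg_cnt[vox])
  ), class = "boundary_set")
}

# Moore (8-connected) boundary tracing of a 2D logical matrix. Returns the
# ordered closed sequence of boundary pixel (row, col) 1-based indices, or
# NULL when the component is empty. Jacob's stopping criterion.
.moore_trace <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  inside <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc && m[r, c]
  fg <- which(m, arr.ind = TRUE)
  if (nrow(fg) == 0) return(NULL)
  # raster-order start: smallest column, then smallest row
  ord <- order(fg[, 2], fg[, 1])
  start <- fg[ord[1], ]
  # Moore neighbourhood, clockwise starting from west
  moves <- rbind(c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1),
                 c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  cur <- start
  backtrack_dir <- 1L  # came from the west (guaranteed background)
  path <- matrix(start, ncol = 2)
  first_next <- NULL
  repeat {
    found <- FALSE
    for (s in 0:7) {
      dir <- ((backtrack_dir - 1L + s) %% 8L) + 1L
      r <- cur[1] + moves[dir, 1]; c <- cur[2] + moves[dir, 2]
      if (inside(r, c)) {
        prev_dir <- ((dir - 2L) %% 8L) + 1L
        nxt <- c(r, c)
        if (nrow(path) == 1) first_next <- nxt
        # stop when we re-enter the start pixel heading to the same second pixel
        if (all(cur == start) && nrow(path) > 2 &&
            !is.null(first_next) && all(nxt == first_next)) {
          return(path)
        }
        path <- rbind(path, nxt)
        # new backtrack: the neighbour we examined just before finding nxt,
        # expressed from nxt's frame
        back_r <- cur[1] + moves[prev_dir, 1]
        back_c <- cur[2] + moves[prev_dir, 2]
        dr <- back_r - r; dc <- back_c - c
        backtrack_dir <- which(moves[, 1] == dr & moves[, 2] == dc)
        cur <- nxt
        found <- TRUE
        break
      }
    }
    if (!found) return(path)       # isolated pixel
    if (nrow(path) > 4L * (nr * nc)) return(path)  # safety net
  }
}

# Largest 4/8-connected component of a 2D logical matrix (8-connectivity).
.largest_component2d8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  labels <- matrix(0L, nr, nc)
  remaining <- which(m)
  lab <- 0L
  while (length(remaining) > 0) {
    lab <- lab + 1L
    frontier <- remaining[1]
    labels[frontier] <- lab
    while (length(frontier) > 0) {
      i0 <- frontier - 1L
      r <- i0 %% nr; c <- i0 %/% nr
      cand <- integer(0)
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        ok <- (r + dr) >= 0 & (r + dr) < nr & (c + dc) >= 0 & (c + dc) < nc
        cand <- c(cand, frontier[ok] + dr + dc * nr)
      }
      cand <- unique(cand)
      cand <- cand[m[cand] & labels[cand] == 0L]
      labels[cand] <- lab
      frontier <- cand
    }
    remaining <- remaining[labels[remaining] == 0L]
  }
  if (lab <= 1L) return(m)
  sizes <- tabulate(labels[labels > 0L])
  labels == which.max(sizes)
}

#' Trace closed contours on every axial slice
#'
#' Per axial (z) slice with foreground, traces an ordered closed boundary
#' polyline (Moore tracing, 8-connectivity) around the largest in-slice
#' component, oriented counter-clockwise. Slices whose contour has fewer than
#' `min_points` points are dropped.
#'
#' @param mask An isotropic [voi_mask()].
#' @param min_points Minimum contour length to keep a slice (default 8).
#' @return List of `slice_contour` objects, each with `points` (n x 2 matrix,
#'   (x, y) mm, closed but without the first point repeated), `slice`
#'   (0-based z index) and `centroid` ((x, y) mm centroid of the traced
#'   component's pixels).
#' @export
slice_contours <- function(mask, min_points = 8L) {
  stopifnot(inherits(mask, "voi_mask"))
  vox <- mask$voxels
  sp <- mask$spacing
  out <- list()
  for (k in seq_len(dim(vox)[3])) {
    sl <- vox[, , k]
    if (!any(sl)) next
    comp <- .largest_component2d8(sl)
    path <- .moore_trace(comp)
    if (is.null(path) || nrow(path) < 2L) next
    # drop consecutive duplicates and a trailing repeat of the start
    keep <- c(TRUE, rowSums(abs(diff(path))) > 0)
    path <- path[keep, , drop = FALSE]
    if (nrow(path) > 1 && all(path[1, ] == path[nrow(path), ])) {
      path <- path[-nrow(path), , drop = FALSE]
    }
    if (nrow(path) < min_points) next
    # (row=i -> x, col=j -> y), 0-based, mm
    pts <- cbind((path[, 1] - 1) * sp[1], (path[, 2] - 1) * sp[2])
    # enforce counter-clockwise orientation (positive shoelace area)
    n <- nrow(pts)
    nxt <- c(2:n, 1)
    area2 <- sum(pts[, 1] * pts[nxt, 2] - pts[nxt, 1] * pts[, 2])
    if (area2 < 0) pts <- pts[n:1, , drop = FALSE]
    cpix <- which(comp, arr.ind = TRUE) - 1L
    centroid <- c(mean(cpix[, 1]) * sp[1], mean(cpix[, 2]) * sp[2])
    out[[length(out) + 1L]] <- structure(
      list(points = unname(pts), slice = k - 1L, centroid = centroid),
      class = "slice_contour")
  }
  out
}

#' Construct a time-intensity curve
#'
#' @param times Acquisition times in seconds, strictly increasing, first
#'   sample precontrast.
#' @param signals Mean VOI signal per acquisition.
#' @param baseline_index Index (1-based) of the precontrast sample; default 1.
#' @return An object of class `ti_curve`.
#' @export
ti_curve <- function(times, signals, baseline_index = 1L) {
  times <- as.numeric(times); signals <- as.numeric(signals)
  if (length(times) != length(signals)) stop("times and signals differ in length")
  if (length(times) < 3L) stop("need at least 3 samples")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (baseline_index != 1L) stop("baseline must be the first sample")
  structure(list(times = times, signals = signals,
                 baseline_index = as.integer(baseline_index)),
            class = "ti_curve")
}

#' Average a 4D dynamic series over a mask
#'
#' @param series 4D array (x, y, z, t) aligned with the mask grid, or a path
#'   to a 4D NIfTI.
#' @param mask A [voi_mask()] on the same grid.
#' @param times Acquisition times (seconds); default a 90 s grid starting at 0.
#' @return A [ti_curve()] with `signal[i]` = mean of acquisition i over the
#'   foreground voxels.
#' @export
mean_curve <- function(series, mask, times = NULL) {
  stopifnot(inherits(mask, "voi_mask"))
  if (is.character(series)) {
    img <- read_nifti(series)
    if (length(img$dim) != 4L) stop("dynamic series must be 4D: ", series)
    series <- img$data
  }
  d <- dim(series)
  if (length(d) != 4L || !all(d[1:3] == dim(mask$voxels))) {
    stop("dynamic series grid does not match the mask grid")
  }
  if (d[4] < 3L) stop("need at least 3 time points")
  fg <- which(mask$voxels)
  nvox <- prod(d[1:3])
  sig <- vapply(seq_len(d[4]), function(t) {
    mean(series[fg + (t - 1L) * nvox])
  }, numeric(1))
  if (is.null(times)) times <- (seq_len(d[4]) - 1) * 90
  ti_curve(times, sig)
}

#' Read per-node curves from CSV
#'
#' Expects columns `node_id,time_s,signal`.
#'
#' @param path CSV path.
#' @return Named list of [ti_curve()] objects, one per node, ordered by time.
#' @export
read_curves_csv <- function(path) {
  if (!file.exists(path)) stop("curves CSV not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("node_id", "time_s", "signal")
  if (!all(need %in% names(df))) {
    stop("curves CSV must have columns: ", paste(need, collapse = ", "))
  }
  out <- lapply(split(df, df$node_id), function(g) {
    g <- g[order(g$time_s), ]
    ti_curve(g$time_s, g$signal)
  })
  out[order(names(out))]
}

#' Write per-node curves to CSV
#'
#' @param curves Named list of [ti_curve()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_curves_csv <- function(curves, path) {
  rows <- do.call(rbind, lapply(names(curves), function(id) {
    cv <- curves[[id]]
    data.frame(node_id = id, time_s = cv$times, signal = cv$signals)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read node labels from CSV
#'
#' Expects columns `node_id,label` (plus optional `reader_id`); labels must be
#' `metastatic` / `nonmetastatic`.
#'
#' @param path CSV path.
#' @return A data.frame.
#' @export
read_labels_csv <- function(path) {
  if (!file.exists(path)) stop("labels CSV not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("node_id", "label") %in% names(df))) {
    stop("labels CSV must have columns node_id, label")
  }
  bad <- setdiff(unique(df$label), c("metastatic", "nonmetastatic"))
  if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "))
  df
}
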