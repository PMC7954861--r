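# 3D nucleus detection in voxel stacks: Gaussian smoothing, rolling-ball
# background elimination (grey opening), global thresholding, connected
# components, seeded region growing, and quality/size filters.

#' Detection configuration
#'
#' Parameters mirror the surface-detection pipeline of the reference
#' instrument: smoothing controlled by a grain size (length scale; the
#' Gaussian sigma is `grain_size / 2`), background elimination by grey
#' opening with a ball of the given diameter, a manual global threshold,
#' region growing to an estimated nucleus diameter, and minimum quality /
#' voxel-count filters. The instrument's printed filter values
#' (quality 5,000-15,000; 10,000 voxels) are instrument-scale; see
#' [imaris_reference_params()]. Defaults here are permissive so that the
#' rule, not the scale, is what the configuration fixes.
#'
#' @param grain_size smoothing grain size, um.
#' @param background_diameter diameter of the background-elimination ball,
#'   um.
#' @param threshold manual global threshold (intensity a.u.).
#' @param growing_diameter estimated nucleus diameter for region growing,
#'   um.
#' @param min_quality minimum quality (integrated background-corrected
#'   intensity) per object.
#' @param min_voxels minimum voxel count per object.
#' @return an object of class `detection_config`.
#' @export
detection_config <- function(grain_size = 1.5, background_diameter = 6.23,
                             threshold = 20, growing_diameter = 8.30,
                             min_quality = 0, min_voxels = 1L) {
  structure(list(grain_size = grain_size,
                 background_diameter = background_diameter,
                 threshold = threshold, growing_diameter = growing_diameter,
                 min_quality = min_quality,
                 min_voxels = as.integer(min_voxels)),
            class = "detection_config")
}

#' Reference instrument parameters
#'
#' The surface-detection and tracking parameter set of the reference
#' pipeline, as printed: grain size 1.5, background sphere diameter 6.23,
#' manual threshold 20, region-growing diameter 8.30, quality above
#' 5,000-15,000, voxel count above 10,000, autoregressive motion tracking
#' with max distance 9-15 um, max gap 3 and track duration above 3,600 s.
#' The quality and voxel-count values are instrument-scale and must be
#' re-calibrated for other data.
#'
#' @return a named list.
#' @export
imaris_reference_params <- function() {
  list(surface_grain_size = 1.5, diameter_of_largest_sphere = 6.23,
       manual_threshold_value = 20, region_growing_estimated_diameter = 8.30,
       quality_above = c(5000, 15000), number_of_voxels_above = 10000,
       algorithm_name = "Autoregressive Motion", max_distance_um = c(9, 15),
       max_gap_size = 3, track_duration_above_s = 3600)
}

# --- image primitives (3D arrays indexed [x, y, z]) -------------------------

# 1D Gaussian kernel with sigma in voxels
gauss_kernel <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# convolve along array axis `axis` with kernel k (replicate-pad boundaries)
conv_axis <- function(a, k, axis) {
  if (length(k) == 1) return(a)
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  n <- dim(ap)[1]
  m <- matrix(ap, nrow = n)
  r <- (length(k) - 1) / 2
  pad <- rbind(m[rep(1, r), , drop = FALSE], m,
               m[rep(n, r), , drop = FALSE])
  K <- matrix(0, n, n + 2 * r)
  for (i in seq_len(n)) K[i, i:(i + 2 * r)] <- k
  out <- K %*% pad
  aperm(array(out, dim = dim(ap)), order(perm))
}

#' 3D Gaussian smoothing
#'
#' @param a 3D array `[x, y, z]`.
#' @param sigma_um Gaussian sigma in um (scalar).
#' @param voxel_size numeric length-3, um per voxel.
#' @return smoothed array.
#' @export
gaussian_blur3d <- function(a, sigma_um, voxel_size = c(1, 1, 1)) {
  for (axis in 1:3) {
    a <- conv_axis(a, gauss_kernel(sigma_um / voxel_size[axis]), axis)
  }
  a
}

# integer offsets of a ball of radius r_um under anisotropic voxel sizes
ball_offsets <- function(r_um, voxel_size) {
  rv <- pmax(0L, floor(r_um / voxel_size))
  g <- expand.grid(dx = -rv[1]:rv[1], dy = -rv[2]:rv[2], dz = -rv[3]:rv[3])
  keep <- (g$dx * voxel_size[1])^2 + (g$dy * voxel_size[2])^2 +
    (g$dz * voxel_size[3])^2 <= r_um^2
  as.matrix(g[keep, ])
}

# shift array by integer offset, padding with `fill`
shift_array <- function(a, off, fill) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- vector("list", 3)
  for (k in 1:3) {
    o <- off[k]
    if (abs(o) >= d[k]) return(out)
    if (o >= 0) { src[[k]] <- 1:(d[k] - o); dst[[k]] <- (1 + o):d[k] }
    else { src[[k]] <- (1 - o):d[k]; dst[[k]] <- 1:(d[k] + o) }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

morph_extreme <- function(a, offsets, fun, fill) {
  out <- NULL
  for (i in seq_len(nrow(offsets))) {
    s <- shift_array(a, offsets[i, ], fill)
    out <- if (is.null(out)) s else fun(out, s)
  }
  out
}

#' Rolling-ball background via grey opening
#'
#' Grey erosion followed by grey dilation with a ball structuring element;
#' the result estimates the smooth background to subtract before
#' thresholding.
#'
#' @param a 3D array `[x, y, z]`.
#' @param diameter_um ball diameter, um.
#' @param voxel_size um per voxel, length 3.
#' @return background array of the same dimensions.
#' @export
grey_opening_background <- function(a, diameter_um, voxel_size = c(1, 1, 1)) {
  off <- ball_offsets(diameter_um / 2, voxel_size)
  er <- morph_extreme(a, off, pmin, fill = Inf)
  morph_extreme(er, off, pmax, fill = -Inf)
}

# connected components (6-connectivity) of a logical 3D mask; returns an
# integer array of labels (0 = background), labels ordered by first voxel
label_components <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  lab <- array(0L, d)
  if (length(idx) == 0) return(lab)
  pos <- arrayInd(idx, d)
  key <- array(0L, d)
  key[idx] <- seq_along(idx)
  parent <- uf_new(length(idx))
  for (axis in 1:3) {
    prev <- pos
    prev[, axis] <- prev[, axis] - 1L
    ok <- prev[, axis] >= 1L
    pi <- key[prev[ok, , drop = FALSE]]
    me <- which(ok)[pi > 0]
    pi <- pi[pi > 0]
    for (k in seq_along(me)) parent <- uf_union(parent, me[k], pi[k])
  }
  roots <- vapply(seq_along(idx), function(i) uf_find(parent, i), 1L)
  lab[idx] <- as.integer(factor(roots, levels = unique(roots)))
  lab
}

# split components into objects: seeds are component-local intensity maxima
# separated by at least the growing diameter (strongest kept); voxels join
# the nearest seed (um metric)
region_grow <- function(lab, intens, growing_diameter, voxel_size) {
  d <- dim(lab)
  out <- array(0L, d)
  next_label <- 0L
  for (comp in seq_len(max(lab))) {
    vox <- which(lab == comp)
    pos <- arrayInd(vox, d)
    pum <- sweep(pos - 0.5, 2, voxel_size, "*")
    iv <- intens[vox]
    # seeds: local maxima (no brighter component voxel within half the
    # growing diameter), then suppression keeps the strongest of any pair
    # closer than the growing diameter
    D <- cross_dist(pum, pum)
    is_max <- vapply(seq_along(vox), function(k) {
      iv[k] >= max(iv[D[k, ] <= growing_diameter / 2])
    }, TRUE)
    cand <- which(is_max)[order(-iv[is_max])]
    seeds <- integer()
    for (k in cand) {
      if (length(seeds) == 0 ||
          all(D[k, seeds] > growing_diameter)) {
        seeds <- c(seeds, k)
      }
    }
    if (length(seeds) == 1) {
      next_label <- next_label + 1L
      out[vox] <- next_label
    } else {
      sd2 <- cross_dist(pum, pum[seeds, , drop = FALSE])
      assign_seed <- max.col(-sd2, ties.method = "first")
      out[vox] <- next_label + assign_seed
      next_label <- next_label + length(seeds)
    }
  }
  out
}

# --- main detection entry ---------------------------------------------------

#' Detect nuclei in one 3D voxel stack
#'
#' Pipeline: Gaussian smoothing (sigma = grain_size / 2) -> background
#' subtraction by grey opening with a ball of the configured diameter ->
#' global threshold -> connected components -> seeded region growing to the
#' estimated diameter -> quality and voxel-count filters. Centroids are
#' intensity-weighted and reported in um; quality is the integrated
#' background-corrected intensity of the object.
#'
#' @param stack 3D numeric array `[x, y, z]`, or a voxel-render channel from
#'   [render_voxels()].
#' @param params a [detection_config()].
#' @param voxel_size um per voxel (length 3); taken from the stack's
#'   `voxel_size` attribute if present.
#' @param origin um position of the grid corner; from the stack attribute or
#'   zero.
#' @param extra_channels optional named list of same-shaped arrays whose
#'   mean intensity within each object mask is reported.
#' @return data frame of detections: `x_um, y_um, z_um`, `voxel_count`,
#'   `quality`, mean intensity per channel, ellipsoid semi-axes
#'   `(a_um >= b_um >= c_um)`, `eccentricity`, `area_um2`. Zero rows when
#'   the image is empty.
#' @export
detect_nuclei <- function(stack, params = detection_config(),
                          voxel_size = NULL, origin = NULL,
                          extra_channels = NULL) {
  voxel_size <- voxel_size %||% attr(stack, "voxel_size")
  if (is.null(voxel_size)) {
    stop("voxel sizes must be supplied (anisotropy matters)")
  }
  if (length(voxel_size) != 3 || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0)) {
    stop("voxel_size must be 3 positive values (um)")
  }
  origin <- origin %||% attr(stack, "origin") %||% c(0, 0, 0)
  stopifnot(inherits(params, "detection_config"))

  sm <- gaussian_blur3d(stack, params$grain_size / 2, voxel_size)
  bg <- grey_opening_background(sm, params$background_diameter, voxel_size)
  corr <- sm - bg
  mask <- sm >= params$threshold
  if (!any(mask)) return(empty_detections())
  lab <- label_components(mask)
  obj <- region_grow(lab, sm, params$growing_diameter, voxel_size)

  d <- dim(stack)
  rows <- lapply(seq_len(max(obj)), function(o) {
    vox <- which(obj == o)
    if (length(vox) < params$min_voxels) return(NULL)
    q <- sum(corr[vox])
    if (q < params$min_quality) return(NULL)
    pos <- arrayInd(vox, d)
    pum <- sweep(sweep(pos - 0.5, 2, voxel_size, "*"), 2, origin, "+")
    w <- stack[vox]
    mor <- morphology_features(pum, w, voxel_size, pos)
    ch <- if (!is.null(extra_channels)) {
      vapply(extra_channels, function(a) mean(a[vox]), 1)
    } else NULL
    out <- data.frame(x_um = sum(pum[, 1] * w) / sum(w),
                      y_um = sum(pum[, 2] * w) / sum(w),
                      z_um = sum(pum[, 3] * w) / sum(w),
                      voxel_count = length(vox), quality = q,
                      a_um = mor$semi_axes[1], b_um = mor$semi_axes[2],
                      c_um = mor$semi_axes[3],
                      eccentricity = mor$eccentricity,
                      area_um2 = mor$area_um2)
    for (nm in names(ch)) out[[paste0("mean_", nm)]] <- ch[[nm]]
    out
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) return(empty_detections())
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

empty_detections <- function() {
  data.frame(x_um = numeric(), y_um = numeric(), z_um = numeric(),
             voxel_count = integer(), quality = numeric(),
             a_um = numeric(), b_um = numeric(), c_um = numeric(),
             eccentricity = numeric(), area_um2 = numeric())
}

#' Morphology features of one object mask
#'
#' Ellipsoid semi-axes from intensity-weighted second moments (scaled so a
#' uniform solid ellipsoid reproduces its own semi-axes), eccentricity of
#' the two largest semi-axes `sqrt(1 - (b/a)^2)`, and the area of the
#' object's XY projection footprint.
#'
#' @param positions_um n x 3 matrix of voxel centre positions, um.
#' @param weights voxel intensities.
#' @param voxel_size um per voxel, length 3.
#' @param positions_vox optional n x 3 integer voxel indices (for the exact
#'   projection-footprint count; derived from positions if omitted).
#' @return list with `semi_axes` (descending, um), `eccentricity`,
#'   `area_um2`.
#' @export
morphology_features <- function(positions_um, weights,
                                voxel_size = c(1, 1, 1),
                                positions_vox = NULL) {
  if (nrow(positions_um) == 0) stop("empty mask")
  w <- weights / sum(weights)
  mu <- colSums(positions_um * w)
  X <- sweep(positions_um, 2, mu)
  if (nrow(positions_um) == 1) {
    return(list(semi_axes = sort(voxel_size / 2, decreasing = TRUE),
                eccentricity = 0,
                area_um2 = voxel_size[1] * voxel_size[2]))
  }
  S <- crossprod(X * sqrt(w))  # weighted covariance
  # subtract the within-voxel variance (uniform over a voxel) so digitised
  # shapes are not inflated by half-voxel smearing
  S <- S - diag(voxel_size^2 / 12)
  ev <- eigen(S, symmetric = TRUE)
  # solid uniform ellipsoid: covariance eigenvalues are axis^2 / 5
  semi <- sqrt(5 * pmax(ev$values, 0))
  semi <- sort(semi, decreasing = TRUE)
  ecc <- if (semi[1] > 0) sqrt(max(0, 1 - (semi[2] / semi[1])^2)) else 0
  if (is.null(positions_vox)) {
    positions_vox <- round(sweep(positions_um, 2, voxel_size, "/") + 0.5)
  }
  foot <- unique(positions_vox[, 1:2, drop = FALSE])
  list(semi_axes = semi, eccentricity = ecc,
       area_um2 = nrow(foot) * voxel_size[1] * voxel_size[2])
}

#' Detect nuclei across rendered frames
#'
#' Applies [detect_nuclei()] to every frame of a voxel render and assembles
#' a `frame_set` usable by the tracker.
#'
#' @param voxels output of [render_voxels()] (named list per frame).
#' @param params a [detection_config()].
#' @param delta_t_min frame interval, minutes.
#' @param channel name of the channel to detect on.
#' @return a `frame_set`.
#' @export
detect_frames <- function(voxels, params = detection_config(),
                          delta_t_min = 8.75, channel = "ch_nuclear") {
  frames <- as.integer(sub("^frame_", "", names(voxels)))
  rows <- lapply(seq_along(voxels), function(i) {
    vol <- voxels[[i]][[channel]]
    extra <- voxels[[i]][setdiff(names(voxels[[i]]), channel)]
    det <- detect_nuclei(vol, params, extra_channels =
                           if (length(extra)) extra else NULL)
    if (nrow(det) == 0) return(NULL)
    cbind(data.frame(frame = frames[i]), det)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  det <- do.call(rbind, rows)
  fs <- frame_set(det, delta_t_min,
                  channels = grep("^mean_", names(det), value = TRUE))
  fs
}
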