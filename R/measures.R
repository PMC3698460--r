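# Binary-mask morphometry: area, trace thickness, Feret (caliper) profile.
# Coordinates: x = column, y = row (top-left origin); angles in degrees from
# the +x axis toward +y, reduced to [0, 180) since calipers are axial.

#' Ink area of a scribble mask
#'
#' @param mask A logical ink mask ([binarize()]).
#' @return Foreground pixel count (area in px^2).
#' @export
measure_area <- function(mask) {
  mask <- as_mask(mask)
  a <- sum(mask)
  if (a == 0L) stop_empty_scribble()
  as.numeric(a)
}

# Shift a matrix by (dr, dc), filling vacated cells with 0.
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Zhang-Suen morphological thinning to a 1-px skeleton. Vectorized over the
# whole matrix; the number of passes is about half the trace width.
skeletonize_mask <- function(mask) {
  m <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask * 1L
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p2 <- shift_mat(m, 1L, 0L)   # value of north neighbour at each pixel
      p3 <- shift_mat(m, 1L, -1L)  # NE
      p4 <- shift_mat(m, 0L, -1L)  # E
      p5 <- shift_mat(m, -1L, -1L) # SE
      p6 <- shift_mat(m, -1L, 0L)  # S
      p7 <- shift_mat(m, -1L, 1L)  # SW
      p8 <- shift_mat(m, 0L, 1L)   # W
      p9 <- shift_mat(m, 1L, 1L)   # NW
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (p2 == 0L & p3 == 1L) + (p3 == 0L & p4 == 1L) +
           (p4 == 0L & p5 == 1L) + (p5 == 0L & p6 == 1L) +
           (p6 == 0L & p7 == 1L) + (p7 == 0L & p8 == 1L) +
           (p8 == 0L & p9 == 1L) + (p9 == 0L & p2 == 1L)
      cond <- m == 1L & B >= 2L & B <= 6L & A == 1L
      if (step == 1L) {
        cond <- cond & (p2 * p4 * p6 == 0L) & (p4 * p6 * p8 == 0L)
      } else {
        cond <- cond & (p2 * p4 * p8 == 0L) & (p2 * p6 * p8 == 0L)
      }
      if (any(cond)) {
        m[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] == 1L
}

# Euclidean distance transform (distance to nearest background pixel), with
# the image border treated as background.
distance_transform <- function(mask) {
  pad <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  pad[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask * 1L
  d <- EBImage::distmap(pad, metric = "euclidean")
  d <- as.matrix(d)[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)]
  d
}

# 2x block (nearest-neighbour) upsampling of a logical mask.
upsample2 <- function(mask) {
  mask[rep(seq_len(nrow(mask)), each = 2L), rep(seq_len(ncol(mask)), each = 2L)]
}

#' Pen-trace thickness of a scribble
#'
#' Automates the manual measurement of trace width on an isolated portion of
#' a stroke: the thickness is twice the half-width of the trace along the
#' medial axis, read off as the lower quartile of the distance-transform
#' values at the skeleton pixels of a 2x block-upsampled mask (at 2x, that
#' statistic in upsampled pixels equals the trace width in original pixels,
#' which removes the even/odd width quantization a native-resolution medial
#' distance has). The lower quartile -- not the median -- is the
#' isolated-portion statistic: wherever strokes or loops merge, the local
#' medial width exceeds the pen width, and in densely perseverated
#' scribbles the merged stretches can be the majority of the skeleton; the
#' isolated stretches an experimenter would measure populate the lower tail.
#'
#' @param mask Logical ink mask.
#' @param ls_min Optional minimum Feret diameter of the mask; when given, a
#'   `BlobWarning` is raised if the estimate exceeds `0.8 * ls_min`
#'   (skeleton collapsed to the centre of a filled blob, so the "thickness"
#'   is really the blob size).
#' @return Thickness in pixels (> 0).
#' @export
estimate_thickness <- function(mask, ls_min = NULL) {
  mask <- as_mask(mask)
  if (!any(mask)) stop_empty_scribble()
  up <- upsample2(mask)
  skel <- skeletonize_mask(up)
  d <- distance_transform(up)
  # keep only ridge peaks: skeleton pixels whose distance value is a local
  # maximum over the 3x3 neighbourhood. Each such value is the radius of an
  # inscribed pen disk; staircase dips of a slanted trace (spuriously
  # narrow) are dropped, merged stretches (spuriously wide) go to the upper
  # tail and are discounted by the quartile below.
  nb <- pmax(shift_mat(d, 1L, 0L), shift_mat(d, -1L, 0L),
             shift_mat(d, 0L, 1L), shift_mat(d, 0L, -1L),
             shift_mat(d, 1L, 1L), shift_mat(d, 1L, -1L),
             shift_mat(d, -1L, 1L), shift_mat(d, -1L, -1L))
  vals <- d[skel & up & d >= nb]
  if (length(vals) == 0L) vals <- d[skel & up]
  if (length(vals) == 0L) vals <- max(d)  # single-pixel-scale mask
  t <- as.numeric(quantile(vals, 0.25, names = FALSE, type = 7))
  t <- max(t, 1)
  if (!is.null(ls_min) && t > 0.8 * ls_min) {
    spindex_warning("BlobWarning", sprintf(
      "thickness %.1f px close to minimum linear size %.1f px: mask is blob-like, thickness unreliable",
      t, ls_min))
  }
  t
}

# Foreground pixel centres as (x, y); reduced to their convex hull when
# large, since caliper extents only depend on the hull.
mask_points <- function(mask, hull = TRUE) {
  idx <- which(mask, arr.ind = TRUE)
  pts <- cbind(x = as.numeric(idx[, 2]), y = as.numeric(idx[, 1]))
  if (hull && nrow(pts) > 3L && nrow(unique(pts)) >= 3L) {
    h <- chull(pts)
    if (length(h) >= 2L) pts <- pts[h, , drop = FALSE]
  }
  pts
}

#' Feret (caliper) diameter at one angle
#'
#' Extent of the projection of the foreground pixel centres onto the probe
#' direction, plus one pixel of footprint so a single pixel has diameter 1.
#'
#' @param mask Logical ink mask.
#' @param angle_deg Probe direction in degrees.
#' @return Diameter in pixels.
#' @export
feret_diameter <- function(mask, angle_deg) {
  pts <- mask_points(as_mask(mask))
  if (nrow(pts) == 0L) stop_empty_scribble()
  th <- angle_deg * pi / 180
  pr <- pts[, 1] * cos(th) + pts[, 2] * sin(th)
  diff(range(pr)) + 1
}

#' Feret diameter profile over all directions
#'
#' Sweeps a caliper over `[0, 180)` degrees and records the diameter at each
#' probe angle, together with the extrema `ls_max` / `ls_min` used by the
#' linear-size flowchart's elongation test.
#'
#' @param mask Logical ink mask.
#' @param angular_step Probe spacing in degrees, in `(0, 15]`.
#' @return An object of class `feret_profile`: list with `angles`,
#'   `diameters`, `ls_max`, `ls_min`, `theta_max` (angle attaining
#'   `ls_max`).
#' @export
feret_profile <- function(mask, angular_step = 1) {
  mask <- as_mask(mask)
  if (!any(mask)) stop_empty_scribble()
  if (!is.numeric(angular_step) || angular_step <= 0 || angular_step > 15) {
    stop_invalid_params("angular_step must be in (0, 15] degrees")
  }
  pts <- mask_points(mask)
  angles <- seq(0, 180 - angular_step / 2, by = angular_step)
  th <- angles * pi / 180
  proj <- pts %*% rbind(cos(th), sin(th))
  diam <- apply(proj, 2L, function(p) diff(range(p))) + 1
  imax <- which.max(diam)
  structure(list(
    angles = angles,
    diameters = as.numeric(diam),
    ls_max = diam[[imax]],
    ls_min = min(diam),
    theta_max = angles[[imax]]
  ), class = "feret_profile")
}

#' @export
print.feret_profile <- function(x, ...) {
  cat(sprintf(
    "<feret_profile> %d angles: LS_max = %.2f px at %g deg, LS_min = %.2f px\n",
    length(x$angles), x$ls_max, x$theta_max, x$ls_min))
  invisible(x)
}
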