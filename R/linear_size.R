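# Direction flowchart for the linear size LS. The scribbling gesture mixes a
# distal component (the strokes/loops themselves) with a proximal
# transportation drift across the sheet; LS must reflect the distal
# component, so the measurement direction is chosen by three ordered rules:
#   I   well-aligned strokes      -> measure along the stroke direction
#   II  elongated scribble        -> measure orthogonally to the major axis
#                                    (the likely transportation direction)
#   III neither                   -> average of LS_max and LS_min

# Gaussian blur that tolerates images smaller than the filter kernel by
# zero-padding before EBImage::gblur and cropping afterwards.
gblur_padded <- function(f, sigma) {
  k <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  pr <- max(0L, k - nrow(f)); pc <- max(0L, k - ncol(f))
  if (pr > 0L || pc > 0L) {
    g <- matrix(0, nrow(f) + 2L * pr, ncol(f) + 2L * pc)
    g[pr + seq_len(nrow(f)), pc + seq_len(ncol(f))] <- f
    g <- EBImage::gblur(g, sigma = sigma)
    g[pr + seq_len(nrow(f)), pc + seq_len(ncol(f)), drop = FALSE]
  } else {
    EBImage::gblur(f, sigma = sigma)
  }
}

# Local tangent orientations along the skeleton, by the structure tensor of
# the smoothed mask. Returns per-pixel tangent angles (deg, axial in
# [0, 180)) and tensor-energy weights.
skeleton_orientations <- function(mask, thickness, smooth_sigma = NULL) {
  skel <- skeletonize_mask(mask)
  if (sum(skel) < 2L) return(NULL)
  f <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  sigma <- if (is.null(smooth_sigma)) max(1.5, thickness / 2) else smooth_sigma
  f <- gblur_padded(f, sigma)
  # central differences; x = column, y = row
  gx <- (shift_mat(f, 0, -1) - shift_mat(f, 0, 1)) / 2
  gy <- (shift_mat(f, -1, 0) - shift_mat(f, 1, 0)) / 2
  jxx <- gblur_padded(gx * gx, 2)
  jyy <- gblur_padded(gy * gy, 2)
  jxy <- gblur_padded(gx * gy, 2)
  sel <- which(skel)
  # gradient (normal) orientation of the dominant tensor eigenvector
  normal <- 0.5 * atan2(2 * jxy[sel], jxx[sel] - jyy[sel]) * 180 / pi
  tangent <- (normal + 90) %% 180
  w <- jxx[sel] + jyy[sel]
  keep <- w > 1e-8
  if (!any(keep)) return(NULL)
  list(tangent_deg = tangent[keep], weight = w[keep])
}

# Weighted axial mean direction and the weighted fraction of tangents within
# +/- band_deg of it.
axial_concentration <- function(tangent_deg, weight, band_deg) {
  a2 <- tangent_deg * pi / 90  # doubled angles
  phi <- (atan2(sum(weight * sin(a2)), sum(weight * cos(a2))) * 90 / pi) %% 180
  dev <- abs(((tangent_deg - phi + 90) %% 180) - 90)
  list(phi = phi, aligned_frac = sum(weight[dev <= band_deg]) / sum(weight))
}

#' Select the linear-size measurement direction
#'
#' Applies the three-rule direction flowchart, strictly in order:
#'
#' * **Rule I** (`I_STROKE_ALIGNED`): for stroke scribbles whose skeleton
#'   tangents are concentrated (a weighted fraction of at least
#'   `coherence_min` lies within `band_deg` of the dominant orientation
#'   `phi`), LS is the Feret diameter along `phi` -- the direction of the
#'   distal oscillation.
#' * **Rule II** (`II_ELONGATED`): otherwise, if the shape is elongated --
#'   `ls_max` strictly more than twice `ls_min` -- LS is the Feret diameter
#'   orthogonal to the angle attaining `ls_max` (not `ls_min` itself, which
#'   can occur off-orthogonal for concave shapes).
#' * **Rule III** (`III_AVERAGE`): otherwise `LS = (ls_max + ls_min) / 2`,
#'   with no associated direction.
#'
#' @param mask Logical ink mask.
#' @param composition A `composition` object or `"strokes"`/`"loops"`.
#' @param profile A [feret_profile()] of the same mask.
#' @param thickness Pen-trace thickness in pixels.
#' @param coherence_min Minimum weighted fraction of aligned tangents for
#'   rule I (default 0.8).
#' @param band_deg Half-width of the alignment band in degrees (default 20).
#' @param direction_deg Optional experimenter override: measure LS along
#'   this direction (rule I semantics, `rule_id = "I_STROKE_ALIGNED"`,
#'   recorded as a user decision).
#' @return List with `linear_size` (px), `rule_id`, `direction_deg` (`NA`
#'   for rule III).
#' @export
select_linear_size <- function(mask, composition, profile, thickness,
                               coherence_min = 0.8, band_deg = 20,
                               direction_deg = NULL) {
  mask <- as_mask(mask)
  composition <- as_composition(composition)
  if (!inherits(profile, "feret_profile")) {
    stop_invalid_params("profile must be a feret_profile")
  }
  if (!is.null(direction_deg)) {
    return(list(linear_size = feret_diameter(mask, direction_deg),
                rule_id = "I_STROKE_ALIGNED",
                direction_deg = direction_deg %% 180))
  }
  if (composition$label == "STROKES") {
    ori <- skeleton_orientations(mask, thickness)
    if (!is.null(ori)) {
      conc <- axial_concentration(ori$tangent_deg, ori$weight, band_deg)
      if (conc$aligned_frac >= coherence_min) {
        return(list(linear_size = feret_diameter(mask, conc$phi),
                    rule_id = "I_STROKE_ALIGNED",
                    direction_deg = conc$phi))
      }
    }
  }
  if (profile$ls_max > 2 * profile$ls_min) {  # strictly more than twice
    ang <- (profile$theta_max + 90) %% 180
    return(list(linear_size = feret_diameter(mask, ang),
                rule_id = "II_ELONGATED",
                direction_deg = ang))
  }
  list(linear_size = (profile$ls_max + profile$ls_min) / 2,
       rule_id = "III_AVERAGE",
       direction_deg = NA_real_)
}

#' Measure a scribble mask
#'
#' Runs the full measurement chain on an ink mask: area, trace thickness,
#' Feret profile, composition (unless overridden) and the flowchart-selected
#' linear size.
#'
#' @inheritParams select_linear_size
#' @param composition `"auto"` (default) to classify from the mask's holes,
#'   or `"strokes"`/`"loops"` as an experimenter override.
#' @param angular_step Feret probe spacing in degrees.
#' @return Object of class `trace_measurements`: list with `area_A`,
#'   `thickness_t`, `linear_size_LS`, `ls_max`, `ls_min`, `rule_id`,
#'   `direction_deg`, `composition`, and `flags` (character vector, e.g.
#'   `"BlobWarning"`).
#' @export
measure_scribble <- function(mask, composition = "auto", angular_step = 1,
                             coherence_min = 0.8, band_deg = 20,
                             direction_deg = NULL) {
  mask <- as_mask(mask)
  flags <- character()
  area <- measure_area(mask)
  profile <- feret_profile(mask, angular_step = angular_step)
  thickness <- withCallingHandlers(
    estimate_thickness(mask, ls_min = profile$ls_min),
    BlobWarning = function(w) {
      flags <<- c(flags, "BlobWarning")
      invokeRestart("muffleWarning")
    })
  comp <- if (identical(composition, "auto")) {
    classify_composition(mask, thickness)
  } else {
    as_composition(composition)
  }
  sel <- select_linear_size(mask, comp, profile, thickness,
                            coherence_min = coherence_min,
                            band_deg = band_deg,
                            direction_deg = direction_deg)
  structure(list(
    area_A = area,
    thickness_t = thickness,
    linear_size_LS = sel$linear_size,
    ls_max = profile$ls_max,
    ls_min = profile$ls_min,
    rule_id = sel$rule_id,
    direction_deg = sel$direction_deg,
    composition = comp,
    flags = flags
  ), class = "trace_measurements")
}

#' @export
print.trace_measurements <- function(x, ...) {
  cat(sprintf(
    paste0("<trace_measurements> A = %.0f px^2, t = %.2f px, LS = %.2f px",
           " (%s%s), LS_max/LS_min = %.1f/%.1f, %s\n"),
    x$area_A, x$thickness_t, x$linear_size_LS, x$rule_id,
    if (is.na(x$direction_deg)) "" else sprintf(" @ %.1f deg", x$direction_deg),
    x$ls_max, x$ls_min, x$composition$label))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
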