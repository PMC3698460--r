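#' Classify a scribble as stroke-composed or loop-composed
#'
#' Elementary movements are either roughly linear (strokes) or roughly
#' circular (loops), and the two scribble families look different: drawn
#' loops enclose paper, strokes do not. The classifier measures the holes of
#' the ink mask (background regions not connected to the image border),
#' keeps those larger than `thickness^2` (crossing strokes produce small
#' sliver holes of about that scale), and labels the scribble LOOPS when the
#' qualifying holes cover at least `hole_frac` of the mask's convex-hull
#' area.
#'
#' The thresholds are heuristics, so the label carries a confidence score
#' and the decision can always be overridden by the experimenter (`source =
#' "USER"` in [score_scribble()]'s `composition` argument), which mirrors
#' how composition is judged by eye in practice.
#'
#' @param mask Logical ink mask.
#' @param thickness Pen-trace thickness in pixels ([estimate_thickness()]).
#' @param hole_frac Fraction of convex-hull area the qualifying holes must
#'   reach for a LOOPS label (default 0.25).
#' @return Object of class `composition`: list with `label` (`"STROKES"` or
#'   `"LOOPS"`), `confidence` in `[0, 1]`, `source = "AUTO"`, `hole_area`,
#'   `hull_area`.
#' @export
classify_composition <- function(mask, thickness, hole_frac = 0.25) {
  mask <- as_mask(mask)
  if (!any(mask)) stop_empty_scribble()
  if (!is.numeric(thickness) || thickness <= 0) {
    stop_invalid_measurement("thickness must be > 0")
  }
  holes <- EBImage::fillHull(mask * 1L) == 1L & !mask
  hole_area <- 0
  if (any(holes)) {
    lab <- EBImage::bwlabel(holes * 1L)
    sizes <- tabulate(lab[lab > 0L])
    hole_area <- sum(sizes[sizes > thickness^2])
  }
  hull_area <- convex_hull_area(mask)
  need <- hole_frac * hull_area
  ratio <- if (need > 0) hole_area / need else 0
  label <- if (ratio >= 1) "LOOPS" else "STROKES"
  confidence <- if (label == "LOOPS") min(1, ratio) else min(1, 1 - ratio)
  new_composition(label, confidence = confidence, source = "AUTO",
                  hole_area = hole_area, hull_area = hull_area)
}

new_composition <- function(label, confidence = 1, source = "AUTO",
                            hole_area = NA_real_, hull_area = NA_real_) {
  label <- toupper(label)
  if (!label %in% c("STROKES", "LOOPS")) {
    stop_invalid_params("composition label must be 'STROKES' or 'LOOPS'")
  }
  structure(list(label = label, confidence = confidence, source = source,
                 hole_area = hole_area, hull_area = hull_area),
            class = "composition")
}

as_composition <- function(x) {
  if (inherits(x, "composition")) return(x)
  if (is.character(x) && length(x) == 1L) {
    return(new_composition(x, confidence = 1, source = "USER"))
  }
  stop_invalid_params("composition must be a 'composition' object or 'strokes'/'loops'")
}

#' @export
print.composition <- function(x, ...) {
  cat(sprintf("<composition> %s (confidence %.2f, %s)\n",
              x$label, x$confidence, x$source))
  invisible(x)
}

# Area of the convex hull of foreground pixel centres (shoelace formula).
convex_hull_area <- function(mask) {
  pts <- mask_points(mask, hull = TRUE)
  if (nrow(pts) < 3L) return(nrow(pts))  # point/segment: degenerate hull
  x <- pts[, 1]; y <- pts[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}
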