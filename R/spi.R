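#' Compute the Scribble Perseveration Index from measurements
#'
#' The index estimates the number of perseverative elementary movements in a
#' scribble from three measurements: ink area `A`, pen-trace thickness `t`
#' and linear size `LS` (all in consistent units; `A` in the square of the
#' unit of `t` and `LS`):
#'
#' * strokes: `SPI = (A/t - t) / (LS - t) - 1`
#' * loops:   `SPI = (A/t - t) / (pi * (LS - t)) - 1`
#'
#' `A/t` stands in for the pen-path length, `LS` (or `pi * LS`, a loop being
#' about pi times as long as its diameter) for the mean element length, and
#' the `- t` adjustments make a point-contact dot (where `LS = t` and
#' `A` is about `t^2`) score correctly null. Statistical fluctuation can make
#' the raw value negative; since a count of perseverative movements cannot
#' be, the reported `spi` is clamped at zero (the raw value is kept for
#' diagnostics). When `LS - t` falls below `eps` the ratio is the dot case's
#' 0/0: the raw value is undefined and `spi = 0` with a `DegenerateDot`
#' flag.
#'
#' @param area_A Ink area (px^2), > 0.
#' @param thickness_t Pen-trace thickness (px), > 0.
#' @param linear_size_LS Linear size (px), > 0.
#' @param composition `"strokes"`, `"loops"` or a `composition` object.
#' @param eps Degenerate-dot tolerance on `LS - t` in pixels (default 0.5).
#' @param measurements Optional `trace_measurements` provenance to carry in
#'   the result (filled in automatically by [score_scribble()]).
#' @return Object of class `spi`: list with `spi` (clamped, >= 0),
#'   `raw_spi` (may be negative; `NA` for a degenerate dot), `composition`,
#'   `measurements`, `flags`.
#' @examples
#' compute_spi(1000, 2, 60, "strokes")  # spi ~ 7.59
#' compute_spi(1000, 2, 60, "loops")    # spi ~ 1.73
#' @export
compute_spi <- function(area_A, thickness_t, linear_size_LS, composition,
                        eps = 0.5, measurements = NULL) {
  if (!is.numeric(area_A) || !is.numeric(thickness_t) ||
      !is.numeric(linear_size_LS) ||
      is.na(area_A) || is.na(thickness_t) || is.na(linear_size_LS) ||
      area_A <= 0 || thickness_t <= 0 || linear_size_LS <= 0) {
    stop_invalid_measurement("area_A, thickness_t and linear_size_LS must all be > 0")
  }
  composition <- as_composition(composition)
  flags <- if (!is.null(measurements)) measurements$flags else character()
  if (linear_size_LS - thickness_t < eps) {
    raw <- NA_real_
    spi <- 0
    flags <- c(flags, "DegenerateDot")
  } else {
    num <- area_A / thickness_t - thickness_t
    den <- linear_size_LS - thickness_t
    if (composition$label == "LOOPS") den <- pi * den
    raw <- num / den - 1
    spi <- max(0, raw)
  }
  structure(list(spi = spi, raw_spi = raw, composition = composition,
                 measurements = measurements, flags = flags),
            class = "spi")
}

#' Score a scribble image
#'
#' Full pipeline from a scanned scribble to its SPI: binarize ([binarize()]),
#' measure area / thickness / Feret profile, classify composition (or accept
#' the experimenter's), select the linear size by the direction flowchart
#' ([select_linear_size()]), and evaluate the index ([compute_spi()]).
#'
#' @param x Path to a PNG/TIFF file, a `scribble_image`, a numeric image
#'   matrix, or an existing `scribble_mask`.
#' @param composition `"auto"`, `"strokes"` or `"loops"`.
#' @param threshold `"auto"` (maximum entropy) or a fixed integer in
#'   `[0, 255]`.
#' @param invert Assume light ink on dark background.
#' @param largest_component Restrict to the largest connected ink component.
#' @param direction_deg Optional override of the LS measurement direction.
#' @param eps Degenerate-dot tolerance, px.
#' @param coherence_min,band_deg Rule I alignment parameters
#'   ([select_linear_size()]).
#' @param angular_step Feret probe spacing, degrees.
#' @return An `spi` object with full measurement provenance.
#' @examples
#' traj <- stroke_trajectory(n_strokes = 10, stroke_length = 60,
#'                           drift_per_stroke = 6, seed = 1)
#' img <- render_trajectory(traj, pen_thickness = 3)
#' score_scribble(img)
#' @export
score_scribble <- function(x, composition = "auto", threshold = "auto",
                           invert = FALSE, largest_component = FALSE,
                           direction_deg = NULL, eps = 0.5,
                           coherence_min = 0.8, band_deg = 20,
                           angular_step = 1) {
  mask <- if (inherits(x, "scribble_mask")) {
    x
  } else {
    img <- if (is.character(x)) read_scribble(x) else as_scribble_image(x)
    binarize(img, threshold = threshold, invert = invert,
             largest_component = largest_component)
  }
  meas <- measure_scribble(mask, composition = composition,
                           angular_step = angular_step,
                           coherence_min = coherence_min, band_deg = band_deg,
                           direction_deg = direction_deg)
  compute_spi(meas$area_A, meas$thickness_t, meas$linear_size_LS,
              meas$composition, eps = eps, measurements = meas)
}

#' @export
print.spi <- function(x, ...) {
  raw <- if (is.na(x$raw_spi)) "degenerate dot" else sprintf("raw %.4f", x$raw_spi)
  cat(sprintf("SPI = %.4f  (%s, %s composition)\n",
              x$spi, raw, tolower(x$composition$label)))
  if (!is.null(x$measurements)) print(x$measurements)
  if (length(x$flags)) cat("flags:", paste(unique(x$flags), collapse = ", "), "\n")
  invisible(x)
}

#' Flatten an SPI result to a one-row data frame
#'
#' Columns match the CSV/JSON row schema written by the command-line tools:
#' id, area, thickness, linear size, Feret extrema, flowchart rule,
#' direction, composition, raw and clamped SPI, and flags.
#'
#' @param x An `spi` object.
#' @param row.names,optional Ignored (data.frame method signature).
#' @param id Identifier for the `id` column.
#' @param ... Unused.
#' @export
as.data.frame.spi <- function(x, row.names = NULL, optional = FALSE,
                              id = NA_character_, ...) {
  m <- x$measurements
  data.frame(
    id = id,
    area_px2 = if (is.null(m)) NA_real_ else m$area_A,
    thickness_px = if (is.null(m)) NA_real_ else m$thickness_t,
    ls_px = if (is.null(m)) NA_real_ else m$linear_size_LS,
    ls_max_px = if (is.null(m)) NA_real_ else m$ls_max,
    ls_min_px = if (is.null(m)) NA_real_ else m$ls_min,
    rule_id = if (is.null(m)) NA_character_ else m$rule_id,
    direction_deg = if (is.null(m)) NA_real_ else m$direction_deg,
    composition = x$composition$label,
    composition_source = x$composition$source,
    raw_spi = x$raw_spi,
    spi = x$spi,
    flags = paste(unique(x$flags), collapse = ";"),
    stringsAsFactors = FALSE
  )
}
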