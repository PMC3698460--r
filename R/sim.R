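# Scribble kinematics simulator. A scribble is modelled as the paper trace
# of a two-component gesture: a distal component producing the elementary
# movements (back-and-forth strokes, or full loops) and a proximal
# "transportation" drift of the arm across the sheet. Ground truth (true
# element count N, exact path length L, mean element length l = L/N) is
# known by construction, which is what validation needs.

new_trajectory <- function(points, element_breaks, kind, ground_truth) {
  structure(list(points = points, element_breaks = element_breaks,
                 kind = kind, ground_truth = ground_truth),
            class = "scribble_trajectory")
}

polyline_length <- function(points) {
  if (nrow(points) < 2L) return(0)
  sum(sqrt(rowSums(diff(points)^2)))
}

#' Simulate a stroke scribble trajectory
#'
#' Produces a zigzag polyline: the pen oscillates back and forth along a
#' dominant axis (the distal component) while drifting orthogonally to it
#' (the transportation component). Each oscillation half-cycle is one
#' elementary stroke.
#'
#' @param n_strokes True number of strokes N (>= 1).
#' @param stroke_length Nominal stroke length, px.
#' @param drift_per_stroke Orthogonal transportation drift per stroke, px.
#' @param angle_deg Direction of the stroke axis, degrees.
#' @param length_jitter Fractional s.d. of per-stroke length variation.
#' @param angle_jitter S.d. of per-stroke angular wobble, degrees.
#' @param seed Integer seed; identical seeds give identical trajectories.
#' @return A `scribble_trajectory` whose `ground_truth` holds `n_elements`,
#'   `total_length_L` (exact polyline length), `mean_element_length_l`,
#'   and `seed`.
#' @export
stroke_trajectory <- function(n_strokes, stroke_length, drift_per_stroke = 0,
                              angle_deg = 90, length_jitter = 0,
                              angle_jitter = 0, seed = 1) {
  if (n_strokes < 1 || stroke_length <= 0) {
    stop_invalid_params("n_strokes >= 1 and stroke_length > 0 required")
  }
  if (length_jitter < 0 || angle_jitter < 0) {
    stop_invalid_params("jitters must be >= 0")
  }
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  # Distal oscillation between a drifting baseline rail and a far rail:
  # even-numbered vertices sit on the baseline (arm-wrist position), odd
  # ones at the jittered stroke tip, so jitter perturbs individual strokes
  # without accumulating into a positional random walk that would swamp the
  # transportation drift.
  a0 <- angle_deg * pi / 180
  u0 <- c(cos(a0), sin(a0))                 # distal (stroke) axis
  v0 <- c(-sin(a0), cos(a0))                # orthogonal transportation axis
  pts <- matrix(0, n_strokes + 1L, 2L)
  for (i in seq_len(n_strokes + 1L)) {
    base <- (i - 1L) * drift_per_stroke * v0
    if (i %% 2L == 0L) {                    # stroke tip
      len <- stroke_length * max(0.1, 1 + rnorm(1, 0, length_jitter))
      ang <- a0 + rnorm(1, 0, angle_jitter) * pi / 180
      base <- base + len * c(cos(ang), sin(ang))
    }
    pts[i, ] <- base
  }
  gt <- list(n_elements = n_strokes,
             total_length_L = polyline_length(pts),
             pen_thickness = NA_real_, seed = seed)
  gt$mean_element_length_l <- gt$total_length_L / n_strokes
  new_trajectory(pts, element_breaks = seq_len(n_strokes - 1L) + 1L,
                 kind = "STROKES", ground_truth = gt)
}

#' Simulate a loop scribble trajectory
#'
#' Concatenates `n_loops` full circles whose centres drift across the sheet
#' (the transportation component). Each circle is one elementary loop; the
#' ground-truth path length is the sum of the sampled circumferences, which
#' converges to `pi * diameter` per loop as sampling densifies.
#'
#' @param n_loops True number of loops N (>= 1).
#' @param loop_diameter Nominal loop diameter, px.
#' @param drift_per_loop Centre drift between consecutive loops, px.
#' @param diameter_jitter Fractional s.d. of per-loop diameter variation.
#' @param points_per_loop Samples per circle (>= 72).
#' @param seed Integer seed.
#' @return A `scribble_trajectory` (see [stroke_trajectory()]).
#' @export
loop_trajectory <- function(n_loops, loop_diameter, drift_per_loop = 0,
                            diameter_jitter = 0, points_per_loop = 90,
                            seed = 1) {
  if (n_loops < 1 || loop_diameter <= 0) {
    stop_invalid_params("n_loops >= 1 and loop_diameter > 0 required")
  }
  if (points_per_loop < 72) {
    stop_invalid_params("points_per_loop must be >= 72 for a faithful circumference")
  }
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  pts_list <- vector("list", n_loops)
  L <- 0
  breaks <- integer(0)
  npts <- 0L
  for (i in seq_len(n_loops)) {
    d <- loop_diameter * max(0.1, 1 + rnorm(1, 0, diameter_jitter))
    r <- d / 2
    centre <- c((i - 1L) * drift_per_loop, 0)
    th <- seq(0, 2 * pi, length.out = points_per_loop + 1L)
    circ <- cbind(centre[1] + r * cos(th), centre[2] + r * sin(th))
    L <- L + polyline_length(circ)
    pts_list[[i]] <- circ
    npts <- npts + nrow(circ)
    if (i < n_loops) breaks <- c(breaks, npts + 1L)
  }
  pts <- do.call(rbind, pts_list)
  gt <- list(n_elements = n_loops, total_length_L = L,
             pen_thickness = NA_real_, seed = seed)
  gt$mean_element_length_l <- L / n_loops
  new_trajectory(pts, element_breaks = breaks, kind = "LOOPS",
                 ground_truth = gt)
}

#' @export
print.scribble_trajectory <- function(x, ...) {
  gt <- x$ground_truth
  cat(sprintf("<scribble_trajectory> %s: N = %d, L = %.1f px, l = %.1f px\n",
              x$kind, gt$n_elements, gt$total_length_L,
              gt$mean_element_length_l))
  invisible(x)
}

#' Rasterize a trajectory with a round pen
#'
#' Stamps a disk of diameter `pen_thickness` along the densely resampled
#' path: a pixel is inked when its centre lies within `pen_thickness / 2` of
#' the path. The canvas is the path's bounding box plus the pen radius and
#' `margin`; background is white (255), ink black (0).
#'
#' @param trajectory A `scribble_trajectory`.
#' @param pen_thickness Pen diameter in px (>= 1).
#' @param margin White border width in px.
#' @return A `scribble_image` (0-255 integer matrix).
#' @export
render_trajectory <- function(trajectory, pen_thickness, margin = 5) {
  if (!inherits(trajectory, "scribble_trajectory")) {
    stop_invalid_params("trajectory must be a scribble_trajectory")
  }
  if (!is.numeric(pen_thickness) || pen_thickness < 1) {
    stop_invalid_params("pen_thickness must be >= 1 px")
  }
  pts <- trajectory$points
  r <- pen_thickness / 2
  # the 0.2071 sub-pixel offset keeps pixel centres off exact stadium
  # boundaries for axis-aligned paths with half-integer radii, which would
  # otherwise gain a systematic one-pixel width inflation
  pad <- r + margin + 0.2071
  x <- pts[, 1] - min(pts[, 1]) + pad
  y <- pts[, 2] - min(pts[, 2]) + pad
  w <- max(1L, ceiling(max(x) + pad))
  h <- max(1L, ceiling(max(y) + pad))
  ink <- matrix(FALSE, h, w)
  if (nrow(pts) == 1L) {
    ink <- stamp_segment(ink, c(x, y), c(x, y), r)
  } else {
    for (i in seq_len(nrow(pts) - 1L)) {
      ink <- stamp_segment(ink, c(x[i], y[i]), c(x[i + 1L], y[i + 1L]), r)
    }
  }
  img <- matrix(255L, h, w)
  img[ink] <- 0L
  as_scribble_image(img)
}

# Ink every pixel whose centre lies within r of segment a-b (exact
# point-to-segment distance, no grid rounding), i.e. a stadium stamp.
stamp_segment <- function(ink, a, b, r) {
  cs <- max(1L, floor(min(a[1], b[1]) - r)):min(ncol(ink), ceiling(max(a[1], b[1]) + r))
  rs <- max(1L, floor(min(a[2], b[2]) - r)):min(nrow(ink), ceiling(max(a[2], b[2]) + r))
  px <- rep(cs, each = length(rs))
  py <- rep(rs, times = length(cs))
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) {
    d2 <- (px - a[1])^2 + (py - a[2])^2
  } else {
    t <- pmin(1, pmax(0, ((px - a[1]) * ab[1] + (py - a[2]) * ab[2]) / len2))
    d2 <- (px - (a[1] + t * ab[1]))^2 + (py - (a[2] + t * ab[2]))^2
  }
  hit <- d2 <= r^2
  ink[cbind(py[hit], px[hit])] <- TRUE
  ink
}

#' Define a simulation design
#'
#' Factorial design for the in-silico proxy-validation experiment: pen
#' thickness x composition kind x perseveration level, with repetitions.
#' The defaults mirror the validation conditions the index was assessed
#' under: two pen widths (ordinary pen vs. thick crayon analogue, 2 and 6 px
#' at a 100-dpi-like scale), strokes vs. loops, and six perseveration levels
#' spanning the movement-count range observed in patients (N from 1 to 22),
#' four repetitions per cell — 96 scribbles.
#'
#' @param pen_thicknesses Pen diameters, px.
#' @param kinds Subset of `c("STROKES", "LOOPS")`.
#' @param levels Target true element counts N.
#' @param repetitions Repetitions per cell (>= 1).
#' @param base_seed Integer master seed; per-item seeds are derived from it.
#' @param stroke_length,drift_per_stroke,length_jitter,angle_jitter
#'   Stroke-cell generator settings ([stroke_trajectory()]).
#' @param loop_diameter,drift_per_loop,diameter_jitter Loop-cell generator
#'   settings ([loop_trajectory()]).
#' @return A `design_spec` list.
#' @export
design_spec <- function(pen_thicknesses = c(2, 6),
                        kinds = c("STROKES", "LOOPS"),
                        levels = c(1, 3, 6, 10, 15, 22),
                        repetitions = 4,
                        base_seed = 1,
                        stroke_length = 60, drift_per_stroke = 6,
                        length_jitter = 0.1, angle_jitter = 8,
                        loop_diameter = 40, drift_per_loop = 8,
                        diameter_jitter = 0.1) {
  if (!length(pen_thicknesses) || !length(kinds) || !length(levels) ||
      repetitions < 1) {
    stop_invalid_params("design lists must be nonempty and repetitions >= 1")
  }
  structure(list(
    pen_thicknesses = pen_thicknesses,
    kinds = toupper(kinds),
    levels = as.integer(levels),
    repetitions = as.integer(repetitions),
    base_seed = as.integer(base_seed),
    stroke_length = stroke_length, drift_per_stroke = drift_per_stroke,
    length_jitter = length_jitter, angle_jitter = angle_jitter,
    loop_diameter = loop_diameter, drift_per_loop = drift_per_loop,
    diameter_jitter = diameter_jitter
  ), class = "design_spec")
}

#' Read a design from a JSON config file
#'
#' Fields are the arguments of [design_spec()]; absent fields keep their
#' defaults.
#'
#' @param path JSON file path.
#' @return A `design_spec`.
#' @export
read_design_spec <- function(path) {
  if (!file.exists(path)) stop_io_failure(sprintf("no such config file '%s'", path))
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  keep <- intersect(names(cfg), names(formals(design_spec)))
  do.call(design_spec, cfg[keep])
}

# Stable per-item seed from (base_seed, cell indices, repetition). A small
# multiplicative hash keeps items independently reproducible and < 2^31.
item_seed <- function(base_seed, i_thick, i_kind, i_level, rep) {
  h <- as.double(base_seed)
  for (k in c(i_thick, i_kind, i_level, rep)) {
    h <- (h * 31 + k * 2654435) %% 2147483629
  }
  as.integer(h)
}

#' Generate a simulated scribble dataset
#'
#' Simulates and renders every cell x repetition of a [design_spec()],
#' writing one grayscale PNG per item plus a `manifest.csv` describing each
#' (file, kind, pen thickness, target and true N, true path length L, true
#' mean element length l, per-item seed). Deterministic: identical
#' `(spec, base_seed)` reproduce identical files.
#'
#' @param spec A `design_spec` (default: the standard 2 x 2 x 6 x 4 design).
#' @param out_dir Output directory (created if missing).
#' @return The manifest as a data frame (invisibly written to
#'   `out_dir/manifest.csv`); the per-item trajectory is regenerable from
#'   the recorded seed.
#' @export
simulate_design <- function(spec = design_spec(), out_dir) {
  if (!inherits(spec, "design_spec")) stop_invalid_params("spec must be a design_spec")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2L) != 0L) {
    stop_io_failure(sprintf("output directory '%s' is not writable", out_dir))
  }
  rows <- list()
  n <- 0L
  for (it in seq_along(spec$pen_thicknesses)) {
    for (ik in seq_along(spec$kinds)) {
      for (il in seq_along(spec$levels)) {
        for (r in seq_len(spec$repetitions)) {
          n <- n + 1L
          seed <- item_seed(spec$base_seed, it, ik, il, r)
          kind <- spec$kinds[ik]
          lev <- spec$levels[il]
          traj <- if (kind == "STROKES") {
            stroke_trajectory(lev, spec$stroke_length,
                              drift_per_stroke = spec$drift_per_stroke,
                              length_jitter = spec$length_jitter,
                              angle_jitter = spec$angle_jitter, seed = seed)
          } else {
            loop_trajectory(lev, spec$loop_diameter,
                            drift_per_loop = spec$drift_per_loop,
                            diameter_jitter = spec$diameter_jitter,
                            seed = seed)
          }
          pen <- spec$pen_thicknesses[it]
          img <- render_trajectory(traj, pen_thickness = pen)
          id <- sprintf("scribble_%03d_%s_t%g_n%02d_r%d",
                        n, tolower(kind), pen, lev, r)
          fp <- file.path(out_dir, paste0(id, ".png"))
          write_scribble_png(img, fp)
          gt <- traj$ground_truth
          rows[[n]] <- data.frame(
            id = id, filepath = fp, kind = kind, pen_thickness = pen,
            target_n = lev, true_n = gt$n_elements,
            true_L = gt$total_length_L, true_l = gt$mean_element_length_l,
            seed = seed, stringsAsFactors = FALSE)
        }
      }
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}

# Seed handling: use a private RNG state so simulation does not disturb the
# caller's random stream, and repeated calls with one seed are identical.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed) %% 2147483647L)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
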