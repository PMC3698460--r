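# Shared fixtures and independent oracles, all built in code.

# Solid axis-aligned rectangle mask (h rows x w cols) centred in a canvas.
rect_mask <- function(w, h, canvas = c(h + 10L, w + 10L)) {
  m <- matrix(FALSE, canvas[1], canvas[2])
  r0 <- floor((canvas[1] - h) / 2)
  c0 <- floor((canvas[2] - w) / 2)
  m[r0 + seq_len(h), c0 + seq_len(w)] <- TRUE
  m
}

# Filled disk of the given diameter.
disk_mask <- function(diameter, canvas = diameter + 10L) {
  c0 <- (canvas + 1) / 2
  xy <- expand.grid(row = seq_len(canvas), col = seq_len(canvas))
  matrix((xy$row - c0)^2 + (xy$col - c0)^2 <= (diameter / 2)^2,
         canvas, canvas)
}

# One-to-two-pixel-wide circular ring (outer diameter, ring width in px).
annulus_mask <- function(outer_diameter, width, canvas = outer_diameter + 10L) {
  c0 <- (canvas + 1) / 2
  m <- matrix(FALSE, canvas, canvas)
  th <- seq(0, 2 * pi, length.out = 2880L)
  for (r in (outer_diameter / 2 - width + 1):(outer_diameter / 2)) {
    m[cbind(pmax(1, pmin(canvas, round(c0 + r * sin(th)))),
            pmax(1, pmin(canvas, round(c0 + r * cos(th)))))] <- TRUE
  }
  m
}

# Brute-force Feret oracle: projection extent of foreground pixel centres
# (all of them, no hull shortcut) over a dense angle grid, +1 px footprint.
feret_oracle <- function(mask, step = 0.5) {
  idx <- which(mask, arr.ind = TRUE)
  angles <- seq(0, 180 - step / 2, by = step)
  d <- vapply(angles, function(a) {
    th <- a * pi / 180
    pr <- idx[, 2] * cos(th) + idx[, 1] * sin(th)
    diff(range(pr)) + 1
  }, numeric(1))
  list(angles = angles, diameters = d,
       ls_max = max(d), ls_min = min(d),
       theta_max = angles[which.max(d)])
}

# Independent arithmetic evaluation of the index (no shared code path).
spi_oracle <- function(A, t, LS, loops = FALSE) {
  den <- LS - t
  if (loops) den <- pi * den
  max(0, (A / t - t) / den - 1)
}

# Random connected-ish small mask for property tests: union of a few
# random rectangles, guaranteed nonempty.
random_mask <- function(max_side = 40L) {
  m <- matrix(FALSE, sample(8:max_side, 1), sample(8:max_side, 1))
  for (i in seq_len(sample(1:4, 1))) {
    r <- sort(sample(seq_len(nrow(m)), 2))
    c <- sort(sample(seq_len(ncol(m)), 2))
    m[r[1]:r[2], c[1]:c[2]] <- TRUE
  }
  m
}

# Rotate a mask 90 degrees counter-clockwise (in matrix terms).
rot90_mask <- function(m) {
  t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
}

# One shared full-design simulation + validation for the acceptance-level
# checks (built lazily, cached for the session).
default_design_report <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "spindex-default-design")
      man <- simulate_design(design_spec(base_seed = 1), dir)
      cache <<- list(manifest = man, report = validate_design(man))
    }
    cache
  }
})
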