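# Proxy-validation harness: how well does SPI track the true movement count
# N on a dataset where N is known? Reports Pearson correlations (SPI and,
# as the competing naive proxy, raw ink area), the OLS fit of SPI on N, and
# the implied percent under-estimation.

#' Pearson correlation with degenerate-input guards
#'
#' @param xs,ys Numeric vectors of equal length (>= 3), each with nonzero
#'   variance.
#' @return Sample Pearson product-moment correlation.
#' @export
pearson_r <- function(xs, ys) {
  check_paired(xs, ys)
  cor(xs, ys, method = "pearson")
}

#' Ordinary least-squares line fit
#'
#' @inheritParams pearson_r
#' @return Named numeric `c(slope, intercept)` of the OLS fit of `ys` on
#'   `xs`.
#' @export
fit_line <- function(xs, ys) {
  check_paired(xs, ys, min_n = 2L)
  b <- coef(lm(ys ~ xs))
  c(slope = unname(b[2]), intercept = unname(b[1]))
}

check_paired <- function(xs, ys, min_n = 3L) {
  if (length(xs) != length(ys)) stop_degenerate_input("series lengths differ")
  if (length(xs) < min_n) {
    stop_degenerate_input(sprintf("need at least %d paired observations", min_n))
  }
  if (anyNA(xs) || anyNA(ys)) stop_degenerate_input("series contain NA")
  if (var(xs) == 0 || var(ys) == 0) {
    stop_degenerate_input("constant series: correlation/regression undefined")
  }
  invisible(TRUE)
}

#' Percent under-estimation implied by a regression slope
#'
#' A proxy regressed on the truth with slope `b` under-estimates by
#' `100 * (1 - b)` percent. Displayed to one decimal by the print method.
#'
#' @param slope Finite regression slope.
#' @return Percentage, `100 * (1 - slope)`.
#' @export
underestimation <- function(slope) {
  if (!is.numeric(slope) || !is.finite(slope)) {
    stop_invalid_params("slope must be finite")
  }
  100 * (1 - slope)
}

#' Validate SPI against ground truth on a simulated dataset
#'
#' Scores every image of a [simulate_design()] manifest and assembles the
#' proxy-validation statistics: `r_spi` (Pearson correlation of true N with
#' the clamped SPI), `r_area` (with raw ink area, the naive competing
#' proxy), the OLS fit of SPI on N and the implied percent under-estimation.
#' Composition is taken from the manifest's `kind` column (it is known by
#' construction, as it is to the experimenter who drew the scribble); set
#' `composition = "auto"` to exercise the classifier instead. Items that
#' fail to score are excluded and counted, not fatal.
#'
#' @param manifest Data frame from [simulate_design()] (or the path of a
#'   `manifest.csv`); needs columns `filepath`, `true_n` and, unless
#'   `composition = "auto"`, `kind`.
#' @param composition `"manifest"` (default) or `"auto"`.
#' @param ... Passed on to [score_scribble()] (e.g. `threshold`).
#' @return Object of class `spi_validation` with fields `r_spi`, `r_area`,
#'   `slope`, `intercept`, `underestimation_pct`, `n_items`, `n_failed` and
#'   the `per_item` table; has `print`, `summary`, `coef` and `plot`
#'   methods.
#' @export
validate_design <- function(manifest, composition = "manifest", ...) {
  if (is.character(manifest)) {
    if (!file.exists(manifest)) {
      stop_io_failure(sprintf("no such manifest '%s'", manifest))
    }
    manifest <- read.csv(manifest, stringsAsFactors = FALSE)
  }
  if (!nrow(manifest)) stop_degenerate_input("empty manifest")
  rows <- vector("list", nrow(manifest))
  failed <- 0L
  for (i in seq_len(nrow(manifest))) {
    comp <- if (identical(composition, "manifest")) {
      tolower(manifest$kind[i])
    } else {
      composition
    }
    res <- tryCatch(
      suppressWarnings(
        score_scribble(manifest$filepath[i], composition = comp, ...)),
      spindex_error = function(e) NULL,
      error = function(e) NULL)
    if (is.null(res)) {
      failed <- failed + 1L
      next
    }
    rows[[i]] <- data.frame(
      id = if ("id" %in% names(manifest)) manifest$id[i] else as.character(i),
      true_n = manifest$true_n[i],
      spi = res$spi,
      area = res$measurements$area_A,
      rule_id = res$measurements$rule_id,
      stringsAsFactors = FALSE)
  }
  per_item <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(per_item) || nrow(per_item) < 3L) {
    stop_degenerate_input("fewer than 3 items scored successfully")
  }
  r_spi <- pearson_r(per_item$true_n, per_item$spi)
  r_area <- pearson_r(per_item$true_n, per_item$area)
  fit <- fit_line(per_item$true_n, per_item$spi)
  structure(list(
    r_spi = r_spi, r_area = r_area,
    slope = unname(fit["slope"]), intercept = unname(fit["intercept"]),
    underestimation_pct = underestimation(unname(fit["slope"])),
    n_items = nrow(per_item), n_failed = failed,
    per_item = per_item
  ), class = "spi_validation")
}

#' @export
print.spi_validation <- function(x, ...) {
  cat("SPI proxy validation\n")
  cat(sprintf("  items scored: %d (%d failed)\n", x$n_items, x$n_failed))
  cat(sprintf("  r(N, SPI)  = %+.4f\n", x$r_spi))
  cat(sprintf("  r(N, area) = %+.4f\n", x$r_area))
  cat(sprintf("  OLS: SPI = %.4f x N %+.4f\n", x$slope, x$intercept))
  cat(sprintf("  N under-estimation: %.1f%%\n", x$underestimation_pct))
  invisible(x)
}

#' @export
summary.spi_validation <- function(object, ...) {
  print(object)
  agg <- aggregate(cbind(spi, area) ~ true_n, data = object$per_item, FUN = mean)
  cat("\nCell means by true N:\n")
  print(agg, row.names = FALSE)
  invisible(object)
}

#' @export
coef.spi_validation <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Plot SPI against true movement count
#'
#' Scatter of per-item SPI versus true N with the OLS line and the identity
#' (no-under-estimation) reference.
#'
#' @param x An `spi_validation` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.spi_validation <- function(x, ...) {
  d <- x$per_item
  plot(d$true_n, d$spi, xlab = "true N (elementary movements)",
       ylab = "SPI", pch = 16, col = "#00000088", ...)
  abline(x$intercept, x$slope, col = "firebrick", lwd = 2)
  abline(0, 1, lty = 3, col = "grey40")
  legend("topleft", bty = "n",
         legend = c(sprintf("OLS: %.3f N %+.3f", x$slope, x$intercept),
                    "identity (no under-estimation)"),
         col = c("firebrick", "grey40"), lty = c(1, 3), lwd = c(2, 1))
  invisible(x)
}

#' Serialize a validation report
#'
#' Writes the headline statistics as JSON and, optionally, the per-item
#' table as CSV.
#'
#' @param report An `spi_validation` object.
#' @param json_path Output JSON path.
#' @param csv_path Optional per-item CSV path.
#' @return `json_path`, invisibly.
#' @export
write_validation_report <- function(report, json_path, csv_path = NULL) {
  out <- report[c("r_spi", "r_area", "slope", "intercept",
                  "underestimation_pct", "n_items", "n_failed")]
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_path)) write.csv(report$per_item, csv_path, row.names = FALSE)
  invisible(json_path)
}
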