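#' Mean of a triplet of diameter readings
#'
#' Specimens are measured at three points along their length in each view
#' (top and side); the per-axis diameter is the arithmetic mean of the three
#' readings.
#'
#' @param readings Numeric vector of exactly three strictly positive
#'   diameter readings (mm).
#' @param resolution_mm Optional instrument resolution; when non-`NULL`,
#'   each reading is rounded to the nearest multiple of this value before
#'   averaging (the stereomicroscope reticle resolves 1 micron, i.e.
#'   `0.001`). Default `NULL` (no rounding), appropriate for synthetic data.
#' @return Mean diameter in mm.
#' @export
#' @examples
#' mean_diameter(c(0.090, 0.100, 0.110))
mean_diameter <- function(readings, resolution_mm = NULL) {
  if (length(readings) != 3L || anyNA(readings)) {
    stop("exactly three non-missing diameter readings are required")
  }
  if (any(readings <= 0)) {
    stop("diameter readings must be strictly positive")
  }
  if (!is.null(resolution_mm)) {
    readings <- round(readings / resolution_mm) * resolution_mm
  }
  mean(readings)
}

#' Elliptical cross-sectional area from two orthogonal diameters
#'
#' The cross-section is modeled as an ellipse whose axes are the mean top
#' and side diameters, so CSA = pi/4 * d_top * d_side. For a circular
#' specimen (equal diameters) this reduces to pi d^2 / 4.
#'
#' @param d_top,d_side Mean diameters (mm), both strictly positive.
#' @return Area in mm^2. Symmetric in its arguments.
#' @export
ellipse_csa <- function(d_top, d_side) {
  .check_positive_diams(d_top, d_side)
  pi / 4 * d_top * d_side
}

#' Axis ratio of a specimen cross-section
#'
#' Major-axis over minor-axis diameter; 1 for a circle, > 1 otherwise.
#' Computed from the two per-specimen mean diameters regardless of which
#' view (top or side) holds the major axis.
#'
#' @inheritParams ellipse_csa
#' @return Dimensionless ratio >= 1.
#' @export
axis_ratio <- function(d_top, d_side) {
  .check_positive_diams(d_top, d_side)
  pmax(d_top, d_side) / pmin(d_top, d_side)
}

#' Modulus error factor of a single-diameter circular assumption
#'
#' Many protocols measure only one (typically the top, usually major)
#' diameter and assume a circular cross-section. The assumed circular CSA
#' then overestimates the true elliptical CSA by d_major/d_minor, so the
#' engineering stress -- and with it the elastic modulus -- is
#' underestimated by the same factor.
#'
#' @param d_major,d_minor Ordered diameters (mm), `d_major >= d_minor > 0`.
#' @return The factor (circular CSA from d_major) / (elliptical CSA), which
#'   equals the axis ratio.
#' @export
single_axis_error_factor <- function(d_major, d_minor) {
  .check_positive_diams(d_major, d_minor)
  if (any(d_major < d_minor)) {
    stop("d_major must be >= d_minor; order the axes before calling")
  }
  (pi / 4 * d_major^2) / ellipse_csa(d_major, d_minor)
}

.check_positive_diams <- function(a, b) {
  if (anyNA(a) || anyNA(b) || any(a <= 0) || any(b <= 0)) {
    stop("diameters must be strictly positive and non-missing")
  }
  invisible(TRUE)
}

#' Construct the geometry record for one specimen
#'
#' Averages the top and side diameter triplets and derives the elliptical
#' CSA and axis ratio.
#'
#' @param top_diameters,side_diameters Numeric triplets of readings (mm).
#' @param specimen_id Optional identifier carried through.
#' @param resolution_mm Passed to [mean_diameter()].
#' @return An object of class `specimen_geometry`: a list with
#'   `top_diameters`, `side_diameters`, `mean_top`, `mean_side`, `csa`
#'   (mm^2) and `axis_ratio`.
#' @export
specimen_geometry <- function(top_diameters, side_diameters,
                              specimen_id = NA_character_,
                              resolution_mm = NULL) {
  mean_top <- mean_diameter(top_diameters, resolution_mm)
  mean_side <- mean_diameter(side_diameters, resolution_mm)
  structure(
    list(
      specimen_id = specimen_id,
      top_diameters = top_diameters,
      side_diameters = side_diameters,
      mean_top = mean_top,
      mean_side = mean_side,
      csa = ellipse_csa(mean_top, mean_side),
      axis_ratio = axis_ratio(mean_top, mean_side)
    ),
    class = "specimen_geometry"
  )
}

#' @export
print.specimen_geometry <- function(x, ...) {
  cat("Specimen geometry", if (!is.na(x$specimen_id)) x$specimen_id, "\n")
  cat(sprintf("  mean top/side diameter: %.4f / %.4f mm\n",
              x$mean_top, x$mean_side))
  cat(sprintf("  elliptical CSA: %.6f mm^2   axis ratio: %.3f\n",
              x$csa, x$axis_ratio))
  invisible(x)
}

#' Derive geometry columns on a specimen table
#'
#' Adds `mean_top`, `mean_side`, `csa_mm2` and `axis_ratio` to a
#' data.frame carrying `top1..top3` and `side1..side3` diameter readings
#' (mm).
#'
#' @param df Data.frame of specimens.
#' @param resolution_mm Passed to [mean_diameter()].
#' @return The data.frame with derived columns appended.
#' @export
derive_geometry <- function(df, resolution_mm = NULL) {
  need <- c(paste0("top", 1:3), paste0("side", 1:3))
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("specimen table missing columns: ", paste(missing, collapse = ", "))
  }
  df$mean_top <- vapply(seq_len(nrow(df)), function(i) {
    mean_diameter(as.numeric(df[i, paste0("top", 1:3)]), resolution_mm)
  }, numeric(1))
  df$mean_side <- vapply(seq_len(nrow(df)), function(i) {
    mean_diameter(as.numeric(df[i, paste0("side", 1:3)]), resolution_mm)
  }, numeric(1))
  df$csa_mm2 <- ellipse_csa(df$mean_top, df$mean_side)
  df$axis_ratio <- axis_ratio(df$mean_top, df$mean_side)
  df
}

#' Read specimen geometry from CSV
#'
#' Expects columns `specimen_id, group, muscle, specimen_type,
#' top1..top3, side1..side3` with diameters in mm, and appends derived
#' `mean_top`, `mean_side`, `csa_mm2`, `axis_ratio` columns.
#'
#' @param path CSV file path.
#' @param resolution_mm Passed to [mean_diameter()].
#' @return A data.frame, one row per specimen.
#' @export
read_geometry_csv <- function(path, resolution_mm = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "group", "muscle", "specimen_type")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("geometry CSV missing columns: ", paste(missing, collapse = ", "))
  }
  tryCatch(derive_geometry(df, resolution_mm), error = function(e) {
    stop("geometry CSV missing columns: ", conditionMessage(e))
  })
}
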