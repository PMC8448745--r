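#' Labeled muscle section image
#'
#' Holds a binary collagen-I mask and an integer fiber-label raster of the
#' same dimensions (0 = background/ECM, k = fiber k), plus the pixel size.
#' Rasters are row-major matrices indexed `[row, col]`; polygon vertices
#' use (x = column, y = row) pixel coordinates with pixel centers at
#' integer positions.
#'
#' @param collagen_mask Logical or 0/1 matrix.
#' @param fiber_labels Integer matrix, same dim, values >= 0.
#' @param pixel_size_um Physical pixel size (um/pixel), default 1.
#' @return An object of class `section_image`.
#' @export
section_image <- function(collagen_mask, fiber_labels, pixel_size_um = 1) {
  collagen_mask <- matrix(as.logical(collagen_mask),
                          nrow = nrow(collagen_mask))
  if (!identical(dim(collagen_mask), dim(fiber_labels))) {
    stop("collagen mask and fiber labels must share dimensions")
  }
  if (any(fiber_labels < 0)) stop("fiber labels must be non-negative")
  stopifnot(pixel_size_um > 0)
  structure(
    list(collagen_mask = collagen_mask,
         fiber_labels = fiber_labels,
         pixel_size_um = pixel_size_um),
    class = "section_image"
  )
}

#' @export
print.section_image <- function(x, ...) {
  cat(sprintf("Section image %d x %d px (%.2f um/px): %d fibers, %.1f%% collagen-positive\n",
              nrow(x$collagen_mask), ncol(x$collagen_mask), x$pixel_size_um,
              length(setdiff(unique(as.vector(x$fiber_labels)), 0L)),
              100 * mean(x$collagen_mask)))
  invisible(x)
}

#' Paired internal/external bundle segmentation
#'
#' Two closed polygons outlining one bundle: the type-A border passes
#' internal to the edges of the boundary fibers, the type-B border passes
#' external to them, so the A region is nested inside the B region.
#'
#' @param polygon_A,polygon_B Two-column matrices (x, y) of vertices in
#'   pixel coordinates; closure is implicit (last vertex joins the first).
#' @return An object of class `bundle_segmentation`.
#' @export
bundle_segmentation <- function(polygon_A, polygon_B) {
  polygon_A <- as.matrix(polygon_A); polygon_B <- as.matrix(polygon_B)
  if (ncol(polygon_A) != 2L || ncol(polygon_B) != 2L) {
    stop("polygons must be two-column (x, y) matrices")
  }
  if (nrow(polygon_A) < 3L || nrow(polygon_B) < 3L) {
    stop("polygons need at least 3 vertices")
  }
  structure(list(polygon_A = polygon_A, polygon_B = polygon_B),
            class = "bundle_segmentation")
}

# Even-odd (crossing-number) point-in-polygon test for pixel centers,
# vectorized over points. Points exactly on an edge follow the half-open
# crossing rule, which keeps shared edges unambiguous.
points_in_polygon <- function(px, py, polygon) {
  vx <- polygon[, 1L]; vy <- polygon[, 2L]
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# logical matrix of pixels whose centers fall inside the polygon
.polygon_pixel_mask <- function(dim_img, polygon) {
  nr <- dim_img[1L]; nc <- dim_img[2L]
  px <- rep(seq_len(nc), each = nr)   # x = column
  py <- rep(seq_len(nr), times = nc)  # y = row
  matrix(points_in_polygon(px, py, polygon), nrow = nr, ncol = nc)
}

#' Collagen area fraction inside a polygon
#'
#' Collagen-positive pixels divided by all pixels whose centers fall
#' inside the polygon (even-odd rule).
#'
#' @param image A [section_image()].
#' @param polygon Two-column (x, y) vertex matrix.
#' @return Fraction in `[0, 1]`.
#' @export
polygon_area_fraction <- function(image, polygon) {
  m <- .polygon_pixel_mask(dim(image$collagen_mask), polygon)
  n_in <- sum(m)
  if (n_in == 0L) stop("polygon encloses no pixel centers")
  sum(image$collagen_mask & m) / n_in
}

#' Bundle collagen fraction from the two segmentations
#'
#' The A (internal) and B (external) borders bracket the true bundle
#' outline; their area fractions are averaged to estimate the bundle's
#' collagen-I content.
#'
#' @param frac_A,frac_B Area fractions from the type-A and type-B
#'   segmentations, both in `[0, 1]`.
#' @return Arithmetic mean of the two fractions.
#' @export
bundle_collagen_fraction <- function(frac_A, frac_B) {
  if (any(c(frac_A, frac_B) < 0) || any(c(frac_A, frac_B) > 1)) {
    stop("fractions must lie in [0, 1]")
  }
  (frac_A + frac_B) / 2
}

#' Count fibers inside a polygon
#'
#' A fiber belongs to the bundle when the majority of its labeled pixels
#' fall inside the polygon (collagen-I never occurs inside fibers, so
#' labeled fibers are directly countable).
#'
#' @param image A [section_image()].
#' @param polygon Two-column (x, y) vertex matrix.
#' @return Integer fiber count (possibly 0).
#' @export
count_fibers <- function(image, polygon) {
  m <- .polygon_pixel_mask(dim(image$fiber_labels), polygon)
  labs <- image$fiber_labels
  ids <- setdiff(unique(as.vector(labs)), 0L)
  sum(vapply(ids, function(k) {
    tot <- sum(labs == k)
    inside <- sum(labs == k & m)
    inside > tot / 2
  }, logical(1)))
}

#' Measure one bundle from a section image
#'
#' Applies both segmentations, averages their collagen fractions, and
#' counts fibers inside the external (type-B) border.
#'
#' @param image A [section_image()].
#' @param seg A [bundle_segmentation()].
#' @return List with `frac_A`, `frac_B`, `collagen_fraction`, `n_fibers`.
#' @export
measure_bundle <- function(image, seg) {
  fa <- polygon_area_fraction(image, seg$polygon_A)
  fb <- polygon_area_fraction(image, seg$polygon_B)
  list(frac_A = fa, frac_B = fb,
       collagen_fraction = bundle_collagen_fraction(fa, fb),
       n_fibers = count_fibers(image, seg$polygon_B))
}

#' Read a section image from mask and label rasters
#'
#' Accepts PNG or TIFF files; the collagen mask is binarized at 0.5 and
#' label values are rounded to integers (labels are stored as intensity
#' k/255 in 8-bit files written by [write_section_image()]).
#'
#' @param mask_path Path to the binary collagen mask (PNG/TIFF).
#' @param labels_path Path to the integer fiber-label raster (PNG/TIFF).
#' @param pixel_size_um Pixel size (um/pixel).
#' @return A [section_image()].
#' @export
read_section_image <- function(mask_path, labels_path, pixel_size_um = 1) {
  mask <- .read_raster(mask_path)
  labs <- .read_raster(labels_path)
  section_image(mask > 0.5, matrix(as.integer(round(labs * 255)),
                                   nrow = nrow(labs)),
                pixel_size_um)
}

#' Write a section image to PNG rasters
#'
#' @param image A [section_image()].
#' @param mask_path,labels_path Output PNG paths. Labels are encoded as
#'   intensity k/255, limiting files to 255 fibers.
#' @export
write_section_image <- function(image, mask_path, labels_path) {
  png::writePNG(image$collagen_mask * 1, mask_path)
  if (max(image$fiber_labels) > 255) stop("more than 255 fiber labels")
  png::writePNG(image$fiber_labels / 255, labels_path)
}

.read_raster <- function(path) {
  img <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img
}

#' Read polygons from a CSV vertex list
#'
#' Expects columns `polygon` (identifier, e.g. "A"/"B"), `x_px`, `y_px`.
#'
#' @param path CSV file path.
#' @return Named list of two-column vertex matrices.
#' @export
read_polygons_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("polygon", "x_px", "y_px")
  if (!all(need %in% names(df))) {
    stop("polygon CSV must have columns: ", paste(need, collapse = ", "))
  }
  lapply(split(df, df$polygon), function(d) {
    cbind(x = d$x_px, y = d$y_px)
  })
}
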