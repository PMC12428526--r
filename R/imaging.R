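#' Pixel calibration for a plankton scanner
#'
#' The scanner digitises at a fixed optical resolution, so one pixel side
#' corresponds to a known physical length. The default, 10.58 µm per pixel,
#' is the standard calibration for ZooScan-class instruments at 2400 dpi.
#'
#' @param pixel_pitch_um Physical size of one pixel side, in micrometres.
#'   Must be a single positive number.
#' @return An object of class `pixel_calibration`.
#' @export
#' @examples
#' cal <- pixel_calibration()
#' area_px_to_mm2(10000, cal) # 1.11935 mm^2
pixel_calibration <- function(pixel_pitch_um = 10.58) {
  if (!is.numeric(pixel_pitch_um) || length(pixel_pitch_um) != 1 ||
      !is.finite(pixel_pitch_um) || pixel_pitch_um <= 0) {
    stop("`pixel_pitch_um` must be a single positive number", call. = FALSE)
  }
  structure(list(pixel_pitch_um = pixel_pitch_um), class = "pixel_calibration")
}

#' @export
print.pixel_calibration <- function(x, ...) {
  cat("Pixel calibration:", x$pixel_pitch_um, "µm per pixel\n")
  invisible(x)
}

as_pixel_calibration <- function(cal) {
  if (inherits(cal, "pixel_calibration")) return(cal)
  pixel_calibration(cal)
}

#' Convert a pixel area to square millimetres
#'
#' @param area_px Object area as a count of foreground pixels (may be a
#'   vector). Must be non-negative.
#' @param cal A [pixel_calibration()], or a bare pixel pitch in µm.
#' @return Area in mm².
#' @export
area_px_to_mm2 <- function(area_px, cal = pixel_calibration()) {
  cal <- as_pixel_calibration(cal)
  if (any(!is.finite(area_px)) || any(area_px < 0)) {
    stop("`area_px` must be non-negative and finite", call. = FALSE)
  }
  area_px * (cal$pixel_pitch_um / 1000)^2
}

#' Equivalent spherical diameter from a projected area
#'
#' ESD is the diameter of the circle with the same area as the object's
#' 2-D silhouette: ESD = 2 * sqrt(A / pi), in mm when A is in mm².
#'
#' @param area_mm2 Projected ("area excluded") object area in mm²; vectorised.
#' @return ESD in mm.
#' @export
esd_from_area <- function(area_mm2) {
  if (any(!is.finite(area_mm2)) || any(area_mm2 < 0)) {
    stop("`area_mm2` must be non-negative and finite", call. = FALSE)
  }
  2 * sqrt(area_mm2 / pi)
}

#' Spherical biovolume from ESD
#'
#' Biovolume is the volume of the sphere whose diameter equals the ESD:
#' (4/3) * pi * (ESD/2)^3, in mm³.
#'
#' @param esd_mm Equivalent spherical diameter in mm; vectorised.
#' @return Biovolume in mm³.
#' @export
biovolume_from_esd <- function(esd_mm) {
  if (any(!is.finite(esd_mm)) || any(esd_mm < 0)) {
    stop("`esd_mm` must be non-negative and finite", call. = FALSE)
  }
  (4 / 3) * pi * (esd_mm / 2)^3
}

#' Read a grayscale scan image
#'
#' Reads PNG or TIFF into a plain numeric matrix (rows = image rows, i.e.
#' height; columns = width) with intensities on the 0–255 scale. RGB input
#' is converted by Rec. 601 luminance.
#'
#' @param path Path to a PNG or TIFF file.
#' @return A numeric `height x width` matrix with values in [0, 255].
#' @export
read_gray_image <- function(path) {
  img <- EBImage::readImage(path)
  if (EBImage::colorMode(img) == EBImage::Color) {
    img <- EBImage::channel(img, "luminance")
  }
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) > 2) dat <- dat[, , 1]
  # EBImage stores (x, y): transpose to the row-major height x width convention
  t(dat) * 255
}

#' Write a grayscale image matrix to PNG
#'
#' @param image Numeric matrix with values in [0, 255].
#' @param path Output path; format follows the extension (.png or .tif/.tiff).
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(image, path) {
  check_gray_image(image)
  type <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "png"
  EBImage::writeImage(EBImage::Image(t(image) / 255), path, type = type)
  invisible(path)
}

check_gray_image <- function(image) {
  if (!is.matrix(image) || !is.numeric(image) || nrow(image) < 1 || ncol(image) < 1) {
    stop("image must be a non-empty numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(image)) || any(image < 0) || any(image > 255)) {
    stop("image intensities must lie in [0, 255]", call. = FALSE)
  }
  invisible(image)
}

# 8-connected component labelling (two-pass union-find). Returns an integer
# matrix; labels are assigned in raster-scan (row-major) order of each
# component's first pixel, so label 1 is the component whose topmost-leftmost
# pixel comes first.
label_components_8 <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  fg <- which(mask)                       # column-major linear indices
  out <- matrix(0L, nr, nc)
  if (length(fg) == 0L) return(out)

  id <- integer(nr * nc)                  # fg pixel -> provisional label
  id[fg] <- seq_along(fg)
  parent <- seq_along(fg)

  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }

  rr <- ((fg - 1L) %% nr) + 1L
  cc <- ((fg - 1L) %/% nr) + 1L
  # forward neighbours: E, S, SE, NE (covers all 8-neighbour adjacencies once)
  shifts <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(-1L, 1L))
  for (sh in shifts) {
    rn <- rr + sh[1]
    cn <- cc + sh[2]
    ok <- rn >= 1L & rn <= nr & cn >= 1L & cn <= nc
    nb <- (cn[ok] - 1L) * nr + rn[ok]
    a <- id[fg[ok]]
    b <- id[nb]
    hit <- b > 0L
    a <- a[hit]
    b <- b[hit]
    for (k in seq_along(a)) {
      ra <- find_root(a[k])
      rb <- find_root(b[k])
      if (ra != rb) parent[rb] <- ra
    }
  }

  root <- vapply(seq_along(fg), find_root, integer(1))
  # rank components by the raster-scan position of their first pixel
  raster_key <- (rr - 1L) * nc + (cc - 1L)
  first_key <- tapply(raster_key, root, min)
  ord <- rank(first_key)
  relabel <- integer(max(root))
  relabel[as.integer(names(first_key))] <- as.integer(ord)
  out[fg] <- relabel[root]
  out
}

#' Segment dark objects out of a grayscale scan
#'
#' Emulates the measurement stage of plankton-scanner processing: optional
#' background subtraction, global thresholding (Otsu by default), and
#' 8-connected component labelling of the dark foreground. Components
#' smaller than `min_area_px` are discarded as noise specks.
#'
#' Objects are assumed dark on a light background (scanner transparency
#' convention). With a `background` scan, segmentation thresholds the
#' difference `background - image`, which cancels illumination structure.
#'
#' @param image Numeric `height x width` matrix, intensities in [0, 255].
#' @param background Optional background scan, same shape as `image`.
#' @param threshold `"otsu"` (default) or a fixed numeric cut on the 0–255
#'   scale. With a background, the cut applies to `background - image`
#'   (foreground above the cut); without, to `image` (foreground below).
#' @param min_area_px Minimum component area kept, in pixels. The default,
#'   30 px, corresponds to about 0.34 mm ESD at the default calibration —
#'   just under a 335-µm net mesh, so nothing a net retains is dropped.
#' @return A tibble with one row per object: `label_id`, `area_px`,
#'   half-open 0-based bounding box (`row_min`, `row_max`, `col_min`,
#'   `col_max`), centroid (`centroid_row`, `centroid_col`, 0-based), and
#'   `border_flag` (TRUE when the object touches the image edge). Zero rows
#'   when nothing is found.
#' @export
segment_objects <- function(image, background = NULL, threshold = "otsu",
                            min_area_px = 30) {
  check_gray_image(image)
  if (!is.null(background)) {
    check_gray_image(background)
    if (!identical(dim(image), dim(background))) {
      stop("image and background have different shapes", call. = FALSE)
    }
    signal <- pmax(background - image, 0)   # dark objects -> high signal
    dark_is_high <- TRUE
  } else {
    signal <- image
    dark_is_high <- FALSE
  }

  if (identical(threshold, "otsu")) {
    if (diff(range(signal)) < 1e-9) {
      # featureless image: nothing to segment
      return(empty_regions())
    }
    thr <- EBImage::otsu(EBImage::Image(t(signal) / 255),
                         range = c(0, 1), levels = 256) * 255
    # Otsu always splits, even pure noise: accept the split only if the two
    # classes are well separated. Splitting a unimodal Gaussian at its mean
    # gives separation/within-class-sd ~ 2.7; real dark objects on a light
    # background give 10x that.
    lo <- signal[signal <= thr]
    hi <- signal[signal > thr]
    if (length(lo) < 2 || length(hi) < 2) return(empty_regions())
    within <- sqrt((sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)) /
                     length(signal))
    if ((mean(hi) - mean(lo)) < 4 * within) return(empty_regions())
  } else if (is.numeric(threshold) && length(threshold) == 1) {
    thr <- threshold
  } else {
    stop("`threshold` must be \"otsu\" or a single number", call. = FALSE)
  }

  mask <- if (dark_is_high) signal > thr else signal < thr
  if (!any(mask)) return(empty_regions())

  lab <- label_components_8(mask)
  nr <- nrow(lab)
  nc <- ncol(lab)
  fg <- which(lab > 0L)
  labv <- lab[fg]
  rr <- ((fg - 1L) %% nr) + 1L
  cc <- ((fg - 1L) %/% nr) + 1L

  area <- tabulate(labv)
  keep <- which(area >= min_area_px)
  if (length(keep) == 0L) return(empty_regions())

  stats <- tibble::tibble(
    label_id = keep,
    area_px = area[keep],
    row_min = as.integer(tapply(rr, labv, min)[as.character(keep)]) - 1L,
    row_max = as.integer(tapply(rr, labv, max)[as.character(keep)]),
    col_min = as.integer(tapply(cc, labv, min)[as.character(keep)]) - 1L,
    col_max = as.integer(tapply(cc, labv, max)[as.character(keep)]),
    centroid_row = as.numeric(tapply(rr, labv, mean)[as.character(keep)]) - 1,
    centroid_col = as.numeric(tapply(cc, labv, mean)[as.character(keep)]) - 1
  )
  stats$border_flag <- stats$row_min == 0L | stats$col_min == 0L |
    stats$row_max == nr | stats$col_max == nc
  # compact labels after the size filter, preserving raster order
  stats$label_id <- seq_len(nrow(stats))
  stats
}

empty_regions <- function() {
  tibble::tibble(
    label_id = integer(), area_px = integer(),
    row_min = integer(), row_max = integer(),
    col_min = integer(), col_max = integer(),
    centroid_row = numeric(), centroid_col = numeric(),
    border_flag = logical()
  )
}

#' Calibrated measurements for segmented objects
#'
#' Adds physical measurements — area in mm², ESD and spherical biovolume —
#' to a table of segmented regions.
#'
#' @param regions Output of [segment_objects()].
#' @param cal A [pixel_calibration()].
#' @return The input tibble with `area_mm2`, `esd_mm` and `biovolume_mm3`
#'   columns appended.
#' @export
measure_objects <- function(regions, cal = pixel_calibration()) {
  cal <- as_pixel_calibration(cal)
  regions$area_mm2 <- area_px_to_mm2(regions$area_px, cal)
  regions$esd_mm <- esd_from_area(regions$area_mm2)
  regions$biovolume_mm3 <- biovolume_from_esd(regions$esd_mm)
  regions
}
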