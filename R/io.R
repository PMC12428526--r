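#' Column dialect for per-object detection tables
#'
#' Detection tables are tab-separated exports in the style of web
#' annotation platforms for plankton images: one row per segmented object,
#' with the object's pixel area and its taxonomic annotation. Real exports
#' carry dozens of columns; the dialect maps only the ones this analysis
#' needs, and every unmapped column is passed through untouched.
#'
#' @param object_id,area_px,species,stage,sample_id Column names in the
#'   file for the corresponding fields. `stage` may be absent in the file.
#' @return A `detection_dialect` list.
#' @export
detection_dialect <- function(object_id = "object_id",
                              area_px = "area_px",
                              species = "species",
                              stage = "stage",
                              sample_id = "sample_id") {
  structure(list(object_id = object_id, area_px = area_px,
                 species = species, stage = stage, sample_id = sample_id),
            class = "detection_dialect")
}

#' Read a per-object detection table
#'
#' Reads a TSV of segmented-object annotations, validates it, and derives
#' the physical measurements (area mm², ESD, biovolume) from the pixel
#' area when they are not already present.
#'
#' @param path Path to a tab-separated UTF-8 file.
#' @param dialect A [detection_dialect()] mapping file columns to fields.
#' @param cal A [pixel_calibration()] used when deriving measurements.
#' @return A tibble of detections: `object_id`, `sample_id`, `species`,
#'   `stage` (NA if absent), `area_px`, `area_mm2`, `esd_mm`,
#'   `biovolume_mm3`, plus any passthrough columns.
#' @export
read_detection_table <- function(path, dialect = detection_dialect(),
                                 cal = pixel_calibration()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")

  required <- c("object_id", "species", "sample_id")
  for (field in required) {
    col <- dialect[[field]]
    if (!col %in% names(raw)) {
      stop("detection table is missing required column `", col,
           "` (field ", field, ")", call. = FALSE)
    }
  }
  has_size <- dialect$area_px %in% names(raw) ||
    any(c("area_mm2", "esd_mm") %in% names(raw))
  if (!has_size) {
    stop("detection table needs a size column: `", dialect$area_px,
         "` (pixels), `area_mm2` or `esd_mm`", call. = FALSE)
  }

  out <- raw
  for (field in c("object_id", "area_px", "species", "stage", "sample_id")) {
    col <- dialect[[field]]
    if (col %in% names(raw) && col != field) {
      names(out)[names(out) == col] <- field
    }
  }
  if (!"stage" %in% names(out)) out$stage <- NA_character_

  if ("area_px" %in% names(out)) {
    if (!is.numeric(out$area_px)) {
      stop("column `", dialect$area_px, "` must be numeric", call. = FALSE)
    }
    bad <- which(!is.finite(out$area_px) | out$area_px < 0)
    if (length(bad)) {
      stop("negative or missing area in column `", dialect$area_px,
           "`, row ", bad[1], call. = FALSE)
    }
    if (!"area_mm2" %in% names(out)) {
      out$area_mm2 <- area_px_to_mm2(out$area_px, cal)
    }
  } else if (!"area_mm2" %in% names(out)) {
    out$area_mm2 <- pi * (out$esd_mm / 2)^2
  }
  if (!"esd_mm" %in% names(out)) out$esd_mm <- esd_from_area(out$area_mm2)
  if (!"biovolume_mm3" %in% names(out)) {
    out$biovolume_mm3 <- biovolume_from_esd(out$esd_mm)
  }
  front <- intersect(c("object_id", "sample_id", "species", "stage", "area_px",
                       "area_mm2", "esd_mm", "biovolume_mm3"), names(out))
  dplyr::relocate(out, dplyr::all_of(front))
}

# normalise numeric columns to 6 significant digits so that write -> read
# -> write round-trips byte-identically
signif_cols <- function(df, digits = 6) {
  plain_double <- function(x) is.double(x) && is.null(attributes(x))
  dplyr::mutate(df, dplyr::across(dplyr::where(plain_double),
                                  ~ signif(.x, digits)))
}

#' Write a detection table
#'
#' Tab-separated UTF-8; doubles are written at 6 significant digits so a
#' write–read–write cycle is byte-identical.
#'
#' @param detections Detection tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_detection_table <- function(detections, path) {
  readr::write_tsv(signif_cols(detections), path)
  invisible(path)
}

#' Read tow metadata
#'
#' Reads a TSV describing one net-layer sample per row: sample id, date,
#' day/night flag, layer bounds, filtered volume and aliquot fraction
#' (accepted as a number or a "1/8"-style ratio). The layer scheme of each
#' tow (date × day/night) is validated: ordered from the surface down,
#' non-overlapping, positive thickness.
#'
#' @param path Path to a tab-separated file.
#' @return A tibble with columns `sample_id`, `date`, `day_night`, `top_m`,
#'   `bottom_m`, `filtered_volume_m3`, `aliquot_fraction` (numeric), plus
#'   any extra columns present.
#' @export
read_tow_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  need <- c("sample_id", "date", "day_night", "top_m", "bottom_m",
            "filtered_volume_m3", "aliquot_fraction")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("tow metadata missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  raw$aliquot_fraction <- parse_fraction(raw$aliquot_fraction)
  if (!all(raw$day_night %in% c("D", "N"))) {
    stop("day_night must be \"D\" or \"N\"", call. = FALSE)
  }
  check_tow_metadata(raw)
  split(seq_len(nrow(raw)),
        paste(raw$date, raw$day_night)) |>
    lapply(function(i) validate_layers(dplyr::arrange(raw[i, ], .data$top_m)))
  raw
}

parse_fraction <- function(x) {
  if (is.numeric(x)) return(x)
  vapply(as.character(x), function(s) {
    if (grepl("^\\s*\\d+\\s*/\\s*\\d+\\s*$", s)) {
      parts <- as.numeric(strsplit(s, "/")[[1]])
      parts[1] / parts[2]
    } else {
      as.numeric(s)
    }
  }, numeric(1), USE.NAMES = FALSE)
}

#' Write tow metadata
#'
#' @param metas Tow metadata tibble.
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_tow_metadata <- function(metas, path) {
  readr::write_tsv(signif_cols(metas), path)
  invisible(path)
}

#' The packaged stratified-tow metadata fixture
#'
#' Eight day/night tows (October, February, April, July; one day and one
#' night tow each) over the standard eight-layer 0–1,000 m scheme, with the
#' published tow dates and day/night flags. Per-layer filtered volumes were
#' not published, so the fixture carries synthetic volumes (6 m³ per metre
#' of layer thickness); aliquot fractions span the realistic 1/2–1/128
#' range, richer shallow samples being split harder.
#'
#' @return Tow metadata tibble, 64 rows.
#' @export
k2_tow_metadata <- function() {
  read_tow_metadata(system.file("extdata", "tow_metadata_k2.tsv",
                                package = "zooscanr"))
}

#' Run configuration
#'
#' Bundles the tunable settings of a pipeline run so they can be serialized
#' next to the outputs for provenance and re-running.
#'
#' @param pixel_pitch_um Scanner calibration, µm per pixel.
#' @param bin_width_mm ESD histogram bin width, mm.
#' @param min_area_px Segmentation minimum object area, px.
#' @param ambiguity_ratio Stage-classifier ambiguity threshold.
#' @param metridia_threshold_mm ESD split between *M. pacifica* and the
#'   large congeners, mm.
#' @param seed Integer seed for stochastic stages.
#' @return A `run_config` list.
#' @export
run_config <- function(pixel_pitch_um = 10.58, bin_width_mm = 0.1,
                       min_area_px = 30, ambiguity_ratio = 3,
                       metridia_threshold_mm = 2, seed = 1L) {
  cfg <- list(pixel_pitch_um = pixel_pitch_um, bin_width_mm = bin_width_mm,
              min_area_px = min_area_px, ambiguity_ratio = ambiguity_ratio,
              metridia_threshold_mm = metridia_threshold_mm,
              seed = as.integer(seed))
  stopifnot(cfg$pixel_pitch_um > 0, cfg$bin_width_mm > 0,
            cfg$min_area_px >= 0, cfg$ambiguity_ratio >= 1,
            cfg$metridia_threshold_mm > 0)
  structure(cfg, class = "run_config")
}

#' Write / read a run configuration (YAML)
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `write_run_config`: `path` invisibly; `read_run_config`: a
#'   `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}
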