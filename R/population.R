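#' The standard eight-layer depth scheme
#'
#' The stratified net samples the 0–1,000 m water column in eight discrete
#' layers: 0–50, 50–100, 100–150, 150–200, 200–300, 300–500, 500–750 and
#' 750–1,000 m. Depth is metres below the surface, positive downward.
#'
#' @return A tibble with columns `top_m` and `bottom_m`, one row per layer,
#'   ordered from the surface down.
#' @export
standard_layers <- function() {
  tibble::tibble(
    top_m    = c(0, 50, 100, 150, 200, 300, 500, 750),
    bottom_m = c(50, 100, 150, 200, 300, 500, 750, 1000)
  )
}

#' Validate a depth-layer scheme
#'
#' Checks that layers have positive thickness, are ordered from the surface
#' down, and do not overlap.
#'
#' @param layers Tibble with `top_m` and `bottom_m` columns.
#' @return `layers`, invisibly; errors otherwise.
#' @export
validate_layers <- function(layers) {
  if (!all(c("top_m", "bottom_m") %in% names(layers))) {
    stop("layer scheme needs `top_m` and `bottom_m` columns", call. = FALSE)
  }
  if (any(layers$top_m < 0) || any(layers$bottom_m <= layers$top_m)) {
    stop("each layer needs 0 <= top_m < bottom_m", call. = FALSE)
  }
  if (nrow(layers) > 1) {
    if (is.unsorted(layers$top_m, strictly = TRUE)) {
      stop("layers must be ordered from the surface down", call. = FALSE)
    }
    if (any(layers$top_m[-1] < layers$bottom_m[-nrow(layers)])) {
      stop("layers overlap", call. = FALSE)
    }
  }
  invisible(layers)
}

#' Whole-sample concentration from an aliquot count
#'
#' A net sample is split into an aliquot (1/2 ... 1/128 of the sample)
#' before scanning; counts are scaled back by the aliquot fraction and
#' divided by the seawater volume the net filtered:
#' `conc = (count / aliquot_fraction) / filtered_volume_m3`.
#' The same arithmetic applies to a summed biovolume per aliquot, giving
#' mm³ m⁻³.
#'
#' @param count Individuals counted (or biovolume summed) in the aliquot;
#'   vectorised.
#' @param aliquot_fraction Scanned fraction of the sample, in (0, 1].
#' @param filtered_volume_m3 Volume filtered by the net, m³ (> 0).
#' @return Concentration per m³.
#' @export
concentration <- function(count, aliquot_fraction, filtered_volume_m3) {
  if (any(count < 0)) stop("`count` must be non-negative", call. = FALSE)
  if (any(aliquot_fraction <= 0) || any(aliquot_fraction > 1)) {
    stop("`aliquot_fraction` must lie in (0, 1]", call. = FALSE)
  }
  if (any(filtered_volume_m3 <= 0)) {
    stop("`filtered_volume_m3` must be positive", call. = FALSE)
  }
  (count / aliquot_fraction) / filtered_volume_m3
}

#' Depth-integrate a concentration over its layer
#'
#' Multiplying a per-m³ concentration by the tow's vertical extent — the
#' layer thickness, `bottom_m - top_m` — gives the areal quantity per m² of
#' sea surface contributed by that layer.
#'
#' @param conc Concentration per m³; vectorised.
#' @param top_m,bottom_m Layer bounds in m, `top_m < bottom_m`.
#' @return Areal quantity per m².
#' @export
areal_from_concentration <- function(conc, top_m, bottom_m) {
  thickness <- bottom_m - top_m
  if (any(top_m < 0) || any(thickness <= 0)) {
    stop("layers need 0 <= top_m < bottom_m", call. = FALSE)
  }
  conc * thickness
}

check_tow_metadata <- function(metas) {
  need <- c("sample_id", "day_night", "top_m", "bottom_m",
            "filtered_volume_m3", "aliquot_fraction")
  miss <- setdiff(need, names(metas))
  if (length(miss)) {
    stop("tow metadata missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(metas$sample_id)) {
    stop("duplicate sample_id in tow metadata", call. = FALSE)
  }
  if (any(metas$filtered_volume_m3 <= 0)) {
    stop("filtered_volume_m3 must be positive", call. = FALSE)
  }
  if (any(metas$aliquot_fraction <= 0) || any(metas$aliquot_fraction > 1)) {
    stop("aliquot_fraction must lie in (0, 1]", call. = FALSE)
  }
  invisible(metas)
}

#' Depth-stratified abundance or biovolume profile
#'
#' Turns per-object detections plus tow metadata into a vertical profile:
#' per layer, the aliquot- and volume-corrected concentration (per m³), the
#' depth-integrated areal quantity (per m²), and the layer's share of the
#' water-column total. The column total integrates the areal values across
#' all sampled layers.
#'
#' Layers present in the metadata but with no detections are genuine zeros;
#' a profile is only built from the layers that were actually sampled, and
#' by default the metadata must cover the water column contiguously from
#' the shallowest top to the deepest bottom (set `allow_partial = TRUE` to
#' integrate over partial coverage).
#'
#' @param detections Tibble with at least `sample_id`; `species`, `stage`
#'   and `biovolume_mm3` are used when filtering/summing.
#' @param metas Tow metadata tibble (one row per net-layer sample):
#'   `sample_id`, `day_night`, `top_m`, `bottom_m`, `filtered_volume_m3`,
#'   `aliquot_fraction`.
#' @param measure `"abundance"` (counts) or `"biovolume"` (summed per-object
#'   spherical biovolume, mm³).
#' @param species,stage Optional filters on the detections.
#' @param day_night Optional `"D"`/`"N"` filter applied to both metadata and
#'   (via the sample link) detections.
#' @param allow_partial Allow a layer scheme that does not tile the water
#'   column contiguously.
#' @return A `vertical_profile`: a tibble with one row per sampled layer
#'   (`top_m`, `bottom_m`, `count`, `conc`, `areal`, `fraction`) carrying
#'   attributes `column_total` (per m²) and `measure`.
#' @export
build_profile <- function(detections, metas,
                          measure = c("abundance", "biovolume"),
                          species = NULL, stage = NULL, day_night = NULL,
                          allow_partial = FALSE) {
  measure <- match.arg(measure)
  check_tow_metadata(metas)
  known_samples <- metas$sample_id
  if (!is.null(day_night)) {
    metas <- dplyr::filter(metas, .data$day_night == !!day_night)
    if (nrow(metas) == 0) stop("no tow metadata for day_night = ", day_night,
                               call. = FALSE)
  }
  metas <- dplyr::arrange(metas, .data$top_m)
  validate_layers(metas)
  if (!allow_partial && nrow(metas) > 1 &&
      any(metas$top_m[-1] != metas$bottom_m[-nrow(metas)])) {
    stop("layer coverage has gaps; use allow_partial = TRUE to integrate anyway",
         call. = FALSE)
  }

  if (!is.null(species)) {
    detections <- dplyr::filter(detections, .data$species %in% !!species)
  }
  if (!is.null(stage)) {
    detections <- dplyr::filter(detections, .data$stage %in% !!stage)
  }
  orphans <- setdiff(unique(detections$sample_id), known_samples)
  if (length(orphans)) {
    stop("detections reference unknown sample_id: ",
         paste(utils::head(orphans, 3), collapse = ", "), call. = FALSE)
  }
  detections <- dplyr::filter(detections, .data$sample_id %in% metas$sample_id)

  per_sample <- if (measure == "abundance") {
    dplyr::count(detections, .data$sample_id, name = "value")
  } else {
    if (!"biovolume_mm3" %in% names(detections)) {
      stop("biovolume profiles need a `biovolume_mm3` column", call. = FALSE)
    }
    dplyr::summarise(dplyr::group_by(detections, .data$sample_id),
                     value = sum(.data$biovolume_mm3), .groups = "drop")
  }

  prof <- metas |>
    dplyr::left_join(per_sample, by = "sample_id") |>
    dplyr::mutate(
      count = ifelse(is.na(.data$value), 0, .data$value),
      conc = concentration(.data$count, .data$aliquot_fraction,
                           .data$filtered_volume_m3),
      areal = areal_from_concentration(.data$conc, .data$top_m, .data$bottom_m)
    ) |>
    dplyr::select(dplyr::all_of(c("sample_id", "top_m", "bottom_m",
                                  "count", "conc", "areal")))

  column_total <- sum(prof$areal)
  prof$fraction <- if (column_total > 0) prof$areal / column_total else
    rep(NA_real_, nrow(prof))

  structure(prof,
            class = c("vertical_profile", class(prof)),
            column_total = column_total,
            measure = measure)
}

#' @export
print.vertical_profile <- function(x, ...) {
  cat(sprintf("Vertical profile (%s): column total %.4g per m2\n",
              attr(x, "measure"), attr(x, "column_total")))
  NextMethod()
}

#' Column total of a vertical profile
#'
#' @param profile A `vertical_profile`.
#' @return The water-column integrated quantity, per m².
#' @export
column_total <- function(profile) {
  attr(profile, "column_total")
}

#' Abundance-weighted mean depth
#'
#' The standard single-number summary of a vertical distribution: the
#' areal-abundance-weighted mean of the layer midpoints,
#' `WMD = sum(midpoint * areal) / sum(areal)`. Resolution is limited by the
#' layer scheme — all mass inside a layer is treated as sitting at its
#' midpoint.
#'
#' @param profile A `vertical_profile` with a positive column total.
#' @return Depth in m.
#' @export
weighted_mean_depth <- function(profile) {
  total <- attr(profile, "column_total")
  if (is.null(total) || !is.finite(total) || total <= 0) {
    stop("weighted mean depth is undefined for an empty profile", call. = FALSE)
  }
  mid <- (profile$top_m + profile$bottom_m) / 2
  sum(mid * profile$areal) / total
}

#' Diel vertical migration amplitude
#'
#' The day-minus-night difference in weighted mean depth. Positive values
#' mean the population sits deeper by day and ascends at night — the diel
#' vertical migration (DVM) signature. Values near zero mean no diel change,
#' as for a seasonal (ontogenetic) migrant.
#'
#' @param day,night `vertical_profile`s over the same layer scheme.
#' @return Depth difference in m (positive = nocturnal ascent).
#' @export
dvm_amplitude <- function(day, night) {
  if (nrow(day) != nrow(night) ||
      !isTRUE(all.equal(day$top_m, night$top_m)) ||
      !isTRUE(all.equal(day$bottom_m, night$bottom_m))) {
    stop("day and night profiles use different layer schemes", call. = FALSE)
  }
  weighted_mean_depth(day) - weighted_mean_depth(night)
}
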