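#' Per-stage ESD reference table
#'
#' Loads a copepodite-stage ESD reference: for each species and stage
#' (C1, C2, C3, C4F, C4M, C5F, C5M, C6F, C6M), the mean and standard
#' deviation of the equivalent spherical diameter in mm, measured on
#' stage-sorted individuals. The packaged default covers *Metridia
#' pacifica* and *Eucalanus bungii*.
#'
#' @param path Path to a TSV with columns `species`, `stage`,
#'   `mean_esd_mm`, `sd_esd_mm`. Defaults to the packaged table.
#' @return A tibble, validated: positive means, strictly positive sds.
#' @export
stage_reference <- function(path = system.file("extdata",
                                               "stage_reference_table.tsv",
                                               package = "zooscanr")) {
  ref <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  need <- c("species", "stage", "mean_esd_mm", "sd_esd_mm")
  miss <- setdiff(need, names(ref))
  if (length(miss)) {
    stop("stage reference missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(ref$mean_esd_mm <= 0)) {
    stop("stage reference means must be positive", call. = FALSE)
  }
  if (any(ref$sd_esd_mm <= 0)) {
    stop("stage reference sds must be strictly positive", call. = FALSE)
  }
  if (anyDuplicated(ref[c("species", "stage")])) {
    stop("duplicated species/stage rows in stage reference", call. = FALSE)
  }
  ref
}

#' Build a stage reference from stage-sorted measurements
#'
#' Computes, per species and stage, the sample mean and sample standard
#' deviation (n − 1 denominator) of measured ESDs — the calculation done on
#' stage-sorted scan measurements to calibrate the reference table.
#'
#' @param measurements Tibble with columns `species`, `stage`, `esd_mm`.
#' @return A stage-reference tibble (`species`, `stage`, `n`, `mean_esd_mm`,
#'   `sd_esd_mm`). Errors if any stage has fewer than two measurements;
#'   warns if a stage has zero spread (a degenerate reference row).
#' @export
stage_reference_from_measurements <- function(measurements) {
  need <- c("species", "stage", "esd_mm")
  miss <- setdiff(need, names(measurements))
  if (length(miss)) {
    stop("measurements missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ref <- measurements |>
    dplyr::group_by(.data$species, .data$stage) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_esd_mm = mean(.data$esd_mm),
      sd_esd_mm = stats::sd(.data$esd_mm),
      .groups = "drop"
    )
  if (any(ref$n < 2)) {
    bad <- ref[ref$n < 2, ]
    stop("need at least 2 measurements per stage; got ", bad$n[1], " for ",
         bad$species[1], " ", bad$stage[1], call. = FALSE)
  }
  if (any(ref$sd_esd_mm == 0)) {
    warning("zero ESD spread for some stage(s); reference sd must be positive",
            call. = FALSE)
  }
  ref
}

#' Assign copepodite stages from ESD
#'
#' A Gaussian maximum-posterior stand-in for microscope staging: each
#' candidate stage s of the species contributes a likelihood
#' Normal(esd; mean_s, sd_s), and with equal priors the posterior is the
#' normalised likelihood. The stage with the highest posterior is assigned.
#'
#' ESD alone cannot separate late stages whose size ranges overlap (for
#' *E. bungii*, C4F/C4M, and C5F/C5M against small adult C6M), so instead of
#' collapsing them the assignment carries an `ambiguous` flag, raised when
#' the best posterior is less than `ambiguity_ratio` times the runner-up.
#'
#' @param esd_mm ESD values in mm (vectorised); must be positive.
#' @param species Species label, matching the reference table.
#' @param ref Stage reference tibble, default the packaged table.
#' @param ambiguity_ratio Top-two posterior ratio below which the call is
#'   flagged ambiguous; default 3.
#' @return A tibble with one row per input: `esd_mm`, `stage`, `posterior`
#'   (of the assigned stage), `runner_up`, `posterior_ratio`, `ambiguous`.
#'   The full posterior matrix (rows = inputs, columns = stages) is attached
#'   as attribute `"posteriors"`.
#' @export
classify_stage <- function(esd_mm, species, ref = stage_reference(),
                           ambiguity_ratio = 3) {
  rows <- ref[ref$species == species, ]
  if (nrow(rows) == 0) {
    stop("species not in stage reference: ", species, call. = FALSE)
  }
  if (any(!is.finite(esd_mm)) || any(esd_mm <= 0)) {
    stop("`esd_mm` must be positive", call. = FALSE)
  }
  lik <- vapply(seq_len(nrow(rows)), function(i) {
    stats::dnorm(esd_mm, rows$mean_esd_mm[i], rows$sd_esd_mm[i])
  }, numeric(length(esd_mm)))
  lik <- matrix(lik, nrow = length(esd_mm),
                dimnames = list(NULL, rows$stage))
  post <- lik / rowSums(lik)

  best <- max.col(post, ties.method = "first")
  top <- post[cbind(seq_along(esd_mm), best)]
  second_val <- vapply(seq_along(esd_mm), function(i) {
    if (ncol(post) < 2) return(NA_real_)
    max(post[i, -best[i]])
  }, numeric(1))
  second_idx <- vapply(seq_along(esd_mm), function(i) {
    if (ncol(post) < 2) return(NA_integer_)
    cand <- seq_len(ncol(post))[-best[i]]
    cand[which.max(post[i, -best[i]])]
  }, integer(1))

  ratio <- top / second_val
  out <- tibble::tibble(
    esd_mm = esd_mm,
    species = species,
    stage = rows$stage[best],
    posterior = top,
    runner_up = rows$stage[second_idx],
    posterior_ratio = ratio,
    ambiguous = is.finite(ratio) & ratio < ambiguity_ratio
  )
  attr(out, "posteriors") <- post
  out
}

#' Split Metridia detections into species groups by the 2-mm rule
#'
#' Among the four sympatric *Metridia* species, *M. pacifica* stays below
#' 2 mm ESD while *M. okhotensis*, *M. asymmetrica* and *M. curticauda*
#' exceed it. ESD cannot resolve the three large congeners from one
#' another, so they are returned as a single `large_metridia` group.
#'
#' @param esd_mm ESD in mm (vectorised, positive).
#' @param threshold_mm Split point; ESD at or above it is `large_metridia`
#'   (the boundary itself goes to the large group). Default 2.
#' @return A factor with levels `pacifica`, `large_metridia`.
#' @export
split_metridia <- function(esd_mm, threshold_mm = 2) {
  if (any(!is.finite(esd_mm)) || any(esd_mm <= 0)) {
    stop("`esd_mm` must be positive", call. = FALSE)
  }
  factor(ifelse(esd_mm < threshold_mm, "pacifica", "large_metridia"),
         levels = c("pacifica", "large_metridia"))
}

#' Size-frequency histogram on a fixed ESD grid
#'
#' Bins ESD values into half-open intervals `[k*w, (k+1)*w)` aligned to the
#' origin (default width 0.1 mm). Each value contributes its weight —
#' typically its areal-abundance contribution (per m²), or 1 for raw counts
#' — so the histogram total equals the total of the contributing measure.
#'
#' @param esd_mm ESD values in mm.
#' @param weights Per-value weights (default all 1).
#' @param bin_width Bin width in mm, default 0.1.
#' @return A `size_histogram` tibble (`bin_lo`, `bin_hi`, `value`) covering
#'   the occupied range contiguously, with attributes `bin_width` and
#'   `total`. Zero-row input gives a zero-row histogram with total 0.
#' @export
esd_histogram <- function(esd_mm, weights = NULL, bin_width = 0.1) {
  if (bin_width <= 0) stop("`bin_width` must be positive", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(esd_mm))
  if (length(weights) != length(esd_mm)) {
    stop("`weights` must match `esd_mm` in length", call. = FALSE)
  }
  if (any(weights < 0)) stop("`weights` must be non-negative", call. = FALSE)
  if (length(esd_mm) == 0) {
    out <- tibble::tibble(bin_lo = numeric(), bin_hi = numeric(),
                          value = numeric())
    return(structure(out, class = c("size_histogram", class(out)),
                     bin_width = bin_width, total = 0))
  }
  idx <- floor(esd_mm / bin_width)          # half-open [lo, hi) binning
  grid <- seq(min(idx), max(idx))
  val <- vapply(grid, function(k) sum(weights[idx == k]), numeric(1))
  out <- tibble::tibble(
    bin_lo = grid * bin_width,
    bin_hi = (grid + 1) * bin_width,
    value = val
  )
  structure(out, class = c("size_histogram", class(out)),
            bin_width = bin_width, total = sum(weights))
}

#' Size-by-depth composition matrix
#'
#' The joint size × depth decomposition shown under vertical-distribution
#' panels: each cell holds the percentage of the water-column total areal
#' abundance contributed by one 0.1-mm ESD bin in one depth layer. Cells
#' over all bins and layers sum to 100%.
#'
#' Each detection contributes an areal weight of
#' `(1 / aliquot_fraction) / filtered_volume_m3 * layer thickness` — the
#' whole-sample, depth-integrated contribution of one scanned individual.
#'
#' @param detections Tibble with `sample_id` and `esd_mm`.
#' @param metas Tow metadata (see [build_profile()]); filter to one
#'   day/night condition via `day_night` if the metadata holds both.
#' @param bin_width ESD bin width in mm, default 0.1.
#' @param species,day_night Optional filters, as in [build_profile()].
#' @return A numeric matrix, rows = ESD bins (names `"[lo,hi)"`), columns =
#'   depth layers (names `"top-bottom m"`), values in percent; attributes
#'   `bin_lo`, `layers`, `column_total`.
#' @export
size_depth_matrix <- function(detections, metas, bin_width = 0.1,
                              species = NULL, day_night = NULL) {
  check_tow_metadata(metas)
  if (!is.null(day_night)) {
    metas <- dplyr::filter(metas, .data$day_night == !!day_night)
  }
  metas <- dplyr::arrange(metas, .data$top_m)
  validate_layers(metas)
  if (!is.null(species)) {
    detections <- dplyr::filter(detections, .data$species %in% !!species)
  }
  orphans <- setdiff(unique(detections$sample_id), metas$sample_id)
  if (length(orphans) && is.null(day_night)) {
    stop("detections reference unknown sample_id: ",
         paste(utils::head(orphans, 3), collapse = ", "), call. = FALSE)
  }
  detections <- dplyr::filter(detections, .data$sample_id %in% metas$sample_id)

  det <- dplyr::left_join(detections, metas, by = "sample_id",
                          suffix = c("", ".meta"))
  det$weight <- (1 / det$aliquot_fraction) / det$filtered_volume_m3 *
    (det$bottom_m - det$top_m)

  layer_names <- sprintf("%g-%g m", metas$top_m, metas$bottom_m)
  if (nrow(det) == 0) {
    mat <- matrix(numeric(0), nrow = 0, ncol = nrow(metas),
                  dimnames = list(NULL, layer_names))
    return(structure(mat, bin_lo = numeric(), layers = metas[
      c("top_m", "bottom_m")], column_total = 0))
  }

  idx <- floor(det$esd_mm / bin_width)
  grid <- seq(min(idx), max(idx))
  bin_names <- sprintf("[%g,%g)", grid * bin_width, (grid + 1) * bin_width)
  mat <- matrix(0, nrow = length(grid), ncol = nrow(metas),
                dimnames = list(bin_names, layer_names))
  li <- match(det$sample_id, metas$sample_id)
  bi <- match(idx, grid)
  for (k in seq_len(nrow(det))) {
    mat[bi[k], li[k]] <- mat[bi[k], li[k]] + det$weight[k]
  }
  total <- sum(mat)
  mat <- 100 * mat / total
  structure(mat, bin_lo = grid * bin_width,
            layers = metas[c("top_m", "bottom_m")], column_total = total)
}
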