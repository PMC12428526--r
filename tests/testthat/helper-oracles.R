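# Independent oracles and fixture builders used across the test files.

# Exact rasterisation of a filled disk at pixel centres: the ground truth
# against which segmentation areas are judged.
rasterize_disk <- function(nr, nc, cr, cc, radius) {
  rr <- matrix(seq_len(nr), nr, nc)
  cm <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  (rr - cr)^2 + (cm - cc)^2 <= radius^2
}

# Reference connected-component counter: breadth-first flood fill over an
# explicit neighbour table. Independent of the package's union-find labeller.
flood_count <- function(mask, eight = TRUE) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  if (eight) {
    dr <- c(-1, -1, -1, 0, 0, 1, 1, 1); dc <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  } else {
    dr <- c(-1, 0, 0, 1); dc <- c(0, -1, 1, 0)
  }
  comps <- 0L
  for (start in which(mask & !seen)) {
    if (seen[start]) next
    comps <- comps + 1L
    queue <- start
    seen[start] <- TRUE
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      pr <- ((p - 1) %% nr) + 1; pc <- ((p - 1) %/% nr) + 1
      for (k in seq_along(dr)) {
        r2 <- pr + dr[k]; c2 <- pc + dc[k]
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
          q <- (c2 - 1) * nr + r2
          if (mask[q] && !seen[q]) {
            seen[q] <- TRUE
            queue <- c(queue, q)
          }
        }
      }
    }
  }
  comps
}

# Paint boolean masks into a dark-on-light image on the 0-255 scale.
mask_to_image <- function(mask, fg = 40, bg = 220) {
  img <- matrix(bg, nrow(mask), ncol(mask))
  img[mask] <- fg
  img
}

# Single-stage synthetic cohort of n scanned individuals (aliquot 1, one
# condition), for stage-reference recovery checks.
make_cohort <- function(species, stage, n, seed, ref = stage_reference()) {
  row <- ref[ref$species == species & ref$stage == stage, ]
  cfg <- scenario_config(
    species = species,
    stage_weights = stats::setNames(1, stage),
    stage_esd = row[, c("stage", "mean_esd_mm", "sd_esd_mm")],
    day_dist = c(1, 0, 0, 0, 0, 0, 0, 0),
    night_dist = c(1, 0, 0, 0, 0, 0, 0, 0),
    aliquot_fraction = 1,
    n_individuals = n
  )
  pop <- generate_population(cfg, seed = seed)
  pop$detections[grepl("_D_", pop$detections$sample_id), ]
}

# Tiny hand-checkable tow metadata: three contiguous layers, unit aliquot,
# volume = thickness (so conc = count / thickness and areal = count).
toy_metas <- function() {
  tibble::tibble(
    sample_id = c("T_L1", "T_L2", "T_L3"),
    date = "2010-10-29",
    day_night = "D",
    top_m = c(0, 50, 100),
    bottom_m = c(50, 100, 150),
    filtered_volume_m3 = c(50, 50, 50),
    aliquot_fraction = 1
  )
}

toy_detections <- function(counts, esd = 1) {
  tibble::tibble(
    object_id = as.character(seq_len(sum(counts))),
    sample_id = rep(c("T_L1", "T_L2", "T_L3"), counts),
    species = "Metridia pacifica",
    stage = NA_character_,
    esd_mm = esd,
    biovolume_mm3 = biovolume_from_esd(esd)
  )
}
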