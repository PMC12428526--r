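test_that("scenario configs validate their distributions", {
  ref <- stage_reference()
  mp <- ref[ref$species == "Metridia pacifica", c("stage", "mean_esd_mm", "sd_esd_mm")]
  expect_error(
    scenario_config("Metridia pacifica", stage_weights = c(C1 = 1),
                    stage_esd = mp, day_dist = rep(0.2, 8),
                    night_dist = rep(1 / 8, 8)),
    "sum to 1")
  expect_error(
    scenario_config("Metridia pacifica", stage_weights = c(Cx = 1),
                    stage_esd = mp, day_dist = rep(1 / 8, 8),
                    night_dist = rep(1 / 8, 8)),
    "missing from")
  expect_error(preset("no_such_scenario"))
})

test_that("generation is reproducible under a fixed seed", {
  cfg <- preset("mpacifica_dvm", n_individuals = 300)
  a <- generate_population(cfg, seed = 13)
  b <- generate_population(cfg, seed = 13)
  expect_identical(a$detections, b$detections)
  expect_identical(a$metas, b$metas)
  c <- generate_population(cfg, seed = 14)
  expect_false(identical(a$detections, c$detections))
})

test_that("an empty population still yields valid metadata", {
  cfg <- preset("ebungii_svm_october", n_individuals = 0)
  pop <- generate_population(cfg, seed = 1)
  expect_equal(nrow(pop$detections), 0)
  expect_equal(nrow(pop$metas), 16)
  expect_silent(validate_layers(dplyr::arrange(
    pop$metas[pop$metas$day_night == "D", ], top_m)))
})

test_that("ESD draws are truncated strictly above zero", {
  ref <- stage_reference()
  det <- make_cohort("Metridia pacifica", "C1", 20000, seed = 3)
  expect_true(all(det$esd_mm > 0))
  # detections are internally consistent: biovolume matches the sphere formula
  expect_equal(det$biovolume_mm3, biovolume_from_esd(det$esd_mm))
  expect_equal(det$area_mm2, pi * (det$esd_mm / 2)^2)
})

test_that("per-stage ESD means match the configured parameters at n = 1000", {
  ref <- stage_reference()
  z <- numeric(nrow(ref))
  sd_rel <- numeric(nrow(ref))
  for (i in seq_len(nrow(ref))) {
    det <- make_cohort(ref$species[i], ref$stage[i], 1000, seed = 20251001 + i)
    est <- stage_reference_from_measurements(det)
    z[i] <- abs(est$mean_esd_mm - ref$mean_esd_mm[i]) /
      (ref$sd_esd_mm[i] / sqrt(1000))
    sd_rel[i] <- abs(est$sd_esd_mm - ref$sd_esd_mm[i]) / ref$sd_esd_mm[i]
  }
  # 2 SE is a 95% band: demand calibration, not perfection, across 18 stages
  expect_lte(sum(z > 2), 3)
  expect_true(all(z < 5))
  expect_true(all(sd_rel < 0.10))
})

test_that("aliquot thinning halves the expected emitted count per halving", {
  ref <- stage_reference()
  mp <- ref[ref$species == "Metridia pacifica", c("stage", "mean_esd_mm", "sd_esd_mm")]
  counts <- sapply(1:20, function(s) {
    cfg <- scenario_config("Metridia pacifica", stage_weights = c(C6F = 1),
                           stage_esd = mp, day_dist = c(1, rep(0, 7)),
                           night_dist = c(1, rep(0, 7)),
                           aliquot_fraction = 1 / 4, n_individuals = 400)
    pop <- generate_population(cfg, seed = 9000 + s)
    sum(grepl("_D_", pop$detections$sample_id))
  })
  # E[count] = 400/4 = 100; mean of 20 replicates has se sqrt(75)/sqrt(20) ~ 1.9
  expect_lt(abs(mean(counts) - 100), 3 * sqrt(400 * 0.25 * 0.75 / 20))
})

test_that("presets encode the documented migration structure", {
  svm <- preset("ebungii_svm_october")
  expect_identical(svm$day_dist, svm$night_dist)
  dvm <- preset("mpacifica_dvm")
  expect_gt(dvm$night_dist$.default[1], dvm$day_dist$.default[1])
  expect_identical(dvm$day_dist$C6M, dvm$night_dist$C6M)  # males stay deep
  jul <- preset("ebungii_july_recruitment")
  expect_gt(jul$day_dist$C1[1], 0.5)
  mix <- preset("metridia_mixture", n_individuals = 1000)
  pop <- generate_population(mix, seed = 31)
  grp <- split_metridia(pop$detections$esd_mm)
  expect_true(all(c("pacifica", "large_metridia") %in% grp))
})

test_that("scan images are reproducible with exact rasterised truth", {
  a <- generate_scan_image(4, seed = 8)
  b <- generate_scan_image(4, seed = 8)
  expect_identical(a$image, b$image)
  expect_equal(nrow(a$truth), 4)
  blank <- generate_scan_image(0, seed = 1)
  expect_equal(nrow(blank$truth), 0)
  expect_equal(nrow(segment_objects(blank$image)), 0)
  # truth areas equal an independent re-rasterisation of each ellipse
  tr <- a$truth
  for (i in seq_len(nrow(tr))) {
    nr <- nrow(a$image); nc <- ncol(a$image)
    rr <- matrix(seq_len(nr) - (tr$center_row[i] + 1), nr, nc)
    cm <- matrix(seq_len(nc) - (tr$center_col[i] + 1), nr, nc, byrow = TRUE)
    u <- (rr * cos(tr$theta[i]) + cm * sin(tr$theta[i])) / tr$a_px[i]
    v <- (-rr * sin(tr$theta[i]) + cm * cos(tr$theta[i])) / tr$b_px[i]
    expect_equal(sum(u^2 + v^2 <= 1), tr$area_px[i])
  }
})

test_that("overcrowded images fail with a placement error", {
  expect_error(generate_scan_image(200, radius_range_px = c(15, 20),
                                   shape = c(100, 100), seed = 2,
                                   max_retries = 20),
               "without overlap")
})
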