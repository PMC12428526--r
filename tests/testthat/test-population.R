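test_that("aliquot counts scale to whole-sample concentration", {
  expect_equal(concentration(20, 1 / 8, 400), 0.4)
  expect_equal(concentration(0, 1 / 8, 400), 0)
  expect_equal(concentration(5, 1, 5), 1)
  expect_error(concentration(1, 0, 10), "aliquot")
  expect_error(concentration(1, 0.5, 0), "volume")
  expect_error(concentration(-1, 0.5, 10), "non-negative")
})

test_that("depth integration multiplies by layer thickness", {
  expect_equal(areal_from_concentration(0.4, 0, 50), 20)
  expect_equal(areal_from_concentration(1, 300, 500), 200)
  expect_error(areal_from_concentration(1, 50, 50), "top_m < bottom_m")
})

test_that("layer schemes must be ordered, non-overlapping, positive", {
  expect_silent(validate_layers(standard_layers()))
  bad <- tibble::tibble(top_m = c(50, 0), bottom_m = c(100, 50))
  expect_error(validate_layers(bad), "ordered")
  overlapping <- tibble::tibble(top_m = c(0, 40), bottom_m = c(50, 100))
  expect_error(validate_layers(overlapping), "overlap")
})

test_that("profile fractions are areal proportions that sum to one", {
  prof <- build_profile(toy_detections(c(20, 60, 20)), toy_metas())
  expect_equal(prof$fraction, c(0.2, 0.6, 0.2))
  expect_equal(sum(prof$fraction), 1)
  expect_equal(prof$areal, prof$conc * (prof$bottom_m - prof$top_m))
  expect_equal(column_total(prof), sum(prof$areal))
  # all mass in one layer
  prof1 <- build_profile(toy_detections(c(0, 35, 0)), toy_metas())
  expect_equal(prof1$fraction, c(0, 1, 0))
})

test_that("unsampled layers are an error unless partial coverage is allowed", {
  metas <- toy_metas()[c(1, 3), ]               # 50-100 m never towed
  det <- toy_detections(c(5, 0, 5))
  det <- det[det$sample_id != "T_L2", ]
  expect_error(build_profile(det, metas), "gaps")
  prof <- build_profile(det, metas, allow_partial = TRUE)
  expect_equal(nrow(prof), 2)
  expect_equal(sum(prof$fraction), 1)
})

test_that("detections with unknown sample ids are a linkage error", {
  det <- toy_detections(c(1, 1, 1))
  det$sample_id[1] <- "nowhere"
  expect_error(build_profile(det, toy_metas()), "unknown sample_id")
})

test_that("zero detections give a zero column total and undefined fractions", {
  prof <- build_profile(toy_detections(integer(3)), toy_metas())
  expect_equal(column_total(prof), 0)
  expect_true(all(is.na(prof$fraction)))
  expect_error(weighted_mean_depth(prof), "undefined")
})

test_that("biovolume profiles sum per-object sphere volumes", {
  det <- toy_detections(c(2, 0, 0), esd = 1)    # two unit-ESD objects in layer 1
  prof <- build_profile(det, toy_metas(), measure = "biovolume")
  # 2 spheres of pi/6 mm3 in 50 m3 -> conc; x 50 m thickness
  expect_equal(prof$conc[1], 2 * (pi / 6) / 50)
  expect_equal(prof$areal[1], 2 * (pi / 6))
})

test_that("halving the aliquot while halving counts leaves concentration unchanged", {
  metas <- toy_metas()
  full <- build_profile(toy_detections(c(40, 0, 0)), metas)
  metas$aliquot_fraction <- 0.5
  half <- build_profile(toy_detections(c(20, 0, 0)), metas)
  expect_equal(half$conc, full$conc)
})

test_that("profiles are additive over disjoint groups", {
  pop <- generate_population(preset("mpacifica_dvm", n_individuals = 800), seed = 5)
  young <- c("C1", "C2", "C3")
  a <- build_profile(pop$detections, pop$metas, day_night = "N", stage = young)
  b <- build_profile(pop$detections, pop$metas, day_night = "N",
                     stage = setdiff(unique(pop$detections$stage), young))
  ab <- build_profile(pop$detections, pop$metas, day_night = "N")
  expect_equal(a$areal + b$areal, ab$areal)
  expect_equal(column_total(a) + column_total(b), column_total(ab))
})

test_that("weighted mean depth is the areal-weighted layer midpoint", {
  expect_equal(weighted_mean_depth(
    build_profile(toy_detections(c(10, 0, 0)), toy_metas())), 25)
  expect_equal(weighted_mean_depth(
    build_profile(toy_detections(c(1, 2, 1)), toy_metas())), 75)
  # symmetric mass at the column extremes averages to the centre
  layers <- standard_layers()
  metas <- tibble::tibble(
    sample_id = paste0("S_L", 1:8), date = "2010-10-29", day_night = "D",
    top_m = layers$top_m, bottom_m = layers$bottom_m,
    filtered_volume_m3 = 6 * (layers$bottom_m - layers$top_m),
    aliquot_fraction = 1
  )
  det <- tibble::tibble(
    object_id = as.character(1:72),
    sample_id = rep(c("S_L1", "S_L8"), c(30, 42)),  # equal areal after scaling
    species = "x", stage = NA_character_, esd_mm = 1,
    biovolume_mm3 = pi / 6
  )
  # areal_L1 = 30/300*50 = 5; areal_L8 = 42/1500*250 = 7 -> WMD weighted
  prof <- build_profile(det, metas)
  expect_equal(weighted_mean_depth(prof), (5 * 25 + 7 * 875) / 12)
})

test_that("identical day and night profiles give zero migration amplitude", {
  d <- build_profile(toy_detections(c(3, 4, 3)), toy_metas())
  expect_equal(dvm_amplitude(d, d), 0)
  metas_n <- toy_metas(); metas_n$day_night <- "N"
  deep <- build_profile(toy_detections(c(0, 0, 10)), toy_metas())
  shallow <- build_profile(toy_detections(c(10, 0, 0)), metas_n)
  expect_equal(dvm_amplitude(deep, shallow), 100)
  short <- build_profile(toy_detections(c(5, 5, 0)), toy_metas()[1:2, ],
                         allow_partial = TRUE)
  expect_error(dvm_amplitude(deep, short), "layer schemes")
})

test_that("estimated layer fractions recover the generator truth within binomial error", {
  cfg <- preset("mpacifica_dvm", n_individuals = 2000)
  pop <- generate_population(cfg, seed = 101)
  truth <- pop$truth$night_fractions
  prof <- build_profile(pop$detections, pop$metas, day_night = "N")
  # effective per-layer counts after aliquot thinning set the binomial band
  n_eff <- 2000 * cfg$aliquot_fraction
  se <- sqrt(truth * (1 - truth) / n_eff)
  expect_true(all(abs(prof$fraction - truth) < pmax(2.5 * se, 0.015)))
})
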