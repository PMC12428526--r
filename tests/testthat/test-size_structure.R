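test_that("the packaged stage reference is valid and ordered", {
  ref <- stage_reference()
  expect_equal(nrow(ref), 18)
  expect_setequal(unique(ref$species),
                  c("Metridia pacifica", "Eucalanus bungii"))
  expect_true(all(ref$sd_esd_mm > 0))
  # female line C1 -> C6F grows strictly within each species
  for (sp in unique(ref$species)) {
    f <- ref[ref$species == sp & ref$stage %in% c("C1", "C2", "C3", "C4F", "C5F", "C6F"), ]
    f <- f[match(c("C1", "C2", "C3", "C4F", "C5F", "C6F"), f$stage), ]
    expect_true(all(diff(f$mean_esd_mm) > 0))
  }
})

test_that("adult-female size ratio between the two species is 2.22x, 10.9x in biovolume", {
  ref <- stage_reference()
  eb <- ref$mean_esd_mm[ref$species == "Eucalanus bungii" & ref$stage == "C6F"]
  mp <- ref$mean_esd_mm[ref$species == "Metridia pacifica" & ref$stage == "C6F"]
  expect_equal(round(eb / mp, 2), 2.22)
  expect_equal(round((eb / mp)^3, 1), 10.9)
  expect_equal(biovolume_from_esd(eb) / biovolume_from_esd(mp), (eb / mp)^3)
})

test_that("stage references from measurements use sample mean and n-1 sd", {
  m <- tibble::tibble(species = "s", stage = "C1",
                      esd_mm = c(1.6, 1.726, 1.852))
  ref <- stage_reference_from_measurements(m)
  expect_equal(ref$mean_esd_mm, 1.726)
  expect_equal(ref$sd_esd_mm, sd(c(1.6, 1.726, 1.852)))
  expect_warning(
    stage_reference_from_measurements(
      tibble::tibble(species = "s", stage = "C1", esd_mm = c(1, 1, 1))),
    "zero ESD spread")
  expect_error(
    stage_reference_from_measurements(
      tibble::tibble(species = "s", stage = "C1", esd_mm = 1)),
    "at least 2")
})

test_that("large synthetic cohorts recover their generating parameters", {
  # 500-draw adult-female cohorts over ten seeds: the standardised errors of
  # the recovered means must behave like N(0, 1) — unbiased pooled mean
  # (3 sigma on the pooled scale), most replicates inside the 2 SE band —
  # and the recovered sd must stay within 10%
  z <- sd_err <- numeric(10)
  for (s in 1:10) {
    det <- make_cohort("Eucalanus bungii", "C6F", 500, seed = 70 + s)
    est <- stage_reference_from_measurements(det)
    z[s] <- (est$mean_esd_mm - 3.827) / (0.276 / sqrt(500))
    sd_err[s] <- abs(est$sd_esd_mm - 0.276) / 0.276
  }
  expect_lt(abs(mean(z)), 3 / sqrt(10))
  expect_gte(sum(abs(z) < 2), 8)
  expect_true(all(sd_err < 0.10))
})

test_that("stage classification returns the generating stage at each reference mean", {
  ref <- stage_reference()
  # stages whose ESD ranges do not collide with a neighbour's
  mp <- ref[ref$species == "Metridia pacifica", ]
  res <- classify_stage(mp$mean_esd_mm, "Metridia pacifica", ref)
  expect_equal(res$stage, mp$stage)
  eb_clear <- c("C1", "C2", "C3", "C6F")
  eb <- ref[ref$species == "Eucalanus bungii" & ref$stage %in% eb_clear, ]
  res_eb <- classify_stage(eb$mean_esd_mm, "Eucalanus bungii", ref)
  expect_equal(res_eb$stage, eb$stage)
  expect_false(any(res_eb$ambiguous))
  post <- attr(res_eb, "posteriors")
  expect_equal(rowSums(post), rep(1, nrow(eb)))
  expect_true(all(post >= 0))
})

test_that("overlapping late stages are flagged ambiguous, not collapsed", {
  res <- classify_stage(2.90, "Eucalanus bungii")
  expect_true(res$ambiguous)
  post <- attr(res, "posteriors")
  # C5F, C5M and C6M all carry visible posterior mass at 2.90 mm
  expect_true(all(post[1, c("C5F", "C5M", "C6M")] > 0.1))
  expect_lt(res$posterior_ratio, 3)
  expect_error(classify_stage(1, "Calanus glacialis"), "not in stage reference")
  expect_error(classify_stage(-1, "Eucalanus bungii"), "positive")
})

test_that("the 2-mm rule separates M. pacifica from the large congeners", {
  expect_equal(as.character(split_metridia(c(1.726, 2.0, 3.0))),
               c("pacifica", "large_metridia", "large_metridia"))
  expect_equal(as.character(split_metridia(1.99)), "pacifica")
  expect_error(split_metridia(0), "positive")
})

test_that("ESD histograms bin half-open on an origin-aligned grid", {
  h <- esd_histogram(0.426)
  expect_equal(h$bin_lo[h$value > 0], 0.4)
  h2 <- esd_histogram(0.5)                      # boundary goes up
  expect_equal(h2$bin_lo[h2$value > 0], 0.5)
  expect_equal(attr(esd_histogram(numeric(0)), "total"), 0)
})

test_that("histogram mass equals the input mass, weighted or not", {
  set.seed(4)
  esd <- runif(300, 0.3, 4)
  w <- rexp(300)
  h <- esd_histogram(esd, w)
  expect_equal(sum(h$value), sum(w))
  expect_equal(attr(h, "total"), sum(w))
  expect_equal(sum(esd_histogram(esd)$value), 300)
  # bins tile the range contiguously at the requested width
  expect_equal(h$bin_hi - h$bin_lo, rep(0.1, nrow(h)))
  expect_equal(h$bin_lo[-1], h$bin_hi[-nrow(h)])
})

test_that("the modal bin of a stage cohort sits at the stage mean", {
  set.seed(11)
  esd <- rnorm(1000, 1.726, 0.121)
  h <- esd_histogram(esd)
  expect_equal(h$bin_lo[which.max(h$value)], 1.7)
})

test_that("size-depth matrices are percentages of the column total", {
  det <- toy_detections(c(0, 8, 0), esd = 1.25)
  m <- size_depth_matrix(det, toy_metas())
  expect_equal(sum(m), 100)
  expect_equal(unname(m[1, 2]), 100)            # single size, single layer
  pop <- generate_population(preset("mpacifica_dvm", n_individuals = 1000), seed = 21)
  mn <- size_depth_matrix(pop$detections, pop$metas, day_night = "N")
  md <- size_depth_matrix(pop$detections, pop$metas, day_night = "D")
  expect_equal(sum(mn), 100)
  expect_equal(sum(md), 100)
  # nocturnal ascent: more of the night matrix lives in the 0-50 m column
  expect_gt(sum(mn[, 1]), sum(md[, 1]))
})
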