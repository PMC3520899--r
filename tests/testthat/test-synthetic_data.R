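test_that("plate generator is deterministic and conserves the plate design", {
  cfg <- plate_sim_config(n_plates = 3, seed = 11)
  a <- generate_plate_set(cfg)
  b <- generate_plate_set(cfg)
  expect_identical(a$plates, b$plates)
  expect_identical(a$truth, b$truth)

  # byte-identical on disk as well
  fa <- withr::local_tempfile(fileext = ".csv")
  fb <- withr::local_tempfile(fileext = ".csv")
  write_screen_csv(a$plates, fa)
  write_screen_csv(b$plates, fb)
  expect_identical(unname(tools::md5sum(fa)), unname(tools::md5sum(fb)))

  # 4 mock + 4 vector wells in column 12, 88 samples, per plate
  for (p in unique(a$plates$plate_id)) {
    pl <- a$plates[a$plates$plate_id == p, ]
    expect_identical(as.vector(table(pl$role)[c("mock", "sample", "vector")]),
                     c(4L, 88L, 4L))
    expect_true(all(well_col(pl$well[pl$role != "sample"]) == 12))
  }
  # one truth record per well, truth v_true present except for mocks
  expect_identical(nrow(a$truth), nrow(a$plates))
  expect_true(all(is.na(a$truth$v_true[a$truth$role == "mock"])))
  expect_true(all(!is.na(a$truth$v_true[a$truth$role != "mock"])))
})

test_that("raw values decompose as background plus truth; mock mean tracks background as noise vanishes", {
  cfg <- plate_sim_config(n_plates = 2, mock_noise_sd = 0, seed = 5)
  sim <- generate_plate_set(cfg)
  m <- merge(sim$plates, sim$truth[, c("plate_id", "well", "v_true", "background")])
  nonmock <- m[m$role != "mock", ]
  expect_equal(nonmock$fluor_raw, nonmock$background + nonmock$v_true,
               tolerance = 1e-12)
  mock <- m[m$role == "mock", ]
  expect_equal(mock$fluor_raw, mock$background, tolerance = 1e-12)
})

test_that("invalid plate configurations are rejected", {
  expect_error(plate_sim_config(seed = 1,
                                component_fractions = c(failed = .5, low = .5,
                                                        typical = .2, high = -.2)),
               "configuration error")
  expect_error(plate_sim_config(seed = 1, mock_noise_sd = -1),
               "configuration error")
  expect_error(plate_sim_config(n_plates = 1), "mandatory")
})

test_that("degenerate mixture of far-above-threshold wells classifies 100% sufficient", {
  cfg <- plate_sim_config(
    n_plates = 3,
    mock_noise_sd = 100, vector_mean = 6000, vector_sd = 100,
    component_fractions = c(failed = 0, low = 0, typical = 1, high = 0),
    component_params = list(
      failed  = list(meanlog = 1, sdlog = .3, shift = 0),
      low     = list(meanlog = 7, sdlog = .1, shift = 1000),
      typical = list(meanlog = 8, sdlog = .2, shift = 10000),
      high    = list(meanlog = 8, sdlog = .3, shift = 60000)),
    dna_fail_fraction = 0, seed = 23)
  sim <- generate_plate_set(cfg)
  norm <- normalize_plates(sim$plates)
  thr <- compute_thresholds(norm)
  calls <- classify_wells(norm, thr)
  expect_true(all(calls$category == "sufficient"))
})

test_that("mixture proportions are recovered by classification on 50 default plates", {
  cfg <- plate_sim_config(n_plates = 50, seed = 31)
  sim <- generate_plate_set(cfg)
  n <- sum(sim$truth$role == "sample")
  # truth labels are a multinomial draw from the configured fractions
  for (k in names(cfg$component_fractions)) {
    p <- cfg$component_fractions[[k]]
    obs <- sum(sim$truth$component == k, na.rm = TRUE) / n
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(obs - p), 3 * se + 1e-12)
  }
  # and downstream classification agrees with truth-expected categories
  # for the overwhelming majority of wells (under the default mixture the
  # low component genuinely straddles the detection threshold, so
  # mock-estimation noise flips a small fraction of borderline wells)
  norm <- normalize_plates(sim$plates)
  thr <- compute_thresholds(norm)
  calls <- classify_wells(norm, thr)
  m <- merge(calls, sim$truth[, c("plate_id", "well", "v_true")])
  expected <- mapply(truth_category, m$v_true, m$dna_ng_ul,
                     MoreArgs = list(thr = thr))
  expect_gt(mean(as.character(m$category) == expected), 0.95)
})

test_that("well-image generator: truth classes replay from the documented RNG stream", {
  cfg <- image_sim_config(width = 320, height = 320, n_nuclei = 200,
                          nucleus_radius_range = c(3, 5), min_gap = 4,
                          marker_positive_fraction = 0.6, seed = 77)
  img <- generate_well_image(cfg)
  expect_identical(nrow(img$truth), 200L)
  # replay the generator's draw order: radii first, then marker classes
  set.seed(77)
  radii <- runif(200, 3, 5)
  replay_pos <- runif(200) < 0.6
  expect_identical(img$truth$marker_positive, replay_pos)
  expect_equal(img$truth$radius, radii, tolerance = 1e-12)
  expect_identical(sum(img$truth$marker_positive), sum(replay_pos))
})

test_that("well-image generator edge cases and determinism", {
  blank <- generate_well_image(small_image_config(seed = 3, n_nuclei = 0))
  expect_identical(nrow(blank$truth), 0L)
  expect_identical(names(blank$channels), c("DAPI", "GFP"))
  expect_identical(nrow(segment_nuclei(blank$channels$DAPI)$nuclei), 0L)

  allpos <- generate_well_image(small_image_config(seed = 4, frac = 1))
  expect_true(all(allpos$truth$marker_positive))

  a <- generate_well_image(small_image_config(seed = 9))
  b <- generate_well_image(small_image_config(seed = 9))
  expect_identical(a$channels, b$channels)
  expect_identical(a$truth, b$truth)

  # impossible placement errors out after bounded retries
  expect_error(generate_well_image(
    image_sim_config(width = 48, height = 48, n_nuclei = 50,
                     nucleus_radius_range = c(5, 6), seed = 2)),
    "placement error")
})

test_that("live/dead generator puts PI blobs only at dead nuclei and GFP only at positives", {
  nodead <- generate_livecell_image(
    small_image_config(seed = 12, channel_set = "live_dead",
                       dead_fraction = 0))
  # PI channel is pure background: nothing segmentable
  expect_identical(nrow(segment_nuclei(nodead$channels$PI)$nuclei), 0L)
  expect_lt(max(nodead$channels$PI),
            nodead$config$background + 6 * nodead$config$noise_sd)

  alldead <- generate_livecell_image(
    small_image_config(seed = 13, channel_set = "live_dead",
                       dead_fraction = 1))
  seg_pi <- segment_nuclei(alldead$channels$PI)
  expect_identical(nrow(seg_pi$nuclei), nrow(alldead$truth))

  a <- generate_livecell_image(small_image_config(seed = 14,
                                                  channel_set = "live_dead",
                                                  dead_fraction = .3))
  b <- generate_livecell_image(small_image_config(seed = 14,
                                                  channel_set = "live_dead",
                                                  dead_fraction = .3))
  expect_identical(a$channels, b$channels)

  # wrong channel_set is rejected both ways
  expect_error(generate_livecell_image(small_image_config(seed = 1)),
               "live_dead")
  expect_error(generate_well_image(
    small_image_config(seed = 1, channel_set = "live_dead")),
    "nuclear_marker")
})
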