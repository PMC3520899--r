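# Rasterized high-contrast disc for closed-form segmentation checks.
raster_disc <- function(size = 64, radius = 10, amp = 30000, bg = 100) {
  ctr <- (size + 1) / 2
  d <- sqrt(outer((1:size - ctr)^2, (1:size - ctr)^2, "+"))
  m <- matrix(bg, size, size)
  m[d <= radius] <- amp
  m
}

test_that("segmentation recovers a single rasterized disc with its area", {
  img <- raster_disc(radius = 10)
  seg <- segment_nuclei(img, segmentation_params(smooth_sigma = 1))
  expect_identical(nrow(seg$nuclei), 1L)
  expect_lt(abs(seg$nuclei$area - pi * 10^2) / (pi * 10^2), 0.10)
  # centroid in 0-based coordinates at the disc centre
  expect_equal(seg$nuclei$row, (64 + 1) / 2 - 1, tolerance = 0.5)
  expect_equal(seg$nuclei$col, (64 + 1) / 2 - 1, tolerance = 0.5)
})

test_that("segmentation returns zero nuclei on blank or constant images", {
  expect_identical(nrow(segment_nuclei(matrix(500, 64, 64))$nuclei), 0L)
  set.seed(2)
  noise <- matrix(150 + abs(rnorm(128 * 128, 0, 80)), 128, 128)
  expect_identical(nrow(segment_nuclei(noise)$nuclei), 0L)
  expect_error(segment_nuclei(array(1, c(4, 4, 2))), "2-D")
  expect_error(segment_nuclei(matrix(c(1, -5, 2, 3), 2, 2)), "finite")
})

test_that("connectivity convention controls component merging", {
  # two blocks touching only at a corner
  m <- matrix(0, 20, 20)
  m[3:8, 3:8] <- 1000
  m[9:14, 9:14] <- 1000
  p8 <- segmentation_params(smooth_sigma = 0, threshold_method = "fixed",
                            fixed_threshold = 500, min_area = 10,
                            connectivity = 8)
  p4 <- segmentation_params(smooth_sigma = 0, threshold_method = "fixed",
                            fixed_threshold = 500, min_area = 10,
                            connectivity = 4)
  expect_identical(nrow(segment_nuclei(m, p8)$nuclei), 1L)
  expect_identical(nrow(segment_nuclei(m, p4)$nuclei), 2L)
})

test_that("holes inside nuclei are filled before measurement", {
  img <- raster_disc(radius = 12)
  ctr <- (64 + 1) / 2
  img[(ctr - 2):(ctr + 2), (ctr - 2):(ctr + 2)] <- 100  # punched hole
  seg <- segment_nuclei(img, segmentation_params(smooth_sigma = 0,
                                                 threshold_method = "fixed",
                                                 fixed_threshold = 15000))
  expect_identical(nrow(seg$nuclei), 1L)
  expect_gte(seg$nuclei$area, sum(raster_disc(radius = 12) > 15000))
})

test_that("marker scoring equals brute-force pixel means", {
  # hand-built 5x5 mask over known pixel values
  lab <- matrix(0L, 5, 5)
  lab[2:4, 2:3] <- 1L
  seg <- structure(list(labels = lab,
                        nuclei = data.frame(nucleus = 1L, row = 2, col = 1.5,
                                            area = 6)),
                   class = "nucleus_segmentation")
  marker <- matrix(seq_len(25) * 3, 5, 5)
  rec <- score_marker(seg, marker)
  expect_equal(rec$marker_mean, sum(marker[lab == 1L]) / 6, tolerance = 1e-12)
  expect_equal(rec$marker_mean, pixel_loop_means(lab, marker), tolerance = 1e-9)

  # uniform and zero marker images
  img <- generate_well_image(small_image_config(seed = 21))
  s <- segment_nuclei(img$channels$DAPI)
  uni <- score_marker(s, matrix(7, 192, 192))
  expect_true(all(uni$marker_mean == 7))
  zero <- score_marker(s, matrix(0, 192, 192))
  expect_true(all(zero$marker_mean == 0))
  expect_error(score_marker(s, matrix(0, 10, 10)), "shape")
})

test_that("marker threshold calibration: quantile path, fallback path, errors", {
  # large mock sample: 0.995 quantile within 2% of the normal closed form
  set.seed(42)
  mu <- 500; sigma <- 60
  x <- rnorm(1e5, mu, sigma)
  thr <- calibrate_marker_threshold(x)
  expect_lt(abs(thr - (mu + stats::qnorm(0.995) * sigma)) /
              (mu + stats::qnorm(0.995) * sigma), 0.02)

  # constant mocks
  expect_equal(calibrate_marker_threshold(rep(5, 500)), 5)

  # below 200 nuclei: mean + 3 SD fallback, against explicit arithmetic
  y <- rnorm(100, 300, 40)
  m <- sum(y) / 100
  s <- sqrt(sum((y - m)^2) / 99)
  expect_equal(calibrate_marker_threshold(y), m + 3 * s, tolerance = 1e-12)

  expect_error(calibrate_marker_threshold(numeric(0)), "calibration error")
})

test_that("transduction rate counts strict exceedances and handles empty wells", {
  rec <- data.frame(nucleus = 1:4, row = 0, col = 0, area = 50,
                    marker_mean = c(10, 20, 20, 30))
  r <- transduction_rate(rec, threshold = 20)
  expect_identical(r$result$n_positive, 1L)   # ties stay negative
  expect_equal(r$result$rate, 0.25)
  expect_identical(r$records$marker_positive, c(FALSE, FALSE, FALSE, TRUE))

  r0 <- transduction_rate(rec, threshold = 100)
  expect_equal(r0$result$rate, 0)

  empty <- rec[0, ]
  re <- transduction_rate(empty, threshold = 20)
  expect_identical(re$result$n_nuclei, 0L)
  expect_true(is.na(re$result$rate))

  expect_error(transduction_rate(rec, threshold = Inf), "finite")
})

test_that("transduction rate is invariant to common affine intensity rescaling", {
  img <- generate_well_image(small_image_config(seed = 33, frac = 0.4,
                                                n_nuclei = 50))
  mock <- generate_well_image(small_image_config(seed = 34, frac = 0,
                                                 n_nuclei = 50))
  seg <- segment_nuclei(img$channels$DAPI)
  mock_seg <- segment_nuclei(mock$channels$DAPI)

  rate_at <- function(a, b) {
    sc <- function(m) a * m + b
    mm <- score_marker(mock_seg, sc(mock$channels$GFP))$marker_mean
    thr <- calibrate_marker_threshold(mm, min_n_quantile = 10)
    rec <- score_marker(seg, sc(img$channels$GFP))
    transduction_rate(rec, thr)$result$rate
  }
  base <- rate_at(1, 0)
  expect_equal(rate_at(3.7, 0), base)
  expect_equal(rate_at(0.25, 1000), base)
})

test_that("rate estimator is unbiased over many wells at p = 0.3 (record-level)", {
  # 200 seeded wells of 100 nuclei each with separable intensities
  set.seed(301)
  p <- 0.3; n <- 100; wells <- 200
  rates <- replicate(wells, {
    pos <- runif(n) < p
    means <- ifelse(pos, rnorm(n, 8000, 200), rnorm(n, 300, 60))
    rec <- data.frame(nucleus = 1:n, row = 0, col = 0, area = 50,
                      marker_mean = means)
    transduction_rate(rec, threshold = 4150)$result$rate
  })
  se <- sqrt(p * (1 - p) / (n * wells))
  expect_lt(abs(mean(rates) - p), 3 * se)
  expect_true(all(rates >= 0 & rates <= 1))
})

test_that("live/dead counting reports independent per-channel counts", {
  lc <- generate_livecell_image(
    image_sim_config(width = 320, height = 320, n_nuclei = 80,
                     marker_positive_fraction = 0.5,
                     channel_set = "live_dead", dead_fraction = 0.25,
                     seed = 51))
  res <- count_live_dead(lc$channels$Hoechst, lc$channels$PI,
                         lc$channels$GFP, gfp_threshold = 4000)
  expect_identical(res$hoechst_count, 80L)
  expect_identical(res$pi_count, sum(lc$truth$dead))
  expect_identical(res$gfp_count, sum(lc$truth$marker_positive))
  expect_equal(res$gfp_fraction_of_hoechst,
               mean(lc$truth$marker_positive), tolerance = 0.05)
  expect_true(res$gfp_fraction_of_hoechst >= 0 &&
                res$gfp_fraction_of_hoechst <= 1)

  # blank GFP channel -> fraction 0 with a sane threshold
  bg <- matrix(150, 320, 320)
  res0 <- count_live_dead(lc$channels$Hoechst, lc$channels$PI, bg,
                          gfp_threshold = 1000)
  expect_equal(res0$gfp_fraction_of_hoechst, 0)
  expect_identical(res0$gfp_count, 0L)

  expect_error(count_live_dead(lc$channels$Hoechst, lc$channels$PI,
                               matrix(0, 2, 2), gfp_threshold = 1),
               "shape|shape|shape|share")
})
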