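test_that("noiseless homogeneous phantom follows the closed-form decay", {
  cfg <- noiseless_config(mu = 0.01, refl = 1000)
  fr <- generate_frame(cfg, frame_seed = 7, raw = TRUE)
  b <- fr$contour[1]
  # 100 px beyond the lumen: I = 1000 * exp(-2 * 0.01 * 100)
  expect_equal(fr$intensity_raw[1, b + 100], 1000 * exp(-2), tolerance = 1e-10)
  # every depth, every A-line
  for (i in c(1, 5, 16)) {
    d <- seq(0, 250)
    expect_equal(fr$intensity_raw[i, fr$contour[i] + d],
                 1000 * exp(-2 * 0.01 * d), tolerance = 1e-10)
  }
  # inside the lumen there is no signal
  expect_true(all(fr$intensity_raw[cbind(1:16, fr$contour - 1L)] == 0))
})

test_that("inclusions occupy exactly their angular x depth span", {
  cfg <- small_config(speckle_shape = Inf, noise_floor = 0)
  inc <- list(class = "calcified_fibrous", aline_start = 10L,
              aline_len = 10L, depth_start = 50L, depth_len = 50L)
  fr <- generate_frame(cfg, frame_seed = 3, inclusions = list(inc))
  id <- plaque_classes()[["calcified_fibrous"]]
  expect_identical(sum(fr$labels == id), 10L * 50L)
  # wrap across the seam
  inc$aline_start <- 60L   # 60..64 then 1..5
  fr <- generate_frame(cfg, frame_seed = 3, inclusions = list(inc))
  expect_identical(sum(fr$labels == id), 10L * 50L)
  expect_true(any(fr$labels[64, ] == id) && any(fr$labels[1, ] == id))
})

test_that("every pixel has exactly one label; lumen label inside the lumen", {
  cfg <- small_config()
  inc <- list(class = "lipid_pool", aline_start = 5L, aline_len = 12L,
              depth_start = 40L, depth_len = 30L)
  fr <- generate_frame(cfg, frame_seed = 11, inclusions = list(inc))
  expect_true(all(fr$labels %in% plaque_classes()))
  depth_idx <- matrix(seq_len(cfg$depth_px), cfg$n_alines, cfg$depth_px,
                      byrow = TRUE)
  lumen <- depth_idx < matrix(fr$contour, cfg$n_alines, cfg$depth_px)
  expect_true(all(fr$labels[lumen] == 0L))
  expect_true(all(fr$labels[!lumen] != 0L))
})

test_that("overlapping inclusions of different classes error without priority", {
  cfg <- small_config()
  incs <- list(
    list(class = "lipid_pool", aline_start = 5L, aline_len = 10L,
         depth_start = 40L, depth_len = 30L),
    list(class = "calcified_fibrous", aline_start = 8L, aline_len = 10L,
         depth_start = 50L, depth_len = 30L)
  )
  expect_error(generate_frame(cfg, 1, inclusions = incs), "priority")
  fr <- generate_frame(cfg, 1, inclusions = incs,
                       priority = c("calcified_fibrous", "lipid_pool"))
  ids <- plaque_classes()
  # the contested block belongs to the higher-priority class
  expect_true(all(fr$labels[9:14, 51:69] == ids[["calcified_fibrous"]]))
})

test_that("identical config and seed reproduce byte-identical files", {
  cfg <- small_config()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- generate_dataset(cfg, 1, 1, 2, seed = 5, dir = d1, keep_arrays = TRUE)
  m2 <- generate_dataset(cfg, 1, 1, 2, seed = 5, dir = d2)
  for (k in seq_len(nrow(m1))) {
    expect_identical(readBin(m1$image_path[k], "raw", 1e6),
                     readBin(m2$image_path[k], "raw", 1e6))
    expect_identical(readBin(m1$label_path[k], "raw", 1e6),
                     readBin(m2$label_path[k], "raw", 1e6))
  }
  # and the written images round-trip through the readers
  expect_identical(read_polar_tiff(m1$image_path[1]), m1$image[[1]])
  expect_identical(read_label_png(m1$label_path[1]), m1$labels[[1]])
})

test_that("speckle-averaged intensity matches the closed form within 2%", {
  # one homogeneous A-line, speckle on, averaged over many realizations
  tm <- list(fibrous = tissue_model("fibrous", 0.012, 1, 0, 0))
  cfg <- phantom_config(n_alines = 32L, depth_px = 120L, lumen_radius_px = 10,
                        lumen_eccentricity = 0, lumen_noise_px = 0,
                        tissue_models = tm, speckle_shape = 4,
                        noise_floor = 0, full_scale = 6)
  acc <- 0
  n_rep <- 400  # 400 frames x 32 A-lines = 12800 realizations per depth
  for (s in seq_len(n_rep)) {
    fr <- generate_frame(cfg, frame_seed = s, raw = TRUE)
    sig <- t(vapply(seq_len(32), function(i) {
      fr$intensity_raw[i, fr$contour[i] + 0:99]
    }, numeric(100)))
    acc <- acc + colMeans(sig)
  }
  mean_profile <- acc / n_rep
  expected <- exp(-2 * 0.012 * (0:99))
  expect_true(all(abs(mean_profile / expected - 1) < 0.02))
})

test_that("higher attenuation strictly darkens all depths behind the tissue", {
  f1 <- generate_frame(noiseless_config(mu = 0.01), 2, raw = TRUE)
  f2 <- generate_frame(noiseless_config(mu = 0.02), 2, raw = TRUE)
  b <- f1$contour[1]
  behind <- (b + 1):(b + 200)
  expect_true(all(f2$intensity_raw[1, behind] < f1$intensity_raw[1, behind]))
})

test_that("dataset hierarchy counts and prevalence behave as configured", {
  cfg <- small_config()
  m <- generate_dataset(cfg, n_hearts = 2, arteries_per_heart = 2,
                        frames_per_artery = 3, seed = 9)
  expect_identical(nrow(m), 12L)
  expect_identical(dplyr::n_distinct(m$artery_id), 4L)
  expect_identical(dplyr::n_distinct(m$heart_id), 2L)
  # degenerate prevalence: a class with probability 0 never appears
  m0 <- generate_dataset(cfg, 1, 1, 8,
                         class_prevalence = c(lipid_pool = 1,
                                              calcified_lipid = 0),
                         seed = 3)
  expect_true(all(!m0$has_calcified_lipid))
  expect_true(!any(vapply(m0$labels, function(L) {
    any(L == plaque_classes()[["calcified_lipid"]])
  }, logical(1))))
  expect_true(all(m0$has_lipid_pool))
})

test_that("presence prevalence converges to the configured probability", {
  # 400 frames at p = 0.5: observed fraction within the 99% binomial band
  cfg <- phantom_config(n_alines = 32L, depth_px = 96L, lumen_radius_px = 10,
                        lumen_eccentricity = 0.05, lumen_noise_px = 1)
  m <- generate_dataset(cfg, 4, 1, 100,
                        class_prevalence = c(lipid_pool = 0.5), seed = 21)
  frac <- mean(m$has_lipid_pool)
  expect_gte(frac, 0.42)
  expect_lte(frac, 0.58)
})

test_that("non-empty output directory is protected", {
  cfg <- small_config()
  d <- withr::local_tempdir()
  writeLines("x", file.path(d, "sentinel.txt"))
  expect_error(generate_dataset(cfg, 1, 1, 1, seed = 1, dir = d),
               "not empty")
  expect_no_error(generate_dataset(cfg, 1, 1, 1, seed = 1, dir = d,
                                   overwrite = TRUE))
})
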