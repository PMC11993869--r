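test_that("lumen detection is exact on a noiseless phantom", {
  cfg <- noiseless_config(n_alines = 32L)
  # vary the lumen for a non-trivial contour
  cfg$lumen_eccentricity <- 0.15
  cfg$lumen_noise_px <- 4
  fr <- generate_frame(cfg, frame_seed = 13)
  expect_identical(detect_lumen(fr), fr$contour)
})

test_that("lumen detection tracks the truth within 3 px under speckle", {
  cfg <- small_config()
  errs <- vapply(seq_len(50), function(s) {
    fr <- generate_frame(cfg, frame_seed = s)
    mean(abs(detect_lumen(fr) - fr$contour))
  }, numeric(1))
  expect_lt(mean(errs), 3)
})

test_that("degenerate frames raise a lumen error", {
  expect_error(detect_lumen(matrix(0, 16, 64)), "no lumen found")
})

test_that("flatten is the expected gather for trivial contours", {
  M <- matrix(seq_len(32 * 300), 32, 300)
  # boundary at column 1 everywhere: identity on the first 200 columns
  f0 <- flatten_frame(M, rep(1L, 32), 200L)
  expect_identical(f0$intensities, M[, 1:200])
  # constant shift c: columns c..c+199
  fc <- flatten_frame(M, rep(41L, 32), 200L)
  expect_identical(fc$intensities, M[, 41:240])
  # out-of-range contour names the offending A-line
  bad <- rep(1L, 32); bad[7] <- 200L
  expect_error(flatten_frame(M, bad, 200L), "7")
})

test_that("flatten/unflatten round-trips every in-crop pixel exactly", {
  withr::with_seed(99, {
    for (k in seq_len(100)) {
      n <- sample(8:40, 1); W <- sample(250:320, 1)
      M <- matrix(rnorm(n * W), n, W)
      contour <- sample.int(W - 200L + 1L, n, replace = TRUE)
      fl <- flatten_frame(M, contour, 200L)
      back <- unflatten_frame(fl$intensities, contour, c(n, W), fill = NA)
      idx <- !is.na(back)
      expect_identical(sum(idx), n * 200L)
      expect_identical(back[idx], M[idx])
    }
  })
})

test_that("circular shift commutes with flatten", {
  withr::with_seed(4, {
    n <- 24L; W <- 260L
    M <- matrix(rnorm(n * W), n, W)
    contour <- sample.int(W - 200L + 1L, n, replace = TRUE)
    for (k in c(1L, 7L, 23L)) {
      shift <- function(v) v[((seq_along(v) - 1L - k) %% length(v)) + 1L]
      Ms <- M[((seq_len(n) - 1L - k) %% n) + 1L, ]
      lhs <- flatten_frame(Ms, shift(contour), 200L)$intensities
      rhs <- flatten_frame(M, contour, 200L)$intensities[
        ((seq_len(n) - 1L - k) %% n) + 1L, ]
      expect_identical(lhs, rhs)
    }
  })
})

test_that("unflatten fills outside the band and conserves target counts", {
  n <- 16L; crop <- 200L
  offsets <- rep(30L, n)
  ones <- matrix(1, n, crop)
  out <- unflatten_frame(ones, offsets, c(n, 300L), fill = 0)
  expect_identical(sum(out == 1), n * crop)
  expect_true(all(out[, 1:29] == 0))
  expect_error(unflatten_frame(ones, offsets, c(n, 150L)), "incompatible")
})

test_that("scan conversion is radially symmetric for angle-constant input", {
  polar <- matrix(rep(exp(-seq_len(64) / 20), each = 48), 48, 64)
  cart <- polar_to_cartesian(polar, 128, "nearest")
  ctr <- (128 + 1) / 2
  xy <- seq_len(128) - ctr
  R <- sqrt(outer(xy^2, xy^2, "+"))
  depth_idx <- floor(R) + 1
  for (r in c(10, 25, 50)) {
    ring <- cart[depth_idx == r & R < 64]
    expect_lt(stats::sd(ring), 1e-12)   # one sampled depth -> one value
  }
})

test_that("nearest-neighbour conversion never invents label values", {
  withr::with_seed(5, {
    lab <- matrix(sample(c(0L, 1L, 3L, 5L), 48 * 64, replace = TRUE), 48, 64)
    cart <- polar_to_cartesian(lab, 160, "nearest", fill = 0L)
    expect_true(all(unique(as.vector(cart)) %in% c(0L, 1L, 3L, 5L)))
  })
})

test_that("rotating the polar rows rotates the cartesian image", {
  withr::with_seed(6, {
    n <- 64L
    polar <- matrix(runif(n * 40), n, 40)
    k <- n / 4L   # a quarter turn maps the pixel grid onto itself
    rolled <- polar[((seq_len(n) - 1L + k) %% n) + 1L, ]
    a <- polar_to_cartesian(rolled, 128, "nearest")
    b <- polar_to_cartesian(polar, 128, "nearest")
    # 90-degree rotations of a square matrix
    rots <- list(t(b)[, nrow(b):1], b[nrow(b):1, ncol(b):1], t(b)[ncol(b):1, ])
    agree <- vapply(rots, function(r) mean(r == a), numeric(1))
    expect_gte(max(agree), 0.999)
  })
})

test_that("log display is monotone, zero-preserving and hits 255", {
  expect_true(all(log_display(matrix(0, 4, 4)) == 0L))
  withr::with_seed(8, {
    M <- matrix(rexp(400, 1 / 500), 20, 20)
    d <- log_display(M)
    o <- order(M)
    expect_true(all(diff(d[o]) >= 0L))
    expect_identical(max(d), 255L)
  })
})
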