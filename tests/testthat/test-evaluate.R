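test_that("Dice handles the canonical cases", {
  t <- matrix(FALSE, 5, 5); t[1:2, 1:5] <- TRUE        # |T| = 10
  p <- matrix(FALSE, 5, 5); p[2:3, 1:5] <- TRUE        # |P| = 10, overlap 5
  expect_identical(as.numeric(dice_coefficient(p, t)), 0.5)
  expect_identical(as.numeric(dice_coefficient(t, t)), 1)
  disj <- matrix(FALSE, 5, 5); disj[5, ] <- TRUE
  expect_identical(as.numeric(dice_coefficient(disj, t)), 0)
  # both empty: degenerate 1
  d <- dice_coefficient(matrix(FALSE, 3, 3), matrix(FALSE, 3, 3))
  expect_identical(as.numeric(d), 1)
  expect_true(attr(d, "degenerate"))
  # symmetry and bounds on random maps
  withr::with_seed(41, {
    for (k in seq_len(20)) {
      a <- matrix(runif(64) > 0.5, 8, 8)
      b <- matrix(runif(64) > 0.5, 8, 8)
      expect_identical(dice_coefficient(a, b), dice_coefficient(b, a))
      expect_true(as.numeric(dice_coefficient(a, b)) >= 0 &&
                    as.numeric(dice_coefficient(a, b)) <= 1)
    }
  })
})

test_that("A-line positivity follows the min-pixel rule", {
  m <- matrix(FALSE, 6, 10)
  expect_identical(aline_positive(m), rep(FALSE, 6))
  m[3, 5] <- TRUE
  expect_identical(which(aline_positive(m)), 3L)
  m4 <- matrix(FALSE, 2, 10); m4[1, 1:4] <- TRUE
  expect_false(aline_positive(m4, min_pixels = 5)[1])
  m4[1, 5] <- TRUE
  expect_true(aline_positive(m4, min_pixels = 5)[1])
})

test_that("the four-A-line worked confusion gives sens = spec = 0.5", {
  truth <- matrix(c(1, 1, 0, 0), 4, 8)
  pred <- matrix(c(1, 0, 1, 0), 4, 8)
  cf <- aline_confusion(pred, truth)
  expect_identical(c(cf$tp, cf$fn, cf$fp, cf$tn), c(1L, 1L, 1L, 1L))
  expect_identical(cf$sensitivity, 0.5)
  expect_identical(cf$specificity, 0.5)
})

test_that("vectorized A-line confusion equals brute-force row enumeration", {
  brute <- function(pred, truth, valid, min_pixels) {
    tp <- fp <- fn <- tn <- 0L
    for (i in seq_len(nrow(pred))) {
      nv <- 0L; np <- 0L; nt <- 0L
      for (j in seq_len(ncol(pred))) {
        if (valid[i, j]) {
          nv <- nv + 1L
          if (pred[i, j]) np <- np + 1L
          if (truth[i, j]) nt <- nt + 1L
        }
      }
      if (nv == 0L) next
      pv <- np >= min_pixels; tv <- nt >= min_pixels
      if (pv && tv) tp <- tp + 1L
      if (pv && !tv) fp <- fp + 1L
      if (!pv && tv) fn <- fn + 1L
      if (!pv && !tv) tn <- tn + 1L
    }
    c(tp, fp, fn, tn)
  }
  withr::with_seed(42, {
    for (k in seq_len(100)) {
      n <- sample(4:12, 1); W <- sample(6:20, 1)
      pred <- matrix(runif(n * W) > 0.6, n, W)
      truth <- matrix(runif(n * W) > 0.6, n, W)
      valid <- matrix(runif(n * W) > 0.25, n, W)
      mp <- sample(1:3, 1)
      cf <- aline_confusion(pred, truth, valid, mp)
      expect_identical(c(cf$tp, cf$fp, cf$fn, cf$tn),
                       brute(pred, truth, valid, mp))
    }
  })
})

test_that("fully excluded A-lines are dropped; empty denominators give NA", {
  pred <- matrix(TRUE, 4, 6); truth <- matrix(TRUE, 4, 6)
  valid <- matrix(TRUE, 4, 6); valid[2, ] <- FALSE
  cf <- aline_confusion(pred, truth, valid)
  expect_identical(cf$n_alines, 3L)
  expect_identical(cf$sensitivity, 1)
  expect_true(is.na(cf$specificity))   # no negative A-lines anywhere
})

test_that("dataset evaluation: self-evaluation is perfect and counts add up", {
  withr::with_seed(43, {
    samples <- lapply(seq_len(6), function(f) {
      mask <- matrix(MASK_BACKGROUND, 16, 24)
      mask[sample(16, 4), 3:10] <- MASK_TARGET
      mask[, 20:24] <- MASK_EXCLUSION
      list(x = matrix(runif(16 * 24), 16, 24), mask = mask,
           frame_id = paste0("f", f))
    })
    truth_preds <- lapply(samples, function(s) s$mask == MASK_TARGET)
    ev <- evaluate_dataset(samples, predictions = truth_preds)
    expect_identical(ev$metrics$dice_mean, 1)
    expect_identical(ev$metrics$sensitivity, 1)
    expect_identical(ev$metrics$specificity, 1)
    expect_identical(nrow(ev$per_frame), 6L)
    # pooled counts equal the per-frame sums
    expect_identical(ev$metrics$tp + ev$metrics$fp + ev$metrics$fn +
                       ev$metrics$tn, sum(ev$per_frame$n_alines))
    expect_identical(ev$metrics$tp, sum(ev$per_frame$tp))
  })
})

test_that("perturbing excluded pixels changes no evaluation metric", {
  withr::with_seed(44, {
    samples <- lapply(seq_len(4), function(f) {
      mask <- matrix(sample(0:2, 12 * 30, replace = TRUE,
                            prob = c(0.3, 0.5, 0.2)), 12, 30)
      list(x = matrix(runif(12 * 30), 12, 30), mask = mask,
           frame_id = paste0("f", f))
    })
    preds <- lapply(samples, function(s) matrix(runif(12 * 30) > 0.5, 12, 30))
    ev1 <- evaluate_dataset(samples, predictions = preds)
    preds2 <- purrr::map2(preds, samples, function(p, s) {
      p[s$mask == MASK_EXCLUSION] <- !p[s$mask == MASK_EXCLUSION]
      p
    })
    ev2 <- evaluate_dataset(samples, predictions = preds2)
    expect_identical(ev1$metrics, ev2$metrics)
    expect_identical(ev1$per_frame, ev2$per_frame)
  })
})

test_that("missing ground truth is reported with frame ids", {
  s <- list(list(x = matrix(0, 4, 4), mask = matrix(1L, 4, 4)),
            list(x = matrix(0, 4, 4), mask = NULL))
  expect_error(evaluate_dataset(s, predictions = list(NULL, NULL)), "2")
})
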