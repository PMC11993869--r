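test_that("circular_pad matches the wrap definition", {
  x <- matrix(as.numeric(1:12), 3, 4, byrow = TRUE)   # rows r0, r1, r2
  p <- circular_pad(x, 1L)
  expect_identical(p, rbind(x[3, ], x, x[1, ]))
  # identity at zero padding
  expect_identical(circular_pad(x, 0L), x)
  expect_error(circular_pad(x, 3L), "smaller")
  # depth padding modes
  pz <- circular_pad(x, 0L, 1L, "zero")
  expect_true(all(pz[, 1] == 0) && all(pz[, 6] == 0))
  pr <- circular_pad(x, 0L, 1L, "reflect")
  expect_identical(pr[, 1], x[, 1])
  expect_identical(pr[, 6], x[, 4])
})

test_that("circular_pad commutes with row shifts (exhaustive on 5x4)", {
  withr::with_seed(51, {
    x <- matrix(rnorm(20), 5, 4)
    shift <- function(m, k) m[((seq_len(nrow(m)) - 1L - k) %% nrow(m)) + 1L, ,
                              drop = FALSE]
    for (k in 0:4) {
      lhs <- circular_pad(shift(x, k), 2L)
      rhs <- circular_pad(x, 2L)
      # restrict to the wrapped band: interior rows of the padded arrays
      # shifted by k must agree
      inner <- 3:7   # rows of the original x inside the padded array
      expect_equal(lhs[inner, ], shift(x, k), tolerance = 0)
      expect_equal(rhs[inner, ], x, tolerance = 0)
      expect_equal(lhs[inner, ], shift(rhs[inner, , drop = FALSE], k),
                   tolerance = 0)
    }
  })
})

test_that("compiled convolution agrees with a plain-loop reference", {
  withr::with_seed(52, {
    for (pad in c("zero", "reflect")) {
      x <- array(rnorm(10 * 8 * 3), c(10, 8, 3))
      w <- array(rnorm(3 * 3 * 3 * 2, sd = 0.5), c(3, 3, 3, 2))
      b <- rnorm(2)
      got <- ivoctseg:::conv3_fwd(x, w, b,
                                  if (pad == "zero") 0L else 1L)
      ref <- conv3_reference(x, w, b, pad)
      expect_equal(got, ref, tolerance = 1e-5)
    }
  })
})

test_that("architecture is deterministic and scales as expected", {
  cfg <- unet_config(3, 8)
  n1 <- build_unet(cfg, seed = 2)
  n2 <- build_unet(cfg, seed = 2)
  expect_identical(n_params(n1), n_params(n2))
  expect_identical(n1$params, n2$params)
  # doubling base channels ~quadruples the 3x3 conv weight count
  conv_count <- function(net) {
    sum(vapply(net$params[grepl("_w$", names(net$params)) &
                            !grepl("up_w|att|out_w", names(net$params))],
               length, numeric(1)))
  }
  n4 <- build_unet(unet_config(3, 16), seed = 2)
  ratio <- conv_count(n4) / conv_count(n1)
  expect_lt(abs(ratio - 4), 4 * 0.05)
})

test_that("untrained network emits probabilities strictly inside (0, 1)", {
  net <- build_unet(unet_config(2, 4), seed = 3)
  x <- matrix(rnorm(32 * 48), 32, 48)
  p <- ivoctseg:::unet_forward(net, x)$p
  expect_true(all(p > 0 & p < 1))
  expect_identical(dim(p), c(32L, 48L))
})

test_that("indivisible input shapes raise an instructive error", {
  net <- build_unet(unet_config(3, 4), seed = 1)
  expect_error(ivoctseg:::unet_forward(net, matrix(0, 30, 48)), "divisible")
})

test_that("thresholding behaves monotonically at prediction time", {
  net <- build_unet(unet_config(2, 4), seed = 4)
  model <- structure(list(net = net, norm = list(mean = 0, sd = 1),
                          target = "lipid_pool"),
                     class = "ivoct_model")
  x <- matrix(rexp(32 * 40), 32, 40)
  pr0 <- predict_frame(model, x, threshold = 0)
  expect_true(all(pr0$mask))
  pr2 <- predict_frame(model, x, threshold = 1.00001)
  expect_true(!any(pr2$mask))
  counts <- vapply(c(0.2, 0.4, 0.6, 0.8),
                   function(th) sum(predict_frame(model, x, th)$mask),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
  # prob map is cropped back to the input width
  expect_identical(dim(pr0$prob), dim(x))
})

test_that("network output is equivariant to angular shifts by the stride", {
  net <- build_unet(unet_config(3, 6), seed = 6)
  H <- 48L; W <- 48L
  withr::with_seed(53, x <- matrix(rnorm(H * W), H, W))
  p <- ivoctseg:::unet_forward(net, x)$p
  s <- net$config$total_stride
  for (k in c(s, 3L * s)) {
    xs <- x[((seq_len(H) - 1L - k) %% H) + 1L, ]
    ps <- ivoctseg:::unet_forward(net, xs)$p
    expect_lt(max(abs(ps - p[((seq_len(H) - 1L - k) %% H) + 1L, ])), 1e-4)
  }
})

test_that("pullback prediction applies the overlay priority and keeps masks", {
  # two stub models via constructed constant-output networks is expensive;
  # instead check the overlay rule through predict_pullback internals on a
  # phantom frame with two trained-free models built from fresh nets
  cfg <- small_config()
  fr <- generate_frame(cfg, 5, inclusions = list(
    list(class = "lipid_pool", aline_start = 5L, aline_len = 20L,
         depth_start = 30L, depth_len = 40L)))
  mk_model <- function(target, seed) {
    structure(list(net = build_unet(unet_config(2, 4), seed = seed),
                   norm = list(mean = 0, sd = 1), target = target),
              class = "ivoct_model")
  }
  expect_error(predict_pullback(list(), list(fr)), "no models")
  models <- list(calcified_lipid = mk_model("calcified_lipid", 1),
                 lipid_pool = mk_model("lipid_pool", 2))
  pb <- predict_pullback(models, list(fr), crop_depth = 80L,
                         contours = list(fr$contour))
  expect_identical(pb$skipped, integer(0))
  masks <- pb$masks[[1]]
  overlay <- pb$overlay_polar[[1]]
  pal <- plaque_classes()
  both <- masks$calcified_lipid > 0 & masks$lipid_pool > 0
  if (any(both)) {
    expect_true(all(overlay[both] == pal[["calcified_lipid"]]))
  }
  only_lp <- masks$lipid_pool > 0 & masks$calcified_lipid == 0
  if (any(only_lp)) {
    expect_true(all(overlay[only_lp] == pal[["lipid_pool"]]))
  }
  # overlay is presentation-only: masks carry exactly the thresholded values
  expect_true(all(masks$lipid_pool %in% c(0, 1)))
})

test_that("analytic gradients match central finite differences", {
  set.seed(55)
  net <- build_unet(unet_config(2, 3), seed = 5)
  x <- matrix(rnorm(8 * 12), 8, 12)
  tmap <- matrix(runif(96) > 0.6, 8, 12)
  vmap <- matrix(runif(96) > 0.2, 8, 12)
  al <- 0.7; be <- 0.3; ga <- 4 / 3
  loss_of <- function(net) {
    as.numeric(tversky_focal_loss(ivoctseg:::unet_forward(net, x)$p,
                                  tmap, vmap, al, be, ga))
  }
  fw <- ivoctseg:::unet_forward(net, x, want_cache = TRUE)
  pv <- fw$p[vmap]; tv <- tmap[vmap] * 1
  dp <- ivoctseg:::tversky_focal_grad(fw$p, tmap, vmap, sum(pv * tv),
                                      sum(pv * (1 - tv)),
                                      sum((1 - pv) * tv), al, be, ga)
  g <- ivoctseg:::unet_backward(net, fw$cache, dp)
  eps <- 5e-3
  errs <- c()
  for (nm in names(net$params)) {
    if (grepl("_b$", nm) && !grepl("att|up|out", nm)) next  # inert conv bias
    pn <- net$params[[nm]]
    for (k in sample(length(pn), min(2L, length(pn)))) {
      n1 <- net; n1$params[[nm]][k] <- pn[k] + eps
      n2 <- net; n2$params[[nm]][k] <- pn[k] - eps
      num <- (loss_of(n1) - loss_of(n2)) / (2 * eps)
      errs <- c(errs, abs(num - g[[nm]][k]) /
                  max(1e-4, abs(num) + abs(g[[nm]][k])))
    }
  }
  # single-precision forward + ReLU kinks put a floor on agreement; the
  # bulk of the coordinates must match closely
  expect_lt(median(errs), 0.01)
  expect_gt(mean(errs < 0.1), 0.85)
})
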