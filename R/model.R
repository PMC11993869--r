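#' Segmentation network configuration
#'
#' A U-Net-type fully convolutional encoder-decoder emitting a per-pixel
#' target probability.  Every convolution pads circularly along the angular
#' axis (rows), connecting the top and bottom edges of the polar image;
#' additive attention gates modulate the skip connections at the two
#' deepest levels ("attention in the middle layers").  One network is
#' trained per plaque type.
#'
#' @param depth_levels number of down/up-sampling stages.
#' @param base_channels channels at the first level; level `i` uses
#'   `base_channels * 2^(i-1)`.
#' @param attention enable attention gates on the two deepest skip
#'   connections.
#' @param pad_depth padding mode along the depth axis, `"zero"` or
#'   `"reflect"` (the angular axis is always circular).
#' @return an `unet_config` list; `total_stride` is `2^depth_levels`, and
#'   network inputs must have both dimensions divisible by it (a 200 px
#'   crop is reflect-padded to 208 internally).
#' @export
unet_config <- function(depth_levels = 4L, base_channels = 16L,
                        attention = TRUE, pad_depth = c("zero", "reflect")) {
  pad_depth <- match.arg(pad_depth)
  depth_levels <- as.integer(depth_levels)
  base_channels <- as.integer(base_channels)
  if (depth_levels < 1L || base_channels < 1L) {
    stop_config("depth_levels and base_channels must be >= 1")
  }
  structure(list(depth_levels = depth_levels, base_channels = base_channels,
                 attention = attention, pad_depth = pad_depth,
                 total_stride = 2L^depth_levels),
            class = "unet_config")
}

att_levels <- function(config) {
  if (!config$attention) return(integer(0))
  D <- config$depth_levels
  sort(unique(pmax(1L, c(D, D - 1L))))
}

level_channels <- function(config, i) config$base_channels * 2L^(i - 1L)

init_conv3 <- function(cin, cout) {
  array(stats::rnorm(9L * cin * cout, 0, sqrt(2 / (9 * cin))),
        c(3L, 3L, cin, cout))
}

init_lin <- function(cin, cout) {
  matrix(stats::rnorm(cin * cout, 0, sqrt(2 / cin)), cin, cout)
}

#' Build an untrained segmentation network
#'
#' Parameter shapes are a pure function of the configuration; the seed only
#' randomizes the initial values (He-scaled normal weights, zero biases).
#'
#' @param config an [unet_config()].
#' @param seed RNG seed for initialization.
#' @return an `ivoct_unet` with the parameter list and configuration.
#' @export
build_unet <- function(config = unet_config(), seed = 1L) {
  stopifnot(inherits(config, "unet_config"))
  D <- config$depth_levels
  p <- list()
  withr::with_seed(as.integer(seed), {
    cin <- 1L
    for (i in seq_len(D)) {
      ci <- level_channels(config, i)
      p[[paste0("enc", i, "_c1_w")]] <- init_conv3(cin, ci)
      p[[paste0("enc", i, "_c1_b")]] <- numeric(ci)
      p[[paste0("enc", i, "_c1_g")]] <- rep(1, ci)
      p[[paste0("enc", i, "_c1_nb")]] <- numeric(ci)
      p[[paste0("enc", i, "_c2_w")]] <- init_conv3(ci, ci)
      p[[paste0("enc", i, "_c2_b")]] <- numeric(ci)
      p[[paste0("enc", i, "_c2_g")]] <- rep(1, ci)
      p[[paste0("enc", i, "_c2_nb")]] <- numeric(ci)
      cin <- ci
    }
    cb <- level_channels(config, D + 1L)
    p[["bot_c1_w"]] <- init_conv3(cin, cb)
    p[["bot_c1_b"]] <- numeric(cb)
    p[["bot_c1_g"]] <- rep(1, cb)
    p[["bot_c1_nb"]] <- numeric(cb)
    p[["bot_c2_w"]] <- init_conv3(cb, cb)
    p[["bot_c2_b"]] <- numeric(cb)
    p[["bot_c2_g"]] <- rep(1, cb)
    p[["bot_c2_nb"]] <- numeric(cb)
    prev <- cb
    for (i in rev(seq_len(D))) {
      ci <- level_channels(config, i)
      p[[paste0("dec", i, "_up_w")]] <- init_lin(prev, ci)
      p[[paste0("dec", i, "_up_b")]] <- numeric(ci)
      if (i %in% att_levels(config)) {
        fi <- max(1L, ci %/% 2L)
        p[[paste0("dec", i, "_att_wg")]] <- init_lin(ci, fi)
        p[[paste0("dec", i, "_att_bg")]] <- numeric(fi)
        p[[paste0("dec", i, "_att_wx")]] <- init_lin(ci, fi)
        p[[paste0("dec", i, "_att_bx")]] <- numeric(fi)
        p[[paste0("dec", i, "_att_psi")]] <- init_lin(fi, 1L)
        p[[paste0("dec", i, "_att_bp")]] <- numeric(1L)
      }
      p[[paste0("dec", i, "_c1_w")]] <- init_conv3(2L * ci, ci)
      p[[paste0("dec", i, "_c1_b")]] <- numeric(ci)
      p[[paste0("dec", i, "_c1_g")]] <- rep(1, ci)
      p[[paste0("dec", i, "_c1_nb")]] <- numeric(ci)
      p[[paste0("dec", i, "_c2_w")]] <- init_conv3(ci, ci)
      p[[paste0("dec", i, "_c2_b")]] <- numeric(ci)
      p[[paste0("dec", i, "_c2_g")]] <- rep(1, ci)
      p[[paste0("dec", i, "_c2_nb")]] <- numeric(ci)
      prev <- ci
    }
    p[["out_w"]] <- init_lin(level_channels(config, 1L), 1L)
    p[["out_b"]] <- numeric(1L)
  })
  structure(list(config = config, params = p), class = "ivoct_unet")
}

#' Number of trainable parameters
#' @param net an `ivoct_unet` or `ivoct_model`.
#' @export
n_params <- function(net) {
  p <- if (inherits(net, "ivoct_model")) net$net$params else net$params
  sum(vapply(p, length, numeric(1)))
}

check_input_shape <- function(config, H, W) {
  s <- config$total_stride
  if (H %% s != 0L || W %% s != 0L) {
    stop_data(paste0(
      "input shape ", H, " x ", W, " not divisible by total stride ", s,
      "; pad the angular axis circularly and the depth axis (e.g. reflect ",
      "200 -> 208) before prediction"))
  }
}

# One conv3x3 -> instance norm -> ReLU block (the standard double-conv
# halves), fused in compiled code; IN internals go into the cache.  The
# conv bias is inert under instance normalization (constant channel shifts
# cancel), so its gradient is identically zero.
conv_in_relu_fwd <- function(h, p, prefix, pad_mode, cache) {
  d <- dim(p[[paste0(prefix, "_w")]])
  blk <- .cpp_conv_in_relu_fwd(h, matrix(p[[paste0(prefix, "_w")]],
                                         9L * d[3], d[4]),
                               p[[paste0(prefix, "_g")]],
                               p[[paste0(prefix, "_nb")]], pad_mode)
  cache[[paste0(prefix, "_blk")]] <- blk
  list(a = blk$a, cache = cache)
}

conv_in_relu_bwd <- function(da, x_in, p, prefix, pad_mode, cache, g) {
  blk <- cache[[paste0(prefix, "_blk")]]
  w4 <- p[[paste0(prefix, "_w")]]
  d <- dim(w4)
  r <- .cpp_conv_in_relu_bwd(x_in, matrix(w4, 9L * d[3], d[4]), da,
                             blk$a, blk$xhat, blk$s,
                             p[[paste0(prefix, "_g")]], pad_mode)
  g[[paste0(prefix, "_g")]] <- r$dg
  g[[paste0(prefix, "_nb")]] <- r$dnb
  g[[paste0(prefix, "_w")]] <- array(r$dw, dim = d)
  g[[paste0(prefix, "_b")]] <- numeric(d[4])
  list(dx = r$dx, g = g)
}

# Forward pass on one image.  x: H x W matrix, already normalized and
# stride-divisible.  Returns list(p = probability matrix, cache).  The
# compiled whole-network path is used everywhere; the R composition below
# (unet_forward_ref/unet_backward_ref) implements the same layers step by
# step and serves as its independent reference in the tests.
unet_forward <- function(net, x, want_cache = FALSE) {
  cfg <- net$config
  check_input_shape(cfg, nrow(x), ncol(x))
  pad_mode <- if (cfg$pad_depth == "zero") PAD_DEPTH_ZERO else PAD_DEPTH_REFLECT
  .cpp_unet_fwd(net$params, x, cfg$depth_levels, pad_mode,
                cfg$attention * 1L, want_cache)
}

unet_backward <- function(net, cache, dprob) {
  .cpp_unet_bwd(net$params, cache, dprob)
}

unet_forward_ref <- function(net, x, want_cache = FALSE) {
  cfg <- net$config
  p <- net$params
  pad_mode <- if (cfg$pad_depth == "zero") PAD_DEPTH_ZERO else PAD_DEPTH_REFLECT
  H <- nrow(x); W <- ncol(x)
  check_input_shape(cfg, H, W)
  D <- cfg$depth_levels
  cache <- list()
  h <- array(x, c(H, W, 1L))
  for (i in seq_len(D)) {
    cache[[paste0("enc", i, "_in")]] <- h
    r1 <- conv_in_relu_fwd(h, p, paste0("enc", i, "_c1"), pad_mode, cache)
    cache <- r1$cache
    a1 <- r1$a
    cache[[paste0("enc", i, "_a1")]] <- a1
    r2 <- conv_in_relu_fwd(a1, p, paste0("enc", i, "_c2"), pad_mode, cache)
    cache <- r2$cache
    a2 <- r2$a
    cache[[paste0("skip", i)]] <- a2
    pool <- .cpp_maxpool2_fwd(a2)
    cache[[paste0("pool", i, "_idx")]] <- pool$idx
    cache[[paste0("pool", i, "_dim")]] <- dim(a2)
    h <- pool$y
  }
  cache[["bot_in"]] <- h
  rb <- conv_in_relu_fwd(h, p, "bot_c1", pad_mode, cache)
  cache <- rb$cache
  b1 <- rb$a
  cache[["bot_a1"]] <- b1
  rb <- conv_in_relu_fwd(b1, p, "bot_c2", pad_mode, cache)
  cache <- rb$cache
  h <- rb$a
  cache[["bot_a2"]] <- h
  for (i in rev(seq_len(D))) {
    u0 <- .cpp_upsample2_fwd(h)
    cache[[paste0("dec", i, "_u0")]] <- u0
    u <- relu(lin1x1_fwd(u0, p[[paste0("dec", i, "_up_w")]],
                         p[[paste0("dec", i, "_up_b")]]))
    cache[[paste0("dec", i, "_u")]] <- u
    s <- cache[[paste0("skip", i)]]
    if (i %in% att_levels(cfg)) {
      dd <- dim(s)
      U <- as_hwc(u); S <- as_hwc(s)
      pre <- sweep(U %*% p[[paste0("dec", i, "_att_wg")]], 2L,
                   p[[paste0("dec", i, "_att_bg")]], "+") +
        sweep(S %*% p[[paste0("dec", i, "_att_wx")]], 2L,
              p[[paste0("dec", i, "_att_bx")]], "+")
      q <- relu(pre)
      alpha <- sigmoid(q %*% p[[paste0("dec", i, "_att_psi")]] +
                         p[[paste0("dec", i, "_att_bp")]][1])
      cache[[paste0("dec", i, "_att_q")]] <- q
      cache[[paste0("dec", i, "_att_alpha")]] <- alpha
      s_gated <- S * as.vector(alpha)
      s <- as_cube(s_gated, dd[1], dd[2])
    }
    cat_ <- concat_c(u, s)
    cache[[paste0("dec", i, "_cat")]] <- cat_
    r1 <- conv_in_relu_fwd(cat_, p, paste0("dec", i, "_c1"), pad_mode, cache)
    cache <- r1$cache
    a1 <- r1$a
    cache[[paste0("dec", i, "_a1")]] <- a1
    r2 <- conv_in_relu_fwd(a1, p, paste0("dec", i, "_c2"), pad_mode, cache)
    cache <- r2$cache
    h <- r2$a
    cache[[paste0("dec", i, "_a2")]] <- h
  }
  cache[["head_in"]] <- h
  logit <- lin1x1_fwd(h, p$out_w, p$out_b)
  prob <- sigmoid(logit)
  cache[["prob"]] <- prob
  out <- list(p = matrix(prob, H, W))
  if (want_cache) out$cache <- cache
  out
}

# Backward pass for one image: dprob is dLoss/dprob (H x W matrix).
# Returns gradient list with the same names/shapes as net$params.
unet_backward_ref <- function(net, cache, dprob) {
  cfg <- net$config
  p <- net$params
  pad_mode <- if (cfg$pad_depth == "zero") PAD_DEPTH_ZERO else PAD_DEPTH_REFLECT
  D <- cfg$depth_levels
  g <- list()
  prob <- cache[["prob"]]
  dlogit <- array(dprob, dim(prob)) * prob * (1 - prob)
  bw <- lin1x1_bwd(cache[["head_in"]], p$out_w, dlogit)
  g$out_w <- bw$dw; g$out_b <- bw$db
  dh <- bw$dx
  for (i in seq_len(D)) {
    r2 <- conv_in_relu_bwd(dh, cache[[paste0("dec", i, "_a1")]], p,
                           paste0("dec", i, "_c2"), pad_mode, cache, g)
    g <- r2$g
    r1 <- conv_in_relu_bwd(r2$dx, cache[[paste0("dec", i, "_cat")]], p,
                           paste0("dec", i, "_c1"), pad_mode, cache, g)
    g <- r1$g
    dcat <- r1$dx
    ci <- level_channels(cfg, i)
    du <- dcat[, , seq_len(ci), drop = FALSE]
    ds_out <- dcat[, , ci + seq_len(ci), drop = FALSE]
    s_full <- cache[[paste0("skip", i)]]
    if (i %in% att_levels(cfg)) {
      dd <- dim(s_full)
      S <- as_hwc(s_full)
      U <- as_hwc(cache[[paste0("dec", i, "_u")]])
      q <- cache[[paste0("dec", i, "_att_q")]]
      alpha <- as.vector(cache[[paste0("dec", i, "_att_alpha")]])
      dSg <- as_hwc(ds_out)
      dalpha <- rowSums(dSg * S)
      dS <- dSg * alpha
      dzp <- dalpha * alpha * (1 - alpha)
      g[[paste0("dec", i, "_att_psi")]] <- t(q) %*% dzp
      g[[paste0("dec", i, "_att_bp")]] <- sum(dzp)
      dq <- dzp %*% t(p[[paste0("dec", i, "_att_psi")]])
      dq[q <= 0] <- 0
      g[[paste0("dec", i, "_att_wg")]] <- t(U) %*% dq
      g[[paste0("dec", i, "_att_bg")]] <- colSums(dq)
      g[[paste0("dec", i, "_att_wx")]] <- t(S) %*% dq
      g[[paste0("dec", i, "_att_bx")]] <- colSums(dq)
      dU_att <- dq %*% t(p[[paste0("dec", i, "_att_wg")]])
      dS <- dS + dq %*% t(p[[paste0("dec", i, "_att_wx")]])
      du <- du + as_cube(dU_att, dd[1], dd[2])
      ds_skip <- as_cube(dS, dd[1], dd[2])
    } else {
      ds_skip <- ds_out
    }
    dz_u <- relu_bwd(du, cache[[paste0("dec", i, "_u")]])
    lb <- lin1x1_bwd(cache[[paste0("dec", i, "_u0")]],
                     p[[paste0("dec", i, "_up_w")]], dz_u)
    g[[paste0("dec", i, "_up_w")]] <- lb$dw
    g[[paste0("dec", i, "_up_b")]] <- lb$db
    dh_coarse <- .cpp_upsample2_bwd(lb$dx)
    # gradient into the skip rejoins the encoder branch later
    cache[[paste0("skip_grad", i)]] <- ds_skip
    dh <- dh_coarse
  }
  # bottleneck, then the encoder chain (deepest level first)
  r2 <- conv_in_relu_bwd(dh, cache[["bot_a1"]], p, "bot_c2", pad_mode,
                         cache, g)
  g <- r2$g
  r1 <- conv_in_relu_bwd(r2$dx, cache[["bot_in"]], p, "bot_c1", pad_mode,
                         cache, g)
  g <- r1$g
  dh <- r1$dx
  for (i in rev(seq_len(D))) {
    pdim <- cache[[paste0("pool", i, "_dim")]]
    dskip <- .cpp_maxpool2_bwd(cache[[paste0("pool", i, "_idx")]], dh,
                               pdim[1], pdim[2], pdim[3])
    dskip <- dskip + cache[[paste0("skip_grad", i)]]
    r2 <- conv_in_relu_bwd(dskip, cache[[paste0("enc", i, "_a1")]], p,
                           paste0("enc", i, "_c2"), pad_mode, cache, g)
    g <- r2$g
    r1 <- conv_in_relu_bwd(r2$dx, cache[[paste0("enc", i, "_in")]], p,
                           paste0("enc", i, "_c1"), pad_mode, cache, g)
    g <- r1$g
    dh <- r1$dx
  }
  g
}

# ---- prediction ------------------------------------------------------------

# Training-time normalization: log-compress, then standardize with the
# training-set statistics recorded on the model.
normalize_input <- function(x, norm) {
  (log1p(x) - norm$mean) / norm$sd
}

# Pad columns on the right (reflect) up to a multiple of the stride; rows
# must already be divisible (the angular extent is fixed by acquisition).
pad_depth_to_stride <- function(x, stride) {
  W <- ncol(x)
  extra <- (stride - W %% stride) %% stride
  if (extra == 0L) return(list(x = x, pad = 0L))
  refl <- x[, W:(W - extra + 1L), drop = FALSE]
  list(x = cbind(x, refl), pad = extra)
}

#' Predict a single flattened frame
#'
#' Normalizes the frame with the model's recorded training statistics,
#' reflect-pads the depth axis to the network stride (200 px -> 208),
#' runs the network and crops back, returning the per-pixel target
#' probability and its thresholded binary mask.
#'
#' @param model an `ivoct_model` from [train_model()] (or an `ivoct_unet`
#'   plus explicit `norm`).
#' @param flattened a `flat_frame` from [flatten_frame()] or an intensity
#'   matrix in the crop domain.
#' @param threshold probability cut for the binary mask; the mask positive
#'   count is non-increasing in the threshold.
#' @param norm optional list(mean, sd) overriding the model's statistics.
#' @return list with `prob` (matrix in `[0,1]`) and `mask` (logical).
#' @export
predict_frame <- function(model, flattened, threshold = 0.5, norm = NULL) {
  net <- if (inherits(model, "ivoct_model")) model$net else model
  norm <- norm %||% model$norm
  if (is.null(norm)) stop_config("no normalization statistics available")
  M <- if (is.list(flattened)) flattened$intensities else flattened
  stopifnot(is.matrix(M))
  xn <- normalize_input(M, norm)
  padded <- pad_depth_to_stride(xn, net$config$total_stride)
  fw <- unet_forward(net, padded$x)
  prob <- fw$p[, seq_len(ncol(M)), drop = FALSE]
  list(prob = prob, mask = prob >= threshold)
}

#' Predict a pullback with one model per plaque type
#'
#' Runs the full inference workflow on a sequence of polar frames: detect
#' the lumen, flatten and crop, predict each plaque type with its own
#' network, and scatter each prediction back to the original polar
#' geometry.  A colorized overlay resolves per-pixel multi-class positivity
#' by fixed priority (calcified lipid > calcified fibrous > lipid pool >
#' fibrofatty) and is rendered in both polar and cartesian form; the
#' per-class masks themselves are not altered by the overlay.
#'
#' @param models named list of `ivoct_model`s (names = target classes).
#' @param frames list of `ivoct_frame`s or intensity matrices.
#' @param crop_depth flattening crop.
#' @param threshold probability cut.
#' @param contours optional list of known lumen contours (bypasses
#'   detection, e.g. for phantoms).
#' @param cartesian_px side length of the cartesian overlay render.
#' @return list with `masks` (per frame: named list of full-size polar
#'   class masks), `overlay_polar`, `overlay_cartesian` (palette-coded
#'   integer matrices), `skipped` (frames failing lumen detection) and
#'   `summary` tibble.
#' @export
predict_pullback <- function(models, frames, crop_depth = 200L,
                             threshold = 0.5, contours = NULL,
                             cartesian_px = NULL) {
  if (length(models) == 0) stop_config("no models")
  if (is.null(names(models)) || any(!nzchar(names(models)))) {
    stop_config("models must be a named list keyed by target class")
  }
  overlay_priority <- c("calcified_lipid", "calcified_fibrous",
                        "lipid_pool", "fibrofatty")
  pal <- plaque_classes()
  results <- vector("list", length(frames))
  overlays_p <- vector("list", length(frames))
  overlays_c <- vector("list", length(frames))
  skipped <- integer(0)
  for (f in seq_along(frames)) {
    fr <- frames[[f]]
    M <- if (is.list(fr)) fr$intensities else fr
    contour <- if (!is.null(contours)) contours[[f]] else {
      tryCatch(detect_lumen(M), error = function(e) NULL)
    }
    if (is.null(contour) ||
        any(contour < 1L | contour > ncol(M) - crop_depth + 1L)) {
      skipped <- c(skipped, f)
      next
    }
    flat <- flatten_frame(M, contour, crop_depth)
    class_masks <- list()
    for (cl in names(models)) {
      pr <- predict_frame(models[[cl]], flat, threshold)
      class_masks[[cl]] <- unflatten_frame(pr$mask * 1, contour, dim(M),
                                           fill = 0)
    }
    overlay <- matrix(0L, nrow(M), ncol(M))
    for (cl in rev(intersect(overlay_priority, names(class_masks)))) {
      overlay[class_masks[[cl]] > 0] <- pal[[cl]]
    }
    results[[f]] <- class_masks
    overlays_p[[f]] <- overlay
    if (!is.null(cartesian_px)) {
      overlays_c[[f]] <- polar_to_cartesian(overlay, cartesian_px, "nearest")
    }
  }
  summary <- tibble::tibble(
    frame = seq_along(frames),
    predicted = !seq_along(frames) %in% skipped
  )
  list(masks = results, overlay_polar = overlays_p,
       overlay_cartesian = overlays_c, skipped = skipped, summary = summary)
}

#' @export
print.ivoct_unet <- function(x, ...) {
  cfg <- x$config
  cat("<ivoct_unet> depth", cfg$depth_levels, "| base", cfg$base_channels,
      "| stride", cfg$total_stride,
      "| attention:", ifelse(cfg$attention, "on", "off"),
      "|", format(n_params(x), big.mark = ","), "params\n")
  invisible(x)
}
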