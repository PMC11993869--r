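#' Tissue optical model for the phantom generator
#'
#' Image formation in the phantom follows a single-scatter exponential-decay
#' model: along each A-line the mean intensity beyond the lumen is
#' `base_reflectivity * exp(-2 * cumulative attenuation)`, multiplied by
#' gamma-distributed speckle and offset by an additive noise floor.  Each
#' plaque class carries its own attenuation, entry reflectivity, border
#' transition width and speckle correlation length, which is what creates
#' the contrasts a segmentation model must learn: calcified tissue has low
#' attenuation, a darker interior and sharp borders; lipid pools attenuate
#' rapidly with diffuse borders; fibrofatty sits in between, deliberately
#' overlapping the lipid-pool range.
#'
#' @param class_id class name from [plaque_classes()] (not `"lumen"`).
#' @param attenuation_mu attenuation coefficient per pixel (>= 0);
#'   at 5 um/px a value of 0.02/px corresponds to 4 mm^-1.
#' @param base_reflectivity mean backscatter at tissue entry, arbitrary
#'   intensity units (> 0).
#' @param border_sharpness edge transition width in pixels (>= 0; 0 = hard
#'   edge).
#' @param texture_scale speckle correlation length in pixels.
#' @return a `tissue_model` list.
#' @export
tissue_model <- function(class_id, attenuation_mu, base_reflectivity,
                         border_sharpness = 1, texture_scale = 1.5) {
  if (!class_id %in% tissue_class_names()) {
    stop_config(paste0("unknown tissue class: ", class_id))
  }
  if (attenuation_mu < 0) stop_config("attenuation_mu must be >= 0")
  if (base_reflectivity <= 0) stop_config("base_reflectivity must be > 0")
  if (border_sharpness < 0) stop_config("border_sharpness must be >= 0")
  structure(list(class_id = class_id, attenuation_mu = attenuation_mu,
                 base_reflectivity = base_reflectivity,
                 border_sharpness = border_sharpness,
                 texture_scale = texture_scale),
            class = "tissue_model")
}

#' Default tissue models
#'
#' One model per tissue class.  Attenuation is per pixel at the default
#' 5 um/px spacing (0.010/px = 2 mm^-1).  Calcium subtypes: low attenuation,
#' dark interior, sharp borders.  Lipid pool: high attenuation (rapid
#' shadowing), bright entry, diffuse borders.  Fibrofatty: intermediate
#' attenuation overlapping lipid pool, so the two are confusable by design.
#'
#' @return named list of [tissue_model()] objects.
#' @export
default_tissue_models <- function() {
  list(
    fibrous           = tissue_model("fibrous",           0.010, 1.00, 1.5, 1.5),
    lipid_pool        = tissue_model("lipid_pool",        0.032, 1.25, 6.0, 2.5),
    calcified_lipid   = tissue_model("calcified_lipid",   0.007, 0.40, 1.0, 1.5),
    fibrofatty        = tissue_model("fibrofatty",        0.020, 1.10, 5.0, 2.5),
    calcified_fibrous = tissue_model("calcified_fibrous", 0.006, 0.45, 1.0, 1.5)
  )
}

#' Phantom configuration
#'
#' Geometry and physics of one synthetic polar IVOCT frame.  Defaults give
#' 504 A-lines x 976 depth samples at 5 um/px (so a 200 px crop is ~1 mm).
#'
#' @param n_alines A-lines per frame (rows; the angular axis, periodic).
#' @param depth_px radial samples per A-line (columns).
#' @param pixel_um axial pixel spacing in micrometers.
#' @param lumen_radius_px mean lumen radius in pixels.
#' @param lumen_eccentricity relative amplitude of the first-harmonic
#'   (elliptic) radius modulation.
#' @param lumen_noise_px amplitude scale of low-order harmonic perturbations
#'   of the lumen contour, pixels.
#' @param inclusions list of inclusions, each a list with elements `class`
#'   (tissue class name), `aline_start` (1-based row), `aline_len` (span in
#'   A-lines, may wrap modulo `n_alines`), `depth_start` (1-based column),
#'   `depth_len`.
#' @param tissue_models named list of [tissue_model()]s, exactly one per
#'   tissue class used.
#' @param speckle_shape gamma shape of the multiplicative speckle (mean 1,
#'   variance 1/shape); `Inf` disables speckle.
#' @param noise_floor additive background intensity (same arbitrary units
#'   as reflectivity).
#' @param full_scale intensity mapped to the top of the 16-bit range when
#'   frames are quantized/stored.
#' @param seed default RNG seed for frame generation.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(n_alines = 504L, depth_px = 976L, pixel_um = 5,
                           lumen_radius_px = 160, lumen_eccentricity = 0.15,
                           lumen_noise_px = 6, inclusions = list(),
                           tissue_models = default_tissue_models(),
                           speckle_shape = 4, noise_floor = 0.005,
                           full_scale = 4, seed = 1L) {
  n_alines <- as.integer(n_alines); depth_px <- as.integer(depth_px)
  if (n_alines < 8L) stop_config("n_alines must be >= 8")
  ids <- vapply(tissue_models, function(t) t$class_id, character(1))
  if (anyDuplicated(ids)) stop_config("duplicate tissue models for a class")
  names(tissue_models) <- ids
  cfg <- structure(list(
    n_alines = n_alines, depth_px = depth_px, pixel_um = pixel_um,
    lumen_radius_px = lumen_radius_px,
    lumen_eccentricity = lumen_eccentricity, lumen_noise_px = lumen_noise_px,
    inclusions = inclusions, tissue_models = tissue_models,
    speckle_shape = speckle_shape, noise_floor = noise_floor,
    full_scale = full_scale, seed = as.integer(seed)
  ), class = "phantom_config")
  for (inc in inclusions) validate_inclusion(inc, cfg)
  cfg
}

validate_inclusion <- function(inc, cfg) {
  need <- c("class", "aline_start", "aline_len", "depth_start", "depth_len")
  if (!all(need %in% names(inc))) {
    stop_config(paste0("inclusion missing field(s): ",
                       paste(setdiff(need, names(inc)), collapse = ", ")))
  }
  if (!inc$class %in% tissue_class_names() || inc$class == "fibrous") {
    stop_config(paste0("inclusion class must be a plaque class, got: ",
                       inc$class))
  }
  if (is.null(cfg$tissue_models[[inc$class]])) {
    stop_config(paste0("no tissue model for inclusion class ", inc$class))
  }
  if (inc$aline_len < 1 || inc$aline_len > cfg$n_alines) {
    stop_config("inclusion aline_len out of range")
  }
  if (inc$depth_start < 1 || inc$depth_len < 1 ||
      inc$depth_start + inc$depth_len - 1 > cfg$depth_px) {
    stop_config("inclusion depth span out of [1, depth_px]")
  }
  invisible(inc)
}

# Rows covered by an inclusion, wrapping modulo n_alines.
inclusion_rows <- function(inc, n) {
  ((inc$aline_start - 1L + seq_len(inc$aline_len) - 1L) %% n) + 1L
}

sample_lumen_contour <- function(cfg) {
  n <- cfg$n_alines
  theta <- 2 * pi * (seq_len(n) - 1L) / n
  phase <- runif(1, 0, 2 * pi)
  r <- cfg$lumen_radius_px * (1 + cfg$lumen_eccentricity * cos(theta - phase))
  for (k in 2:4) {
    r <- r + runif(1, 0, cfg$lumen_noise_px / k) * cos(k * theta + runif(1, 0, 2 * pi))
  }
  r <- pmax(2, pmin(r, cfg$depth_px - 8))
  as.integer(round(r)) + 1L   # first tissue column (1-based)
}

#' Generate one synthetic polar IVOCT frame
#'
#' Renders the intensity image, the per-pixel label map and the true lumen
#' contour for one frame.  Beyond the lumen boundary every pixel carries
#' exactly one class label (fibrous by default, inclusion classes where
#' inclusions are placed); pixels inside the lumen carry the reserved lumen
#' label.  Intensity follows the exponential-decay model of
#' [tissue_model()], with per-class border softness applied by blending the
#' optical properties (never the labels) across borders.
#'
#' The same `(config, frame_seed)` pair always reproduces the same frame,
#' bit-identically at the stored-integer level.
#'
#' @param config a [phantom_config()].
#' @param frame_seed integer seed for this frame's randomness.
#' @param inclusions overrides `config$inclusions` when given.
#' @param priority optional character vector of class names, highest
#'   priority first, resolving overlaps between inclusions of different
#'   classes; without it such overlaps are an error.
#' @param raw keep the unquantized intensity field in the result (for
#'   closed-form checks).
#' @return an `ivoct_frame` list: `intensities` (quantized 16-bit values as
#'   a numeric matrix), `labels` (integer palette matrix), `contour`
#'   (1-based first-tissue column per A-line), plus spacing metadata.
#' @export
generate_frame <- function(config, frame_seed = config$seed,
                           inclusions = NULL, priority = NULL, raw = FALSE) {
  stopifnot(inherits(config, "phantom_config"))
  if (is.null(inclusions)) inclusions <- config$inclusions
  for (inc in inclusions) validate_inclusion(inc, config)
  n <- config$n_alines; W <- config$depth_px
  pal <- plaque_classes()

  withr::with_seed(as.integer(frame_seed), {
    contour <- sample_lumen_contour(config)

    # ---- label map -------------------------------------------------------
    labels <- matrix(pal[["fibrous"]], n, W)
    owner <- matrix(NA_character_, n, W)
    for (inc in inclusions) {
      rows <- inclusion_rows(inc, n)
      cols <- inc$depth_start:(inc$depth_start + inc$depth_len - 1L)
      block_owner <- owner[rows, cols, drop = FALSE]
      clash <- !is.na(block_owner) & block_owner != inc$class
      if (any(clash)) {
        if (is.null(priority)) {
          stop_data(paste0("overlapping inclusions of classes ",
                           inc$class, " and ",
                           paste(unique(block_owner[clash]), collapse = "/"),
                           "; supply a priority order"))
        }
        keep_old <- matrix(match(block_owner, priority) <=
                             match(inc$class, priority) & !is.na(block_owner),
                           nrow(block_owner), ncol(block_owner))
        block_owner[!keep_old] <- inc$class
        owner[rows, cols] <- block_owner
      } else {
        owner[rows, cols] <- inc$class
      }
    }
    for (cl in tissue_class_names()) {
      sel <- !is.na(owner) & owner == cl
      if (any(sel)) labels[sel] <- pal[[cl]]
    }
    lumen <- matrix(seq_len(W), n, W, byrow = TRUE) <
      matrix(contour, n, W)
    labels[lumen] <- pal[["lumen"]]
    storage.mode(labels) <- "integer"

    # ---- optical property fields ----------------------------------------
    mu <- matrix(0, n, W); refl <- matrix(0, n, W)
    wsum <- matrix(0, n, W)
    present <- intersect(tissue_class_names(),
                         names(pal)[match(unique(as.vector(labels)), pal)])
    fields <- list()
    for (cl in present) {
      tm <- config$tissue_models[[cl]]
      ind <- (labels == pal[[cl]]) * 1
      if (tm$border_sharpness >= 0.3) {
        sd <- tm$border_sharpness / 2
        ind <- smooth_rows_circular(smooth_depth(ind, sd), sd)
      }
      fields[[cl]] <- ind
      wsum <- wsum + ind
      mu <- mu + ind * tm$attenuation_mu
      refl <- refl + ind * tm$base_reflectivity
    }
    pos <- wsum > 0
    mu[pos] <- mu[pos] / wsum[pos]
    refl[pos] <- refl[pos] / wsum[pos]
    mu[lumen] <- 0; refl[lumen] <- 0

    # ---- attenuation (path integral excludes the current pixel) ---------
    mu_cum <- t(apply(mu, 1L, cumsum)) - mu
    signal <- refl * exp(-2 * mu_cum)

    # ---- speckle ---------------------------------------------------------
    if (is.finite(config$speckle_shape) && config$speckle_shape > 0) {
      spk <- matrix(rgamma(n * W, shape = config$speckle_shape,
                           rate = config$speckle_shape), n, W)
      scales <- sort(unique(vapply(config$tissue_models[present],
                                   function(t) t$texture_scale, numeric(1))))
      if (length(scales) > 0 && any(scales > 0.3)) {
        smoothed <- lapply(scales, function(s) {
          if (s < 0.3) return(spk)
          smooth_rows_circular(smooth_depth(spk, s / 2), s / 2)
        })
        names(smoothed) <- as.character(scales)
        blend <- matrix(0, n, W); bw <- matrix(0, n, W)
        for (cl in present) {
          s <- config$tissue_models[[cl]]$texture_scale
          blend <- blend + fields[[cl]] * smoothed[[as.character(s)]]
          bw <- bw + fields[[cl]]
        }
        spk_eff <- spk
        spk_eff[pos] <- blend[pos] / bw[pos]
        spk <- spk_eff
      }
    } else {
      spk <- matrix(1, n, W)
    }

    intensity <- signal * spk + config$noise_floor
  })

  stored <- round(pmin(pmax(intensity / config$full_scale, 0), 1) * 65535)
  out <- structure(list(
    intensities = stored, labels = labels, contour = contour,
    pixel_um = config$pixel_um, n_alines = n, depth_px = W,
    full_scale = config$full_scale
  ), class = "ivoct_frame")
  if (raw) out$intensity_raw <- intensity
  out
}

#' Generate a phantom dataset with a heart/artery/frame hierarchy
#'
#' Samples frames organized as hearts containing arteries containing
#' frames, the grouping the split logic needs.  Per frame, each plaque
#' class is present independently with its `class_prevalence` probability;
#' present classes are placed as angularly disjoint inclusions (so no
#' overlap priority is ever needed), with spans allowed to wrap across the
#' polar seam.
#'
#' @param config a [phantom_config()]; its `inclusions` field is ignored
#'   here (inclusions are sampled per frame).
#' @param n_hearts,arteries_per_heart,frames_per_artery hierarchy counts
#'   (all >= 1).
#' @param class_prevalence named per-class probability that a frame
#'   contains the class.
#' @param seed RNG seed for the whole dataset.
#' @param dir output directory; when `NULL` frames stay in memory as list
#'   columns of the manifest.
#' @param overwrite allow writing into an existing non-empty directory.
#' @param keep_arrays keep in-memory arrays in the manifest even when
#'   writing to disk.
#' @return a tibble manifest with columns `heart_id`, `artery_id`,
#'   `frame_id`, `image_path`, `label_path`, one `has_<class>` flag per
#'   plaque class, and (in-memory mode) list columns `image`, `labels`,
#'   `contour`.
#' @export
generate_dataset <- function(config, n_hearts, arteries_per_heart,
                             frames_per_artery,
                             class_prevalence = c(lipid_pool = 0.50,
                                                  calcified_lipid = 0.25,
                                                  fibrofatty = 0.40,
                                                  calcified_fibrous = 0.45),
                             seed = 1L, dir = NULL, overwrite = FALSE,
                             keep_arrays = is.null(dir)) {
  stopifnot(inherits(config, "phantom_config"))
  if (n_hearts < 1 || arteries_per_heart < 1 || frames_per_artery < 1) {
    stop_config("all hierarchy counts must be >= 1")
  }
  bad <- setdiff(names(class_prevalence), setdiff(tissue_class_names(), "fibrous"))
  if (length(bad)) stop_config(paste0("unknown class in prevalence: ", bad[1]))
  if (!is.null(dir)) {
    if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite) {
      stop_data(paste0("output directory not empty: ", dir,
                       " (set overwrite = TRUE)"))
    }
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  }

  n_frames <- n_hearts * arteries_per_heart * frames_per_artery
  seeds <- derive_seeds(seed, n_frames + 1L)
  rows <- vector("list", n_frames)
  q <- 0L
  for (h in seq_len(n_hearts)) {
    for (a in seq_len(arteries_per_heart)) {
      for (f in seq_len(frames_per_artery)) {
        q <- q + 1L
        fs <- seeds[q]
        incs <- withr::with_seed(fs, sample_frame_inclusions(config, class_prevalence))
        fr <- generate_frame(config, frame_seed = seeds[q] %% (2^31 - 2) + 1,
                             inclusions = incs)
        heart_id <- sprintf("H%02d", h)
        artery_id <- sprintf("H%02d_A%d", h, a)
        frame_id <- sprintf("%s_F%03d", artery_id, f)
        image_path <- label_path <- NA_character_
        if (!is.null(dir)) {
          image_path <- file.path(dir, paste0(frame_id, ".tif"))
          label_path <- file.path(dir, paste0(frame_id, "_labels.png"))
          write_polar_tiff(fr$intensities, image_path)
          write_label_png(fr$labels, label_path)
        }
        present <- vapply(names(class_prevalence), function(cl) {
          any(vapply(incs, function(i) i$class == cl, logical(1)))
        }, logical(1))
        row <- tibble::tibble(heart_id = heart_id, artery_id = artery_id,
                              frame_id = frame_id, image_path = image_path,
                              label_path = label_path)
        for (cl in names(class_prevalence)) {
          row[[paste0("has_", cl)]] <- unname(present[cl])
        }
        if (keep_arrays) {
          row$image <- list(fr$intensities)
          row$labels <- list(fr$labels)
          row$contour <- list(fr$contour)
        }
        rows[[q]] <- row
      }
    }
  }
  manifest <- dplyr::bind_rows(rows)
  if (!is.null(dir)) {
    readr::write_csv(dplyr::select(manifest, -dplyr::any_of(c("image", "labels", "contour"))),
                     file.path(dir, "manifest.csv"))
  }
  attr(manifest, "phantom_seed") <- seed
  manifest
}

# Sample angularly disjoint inclusions for the classes present in a frame.
sample_frame_inclusions <- function(config, class_prevalence) {
  n <- config$n_alines; W <- config$depth_px
  present <- names(class_prevalence)[
    rbinom(length(class_prevalence), 1L, class_prevalence) == 1L]
  if (length(present) == 0) return(list())
  present <- sample(present)
  spans <- pmax(4L, round(runif(length(present), 0.08, 0.20) * n))
  total <- sum(spans)
  if (total >= n) spans <- pmax(4L, floor(spans * (n - length(present)) / total))
  slack <- n - sum(spans)
  cuts <- sort(runif(length(present)))
  gaps <- floor(diff(c(0, cuts)) / max(cuts) * slack)
  offset <- sample.int(n, 1L)
  # depth placement beyond the deepest possible lumen radius
  lumen_max <- ceiling(config$lumen_radius_px * (1 + config$lumen_eccentricity) +
                         config$lumen_noise_px) + 3L
  start <- offset
  incs <- vector("list", length(present))
  for (i in seq_along(present)) {
    start <- start + gaps[i]
    d_len <- round(runif(1, 0.08, 0.28) * W)
    d_max <- W - d_len
    d_lo <- min(lumen_max + 2L, d_max)
    d_start <- round(runif(1, d_lo, max(d_lo, min(d_max, lumen_max + 0.30 * W))))
    incs[[i]] <- list(class = present[i],
                      aline_start = ((start - 1L) %% n) + 1L,
                      aline_len = spans[i],
                      depth_start = as.integer(d_start),
                      depth_len = as.integer(d_len))
    start <- start + spans[i]
  }
  incs
}
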