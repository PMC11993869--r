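#' Default experiment configuration
#'
#' The resolved configuration drives [run_experiment()]: dataset source
#' (an existing manifest or a simulated phantom dataset), split policy,
#' model architecture, per-class loss parameters, training schedule,
#' evaluation and rendering options.  Unknown keys in a user YAML are
#' rejected; the resolved (defaults-applied) document is persisted
#' verbatim into every experiment directory, so a directory plus the
#' package version reproduces the experiment.
#'
#' @return nested list of defaults.
#' @export
default_experiment_config <- function() {
  list(
    seed = 1L,
    dataset = list(
      manifest = NULL,
      simulate = list(
        n_hearts = 10L, arteries_per_heart = 2L, frames_per_artery = 10L,
        n_alines = 128L, depth_px = 256L, pixel_um = 5,
        lumen_radius_px = 24, lumen_eccentricity = 0.12, lumen_noise_px = 3,
        speckle_shape = 4, noise_floor = 0.005,
        prevalence = list(lipid_pool = 0.50, calcified_lipid = 0.25,
                          fibrofatty = 0.40, calcified_fibrous = 0.45),
        seed = 1L
      )
    ),
    split = list(mode = "random_grouped", ratios = c(0.70, 0.15, 0.15),
                 seed = 1L, tolerance = 0.05),
    model = list(depth_levels = 4L, base_channels = 16L, attention = TRUE,
                 pad_depth = "zero"),
    loss = list(),
    schedule = list(epochs = 60L, lr = 1e-4, plateau_factor = 0.5,
                    patience = 4L, batch_size = 8L, augment = TRUE,
                    n_runs = 1L),
    classes = c("combined_lipid", "combined_calcium"),
    preprocess = list(crop_depth = 200L, use_true_contour = TRUE,
                      boundary = "auto"),
    evaluate = list(threshold = 0.5, min_pixels = 1L),
    render = list(cartesian_px = 512L, n_examples = 1L)
  )
}

merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user) || !is.list(defaults)) return(user)
  extra <- setdiff(names(user), names(defaults))
  # loss and prevalence sections are keyed by class name, not schema-fixed
  open_sections <- c("loss", "prevalence")
  if (length(extra) > 0 && !basename(path) %in% open_sections) {
    stop_config(paste0("unknown configuration key(s) under '",
                       ifelse(path == "", "<root>", path), "': ",
                       paste(extra, collapse = ", ")))
  }
  out <- defaults
  for (nm in names(user)) {
    out[[nm]] <- if (nm %in% names(defaults)) {
      merge_config(defaults[[nm]], user[[nm]], paste0(path, "/", nm))
    } else {
      user[[nm]]
    }
  }
  out
}

#' Load and validate an experiment YAML
#'
#' @param path YAML file; its keys are validated against
#'   [default_experiment_config()] and merged over the defaults.
#' @return resolved configuration list.
#' @export
load_experiment_config <- function(path) {
  if (!file.exists(path)) stop_config(paste0("config not found: ", path))
  user <- yaml::read_yaml(path)
  cfg <- merge_config(default_experiment_config(), user)
  if (length(cfg$split$ratios) != 3) stop_config("split.ratios must have 3 entries")
  bad <- setdiff(cfg$classes, target_class_names())
  if (length(bad)) stop_config(paste0("unknown class in classes: ", bad[1]))
  cfg
}

experiment_phantom_config <- function(cfg) {
  s <- cfg$dataset$simulate
  phantom_config(
    n_alines = s$n_alines, depth_px = s$depth_px, pixel_um = s$pixel_um,
    lumen_radius_px = s$lumen_radius_px,
    lumen_eccentricity = s$lumen_eccentricity,
    lumen_noise_px = s$lumen_noise_px,
    speckle_shape = s$speckle_shape, noise_floor = s$noise_floor,
    seed = s$seed
  )
}

#' Run a full experiment from a configuration
#'
#' Executes the end-to-end workflow: obtain the dataset (simulate phantoms
#' or load a manifest), split it with artery grouping, train one network
#' per configured class, evaluate Dice and A-line metrics on the
#' validation and test splits, and render example overlays.  The
#' experiment directory receives the resolved config, the split manifest,
#' per-class model weights + sidecars, per-epoch history, metrics tables
#' (one row per class x split, mirroring the usual subtype results layout)
#' and rendered examples.  Any stage failure aborts with the stage name;
#' artifacts written before the failure are kept.
#'
#' @param config a resolved config list or a YAML path.
#' @param out_dir experiment directory (created if needed).
#' @return invisibly, a list with `metrics`, `models`, `manifest`, `dir`.
#' @export
run_experiment <- function(config, out_dir) {
  cfg <- if (is.character(config)) load_experiment_config(config) else {
    merge_config(default_experiment_config(), config)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg, file.path(out_dir, "config_resolved.yaml"))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("experiment stage '", name, "' failed: ",
                   conditionMessage(e)), parent = e)
    })
  }

  manifest <- stage("dataset", {
    if (!is.null(cfg$dataset$manifest)) {
      m <- readr::read_csv(cfg$dataset$manifest, show_col_types = FALSE)
      m
    } else {
      s <- cfg$dataset$simulate
      generate_dataset(experiment_phantom_config(cfg),
                       n_hearts = s$n_hearts,
                       arteries_per_heart = s$arteries_per_heart,
                       frames_per_artery = s$frames_per_artery,
                       class_prevalence = unlist(s$prevalence),
                       seed = s$seed)
    }
  })

  manifest <- stage("split", {
    m <- make_splits(manifest, ratios = unlist(cfg$split$ratios),
                     mode = cfg$split$mode, seed = cfg$split$seed,
                     tolerance = cfg$split$tolerance)
    readr::write_csv(
      dplyr::select(m, -dplyr::any_of(c("image", "labels", "contour"))),
      file.path(out_dir, "split_manifest.csv"))
    m
  })

  model_cfg <- unet_config(cfg$model$depth_levels, cfg$model$base_channels,
                           cfg$model$attention, cfg$model$pad_depth)
  sched <- training_schedule(cfg$schedule$epochs, cfg$schedule$lr,
                             cfg$schedule$plateau_factor,
                             cfg$schedule$patience, cfg$schedule$batch_size,
                             cfg$schedule$augment, cfg$schedule$n_runs)

  models <- list()
  metric_rows <- list()
  per_frame_rows <- list()
  for (cl in cfg$classes) {
    lp <- utils::modifyList(default_loss_params(cl),
                            cfg$loss[[cl]] %||% list())
    samples <- stage(paste0("prepare:", cl), {
      lapply(c(train = "train", validation = "validation", test = "test"),
             function(sp) {
               prepare_training_samples(
                 manifest[manifest$split == sp, , drop = FALSE], cl,
                 crop_depth = cfg$preprocess$crop_depth,
                 use_true_contour = cfg$preprocess$use_true_contour,
                 boundary = cfg$preprocess$boundary)
             })
    })
    model <- stage(paste0("train:", cl), {
      train_model(samples$train, samples$validation, cl,
                  model_config = model_cfg, loss_params = lp,
                  schedule = sched, seed = cfg$seed)
    })
    save_model(model, file.path(out_dir, paste0("model_", cl, ".rds")))
    readr::write_csv(model$history,
                     file.path(out_dir, paste0("history_", cl, ".csv")))
    models[[cl]] <- model
    for (sp in c("validation", "test")) {
      if (length(samples[[sp]]) == 0) next
      ev <- stage(paste0("evaluate:", cl, ":", sp), {
        evaluate_dataset(samples[[sp]], model,
                         threshold = cfg$evaluate$threshold,
                         min_pixels = cfg$evaluate$min_pixels)
      })
      metric_rows[[paste(cl, sp)]] <- dplyr::bind_cols(
        tibble::tibble(class = cl, split = sp), ev$metrics)
      per_frame_rows[[paste(cl, sp)]] <- dplyr::bind_cols(
        tibble::tibble(class = cl, split = sp), ev$per_frame)
    }
  }

  metrics <- dplyr::bind_rows(metric_rows)
  readr::write_csv(metrics, file.path(out_dir, "metrics.csv"))
  readr::write_csv(dplyr::bind_rows(per_frame_rows),
                   file.path(out_dir, "per_frame.csv"))

  stage("render", {
    test_rows <- which(manifest$split == "test")
    n_ex <- min(cfg$render$n_examples, length(test_rows))
    if (n_ex > 0 && !is.null(manifest$image)) {
      for (e in seq_len(n_ex)) {
        row <- manifest[test_rows[e], ]
        fr <- manifest_image(row)
        contours <- if (!is.null(row$contour)) list(row$contour[[1]]) else NULL
        pb <- predict_pullback(models, list(fr),
                               crop_depth = cfg$preprocess$crop_depth,
                               threshold = cfg$evaluate$threshold,
                               contours = contours,
                               cartesian_px = cfg$render$cartesian_px)
        if (length(pb$overlay_polar) >= 1 && !is.null(pb$overlay_polar[[1]])) {
          write_label_png(pb$overlay_polar[[1]],
                          file.path(out_dir, sprintf("example_%02d_polar.png", e)))
          write_label_png(pb$overlay_cartesian[[1]],
                          file.path(out_dir, sprintf("example_%02d_cartesian.png", e)))
          write_label_png(log_display(fr),
                          file.path(out_dir, sprintf("example_%02d_log.png", e)))
        }
      }
    }
  })

  invisible(list(metrics = metrics, models = models, manifest = manifest,
                 dir = out_dir))
}
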