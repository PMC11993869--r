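#' Artery-grouped dataset splitting
#'
#' Assigns whole arteries to train/validation/test so that frames from the
#' same artery never land in different splits (which would contaminate
#' results through within-artery correlation).  `random_grouped` shuffles
#' arteries under the seed and assigns each greedily to the split with the
#' largest remaining frame-count deficit, approaching the requested
#' 70/15/15 as closely as artery granularity allows.  `stratified_grouped`
#' additionally scores each candidate assignment by the maximum per-class
#' prevalence deviation across splits (plus the frame-ratio deviation) and
#' takes the minimizer, spreading every subtype as evenly as the artery
#' layout permits.
#'
#' @param manifest tibble with `heart_id`, `artery_id`, `frame_id` and
#'   (for stratified mode) `has_<class>` columns.
#' @param ratios numeric length-3, train/validation/test, summing to 1.
#' @param mode `"random_grouped"` or `"stratified_grouped"`.
#' @param seed RNG seed; output is deterministic given (manifest, mode,
#'   seed).
#' @param tolerance warn when realized frame proportions miss the target
#'   by more than this.
#' @return the manifest with a `split` factor column; attributes `mode`,
#'   `seed`, `ratios`.
#' @export
make_splits <- function(manifest, ratios = c(0.70, 0.15, 0.15),
                        mode = c("random_grouped", "stratified_grouped"),
                        seed = 1L, tolerance = 0.05) {
  mode <- match.arg(mode)
  stopifnot(length(ratios) == 3, abs(sum(ratios) - 1) < 1e-8)
  splits <- c("train", "validation", "test")
  arteries <- manifest |>
    dplyr::count(.data$artery_id, name = "n_frames")
  if (nrow(arteries) < 3) stop_data("need at least 3 arteries to split")
  N <- sum(arteries$n_frames)
  target <- ratios * N

  class_cols <- grep("^has_", names(manifest), value = TRUE)
  art_classes <- NULL
  if (mode == "stratified_grouped" && length(class_cols) > 0) {
    art_classes <- manifest |>
      dplyr::group_by(.data$artery_id) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(class_cols), sum),
                       .groups = "drop")
  }

  order_idx <- withr::with_seed(as.integer(seed),
                                sample.int(nrow(arteries)))
  arteries <- arteries[order_idx, ]
  if (!is.null(art_classes)) {
    art_classes <- art_classes[match(arteries$artery_id,
                                     art_classes$artery_id), ]
    # rarest classes first so they can still be spread across splits
    class_totals <- colSums(art_classes[class_cols])
    rarity <- apply(art_classes[class_cols], 1L, function(r) {
      present <- r > 0
      if (!any(present)) Inf else min(class_totals[present])
    })
    ord <- order(rarity)
    arteries <- arteries[ord, ]
    art_classes <- art_classes[ord, ]
  }

  assigned <- setNames(numeric(3), splits)
  class_assigned <- if (!is.null(art_classes)) {
    matrix(0, 3, length(class_cols), dimnames = list(splits, class_cols))
  } else NULL
  assignment <- character(nrow(arteries))

  for (a in seq_len(nrow(arteries))) {
    nf <- arteries$n_frames[a]
    if (mode == "random_grouped" || is.null(class_assigned)) {
      deficit <- target - assigned
      pick <- splits[which.max(deficit)]
    } else {
      cls <- as.numeric(art_classes[a, class_cols])
      score <- vapply(splits, function(s) {
        asg <- assigned; asg[s] <- asg[s] + nf
        csg <- class_assigned; csg[s, ] <- csg[s, ] + cls
        tot <- colSums(csg)
        dev <- 0
        for (jc in seq_along(class_cols)) {
          if (tot[jc] > 0) {
            dev <- max(dev, max(abs(csg[, jc] / tot[jc] - ratios)))
          }
        }
        frame_dev <- max(abs(asg / sum(asg) - ratios))
        dev + 0.5 * frame_dev
      }, numeric(1))
      pick <- splits[which.min(score)]
      class_assigned[pick, ] <- class_assigned[pick, ] +
        as.numeric(art_classes[a, class_cols])
    }
    assignment[a] <- pick
    assigned[pick] <- assigned[pick] + nf
  }

  realized <- assigned / N
  if (max(abs(realized - ratios)) > tolerance + 1e-9) {
    warn(paste0("artery granularity limits the split: realized proportions ",
                paste(sprintf("%.3f", realized), collapse = "/"),
                " vs requested ",
                paste(sprintf("%.2f", ratios), collapse = "/")))
  }
  lookup <- setNames(assignment, arteries$artery_id)
  out <- manifest
  out$split <- factor(unname(lookup[manifest$artery_id]), levels = splits)
  attr(out, "split_mode") <- mode
  attr(out, "split_seed") <- as.integer(seed)
  attr(out, "split_ratios") <- ratios
  out
}

#' Plateau-reduction training schedule
#'
#' Hyperparameters of the training loop: 60 epochs from a starting
#' learning rate of 1e-4, with plateau reduction by a factor of 0.5 and
#' patience 4 on the validation loss (the rate halves after the fifth
#' consecutive non-improving epoch).
#'
#' @param epochs training epochs.
#' @param lr starting learning rate (Adam).
#' @param plateau_factor multiplicative reduction on plateau.
#' @param patience non-improving validation epochs tolerated before a
#'   reduction.
#' @param batch_size frames per optimizer step.
#' @param augment apply random circular angular rolls (label-safe by
#'   construction) to training frames.
#' @param n_runs independent restarts; the best run/epoch by validation
#'   Dice supplies the final weights.
#' @return a `training_schedule` list.
#' @export
training_schedule <- function(epochs = 60L, lr = 1e-4, plateau_factor = 0.5,
                              patience = 4L, batch_size = 8L, augment = TRUE,
                              n_runs = 1L) {
  structure(list(epochs = as.integer(epochs), lr = lr,
                 plateau_factor = plateau_factor,
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size), augment = augment,
                 n_runs = as.integer(n_runs)),
            class = "training_schedule")
}

#' Run an epoch loop under plateau learning-rate reduction
#'
#' The schedule logic is factored out of [train_model()] so it can be
#' exercised with arbitrary step/validation closures: each epoch calls
#' `step_fn(lr)` (returning the training loss) then `val_fn()` (returning
#' `list(loss, dice)`), and reduces the learning rate by `plateau_factor`
#' once the validation loss has failed to improve for more than `patience`
#' consecutive epochs.
#'
#' @param epochs,lr,plateau_factor,patience see [training_schedule()].
#' @param step_fn function(lr) -> training loss for one epoch.
#' @param val_fn function() -> list(loss = ..., dice = ...).
#' @return history tibble with one row per epoch: `epoch`, `lr` (the rate
#'   used that epoch), `train_loss`, `val_loss`, `val_dice`.
#' @export
run_training_schedule <- function(epochs, lr, plateau_factor = 0.5,
                                  patience = 4L, step_fn, val_fn) {
  rows <- vector("list", epochs)
  best_val <- Inf
  wait <- 0L
  for (e in seq_len(epochs)) {
    train_loss <- step_fn(lr)
    v <- val_fn()
    rows[[e]] <- tibble::tibble(epoch = e, lr = lr, train_loss = train_loss,
                                val_loss = v$loss, val_dice = v$dice)
    if (v$loss < best_val) {
      best_val <- v$loss
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait > patience) {
        lr <- lr * plateau_factor
        wait <- 0L
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Build training samples from a dataset manifest
#'
#' For each manifest row: take the polar image and label map, flatten both
#' at the lumen (the phantom's true contour when available and requested,
#' otherwise [detect_lumen()]), crop to `crop_depth`, estimate the
#' attenuation boundary, and assemble the three-category training mask for
#' the target class or group.
#'
#' @param manifest dataset manifest (rows of frames), possibly filtered to
#'   one split.
#' @param target class or group name.
#' @param crop_depth flattening crop (default 200 px).
#' @param use_true_contour use the phantom's stored contour when present.
#' @param boundary `"auto"` to estimate the attenuation boundary from the
#'   image, `"full"` to keep the whole crop readable, or a function
#'   `(flat) -> integer vector` (e.g. loading per-frame annotations).
#' @return list of samples: `x` (flattened intensities), `mask`
#'   (three-category matrix), `frame_id`.
#' @export
prepare_training_samples <- function(manifest, target, crop_depth = 200L,
                                     use_true_contour = TRUE,
                                     boundary = "auto") {
  samples <- vector("list", nrow(manifest))
  for (r in seq_len(nrow(manifest))) {
    row <- manifest[r, ]
    M <- manifest_image(row)
    L <- manifest_labels(row)
    contour <- if (use_true_contour && !is.null(row$contour)) {
      row$contour[[1]]
    } else {
      detect_lumen(M)
    }
    contour <- pmin(pmax(contour, 1L), ncol(M) - crop_depth + 1L)
    flat <- flatten_frame(M, contour, crop_depth)
    flat_labels <- flatten_frame(L, contour, crop_depth)$intensities
    lumen_mask <- flat_labels == plaque_classes()[["lumen"]]
    target_map <- combine_labels(flat_labels, target)
    ab <- if (identical(boundary, "auto")) {
      estimate_attenuation_boundary(flat)
    } else if (identical(boundary, "full")) {
      rep(crop_depth, nrow(M))
    } else {
      boundary(flat)
    }
    mask <- build_training_mask(target_map, ab, lumen_mask)
    samples[[r]] <- list(x = flat$intensities, mask = mask,
                         frame_id = row$frame_id)
  }
  samples
}

# Pad a training mask's depth axis with exclusion so it matches the
# stride-padded network input; padded columns can never affect the loss.
pad_mask_to_stride <- function(mask, stride) {
  W <- ncol(mask)
  extra <- (stride - W %% stride) %% stride
  if (extra == 0L) return(mask)
  cbind(mask, matrix(MASK_EXCLUSION, nrow(mask), extra))
}

roll_rows <- function(M, k) {
  n <- nrow(M)
  if (k %% n == 0) return(M)
  M[((seq_len(n) - 1L - k) %% n) + 1L, , drop = FALSE]
}

#' Train one per-plaque-type segmentation network
#'
#' Trains the circular-padded attention U-Net on flattened frames with the
#' Tversky focal loss (computed over the pooled batch, exclusion pixels
#' masked out), Adam, and plateau learning-rate reduction; after every
#' epoch the validation Dice is logged and the returned network carries
#' the weights of the epoch (and restart) with the best validation Dice.
#' Inputs are log-compressed and standardized by training-set statistics
#' recorded on the model.  All randomness (weight init, batch order,
#' augmentation rolls) derives from `seed`.
#'
#' @param train_samples,val_samples sample lists from
#'   [prepare_training_samples()]; they must come from artery-disjoint
#'   splits.
#' @param target class or group name being segmented.
#' @param model_config an [unet_config()].
#' @param loss_params list(alpha, beta, gamma, smooth); defaults to
#'   [default_loss_params()] for the target.
#' @param schedule a [training_schedule()].
#' @param seed master seed for this training job.
#' @return an `ivoct_model`: `net` (selected weights), `norm`, `target`,
#'   `loss_params`, `schedule`, `history` (all runs), `best` (run, epoch,
#'   validation Dice).
#' @export
train_model <- function(train_samples, val_samples, target,
                        model_config = unet_config(),
                        loss_params = default_loss_params(target),
                        schedule = training_schedule(), seed = 1L) {
  if (length(train_samples) == 0 || length(val_samples) == 0) {
    stop_data("empty training or validation set")
  }
  n_target <- sum(vapply(train_samples,
                         function(s) sum(s$mask == MASK_TARGET), numeric(1)))
  if (n_target == 0) stop_data("degenerate target class: no target pixels in the training set")

  logs <- unlist(lapply(train_samples, function(s) log1p(s$x)))
  norm <- list(mean = mean(logs), sd = max(stats::sd(logs), 1e-8))
  rm(logs)
  stride <- model_config$total_stride
  alpha <- loss_params$alpha; beta <- loss_params$beta
  gamma <- loss_params$gamma; smooth <- loss_params$smooth %||% 1e-6

  prep <- function(samples) {
    lapply(samples, function(s) {
      list(x = pad_depth_to_stride(normalize_input(s$x, norm), stride)$x,
           mask = pad_mask_to_stride(s$mask, stride))
    })
  }
  tr <- prep(train_samples)
  va <- prep(val_samples)

  run_seeds <- derive_seeds(seed, schedule$n_runs)
  all_hist <- list()
  best <- list(dice = -Inf, run = NA_integer_, epoch = NA_integer_,
               params = NULL)

  for (run in seq_len(schedule$n_runs)) {
    net <- build_unet(model_config, seed = run_seeds[run])
    opt <- adam_init(net$params)
    epoch_seeds <- derive_seeds(run_seeds[run], schedule$epochs)
    env <- environment()
    epoch_no <- 0L

    step_fn <- function(lr) {
      epoch_no <<- epoch_no + 1L
      es <- epoch_seeds[epoch_no]
      order_ <- withr::with_seed(es, sample.int(length(tr)))
      rolls <- if (schedule$augment) {
        withr::with_seed(es + 1L, sample.int(nrow(tr[[1]]$x), length(tr),
                                             replace = TRUE))
      } else rep(0L, length(tr))
      losses <- c()
      b0 <- 1L
      while (b0 <= length(order_)) {
        idx <- order_[b0:min(b0 + schedule$batch_size - 1L, length(order_))]
        fw <- vector("list", length(idx))
        tmap <- vector("list", length(idx))
        vmap <- vector("list", length(idx))
        tp <- 0; fp_ <- 0; fn_ <- 0
        for (q in seq_along(idx)) {
          s <- tr[[idx[q]]]
          k <- rolls[idx[q]]
          x <- roll_rows(s$x, k)
          m <- roll_rows(s$mask, k)
          fw[[q]] <- unet_forward(net, x, want_cache = TRUE)
          tmap[[q]] <- m == MASK_TARGET
          vmap[[q]] <- m != MASK_EXCLUSION
          p <- fw[[q]]$p
          pv <- p[vmap[[q]]]; tv <- tmap[[q]][vmap[[q]]] * 1
          tp <- tp + sum(pv * tv)
          fp_ <- fp_ + sum(pv * (1 - tv))
          fn_ <- fn_ + sum((1 - pv) * tv)
        }
        den <- tp + alpha * fp_ + beta * fn_ + smooth
        ti <- (tp + smooth) / den
        losses <- c(losses, (1 - ti)^gamma)
        grads <- NULL
        for (q in seq_along(idx)) {
          dp <- tversky_focal_grad(fw[[q]]$p, tmap[[q]], vmap[[q]],
                                   tp, fp_, fn_, alpha, beta, gamma, smooth)
          g <- unet_backward(net, fw[[q]]$cache, dp)
          grads <- if (is.null(grads)) g else {
            purrr::map2(grads, g[names(grads)], `+`)
          }
        }
        upd <- adam_step(net$params, grads, opt, lr)
        net$params <- upd$params
        opt <- upd$state
        assign("net", net, envir = env)
        assign("opt", opt, envir = env)
        b0 <- b0 + schedule$batch_size
      }
      mean(losses)
    }

    val_fn <- function() {
      tp <- 0; fp_ <- 0; fn_ <- 0
      frame_dice <- c()
      for (s in va) {
        p <- unet_forward(net, s$x)$p
        t <- s$mask == MASK_TARGET
        v <- s$mask != MASK_EXCLUSION
        pv <- p[v]; tv <- t[v] * 1
        tp <- tp + sum(pv * tv)
        fp_ <- fp_ + sum(pv * (1 - tv))
        fn_ <- fn_ + sum((1 - pv) * tv)
        pb <- pv >= 0.5
        un <- sum(pb) + sum(tv)
        if (un > 0) frame_dice <- c(frame_dice, 2 * sum(pb & tv == 1) / un)
      }
      den <- tp + alpha * fp_ + beta * fn_ + smooth
      loss <- (1 - (tp + smooth) / den)^gamma
      # selection metric: frame-mean Dice, matching the reported headline
      dice <- if (length(frame_dice) > 0) mean(frame_dice) else 1
      if (dice > best$dice) {
        best <<- list(dice = dice, run = run, epoch = epoch_no,
                      params = net$params)
      }
      list(loss = loss, dice = dice)
    }

    hist <- run_training_schedule(schedule$epochs, schedule$lr,
                                  schedule$plateau_factor, schedule$patience,
                                  step_fn, val_fn)
    hist$run <- run
    all_hist[[run]] <- hist
  }

  net <- build_unet(model_config, seed = run_seeds[1])
  net$params <- best$params
  structure(list(
    net = net, norm = norm, target = target, loss_params = loss_params,
    schedule = schedule, history = dplyr::bind_rows(all_hist),
    best = best[c("dice", "run", "epoch")], seed = as.integer(seed)
  ), class = "ivoct_model")
}

#' @export
print.ivoct_model <- function(x, ...) {
  cat(sprintf(
    "<ivoct_model> target %s | best val Dice %.3f (run %d, epoch %d) | %s params\n",
    x$target, x$best$dice, x$best$run, x$best$epoch,
    format(n_params(x), big.mark = ",")))
  invisible(x)
}

#' Save / load a trained model
#'
#' Weights are serialized to RDS with a human-readable sidecar JSON
#' (`<path>.json`) recording the architecture, normalization statistics,
#' target class, loss parameters and package version.
#'
#' @param model an `ivoct_model`.
#' @param path file path for the weights.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  sidecar <- list(
    target = model$target,
    config = unclass(model$net$config),
    norm = model$norm,
    loss_params = model$loss_params,
    best = model$best,
    n_params = n_params(model),
    package_version = as.character(utils::packageVersion("ivoctseg"))
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
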