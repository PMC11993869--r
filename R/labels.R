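#' Plaque-subtype label vocabulary
#'
#' Per-pixel label maps use a fixed integer palette: 0 = lumen, 1 = fibrous,
#' 2 = lipid pool, 3 = calcified lipid, 4 = fibrofatty, 5 = calcified
#' fibrous.  Two combined groups follow the usual lipid/calcium analysis
#' convention: the lipid group pools lipid pool, calcified lipid and
#' fibrofatty; the calcium group pools calcified lipid and calcified
#' fibrous.  Calcified lipid, being a calcified necrotic core, belongs to
#' both groups; fibrous is background tissue and belongs to neither.
#'
#' @return `plaque_classes()` returns the named integer palette;
#'   `plaque_groups()` the list of combined groups (class-name vectors).
#' @export
plaque_classes <- function() {
  c(lumen = 0L, fibrous = 1L, lipid_pool = 2L, calcified_lipid = 3L,
    fibrofatty = 4L, calcified_fibrous = 5L)
}

#' @rdname plaque_classes
#' @export
plaque_groups <- function() {
  list(
    combined_lipid = c("lipid_pool", "calcified_lipid", "fibrofatty"),
    combined_calcium = c("calcified_lipid", "calcified_fibrous")
  )
}

# Tissue classes that can appear beyond the lumen.
tissue_class_names <- function() setdiff(names(plaque_classes()), "lumen")

# Plaque classes that can be a segmentation target (fibrous is background).
target_class_names <- function() {
  c(setdiff(tissue_class_names(), "fibrous"), names(plaque_groups()))
}

#' Resolve a target class or combined group to palette ids
#'
#' @param target a single class name (e.g. `"lipid_pool"`) or group name
#'   (`"combined_lipid"`, `"combined_calcium"`).
#' @return integer vector of palette ids the target comprises.
#' @export
resolve_target <- function(target) {
  stopifnot(is.character(target), length(target) == 1L)
  pal <- plaque_classes()
  grp <- plaque_groups()
  if (target %in% names(grp)) return(unname(pal[grp[[target]]]))
  if (target %in% names(pal) && target != "lumen") return(unname(pal[target]))
  stop_config(paste0("unknown target class or group: ", target))
}

#' Collapse a label map to a binary target map
#'
#' Marks a pixel positive iff its palette class is the target class or a
#' member of the target group (multiple labels combined into one before
#' they reach the model).
#'
#' @param label_map integer matrix over the fixed palette.
#' @param target class or group name, see [resolve_target()].
#' @return logical matrix of the same shape.
#' @export
combine_labels <- function(label_map, target) {
  pal <- plaque_classes()
  bad <- setdiff(unique(as.vector(label_map)), unname(pal))
  if (length(bad) > 0) {
    stop_data(paste0("unknown label value(s) in map: ",
                     paste(sort(bad), collapse = ", ")))
  }
  ids <- resolve_target(target)
  out <- matrix(as.vector(label_map) %in% ids, nrow(label_map), ncol(label_map))
  out
}

#' Training-mask category codes
#'
#' Three-valued masks fed to the loss: 0 = exclusion (inside the lumen or
#' beyond the attenuation boundary), 1 = background (fibrous and any plaque
#' class not currently trained), 2 = target.
#' @export
MASK_EXCLUSION <- 0L
#' @rdname MASK_EXCLUSION
#' @export
MASK_BACKGROUND <- 1L
#' @rdname MASK_EXCLUSION
#' @export
MASK_TARGET <- 2L

#' Estimate the per-A-line attenuation boundary
#'
#' Beyond some depth the OCT signal has decayed into the noise floor and
#' tissue composition cannot be read; those pixels are excluded from
#' training and evaluation.  Per A-line the boundary is the last readable
#' depth: the first depth at which the running-smoothed intensity falls
#' strictly below a frame-level noise threshold and stays below it for at
#' least `run_px` consecutive pixels.  The threshold is
#' `lo + frac * (hi - lo)` from the frame's low/high intensity quantiles,
#' so a uniformly bright (unattenuated) frame keeps the full crop and an
#' A-line sitting at the frame's noise floor is excluded entirely.
#'
#' @param flattened a lumen-justified frame from [flatten_frame()] or a
#'   plain intensity matrix (A-lines x depth).
#' @param frac threshold position between the low and high quantiles.
#' @param lo_q,hi_q frame quantiles standing for noise floor and tissue
#'   signal.
#' @param smooth_px centered running-mean window along depth.
#' @param run_px pixels the signal must stay sub-threshold to count as gone.
#' @return integer vector, one boundary per A-line, in `[0, crop_depth]`;
#'   0 means the whole A-line is unreadable.
#' @export
estimate_attenuation_boundary <- function(flattened, frac = 0.08,
                                          lo_q = 0.02, hi_q = 0.98,
                                          smooth_px = 7, run_px = 10) {
  M <- if (is.list(flattened)) flattened$intensities else flattened
  stopifnot(is.matrix(M))
  W <- ncol(M)
  lo <- quantile(M, lo_q, names = FALSE)
  hi <- quantile(M, hi_q, names = FALSE)
  thr <- lo + frac * (hi - lo)
  Msm <- smooth_depth(M, smooth_px / 3)   # sd ~ window/3
  below <- Msm < thr
  # run-length condition: below for >= run_px consecutive depths
  run <- matrix(0L, nrow(M), W)
  acc <- integer(nrow(M))
  for (j in W:1) {
    acc <- ifelse(below[, j], acc + 1L, 0L)
    run[, j] <- acc
  }
  start <- first_true_by_row(run >= run_px)
  boundary <- ifelse(is.na(start), W, start - 1L)
  as.integer(boundary)
}

#' Build the three-category training mask
#'
#' Exclusion takes precedence over everything: lumen pixels and pixels at
#' depths beyond the per-A-line attenuation boundary are excluded even when
#' a plaque label extends there.  Among the remaining pixels, positives of
#' the binary target map become target and everything else (fibrous plus
#' plaque classes not currently trained) is background.
#'
#' @param target_map logical matrix from [combine_labels()], in the
#'   flattened crop domain.
#' @param attenuation_boundary integer vector per A-line (see
#'   [estimate_attenuation_boundary()]); pixels at depth > boundary are
#'   excluded.
#' @param lumen_mask optional logical matrix of in-crop lumen pixels.
#' @return integer matrix over `{MASK_EXCLUSION, MASK_BACKGROUND,
#'   MASK_TARGET}`.
#' @export
build_training_mask <- function(target_map, attenuation_boundary,
                                lumen_mask = NULL) {
  stopifnot(is.matrix(target_map))
  n <- nrow(target_map); W <- ncol(target_map)
  if (length(attenuation_boundary) != n) {
    stop_data("attenuation_boundary length must equal the A-line count")
  }
  if (!is.null(lumen_mask) && !all(dim(lumen_mask) == dim(target_map))) {
    stop_data("lumen_mask shape does not match target_map")
  }
  depth <- matrix(seq_len(W), n, W, byrow = TRUE)
  excl <- depth > matrix(attenuation_boundary, n, W)
  if (!is.null(lumen_mask)) excl <- excl | lumen_mask
  mask <- matrix(MASK_BACKGROUND, n, W)
  mask[target_map] <- MASK_TARGET
  mask[excl] <- MASK_EXCLUSION
  storage.mode(mask) <- "integer"
  mask
}
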