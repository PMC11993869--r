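# Shared fixture builders.  Everything is generated in code; nothing is
# read from disk.

# A minimal noiseless phantom configuration with a single homogeneous
# tissue: intensity follows the closed-form exponential exactly.
noiseless_config <- function(mu = 0.01, refl = 1000, n_alines = 16L,
                             depth_px = 300L, lumen_radius_px = 20) {
  phantom_config(
    n_alines = n_alines, depth_px = depth_px,
    lumen_radius_px = lumen_radius_px,
    lumen_eccentricity = 0, lumen_noise_px = 0,
    tissue_models = list(fibrous = tissue_model("fibrous", mu, refl, 0, 0)),
    speckle_shape = Inf, noise_floor = 0, full_scale = max(refl * 1.2, 1)
  )
}

# Small default-physics config used across geometry/label tests.
small_config <- function(...) {
  phantom_config(n_alines = 64L, depth_px = 160L, lumen_radius_px = 18,
                 lumen_eccentricity = 0.1, lumen_noise_px = 2, ...)
}

# Tiny manifest for split tests: n_arteries arteries with frames_per
# frames each, heart = one artery per heart unless stated.
toy_manifest <- function(n_arteries, frames_per = 10L,
                         arteries_per_heart = 1L) {
  rows <- list()
  a <- 0L
  for (h in seq_len(ceiling(n_arteries / arteries_per_heart))) {
    for (k in seq_len(arteries_per_heart)) {
      a <- a + 1L
      if (a > n_arteries) break
      for (f in seq_len(frames_per)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          heart_id = sprintf("H%02d", h),
          artery_id = sprintf("H%02d_A%d", h, k),
          frame_id = sprintf("H%02d_A%d_F%02d", h, k, f)
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

# Reference 3x3 convolution with circular rows / zero-or-reflect columns,
# written as plain loops: the independent oracle for the compiled kernel.
conv3_reference <- function(x, w4, b, pad_depth = "zero") {
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]; Cout <- dim(w4)[4]
  out <- array(0, c(H, W, Cout))
  for (co in seq_len(Cout)) {
    acc <- matrix(b[co], H, W)
    for (ci in seq_len(Cin)) {
      for (dj in -1:1) {
        for (di in -1:1) {
          wgt <- w4[di + 2, dj + 2, ci, co]
          for (j in seq_len(W)) {
            jj <- j + dj
            if (jj < 1 || jj > W) {
              if (pad_depth == "zero") next
              jj <- if (jj < 1) 1 else W
            }
            ii <- ((seq_len(H) - 1 + di) %% H) + 1
            acc[, j] <- acc[, j] + wgt * x[ii, jj, ci]
          }
        }
      }
    }
    out[, , co] <- acc
  }
  out
}
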