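# Synthetic orchard image series with exact ground-truth masks.
#
# Each sample is a fruit rendered as a shaded ellipse whose HSV hue follows a
# monotone green -> orange trajectory over the observation span, with
# per-sample rate variation, per-day jitter, uneven coloration (stripes and
# spots), multiplicative lighting and a day-independent colored-noise
# background with foliage-like blobs. The construction makes the color
# transformation a one-parameter recoverable signal while reproducing the
# nuisance factors (fruit size/position, background, lighting) the losses
# must be robust to.

#' Define a rind color trajectory
#'
#' The rind hue (HSV degrees) decreases linearly in expectation from
#' `hue_start` (green, around 95 deg) toward `hue_end` (orange, around 30
#' deg) at `rate` degrees per day, clamped at `hue_end`, with Gaussian
#' per-day jitter of `noise_sd` degrees.
#'
#' @param hue_start,hue_end Start and end hue in degrees (`hue_start > hue_end`).
#' @param rate Hue decrease in degrees/day (positive).
#' @param noise_sd Per-day hue jitter standard deviation in degrees.
#' @return An object of class `color_trajectory`.
#' @export
color_trajectory <- function(hue_start = 95, hue_end = 30, rate = 65 / 45,
                             noise_sd = 1.5) {
  assert_that(hue_start > hue_end, "hue_start must exceed hue_end (green -> orange)")
  assert_that(rate > 0, "rate must be positive")
  structure(list(hue_start = hue_start, hue_end = hue_end, rate = rate,
                 noise_sd = noise_sd),
            class = "color_trajectory")
}

#' Expected hue of a trajectory at a given day
#'
#' @param traj A [color_trajectory()].
#' @param day Non-negative day index (vectorized).
#' @return Expected hue in degrees (noise-free), clamped to
#'   `[hue_end, hue_start]`.
#' @export
trajectory_hue <- function(traj, day) {
  pmax(traj$hue_end, pmin(traj$hue_start, traj$hue_start - traj$rate * day))
}

#' Define the scene of one synthetic sample view
#'
#' @param size Image size `c(H, W)` in pixels.
#' @param fruit_center Ellipse center `c(x, y)` in pixels.
#' @param fruit_radii Ellipse radii `c(rx, ry)` in pixels (>= 8).
#' @param background_seed Integer seed fixing the (day-independent) background.
#' @param lighting_gain Multiplicative brightness in `[0.7, 1.3]`.
#' @param n_blemishes Number of blemish spots inside the fruit.
#' @param stripe_amp Amplitude (degrees) of the striped hue modulation.
#' @return An object of class `scene_params`.
#' @export
scene_params <- function(size = c(64, 64), fruit_center = size[c(2, 1)] / 2,
                         fruit_radii = c(14, 12), background_seed = 1L,
                         lighting_gain = 1, n_blemishes = 2, stripe_amp = 4) {
  assert_that(all(fruit_radii >= 8), "fruit radii must be >= 8 px")
  assert_that(lighting_gain >= 0.7 && lighting_gain <= 1.3,
              "lighting_gain must lie in [0.7, 1.3]")
  cx <- fruit_center[1]; cy <- fruit_center[2]
  inside <- cx - fruit_radii[1] >= 1 && cx + fruit_radii[1] <= size[2] &&
    cy - fruit_radii[2] >= 1 && cy + fruit_radii[2] <= size[1]
  assert_that(inside, "fruit ellipse must lie fully inside the frame")
  structure(list(size = size, fruit_center = fruit_center,
                 fruit_radii = fruit_radii,
                 background_seed = as.integer(background_seed),
                 lighting_gain = lighting_gain, n_blemishes = n_blemishes,
                 stripe_amp = stripe_amp),
            class = "scene_params")
}

# Smooth low-frequency noise field in [0,1]: coarse uniform grid, bilinearly
# interpolated to H x W.
smooth_noise <- function(H, W, cells = 6) {
  g <- matrix(runif((cells + 1) * (cells + 1)), cells + 1, cells + 1)
  ri <- (seq_len(H) - 0.5) / H * cells
  ci <- (seq_len(W) - 0.5) / W * cells
  r0 <- pmin(floor(ri), cells - 1); c0 <- pmin(floor(ci), cells - 1)
  fr <- ri - r0; fc <- ci - c0
  a <- g[cbind(rep(r0 + 1, W), rep(c0 + 1, each = H))]
  b <- g[cbind(rep(r0 + 2, W), rep(c0 + 1, each = H))]
  cc <- g[cbind(rep(r0 + 1, W), rep(c0 + 2, each = H))]
  d <- g[cbind(rep(r0 + 2, W), rep(c0 + 2, each = H))]
  frm <- rep(fr, W); fcm <- rep(fc, each = H)
  v <- a * (1 - frm) * (1 - fcm) + b * frm * (1 - fcm) +
    cc * (1 - frm) * fcm + d * frm * fcm
  matrix(v, H, W)
}

render_background <- function(scene) {
  H <- scene$size[1]; W <- scene$size[2]
  with_seed(derive_seed(scene$background_seed, 11L), {
    base_hue <- runif(1, 70, 140)            # foliage greens / browns
    hue <- base_hue + 30 * (smooth_noise(H, W, 5) - 0.5)
    sat <- 0.25 + 0.4 * smooth_noise(H, W, 4)
    val <- 0.25 + 0.45 * smooth_noise(H, W, 6)
    # foliage-like darker blobs
    n_blob <- sample(2:4, 1)
    xs <- matrix(rep(seq_len(W), each = H), H, W)
    ys <- matrix(rep(seq_len(H), W), H, W)
    for (i in seq_len(n_blob)) {
      bx <- runif(1, 1, W); by <- runif(1, 1, H); br <- runif(1, W / 8, W / 3)
      d2 <- ((xs - bx)^2 + (ys - by)^2) / br^2
      val <- val * (1 - 0.35 * exp(-d2))
    }
    rgb <- hsv_to_rgb(as.vector(hue), pmin(as.vector(sat), 1),
                      pmin(pmax(as.vector(val), 0), 1))
    array(rgb, c(H, W, 3)) * 255
  })
}

ellipse_mask <- function(scene) {
  H <- scene$size[1]; W <- scene$size[2]
  cx <- scene$fruit_center[1]; cy <- scene$fruit_center[2]
  rx <- scene$fruit_radii[1]; ry <- scene$fruit_radii[2]
  xs <- matrix(rep(seq_len(W), each = H), H, W)
  ys <- matrix(rep(seq_len(H), W), H, W)
  ((xs - cx)^2 / rx^2 + (ys - cy)^2 / ry^2 <= 1) * 1
}

#' Render one synthetic frame
#'
#' Renders the fruit (shaded ellipse with hue `trajectory_hue(traj, day)`
#' plus stripes, spots, low-frequency texture and per-day jitter) over the
#' scene's fixed background, together with its exact binary mask. Rendering
#' is a pure function of `(scene, traj, day, rng_seed)`.
#'
#' @param scene A [scene_params()].
#' @param traj A [color_trajectory()].
#' @param day Integer day index (>= 0).
#' @param rng_seed Integer seed for the per-frame noise.
#' @return A list with elements `image` (`H x W x 3`, `[0, 255]`) and
#'   `mask` (binary `H x W`).
#' @export
render_frame <- function(scene, traj, day, rng_seed = 1L) {
  assert_that(day >= 0, "day must be >= 0")
  H <- scene$size[1]; W <- scene$size[2]
  bg <- render_background(scene)
  mask <- ellipse_mask(scene)
  sel <- which(mask == 1)
  img <- bg
  with_seed(derive_seed(rng_seed, day, 23L), {
    hue0 <- trajectory_hue(traj, day) + rnorm(1, 0, traj$noise_sd)
    xs <- matrix(rep(seq_len(W), each = H), H, W)[sel]
    ys <- matrix(rep(seq_len(H), W), H, W)[sel]
    cx <- scene$fruit_center[1]; cy <- scene$fruit_center[2]
    rx <- scene$fruit_radii[1]; ry <- scene$fruit_radii[2]
    r2 <- ((xs - cx) / rx)^2 + ((ys - cy) / ry)^2
    # uneven coloration: stripes + blemish spots + low-frequency texture,
    # all zero-mean-ish so the mean fruit hue tracks the trajectory
    stripes <- scene$stripe_amp * sin(2 * pi * (xs - cx) / (0.9 * rx) + day / 7)
    tex <- 6 * (smooth_noise(H, W, 4)[sel] - 0.5)
    hue <- hue0 + stripes + tex
    if (scene$n_blemishes > 0) {
      for (i in seq_len(scene$n_blemishes)) {
        bx <- cx + runif(1, -0.6, 0.6) * rx
        by <- cy + runif(1, -0.6, 0.6) * ry
        br <- runif(1, 0.12, 0.25) * min(rx, ry)
        d2 <- ((xs - bx)^2 + (ys - by)^2) / br^2
        hue <- hue + sample(c(-1, 1), 1) * 10 * exp(-d2)
      }
    }
    sat <- pmin(pmax(0.85 + 0.05 * (smooth_noise(H, W, 5)[sel] - 0.5), 0), 1)
    val <- 0.9 * (1 - 0.35 * r2) * scene$lighting_gain
    val <- pmin(pmax(val + rnorm(length(sel), 0, 0.01), 0), 1)
    rgb <- hsv_to_rgb(hue, sat, val) * 255
    img[, , 1][sel] <- rgb[, 1]
    img[, , 2][sel] <- rgb[, 2]
    img[, , 3][sel] <- rgb[, 3]
  })
  list(image = img, mask = mask)
}

#' Generate a labelled synthetic orchard dataset
#'
#' Writes per-sample image series (PNG), exact masks (PNG) and a manifest
#' (CSV) emulating an orchard acquisition campaign: per-sample trajectories
#' drawn from priors around a ~45-day green-to-orange transformation, fruit
#' at varying size and position against varying backgrounds, roughly similar
#' illumination, and optional random frame drop-out emulating missing
#' acquisition days.
#'
#' @param n_samples Number of fruit samples.
#' @param days Number of acquisition days per sample (days `0..days-1`).
#' @param views_per_sample Number of views per sample (1..3: front, bottom,
#'   side; each view has its own scene).
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed; the dataset is a pure function of all arguments.
#' @param size Image size `c(H, W)` (default 64 x 64; use `c(192, 256)` for
#'   full-scale imagery).
#' @param dropout_prob Per-frame drop-out probability (default 0.05).
#' @param rate_range Range of per-sample hue rates (degrees/day) from which
#'   trajectories are drawn.
#' @param noise_sd Per-day hue jitter (degrees).
#' @return The manifest path, invisibly readable via [load_manifest()].
#' @export
generate_dataset <- function(n_samples, days, views_per_sample = 1L,
                             out_dir, seed = 1L, size = c(64, 64),
                             dropout_prob = 0.05,
                             rate_range = c(1.1, 1.8), noise_sd = 1.5) {
  assert_that(n_samples >= 1 && days >= 1, "need at least one sample and one day")
  assert_that(views_per_sample >= 1 && views_per_sample <= 3,
              "views_per_sample must be in 1..3")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  assert_that(dir.exists(out_dir), sprintf("cannot create output dir: %s", out_dir))
  img_dir <- file.path(out_dir, "images")
  msk_dir <- file.path(out_dir, "masks")
  dir.create(img_dir, showWarnings = FALSE)
  dir.create(msk_dir, showWarnings = FALSE)
  H <- size[1]; W <- size[2]
  rows <- list()
  for (s in seq_len(n_samples)) {
    sid <- sprintf("s%03d", s)
    traj <- with_seed(derive_seed(seed, s, 31L), {
      color_trajectory(hue_start = rnorm(1, 95, 4), hue_end = rnorm(1, 30, 3),
                       rate = runif(1, rate_range[1], rate_range[2]),
                       noise_sd = noise_sd)
    })
    for (v in seq_len(views_per_sample)) {
      view <- VIEW_LEVELS[v]
      scene <- with_seed(derive_seed(seed, s, v, 41L), {
        rmax <- floor(min(H, W) / 2) - 2
        assert_that(rmax >= 8,
                    "image too small for a fruit: need min(H, W) >= 20 px")
        rx <- round(runif(1, 8, max(8, min(rmax, 0.28 * W))))
        ry <- round(runif(1, 8, max(8, min(rmax, 0.28 * H))))
        scene_params(size = size,
                     fruit_center = c(runif(1, rx + 2, W - rx - 1),
                                      runif(1, ry + 2, H - ry - 1)),
                     fruit_radii = c(rx, ry),
                     background_seed = derive_seed(seed, s, v, 43L),
                     lighting_gain = runif(1, 0.85, 1.15),
                     n_blemishes = sample(0:3, 1))
      })
      drop <- with_seed(derive_seed(seed, s, v, 47L),
                        runif(days) < dropout_prob)
      if (all(drop)) drop[1] <- FALSE   # keep at least one frame per series
      for (d in seq_len(days) - 1L) {
        if (drop[d + 1L]) next
        fr <- render_frame(scene, traj, d, rng_seed = derive_seed(seed, s, v, d, 53L))
        img_rel <- file.path("images", sprintf("%s_%s_d%02d.png", sid, view, d))
        msk_rel <- file.path("masks", sprintf("%s_%s_d%02d.png", sid, view, d))
        write_image(fr$image, file.path(out_dir, img_rel))
        write_mask(fr$mask, file.path(out_dir, msk_rel))
        rows[[length(rows) + 1L]] <- tibble(
          sample_id = sid, day = d, view = view,
          image_path = img_rel, mask_path = msk_rel)
      }
    }
  }
  manifest <- dplyr::bind_rows(rows)
  path <- file.path(out_dir, "manifest.csv")
  write_manifest(manifest, path)
  invisible(path)
}
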