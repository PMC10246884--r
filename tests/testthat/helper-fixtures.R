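# Shared fixtures, all built in code at test time.

# A tiny manifest on disk with real (1x1-ish) image/mask files.
make_manifest_fixture <- function(rows, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  for (i in seq_len(nrow(rows))) {
    ip <- file.path(dir, rows$image_path[i])
    mp <- file.path(dir, rows$mask_path[i])
    if (!file.exists(ip)) write_image(array(runif(4 * 4 * 3) * 255, c(4, 4, 3)), ip)
    if (!file.exists(mp)) write_mask(matrix(1, 4, 4), mp)
  }
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  path
}

manifest_rows <- function(sample_id, day, view = "front") {
  tibble::tibble(
    sample_id = sample_id, day = day, view = view,
    image_path = sprintf("img_%s_%d_%s.png", sample_id, day, view),
    mask_path = sprintf("msk_%s_%d_%s.png", sample_id, day, view)
  )
}

# Deterministic small random image / mask.
rand_image <- function(h = 8, w = 8, seed = 1) {
  withr::with_seed(seed, array(runif(h * w * 3) * 255, c(h, w, 3)))
}

rand_mask <- function(h = 8, w = 8, seed = 1, p = 0.5) {
  withr::with_seed(seed, {
    m <- matrix(rbinom(h * w, 1, p), h, w)
    if (sum(m) == 0) m[1, 1] <- 1
    m
  })
}

# Constant-color image with a rectangular fruit region of another color.
const_fruit_image <- function(h, w, fruit_rows, fruit_cols, fruit_rgb,
                              bg_rgb = c(40, 90, 40)) {
  img <- array(rep(bg_rgb, each = h * w), c(h, w, 3))
  mask <- matrix(0, h, w)
  mask[fruit_rows, fruit_cols] <- 1
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask == 1] <- fruit_rgb[ch]
    img[, , ch] <- plane
  }
  list(image = img, mask = mask)
}

# A small pre-generated synthetic dataset, cached for the whole test run.
shared_synth_dir <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      dir <<- file.path(tempdir(), "rindcast-shared-synth")
      if (!file.exists(file.path(dir, "manifest.csv"))) {
        generate_dataset(6, 8, 1, dir, seed = 99, size = c(32, 32),
                         dropout_prob = 0)
      }
    }
    dir
  }
})

# Independent Hunter Lab oracle: the sRGB -> XYZ matrix is re-derived from
# the chromaticity coordinates of the sRGB primaries and the D65 white
# point (solving for the primary scales), rather than taken from the
# tabulated matrix the package uses.
hunterlab_oracle <- function(rgb, ka = 172.30, kb = 67.20) {
  prim <- matrix(c(0.64, 0.33, 0.30, 0.60, 0.15, 0.06), 2)   # xR yR xG yG xB yB
  white_xy <- c(0.3127, 0.3290)
  to_xyz <- function(xy) c(xy[1] / xy[2], 1, (1 - xy[1] - xy[2]) / xy[2])
  P <- cbind(to_xyz(prim[, 1]), to_xyz(prim[, 2]), to_xyz(prim[, 3]))
  S <- solve(P, to_xyz(white_xy))
  M <- P %*% diag(S)
  v <- rgb / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  xyz <- as.numeric(M %*% lin) * 100
  wp <- as.numeric(M %*% c(1, 1, 1)) * 100
  xr <- xyz[1] / wp[1]; yr <- xyz[2] / wp[2]; zr <- xyz[3] / wp[3]
  sy <- sqrt(yr)
  if (sy == 0) return(c(L = 0, a = 0, b = 0))
  c(L = 100 * sy, a = ka * (xr - yr) / sy, b = kb * (yr - zr) / sy)
}

hunterlab_grid <- function() {
  expand.grid(r = c(30, 128, 225), g = c(30, 128, 225), b = c(30, 128, 225))
}
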