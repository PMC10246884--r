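#' @importFrom rlang .data abort warn
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm runif setNames cor predict
NULL

# Derive a reproducible child seed from a parent seed and integer tags.
# Keeps results < 2^31 so they are valid R integer seeds.
derive_seed <- function(seed, ...) {
  tags <- c(seed, ...)
  h <- 0
  for (t in tags) h <- (h * 69069 + (as.numeric(t) %% 2147483647) + 1) %% 2147483647
  as.integer(h)
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

stop_rindcast <- function(msg, class = "rindcast_error") {
  abort(msg, class = class)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop_rindcast(msg)
}

# ---- image array helpers -----------------------------------------------------

#' Validate an RGB image array
#'
#' Images throughout the package are plain numeric arrays of dimension
#' `H x W x 3` with channel values on the `[0, 255]` scale.
#'
#' @param x An array.
#' @return `x`, invisibly, after validation.
#' @keywords internal
check_image <- function(x) {
  assert_that(is.array(x) && length(dim(x)) == 3 && dim(x)[3] == 3,
              "image must be an H x W x 3 array")
  assert_that(all(is.finite(x)) && min(x) >= 0 && max(x) <= 255,
              "image values must be finite and within [0, 255]")
  invisible(x)
}

check_mask <- function(m) {
  assert_that(is.matrix(m) || (is.array(m) && length(dim(m)) == 2),
              "mask must be an H x W matrix")
  assert_that(all(m %in% c(0, 1)), "mask must be strictly binary (0/1)")
  invisible(m)
}

check_same_hw <- function(a, b, what = "inputs") {
  da <- dim(a)[1:2]; db <- dim(b)[1:2]
  assert_that(identical(da, db),
              sprintf("%s must share height and width (%s vs %s)",
                      what, paste(da, collapse = "x"), paste(db, collapse = "x")))
  invisible(NULL)
}

# Vectorized HSV (h in degrees, s,v in [0,1]) -> RGB in [0,1].
hsv_to_rgb <- function(h, s, v) {
  h <- (h %% 360) / 60
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- g <- b <- numeric(length(h))
  idx <- i %% 6
  sel <- idx == 0; r[sel] <- v[sel]; g[sel] <- t[sel]; b[sel] <- p[sel]
  sel <- idx == 1; r[sel] <- q[sel]; g[sel] <- v[sel]; b[sel] <- p[sel]
  sel <- idx == 2; r[sel] <- p[sel]; g[sel] <- v[sel]; b[sel] <- t[sel]
  sel <- idx == 3; r[sel] <- p[sel]; g[sel] <- q[sel]; b[sel] <- v[sel]
  sel <- idx == 4; r[sel] <- t[sel]; g[sel] <- p[sel]; b[sel] <- v[sel]
  sel <- idx == 5; r[sel] <- v[sel]; g[sel] <- p[sel]; b[sel] <- q[sel]
  cbind(r, g, b)
}

# Mean HSV hue (degrees) of the masked pixels of an [0,255] RGB image.
# The green->orange range (roughly 30..110 deg) has no wrap-around, so the
# arithmetic mean is appropriate.
#' Mean rind hue inside a mask
#'
#' Returns the mean HSV hue angle (degrees) over the masked pixels of an
#' image on the `[0, 255]` scale. Used to quantify the green-to-orange
#' rind color trajectory.
#'
#' @param image `H x W x 3` array in `[0, 255]`.
#' @param mask Binary `H x W` matrix (1 = fruit).
#' @return Mean hue in degrees.
#' @export
mean_hue <- function(image, mask) {
  check_image(image); check_mask(mask)
  check_same_hw(image, mask, "image and mask")
  assert_that(sum(mask) > 0, "mask is empty")
  sel <- which(mask == 1)
  rgb <- rbind(image[, , 1][sel], image[, , 2][sel], image[, , 3][sel])
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 255)
  mean(hsv[1, ]) * 360
}
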