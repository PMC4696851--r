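# Deterministic generator of synthetic two-stain brightfield images with
# per-pixel ground truth.  The forward model is Beer-Lambert composition
# in OD space: od = c_h * h_vec + c_d * d_vec (+ Gaussian OD noise),
# image = 255 * 10^(-od), quantized to 8 bits.  The "true" stain vectors
# are the reference vectors rotated rigidly by a configurable angle about
# an in-plane axis, so the per-image stain plane genuinely deviates from
# the reference plane -- the situation the PCA optimization corrects.

#' Default parameters of the synthetic IHC generator
#'
#' @param width,height image size in pixels.
#' @param n_objects number of elliptical DAB objects.
#' @param radius_range min/max object semi-axis in pixels.
#' @param h_range range of the smooth background counterstain field (OD
#'   concentration units).
#' @param d_range range of per-object DAB concentrations.
#' @param noise_sd SD of additive Gaussian OD noise per channel (default
#'   0.02; physically multiplicative in transmittance).
#' @param perturb_deg rigid rotation of the true stain vectors away from
#'   the reference pair, in degrees (default 5).
#' @param reference reference basis name the true vectors start from.
#' @param seed integer RNG seed; regeneration with equal parameters is
#'   byte-identical.
#' @return named list of parameters for [generate_ihc()].
#' @export
ihc_params <- function(width = 256L, height = 256L, n_objects = 12L,
                       radius_range = c(8, 20), h_range = c(0.2, 0.6),
                       d_range = c(0.3, 0.9), noise_sd = 0.02,
                       perturb_deg = 5, reference = "ruifrok", seed = 1L) {
  if (radius_range[1] > radius_range[2] || any(radius_range <= 0))
    stop("invalid radius_range")
  if (h_range[1] < 0 || h_range[1] >= h_range[2]) stop("invalid h_range")
  if (d_range[1] < 0 || d_range[1] >= d_range[2]) stop("invalid d_range")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  as.list(environment())
}

# Rodrigues rotation of vector v about unit axis k by angle (radians).
.rotate3 <- function(v, k, angle) {
  k <- k / sqrt(sum(k^2))
  v * cos(angle) + .cross3(k, v) * sin(angle) + k * sum(k * v) * (1 - cos(angle))
}

#' Generate a synthetic two-stain IHC image with ground truth
#'
#' Lays down a smooth background counterstain (hematoxylin) field and
#' elliptical DAB objects, composes them through the Beer-Lambert model
#' with the perturbed true stain vectors, adds OD noise, and quantizes to
#' an 8-bit RGB image.
#'
#' @param params parameter list from [ihc_params()].
#' @return an object of class `synthetic_ihc`: list with `image`
#'   (H x W x 3, integer-valued 8-bit), `true_h`, `true_d` (per-pixel
#'   ground-truth concentrations), `true_basis` (a [stain_basis()]), and
#'   `params`.
#' @export
generate_ihc <- function(params = ihc_params()) {
  p <- params
  ref <- reference_basis(p$reference)
  axis <- ref["h", ] + ref["d", ]             # in-plane axis: tilts the plane
  ang <- p$perturb_deg * pi / 180
  true_basis <- stain_basis(.rotate3(ref["h", ], axis, ang),
                            .rotate3(ref["d", ], axis, ang),
                            label = "synthetic-true")
  H <- p$height; W <- p$width
  withr::with_seed(p$seed, {
    # smooth counterstain field: mean level plus two low-frequency waves
    xs <- matrix(rep(seq_len(W), each = H), H, W) / W
    ys <- matrix(rep(seq_len(H), W), H, W) / H
    ph <- stats::runif(4, 0, 2 * pi)
    field <- sin(2 * pi * xs + ph[1]) + cos(2 * pi * ys + ph[2]) +
             0.5 * sin(4 * pi * (xs + ys) + ph[3]) + 0.5 * cos(4 * pi * (xs - ys) + ph[4])
    field <- (field - min(field)) / max(1e-12, diff(range(field)))
    true_h <- p$h_range[1] + field * diff(p$h_range)
    true_d <- matrix(0, H, W)
    if (p$n_objects > 0L) {
      cx <- stats::runif(p$n_objects, 1, W)
      cy <- stats::runif(p$n_objects, 1, H)
      ra <- stats::runif(p$n_objects, p$radius_range[1], p$radius_range[2])
      rb <- stats::runif(p$n_objects, p$radius_range[1], p$radius_range[2])
      th <- stats::runif(p$n_objects, 0, pi)
      lv <- stats::runif(p$n_objects, p$d_range[1], p$d_range[2])
      X <- matrix(rep(seq_len(W), each = H), H, W)
      Y <- matrix(rep(seq_len(H), W), H, W)
      for (k in seq_len(p$n_objects)) {
        xr <- (X - cx[k]) * cos(th[k]) + (Y - cy[k]) * sin(th[k])
        yr <- -(X - cx[k]) * sin(th[k]) + (Y - cy[k]) * cos(th[k])
        inside <- (xr / ra[k])^2 + (yr / rb[k])^2 <= 1
        true_d[inside] <- pmax(true_d[inside], lv[k])
      }
    }
    od <- array(0, c(H, W, 3L))
    for (ch in 1:3)
      od[, , ch] <- true_h * true_basis["h", ch] + true_d * true_basis["d", ch]
    if (p$noise_sd > 0)
      od <- od + array(stats::rnorm(H * W * 3, 0, p$noise_sd), c(H, W, 3L))
    img <- round(pmin(pmax(255 * 10^(-od), 0), 255))
  })
  structure(list(image = img, true_h = true_h, true_d = true_d,
                 true_basis = true_basis, params = p),
            class = "synthetic_ihc")
}

#' @export
print.synthetic_ihc <- function(x, ...) {
  cat(sprintf("Synthetic IHC image %d x %d: %d objects, OD noise SD %.3g, stain vectors rotated %.3g deg (seed %d)\n",
              x$params$height, x$params$width, x$params$n_objects,
              x$params$noise_sd, x$params$perturb_deg, x$params$seed))
  invisible(x)
}

#' Sample an image from a color map with (u, v) ground truth
#'
#' Draws `n_points` coordinates -- uniformly at random or on a regular
#' grid -- renders them through the map, and arranges the colors into a
#' near-square image.  Used for extraction round-trip checks.
#'
#' @param map a `bivariate_colormap`.
#' @param n_points number of samples (> 0).
#' @param seed RNG seed (random mode).
#' @param mode `"random"` or `"grid"` (a ceiling-sqrt regular lattice of
#'   at least `n_points` points).
#' @return list with `image` (H x W x 3), `u`, `v` (matrices of the
#'   ground-truth coordinates).
#' @export
generate_from_map <- function(map, n_points, seed = 1L,
                              mode = c("random", "grid")) {
  mode <- match.arg(mode)
  stopifnot(inherits(map, "bivariate_colormap"))
  if (n_points < 1L) stop("empty image requested: n_points must be >= 1")
  side <- ceiling(sqrt(n_points))
  n <- side * side
  if (mode == "random") {
    uv <- withr::with_seed(seed, matrix(stats::runif(2 * n), ncol = 2))
    u <- uv[, 1]; v <- uv[, 2]
  } else {
    g <- expand.grid(u = seq(0, 1, length.out = side),
                     v = seq(0, 1, length.out = side))
    u <- g$u; v <- g$v
  }
  cols <- eval_colormap(map, u, v)
  list(image = array(cols, c(side, side, 3L)),
       u = matrix(u, side, side), v = matrix(v, side, side))
}
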