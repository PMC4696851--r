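# sRGB <-> CIELAB <-> optical density conversions.
#
# All conversions are fixed to the sRGB primaries, D65 white point and the
# 2-degree standard observer; perceptual distance is CIE76 (Euclidean in
# CIELAB).  Color math is done in double precision throughout; 8-bit
# quantization happens only when an image file is written.

# sRGB (linear) -> XYZ, D65
.M_RGB2XYZ <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041), nrow = 3, byrow = TRUE)
.M_XYZ2RGB <- solve(.M_RGB2XYZ)
.WHITE_D65 <- c(X = 0.95047, Y = 1.00000, Z = 1.08883)

#' Coerce colors to an n x 3 numeric matrix
#'
#' Accepts an n x 3 matrix, a length-3 vector (one color), or an
#' H x W x 3 array (an image); returns an n x 3 matrix plus the
#' information needed to restore the original shape.
#' @noRd
.as_color_matrix <- function(x) {
  if (is.character(x)) x <- hex_to_rgb(x)
  if (is.array(x) && length(dim(x)) == 3L) {
    d <- dim(x)
    stopifnot(d[3] == 3L)
    list(m = matrix(x, ncol = 3L), dim = d)
  } else if (is.matrix(x)) {
    stopifnot(ncol(x) == 3L)
    list(m = x, dim = NULL)
  } else if (is.numeric(x) && length(x) == 3L) {
    list(m = matrix(x, nrow = 1L), dim = NULL)
  } else {
    stop("colors must be a length-3 vector, an n x 3 matrix or an H x W x 3 array")
  }
}

.restore_shape <- function(m, dim) {
  if (is.null(dim)) m else array(m, dim)
}

#' Parse hexadecimal color codes
#'
#' @param hex character vector of `#RRGGBB` codes (case-insensitive, the
#'   leading `#` is optional).
#' @return n x 3 numeric matrix of 8-bit sRGB intensities in \[0, 255\].
#' @examples
#' hex_to_rgb("#FFAD00")
#' @export
hex_to_rgb <- function(hex) {
  hex <- sub("^#", "", trimws(hex))
  if (any(!grepl("^[0-9a-fA-F]{6}$", hex)))
    stop("invalid hexadecimal color: expected '#RRGGBB'")
  m <- cbind(
    strtoi(substr(hex, 1, 2), 16L),
    strtoi(substr(hex, 3, 4), 16L),
    strtoi(substr(hex, 5, 6), 16L))
  colnames(m) <- c("r", "g", "b")
  m
}

#' Serialize sRGB colors as hexadecimal codes
#'
#' @param rgb colors as accepted by [rgb_to_lab()]; values in \[0, 255\].
#' @return character vector of uppercase `#RRGGBB` codes.
#' @export
rgb_to_hex <- function(rgb) {
  m <- .as_color_matrix(rgb)$m
  m <- round(pmin(pmax(m, 0), 255))
  toupper(sprintf("#%02x%02x%02x", m[, 1], m[, 2], m[, 3]))
}

#' Convert 8-bit sRGB colors to CIELAB
#'
#' Applies the standard sRGB transfer curve, the sRGB-to-XYZ primaries
#' matrix and the CIE 1976 L*a*b* formulas (D65 white, 2-degree observer).
#' Vectorized over whole images.
#'
#' @param rgb a length-3 vector, n x 3 matrix, H x W x 3 array (values in
#'   \[0, 255\]), or a character vector of hex codes.
#' @return CIELAB coordinates in the same shape (columns L, a, b).
#' @examples
#' rgb_to_lab("#FFFFFF")  # (100, 0, 0)
#' @export
rgb_to_lab <- function(rgb) {
  cm <- .as_color_matrix(rgb)
  v <- cm$m / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  xyz <- lin %*% t(.M_RGB2XYZ)
  tt <- sweep(xyz, 2, .WHITE_D65, "/")
  eps <- (6 / 29)^3
  f <- ifelse(tt > eps, tt^(1 / 3), tt / (3 * (6 / 29)^2) + 4 / 29)
  lab <- cbind(116 * f[, 2] - 16,
               500 * (f[, 1] - f[, 2]),
               200 * (f[, 2] - f[, 3]))
  colnames(lab) <- c("L", "a", "b")
  .restore_shape(lab, cm$dim)
}

#' Convert CIELAB colors to 8-bit sRGB
#'
#' Inverse of [rgb_to_lab()].  Colors outside the sRGB gamut are clipped
#' per linear channel to the gamut boundary; which input rows were clipped
#' is reported in the `"clipped"` attribute of the result (a logical
#' vector), never as an error.
#'
#' @param lab CIELAB coordinates (same shapes as [rgb_to_lab()] accepts).
#' @return sRGB intensities in \[0, 255\] (double; not quantized), with
#'   attribute `clipped`.
#' @export
lab_to_rgb <- function(lab) {
  cm <- .as_color_matrix(lab)
  L <- cm$m[, 1]; a <- cm$m[, 2]; b <- cm$m[, 3]
  fy <- (L + 16) / 116
  fx <- fy + a / 500
  fz <- fy - b / 200
  finv <- function(f) ifelse(f > 6 / 29, f^3, 3 * (6 / 29)^2 * (f - 4 / 29))
  xyz <- cbind(finv(fx) * .WHITE_D65[1],
               finv(fy) * .WHITE_D65[2],
               finv(fz) * .WHITE_D65[3])
  lin <- xyz %*% t(.M_XYZ2RGB)
  clipped <- rowSums(lin < -1e-12 | lin > 1 + 1e-12) > 0
  lin <- pmin(pmax(lin, 0), 1)
  v <- ifelse(lin <= 0.0031308, 12.92 * lin, 1.055 * lin^(1 / 2.4) - 0.055)
  out <- 255 * v
  colnames(out) <- c("r", "g", "b")
  out <- .restore_shape(out, cm$dim)
  attr(out, "clipped") <- clipped
  out
}

#' Convert 8-bit sRGB intensities to optical density
#'
#' Beer-Lambert transform `od = -log10(max(I, 1) / 255)` per channel, with
#' reference white I0 = 255.  The floor of one intensity step keeps the OD
#' bounded (about 2.407 at I = 0), which keeps downstream least-squares
#' fits stable.
#'
#' @param rgb colors/images as in [rgb_to_lab()], values in \[0, 255\].
#' @return optical densities (>= 0, dimensionless), same shape.
#' @export
rgb_to_od <- function(rgb) {
  cm <- .as_color_matrix(rgb)
  od <- -log10(pmax(cm$m, 1) / 255)
  colnames(od) <- c("od_r", "od_g", "od_b")
  .restore_shape(od, cm$dim)
}

#' Convert optical density back to 8-bit sRGB intensities
#'
#' @param od optical densities (>= 0), shapes as in [rgb_to_lab()].
#' @return intensities in \[0, 255\] (double).
#' @export
od_to_rgb <- function(od) {
  cm <- .as_color_matrix(od)
  out <- pmin(pmax(255 * 10^(-cm$m), 0), 255)
  colnames(out) <- c("r", "g", "b")
  .restore_shape(out, cm$dim)
}

#' CIE76 perceptual color difference
#'
#' Euclidean distance in CIELAB,
#' `sqrt((dL*)^2 + (da*)^2 + (db*)^2)` -- the perceived contrast between
#' two colors.
#'
#' @param lab1,lab2 CIELAB colors (recycled rowwise if one side is a
#'   single color).
#' @return nonnegative numeric vector of distances.
#' @examples
#' delta_e(rgb_to_lab("#000000"), rgb_to_lab("#FFFFFF"))  # 100
#' @export
delta_e <- function(lab1, lab2) {
  m1 <- .as_color_matrix(lab1)$m
  m2 <- .as_color_matrix(lab2)$m
  if (nrow(m1) == 1L && nrow(m2) > 1L) m1 <- m1[rep(1L, nrow(m2)), , drop = FALSE]
  if (nrow(m2) == 1L && nrow(m1) > 1L) m2 <- m2[rep(1L, nrow(m1)), , drop = FALSE]
  sqrt(rowSums((m1 - m2)^2))
}

#' Ratio of two contrast values
#'
#' `R = C1 / C2`; when `C1 > C2` this is the fold increase of
#' object-to-background contrast of image 1 over image 2.
#'
#' @param c1,c2 nonnegative contrast scalars (`c2` must be positive).
#' @return the ratio `c1 / c2`.
#' @export
contrast_ratio <- function(c1, c2) {
  if (any(c2 <= 0)) stop("contrast_ratio: reference contrast C2 must be > 0 (degenerate comparison)")
  c1 / c2
}
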