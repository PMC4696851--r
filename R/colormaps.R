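# Bivariate color maps: the set of all colors a two-stain image can
# display, indexed by normalized (stain-1, stain-2) intensity (u, v) in
# [0,1]^2.  u is the chromogen (DAB/foreground) axis, v the counterstain
# (hematoxylin/background) axis, and (0,0) is the white, unstained corner.
#
# Designed maps are bilinear patches in CIELAB between four corner colors
# (white at (0,0), black at (1,1), the two free hues at (1,0) and (0,1)),
# which makes them perceptually linear: equal steps in (u,v) give equal
# Delta-E steps along any row or column.  Extracted maps are measured from
# an image by binning its pixels in (u,v) and averaging their colors in
# CIELAB; unobserved bins are filled by harmonic (Laplace) interpolation,
# which is linear across one-dimensional gaps and stays between the
# surrounding observed colors.

.new_colormap <- function(grid, kind, coords, corners = NULL,
                          norm_lo = NULL, norm_hi = NULL,
                          coverage = NULL, clipped_fraction = 0) {
  structure(list(
    grid = grid, kind = kind, coords = coords, corners = corners,
    norm_lo = norm_lo, norm_hi = norm_hi, coverage = coverage,
    clipped_fraction = clipped_fraction,
    K = dim(grid)[1]), class = "bivariate_colormap")
}

#' @export
print.bivariate_colormap <- function(x, ...) {
  cat(sprintf("Bivariate color map (%s), %d x %d", x$kind, x$K, x$K))
  if (!is.null(x$corners))
    cat(";  corners", paste(rgb_to_hex(x$corners), collapse = " "))
  if (x$clipped_fraction > 0)
    cat(sprintf(";  %.1f%% of cells gamut-clipped", 100 * x$clipped_fraction))
  cat("\n")
  invisible(x)
}

#' Design a perceptually linear four-corner color map
#'
#' The map is defined by four corner colors -- white `#FFFFFF` at the
#' unstained corner (0,0), black `#000000` at the doubly saturated corner
#' (1,1), `hue1` at the pure-foreground corner (1,0) and `hue2` at the
#' pure-background corner (0,1) -- and a bilinear interpolation between
#' their CIELAB coordinates.  Interpolation happens in CIELAB first; the
#' grid is converted to sRGB with per-channel gamut clipping last, and the
#' clipped-cell fraction is recorded on the map.
#'
#' @param hue1 foreground (chromogen) corner color: hex string or RGB
#'   triple.
#' @param hue2 background (counterstain) corner color.
#' @param K grid resolution (default 24; map summary statistics reported
#'   by the package refer to this corner-inclusive node grid).
#' @return a `bivariate_colormap` of kind `"designed"` with node
#'   coordinates `seq(0, 1, length.out = K)`.
#' @examples
#' m <- design_map("#006EFF", "#FFAD00")
#' contrast_profile(m)
#' @export
design_map <- function(hue1, hue2, K = 24L) {
  stopifnot(K >= 2L)
  corners <- rbind(white = c(255, 255, 255),
                   hue1 = .as_color_matrix(hue1)$m[1, ],
                   hue2 = .as_color_matrix(hue2)$m[1, ],
                   black = c(0, 0, 0))
  lab_c <- rgb_to_lab(corners)
  u <- seq(0, 1, length.out = K)
  g <- expand.grid(u = u, v = u)             # u varies fastest = row index
  lab <- (1 - g$u) * (1 - g$v) %o% lab_c["white", ] +
         g$u * (1 - g$v) %o% lab_c["hue1", ] +
         (1 - g$u) * g$v %o% lab_c["hue2", ] +
         g$u * g$v %o% lab_c["black", ]
  rgb <- lab_to_rgb(lab)
  clipped <- attr(rgb, "clipped")
  grid <- array(rgb, c(K, K, 3L))
  .new_colormap(grid, "designed", coords = u, corners = corners,
                clipped_fraction = mean(clipped))
}

#' Evaluate a color map at (u, v) coordinates
#'
#' Looks the map up at arbitrary normalized stain coordinates.  The
#' default bilinear lookup interpolates between grid nodes in CIELAB (for
#' a designed map this reproduces the continuous bilinear surface
#' exactly); `"nearest"` snaps to the closest grid cell.  Coordinates are
#' clamped to \[0, 1\] and, beyond the outermost node positions, to the
#' edge of the grid.
#'
#' @param map a `bivariate_colormap`.
#' @param u,v numeric vectors (equal length) of foreground/background
#'   coordinates.
#' @param lookup `"bilinear"` or `"nearest"`.
#' @return n x 3 matrix of sRGB colors (double, in \[0, 255\]).
#' @export
eval_colormap <- function(map, u, v, lookup = c("bilinear", "nearest")) {
  lookup <- match.arg(lookup)
  stopifnot(inherits(map, "bivariate_colormap"), length(u) == length(v))
  K <- map$K
  x <- map$coords
  u <- pmin(pmax(u, x[1]), x[K])
  v <- pmin(pmax(v, x[1]), x[K])
  if (lookup == "nearest") {
    iu <- sapply(u, function(z) which.min(abs(x - z)))
    iv <- sapply(v, function(z) which.min(abs(x - z)))
    return(matrix(map$grid[cbind(rep(iu, 3), rep(iv, 3), rep(1:3, each = length(u)))],
                  ncol = 3, dimnames = list(NULL, c("r", "g", "b"))))
  }
  lab <- rgb_to_lab(map$grid)                 # K x K x 3
  i0 <- pmin(pmax(findInterval(u, x), 1L), K - 1L)
  j0 <- pmin(pmax(findInterval(v, x), 1L), K - 1L)
  fu <- (u - x[i0]) / (x[i0 + 1L] - x[i0])
  fv <- (v - x[j0]) / (x[j0 + 1L] - x[j0])
  out <- matrix(0, length(u), 3L)
  for (k in 1:3) {
    l00 <- lab[cbind(i0, j0, k)];     l10 <- lab[cbind(i0 + 1L, j0, k)]
    l01 <- lab[cbind(i0, j0 + 1L, k)]; l11 <- lab[cbind(i0 + 1L, j0 + 1L, k)]
    out[, k] <- (1 - fu) * (1 - fv) * l00 + fu * (1 - fv) * l10 +
                (1 - fu) * fv * l01 + fu * fv * l11
  }
  res <- lab_to_rgb(out)
  attr(res, "clipped") <- NULL
  colnames(res) <- c("r", "g", "b")
  res
}

#' Extract the bivariate color map inherent in an image
#'
#' Concentrations are clamped to be nonnegative and normalized to \[0, 1\]
#' by per-channel percentile anchors (1st and 99th percentile, robust to
#' specular/dust outliers); pixels are binned into a K x K grid over
#' (u, v), each observed bin's color is the CIELAB mean of its member
#' pixels, and unobserved bins are filled by harmonic interpolation with
#' the observed bins as boundary data.
#'
#' @param image RGB image (H x W x 3, \[0, 255\]) the concentrations came
#'   from.
#' @param conc a `concentration_image` from [deconvolve()], aligned with
#'   `image`.
#' @param K grid resolution (default 64; bins need enough member pixels).
#' @param probs the two percentile anchors (default `c(0.01, 0.99)`).
#' @return a `bivariate_colormap` of kind `"extracted"` with bin-center
#'   coordinates, `coverage` mask, and the `norm_lo`/`norm_hi` anchors
#'   (named `d` and `h`) needed to re-stain reproducibly.
#' @export
extract_map <- function(image, conc, K = 64L, probs = c(0.01, 0.99)) {
  stopifnot(inherits(conc, "concentration_image"), K >= 2L)
  d <- pmax(as.vector(conc$d), 0)
  h <- pmax(as.vector(conc$h), 0)
  lo <- c(d = unname(stats::quantile(d, probs[1])), h = unname(stats::quantile(h, probs[1])))
  hi <- c(d = unname(stats::quantile(d, probs[2])), h = unname(stats::quantile(h, probs[2])))
  if (hi["d"] - lo["d"] < 1e-8 || hi["h"] - lo["h"] < 1e-8)
    stop("degenerate image: a stain channel is (near) constant; cannot normalize")
  u <- pmin(pmax((d - lo["d"]) / (hi["d"] - lo["d"]), 0), 1)
  v <- pmin(pmax((h - lo["h"]) / (hi["h"] - lo["h"]), 0), 1)
  bi <- pmin(floor(u * K) + 1L, K)
  bj <- pmin(floor(v * K) + 1L, K)
  cell <- (bj - 1L) * K + bi
  lab_px <- .as_color_matrix(rgb_to_lab(image))$m
  n_cell <- tabulate(cell, nbins = K * K)
  observed <- n_cell > 0L
  if (sum(observed) < 3L)
    stop("degenerate image: fewer than 3 observed color-map bins")
  lab_grid <- matrix(NA_real_, K * K, 3L)
  for (k in 1:3)
    lab_grid[observed, k] <- (rowsum(lab_px[, k], cell)[, 1]) / n_cell[observed]
  lab_grid <- .harmonic_fill(lab_grid, observed, K)
  rgb <- lab_to_rgb(lab_grid)
  clipped <- attr(rgb, "clipped")
  grid <- array(rgb, c(K, K, 3L))
  .new_colormap(grid, "extracted", coords = (seq_len(K) - 0.5) / K,
                norm_lo = lo, norm_hi = hi,
                coverage = matrix(observed, K, K),
                clipped_fraction = mean(clipped))
}

# Harmonic (Laplace) in-fill of missing grid cells, per column of `vals`
# (n_cells x 3, NA where missing), observed cells as Dirichlet data.
# 4-neighbor grid graph; solved with a sparse Cholesky via Matrix.
.harmonic_fill <- function(vals, observed, K) {
  miss <- which(!observed)
  if (length(miss) == 0L) return(vals)
  idx_of <- integer(K * K); idx_of[miss] <- seq_along(miss)
  ij <- cbind((miss - 1L) %% K + 1L, (miss - 1L) %/% K + 1L)
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  b <- matrix(0, length(miss), ncol(vals))
  deg <- integer(length(miss))
  for (shift in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    ni <- ij[, 1] + shift[1]; nj <- ij[, 2] + shift[2]
    ok <- ni >= 1L & ni <= K & nj >= 1L & nj <= K
    ncell <- (nj[ok] - 1L) * K + ni[ok]
    deg[ok] <- deg[ok] + 1L
    nb_missing <- !observed[ncell]
    src <- which(ok)
    trip_i <- c(trip_i, src[nb_missing])
    trip_j <- c(trip_j, idx_of[ncell[nb_missing]])
    trip_x <- c(trip_x, rep(-1, sum(nb_missing)))
    obs_src <- src[!nb_missing]
    obs_cell <- ncell[!nb_missing]
    if (length(obs_src))
      b[obs_src, ] <- b[obs_src, , drop = FALSE] + vals[obs_cell, , drop = FALSE]
  }
  A <- Matrix::sparseMatrix(
    i = c(seq_along(miss), trip_i),
    j = c(seq_along(miss), trip_j),
    x = c(deg, trip_x),
    dims = c(length(miss), length(miss)))
  sol <- as.matrix(Matrix::solve(A, b))
  vals[miss, ] <- sol
  vals
}

#' Check a corner set against the color-map design rules
#'
#' The design rules for replacement maps: no more than two basic hues
#' among the non-achromatic corners, and red and green hues must not
#' co-occur (red-green color-vision deficiency is the most prevalent).
#' Hue categories are derived from the CIELAB hue angle
#' `atan2(b*, a*)` -- red \[-35, 35), yellow/orange \[35, 100), green
#' \[100, 190), blue \[190, 325) degrees -- with corners of chroma < 10
#' treated as achromatic.  (The red/orange boundary sits at 45 degrees
#' because the CIELAB hue angle of the sRGB red primary is about 40
#' degrees.)
#'
#' @param corners 4 colors (hex strings or 4 x 3 RGB matrix).
#' @return character vector of rule violations (empty if the design is
#'   acceptable).
#' @export
validate_design <- function(corners) {
  m <- .as_color_matrix(corners)$m
  stopifnot(nrow(m) == 4L)
  lab <- rgb_to_lab(m)
  chroma <- sqrt(lab[, 2]^2 + lab[, 3]^2)
  hue <- (atan2(lab[, 3], lab[, 2]) * 180 / pi) %% 360
  cat_of <- function(h) {
    if (h >= 325 || h < 45) "red"
    else if (h < 100) "yellow/orange"
    else if (h < 190) "green"
    else "blue"
  }
  cats <- vapply(hue[chroma >= 10], cat_of, character(1))
  violations <- character(0)
  if (length(unique(cats)) > 2L)
    violations <- c(violations, sprintf(
      "more than two basic hues among non-achromatic corners (%s)",
      paste(unique(cats), collapse = ", ")))
  if (all(c("red", "green") %in% cats))
    violations <- c(violations,
      "red and green hues co-occur (poor for red-green color-vision deficiency)")
  violations
}

#' Perceptual-contrast profile of a color map
#'
#' Measures, for every map entry, the CIE76 distance to a neutral
#' element: the map's center point at (u, v) = (0.5, 0.5) (for a designed
#' map this equals the mean of the four corner colors by the bilinear
#' midpoint identity; for an extracted map the grid midpoint is used).
#'
#' @param map a `bivariate_colormap`.
#' @return an object of class `map_contrast_profile`: list with `center`
#'   (Lab), `distance_grid` (K x K), and `mean`, `sd`, `max` summaries
#'   over all entries.
#' @export
contrast_profile <- function(map) {
  stopifnot(inherits(map, "bivariate_colormap"))
  center_rgb <- eval_colormap(map, 0.5, 0.5)
  center <- rgb_to_lab(center_rgb)[1, ]
  lab <- matrix(rgb_to_lab(map$grid), ncol = 3L)
  d <- sqrt(rowSums(sweep(lab, 2, center)^2))
  structure(list(
    center = center,
    distance_grid = matrix(d, map$K, map$K),
    mean = mean(d), sd = stats::sd(d), max = max(d)), class = "map_contrast_profile")
}

#' @export
print.map_contrast_profile <- function(x, ...) {
  cat(sprintf("Map contrast profile: mean %.1f +/- %.1f, max %.1f (Delta-E to center)\n",
              x$mean, x$sd, x$max))
  invisible(x)
}

#' Surface area of a color map in CIELAB
#'
#' The area of the map's image surface in CIELAB space, computed over the
#' 2(K-1)^2 triangles tiling the K x K grid.  A larger surface means the
#' map spans more perceptually distinct colors.
#'
#' @param map a `bivariate_colormap`.
#' @return scalar area in CIELAB units.
#' @export
map_surface_area <- function(map) {
  stopifnot(inherits(map, "bivariate_colormap"))
  lab <- rgb_to_lab(map$grid)                  # K x K x 3
  K <- map$K
  p <- function(i, j) matrix(lab[cbind(rep(i, 3), rep(j, 3), rep(1:3, each = length(i)))], ncol = 3)
  i <- rep(1:(K - 1), K - 1); j <- rep(1:(K - 1), each = K - 1)
  a00 <- p(i, j); a10 <- p(i + 1L, j); a01 <- p(i, j + 1L); a11 <- p(i + 1L, j + 1L)
  tri_area <- function(A, B, C) {
    u <- B - A; v <- C - A
    cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                u[, 3] * v[, 1] - u[, 1] * v[, 3],
                u[, 1] * v[, 2] - u[, 2] * v[, 1])
    0.5 * sqrt(rowSums(cr^2))
  }
  sum(tri_area(a00, a10, a01)) + sum(tri_area(a11, a10, a01))
}

#' Write a color map to a PNG image plus JSON sidecar
#'
#' @param map a `bivariate_colormap`.
#' @param png_path output PNG (the K x K grid, u increasing left to
#'   right, v bottom to top).
#' @param json_path output JSON sidecar (kind, corners, anchors, K,
#'   clipped fraction); defaults to `png_path` with extension `.json`.
#' @return invisibly, the sidecar list.
#' @export
write_colormap <- function(map, png_path, json_path = NULL) {
  stopifnot(inherits(map, "bivariate_colormap"))
  if (is.null(json_path)) json_path <- paste0(tools::file_path_sans_ext(png_path), ".json")
  img <- aperm(map$grid[, map$K:1, , drop = FALSE], c(1, 2, 3))
  write_image(aperm(img, c(2, 1, 3)), png_path)
  side <- list(
    kind = map$kind, K = map$K,
    coords = map$coords,
    corners = if (!is.null(map$corners)) rgb_to_hex(map$corners) else NULL,
    norm_lo = map$norm_lo, norm_hi = map$norm_hi,
    clipped_fraction = map$clipped_fraction)
  jsonlite::write_json(side, json_path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(side)
}
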