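# Quantitative evaluation: phantom-image pairwise color-map comparison
# and Otsu-based foreground/background contrast measurement.
#
# The phantom is a 6 x 6 layout of equal circles on a homogeneous
# background, defined in normalized stain coordinates and colored only
# when a map is applied.  The field carries (u, v) = (0, 1): no
# chromogen, full counterstain.  Circle k sits on the stain-exchange
# diagonal (u, v) = (level_k, 1 - level_k): with increasing level the
# chromogen progressively displaces the counterstain, so the circles
# sweep the map from the background corner toward the pure-foreground
# corner and the last circle shows the full foreground hue.  Contrast of
# a color-map pair is the mean over circles of the CIE76 distance between
# the rendered circle and the rendered background.

#' Build an abstract 6 x 6 circle phantom
#'
#' @param levels 36 foreground levels in (0, 1\], strictly increasing
#'   (default `(1:36)/36`).
#' @param cell pixel size of one layout cell (default 48).
#' @param radius circle radius in pixels (default 16; must fit in the
#'   cell).
#' @return an object of class `phantom`: list with `u`, `v` (per-pixel
#'   coordinate matrices), `labels` (0 = background, k = circle k),
#'   `levels`, and the geometry.
#' @export
make_phantom <- function(levels = (1:36) / 36, cell = 48L, radius = 16L) {
  if (length(levels) != 36L) stop("phantom needs exactly 36 circle levels")
  if (any(levels <= 0) || any(levels > 1) || any(diff(levels) <= 0))
    stop("levels must be strictly increasing, in (0, 1]")
  if (2L * radius >= cell) stop("circles must fit inside their layout cell")
  W <- H <- 6L * cell
  xs <- matrix(rep(seq_len(W), each = H), H, W)
  ys <- matrix(rep(seq_len(H), W), H, W)
  labels <- matrix(0L, H, W)
  for (k in seq_len(36L)) {
    row <- (k - 1L) %/% 6L; col <- (k - 1L) %% 6L     # row-major layout
    cx <- col * cell + cell / 2; cy <- row * cell + cell / 2
    inside <- (xs - cx)^2 + (ys - cy)^2 <= radius^2
    labels[inside] <- k
  }
  u <- matrix(0, H, W); v <- matrix(1, H, W)
  for (k in seq_len(36L)) {
    u[labels == k] <- levels[k]
    v[labels == k] <- 1 - levels[k]
  }
  structure(list(u = u, v = v, labels = labels, levels = levels,
                 cell = cell, radius = radius), class = "phantom")
}

#' Render a phantom through a four-corner color map
#'
#' Builds `design_map(fg, bg)` and evaluates it at each pixel's (u, v).
#'
#' @param p a [make_phantom()] object.
#' @param fg,bg foreground and background hues (hex or RGB).
#' @param K grid resolution of the designed map.
#' @return RGB image (H x W x 3, double \[0, 255\]).
#' @export
apply_map_to_phantom <- function(p, fg, bg, K = 24L) {
  stopifnot(inherits(p, "phantom"))
  m <- design_map(fg, bg, K = K)
  out <- eval_colormap(m, as.vector(p$u), as.vector(p$v))
  array(out, c(dim(p$u), 3L))
}

#' Phantom contrast of a color-map pair
#'
#' Renders the phantom and measures, per circle, the CIE76 distance
#' between the circle's rendered color and the background's rendered
#' color; returns mean and SD over the 36 circles.  The result depends
#' only on the circle levels, not on canvas resolution.
#'
#' @inheritParams apply_map_to_phantom
#' @return named numeric `c(mean =, sd =)` of raw Delta-E values.
#' @export
phantom_contrast <- function(p, fg, bg, K = 24L) {
  stopifnot(inherits(p, "phantom"))
  img <- apply_map_to_phantom(p, fg, bg, K = K)
  lab <- rgb_to_lab(img)
  labm <- matrix(lab, ncol = 3L)
  lb <- as.vector(p$labels)
  bg_lab <- colMeans(labm[lb == 0L, , drop = FALSE])
  d <- vapply(seq_len(36L), function(k) {
    delta_e(colMeans(labm[lb == k, , drop = FALSE]), bg_lab)
  }, numeric(1))
  c(mean = mean(d), sd = stats::sd(d))
}

#' Packaged phantom color list
#'
#' The 15 colors compared pairwise in the phantom evaluation: white,
#' black, gray, the corner hues of five optimized orange/red-blue maps,
#' and the standard H-DAB brown `#B58C70` and blue `#5C5FA1`.  Four of
#' the optimized hues are the published blue/orange `#006EFF`/`#FFAD00`
#' and red/blue `#FF0000`/`#0093FF` pairs; the remaining three pairs are
#' synthetic stand-ins chosen from the same orange-red/blue hue and
#' lightness families (see the packaged fixture file for per-color
#' provenance).
#'
#' @return data frame with columns `hex` and `role`.
#' @export
phantom_colors <- function() {
  path <- system.file("extdata", "phantom_colors_synthetic.json",
                      package = "restainr", mustWork = TRUE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$colors
}

#' Pairwise phantom-contrast matrix
#'
#' For every ordered (foreground, background) pair of the supplied
#' colors, measures the phantom contrast; all means are then divided by
#' the global maximum mean (and the SDs scaled by the same factor), so
#' the best pair scores 1.
#'
#' @param colors character vector of hex codes (default: the 15 packaged
#'   phantom colors); duplicates are allowed but flagged with a warning.
#' @param p phantom to use (default [make_phantom()]).
#' @param K designed-map grid resolution.
#' @return an object of class `pairwise_contrast_matrix`: list with
#'   `colors`, `mean_grid` and `sd_grid` (n x n, normalized to \[0, 1\],
#'   diagonal 0), and `max_raw` (the unnormalized maximum mean).
#' @export
pairwise_matrix <- function(colors = phantom_colors()$hex,
                            p = make_phantom(), K = 24L) {
  if (is.data.frame(colors)) colors <- colors$hex
  if (anyDuplicated(colors)) warning("duplicate colors in the phantom color list")
  n <- length(colors)
  mean_grid <- sd_grid <- matrix(0, n, n, dimnames = list(colors, colors))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    cs <- phantom_contrast(p, colors[i], colors[j], K = K)
    mean_grid[i, j] <- cs["mean"]; sd_grid[i, j] <- cs["sd"]
  }
  max_raw <- max(mean_grid)
  structure(list(colors = colors,
                 mean_grid = mean_grid / max_raw,
                 sd_grid = sd_grid / max_raw,
                 max_raw = max_raw), class = "pairwise_contrast_matrix")
}

#' @export
print.pairwise_contrast_matrix <- function(x, ...) {
  best <- which(x$mean_grid == 1, arr.ind = TRUE)[1, ]
  cat(sprintf("Pairwise phantom contrast, %d colors; best pair %s on %s (raw mean %.1f)\n",
              length(x$colors), x$colors[best[1]], x$colors[best[2]], x$max_raw))
  invisible(x)
}

#' Otsu threshold of a numeric vector
#'
#' Maximizes the between-class variance of a 256-bin histogram built
#' over the 1st-99th percentile range of the data; implemented from the
#' histogram definition so the threshold is bit-reproducible.
#'
#' @param x numeric values.
#' @param n_bins number of histogram bins (default 256).
#' @param probs percentile range of the histogram (default
#'   `c(0.01, 0.99)`).
#' @return the threshold value (upper edge of the background class).
#' @export
otsu_threshold <- function(x, n_bins = 256L, probs = c(0.01, 0.99)) {
  rng <- stats::quantile(x, probs, names = FALSE)
  if (diff(rng) < 1e-12) stop("degenerate data: no spread for Otsu thresholding")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  xc <- pmin(pmax(x, rng[1]), rng[2])
  h <- tabulate(pmin(findInterval(xc, edges, rightmost.closed = TRUE), n_bins),
                nbins = n_bins)
  w <- h / sum(h)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b[-n_bins])
  edges[k + 1L]
}

#' Segment the DAB-positive foreground of a concentration image
#'
#' Otsu-thresholds the DAB channel and removes connected components
#' (8-connectivity) smaller than `min_object_px`.
#'
#' @param conc a `concentration_image` with matrix-shaped channels.
#' @param min_object_px minimum object size in pixels (default 64).
#' @return logical foreground mask (attribute `threshold` records the
#'   Otsu cut).  Raises an explicit error if the cleaned foreground is
#'   empty.
#' @export
foreground_mask <- function(conc, min_object_px = 64L) {
  stopifnot(inherits(conc, "concentration_image"), is.matrix(conc$d))
  thr <- otsu_threshold(as.vector(conc$d))
  mask <- conc$d > thr
  lab <- .label_components(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_object_px)
  mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  if (!any(mask)) stop("empty foreground after cleaning (no object >= min_object_px)")
  attr(mask, "threshold") <- thr
  mask
}

# Two-pass 8-connectivity labeling with union-find.
.label_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  parent <- integer(0)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  union <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
  nxt <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (!mask[i, j]) next
    nb <- integer(0)
    if (i > 1L && lab[i - 1L, j] > 0L) nb <- c(nb, lab[i - 1L, j])
    if (j > 1L) {
      if (lab[i, j - 1L] > 0L) nb <- c(nb, lab[i, j - 1L])
      if (i > 1L && lab[i - 1L, j - 1L] > 0L) nb <- c(nb, lab[i - 1L, j - 1L])
      if (i < H && lab[i + 1L, j - 1L] > 0L) nb <- c(nb, lab[i + 1L, j - 1L])
    }
    if (length(nb) == 0L) {
      nxt <- nxt + 1L; parent[nxt] <- nxt; lab[i, j] <- nxt
    } else {
      m <- min(nb); lab[i, j] <- m
      for (o in nb) union(m, o)
    }
  }
  if (nxt == 0L) return(lab)
  roots <- vapply(seq_len(nxt), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  lab[lab > 0L] <- relab[lab[lab > 0L]]
  lab
}

#' Object-to-background contrast change after re-staining
#'
#' Computes the mean CIELAB color of the foreground mask and of its
#' complement in both images, the CIE76 contrast between them before and
#' after, and the percentage improvement.
#'
#' @param original,restained RGB images (H x W x 3, same shape).
#' @param mask logical foreground mask (non-empty, non-full).
#' @return an object of class `contrast_report`: list with `fg_before`,
#'   `bg_before`, `fg_after`, `bg_after` (Lab), `contrast_before`,
#'   `contrast_after`, `improvement_pct`.
#' @export
contrast_improvement <- function(original, restained, mask) {
  stopifnot(identical(dim(original), dim(restained)))
  m <- as.vector(mask)
  if (!any(m) || all(m)) stop("degenerate mask: foreground must be non-empty and non-full")
  lab_o <- matrix(rgb_to_lab(original), ncol = 3L)
  lab_r <- matrix(rgb_to_lab(restained), ncol = 3L)
  fg_b <- colMeans(lab_o[m, , drop = FALSE]); bg_b <- colMeans(lab_o[!m, , drop = FALSE])
  fg_a <- colMeans(lab_r[m, , drop = FALSE]); bg_a <- colMeans(lab_r[!m, , drop = FALSE])
  cb <- delta_e(fg_b, bg_b); ca <- delta_e(fg_a, bg_a)
  structure(list(fg_before = fg_b, bg_before = bg_b,
                 fg_after = fg_a, bg_after = bg_a,
                 contrast_before = cb, contrast_after = ca,
                 improvement_pct = 100 * (ca / cb - 1)), class = "contrast_report")
}

#' @export
print.contrast_report <- function(x, ...) {
  cat(sprintf("Object-to-background contrast: %.1f before, %.1f after (%+.1f%%)\n",
              x$contrast_before, x$contrast_after, x$improvement_pct))
  invisible(x)
}
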