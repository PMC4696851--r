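# Unsupervised, PCA-optimized color deconvolution of two-stain images.
#
# The mixing model is Beer-Lambert: in optical-density space a pixel is a
# nonnegative linear combination of unit stain vectors, so zero stain means
# zero OD and the stain plane passes through the origin.  The fit is
# therefore an *uncentered* PCA (SVD of the raw OD pixel matrix): the
# top-two right singular directions span the plane that minimizes the
# out-of-plane sum of squares, and the residual direction is its normal.

#' Construct a stain basis
#'
#' A stain basis holds three unit row vectors in optical-density space:
#' the hematoxylin (counterstain) direction, the DAB (chromogen)
#' direction, and a residual direction that captures what the two stains
#' cannot explain.
#'
#' @param h_vec,d_vec,res_vec numeric length-3 vectors (any scale; rows are
#'   normalized to unit Euclidean norm).  If `res_vec` is `NULL` it is set
#'   to the unit cross product of `h_vec` and `d_vec` (orthogonal to the
#'   stain plane), signed so the 3 x 3 matrix has positive determinant.
#' @param label short text tag ("ruifrok", "fiji", "optimized", or a user
#'   label).
#' @return an object of class `stain_basis`: a 3 x 3 matrix with rows
#'   `h`, `d`, `res` and attribute `label`.
#' @export
stain_basis <- function(h_vec, d_vec, res_vec = NULL, label = "user") {
  unit <- function(v) {
    n <- sqrt(sum(v^2))
    if (n < 1e-12) stop("stain vector has (near) zero norm")
    v / n
  }
  h <- unit(as.numeric(h_vec))
  d <- unit(as.numeric(d_vec))
  if (is.null(res_vec)) {
    r <- .cross3(h, d)
    if (sqrt(sum(r^2)) < 1e-8)
      stop("h_vec and d_vec are (near) collinear; stain plane undefined")
    r <- unit(r)
  } else {
    r <- unit(as.numeric(res_vec))
  }
  m <- rbind(h = h, d = d, res = r)
  if (det(m) < 0) m["res", ] <- -m["res", ]
  if (abs(det(m)) < 1e-8)
    stop("stain basis is singular: residual direction lies in the stain plane")
  colnames(m) <- c("od_r", "od_g", "od_b")
  structure(m, label = label, class = c("stain_basis", "matrix", "array"))
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @export
print.stain_basis <- function(x, ...) {
  cat("Stain basis (", attr(x, "label"), ") in OD space:\n", sep = "")
  print(unclass(x)[, , drop = FALSE], digits = 4)
  invisible(x)
}

#' Published H-DAB reference stain vectors
#'
#' `"ruifrok"` returns the Hematoxylin and DAB absorption vectors from
#' Ruifrok & Johnston's color-deconvolution paper (H = (0.18, 0.20, 0.08),
#' DAB = (0.10, 0.21, 0.29), row-normalized); `"fiji"` returns the
#' renormalized variant shipped with the ImageJ/Fiji colour-deconvolution
#' plugin (H = (0.650, 0.704, 0.286), DAB = (0.268, 0.570, 0.776)).  In
#' both cases the residual direction is the unit normal of the stain
#' plane.
#'
#' @param name `"ruifrok"` or `"fiji"`.
#' @return a [stain_basis()].
#' @export
reference_basis <- function(name = c("ruifrok", "fiji")) {
  name <- match.arg(name)
  switch(name,
    ruifrok = stain_basis(c(0.18, 0.20, 0.08), c(0.10, 0.21, 0.29), label = "ruifrok"),
    fiji    = stain_basis(c(0.650, 0.704, 0.286), c(0.268, 0.570, 0.776), label = "fiji"))
}

#' Fit the stain plane of an image by uncentered PCA
#'
#' Pixels are filtered to those with total OD at or above
#' `background_od_threshold` (near-white pixels carry no stain-direction
#' information), optionally subsampled, and the top-two right singular
#' directions of the raw (uncentered) OD pixel matrix are returned
#' together with their cross-product normal.  The plane passes through the
#' origin, consistent with the Beer-Lambert mixing model.
#'
#' @param od OD pixels: n x 3 matrix or H x W x 3 array (from
#'   [rgb_to_od()]).
#' @param background_od_threshold pixels with `od_r + od_g + od_b` below
#'   this are excluded from the fit (default 0.15).
#' @param max_pixels at most this many pixels enter the SVD (default
#'   200000); subsampling is deterministic given `seed`.
#' @param seed integer seed for the subsampling draw.
#' @return list with `plane_basis` (2 x 3, orthonormal rows), `normal`
#'   (unit 3-vector), `explained_fraction` (fraction of total OD
#'   sum-of-squares captured by the plane) and `n_pixels_used`.
#' @export
fit_stain_plane <- function(od, background_od_threshold = 0.15,
                            max_pixels = 200000L, seed = 1L) {
  m <- .as_color_matrix(od)$m
  keep <- rowSums(m) >= background_od_threshold
  m <- m[keep, , drop = FALSE]
  if (nrow(m) < 3L)
    stop("degenerate input: fewer than 3 non-background pixels (rank 0 after filtering)")
  if (nrow(m) > max_pixels) {
    idx <- withr::with_seed(seed, sample.int(nrow(m), max_pixels))
    m <- m[idx, , drop = FALSE]
  }
  sv <- svd(m, nu = 0, nv = 3)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-30))
    stop("degenerate input: OD pixel data has rank < 2 (single-stain or blank image)")
  v1 <- sv$v[, 1]; v2 <- sv$v[, 2]
  # sign-fix: principal directions point into the nonnegative OD octant
  if (sum(v1) < 0) v1 <- -v1
  if (sum(v2) < 0) v2 <- -v2
  normal <- .cross3(v1, v2)
  normal <- normal / sqrt(sum(normal^2))
  list(
    plane_basis = rbind(C1 = v1, C2 = v2),
    normal = normal,
    explained_fraction = sum(sv$d[1:2]^2) / sum(sv$d^2),
    n_pixels_used = nrow(m))
}

#' Optimize a reference stain basis against a fitted plane
#'
#' Projects the reference hematoxylin and DAB vectors onto the image's
#' fitted stain plane and renormalizes, so the deconvolution residual is
#' minimal while each stain vector keeps the hue of the reference it came
#' from.  The residual direction is the plane normal, signed so the basis
#' matrix has positive determinant.
#'
#' @param reference a [stain_basis()] whose hues anchor the projection.
#' @param plane a plane as returned by [fit_stain_plane()].
#' @return an optimized [stain_basis()] (label `"optimized"`).
#' @export
optimize_basis <- function(reference, plane) {
  stopifnot(inherits(reference, "stain_basis"))
  B <- plane$plane_basis                      # 2 x 3 orthonormal
  proj <- function(v) as.numeric(t(B) %*% (B %*% v))
  h_p <- proj(reference["h", ])
  d_p <- proj(reference["d", ])
  if (sqrt(sum(h_p^2)) < 1e-6 || sqrt(sum(d_p^2)) < 1e-6)
    stop("a reference stain vector is (near) orthogonal to the fitted plane; hue orientation unrecoverable")
  stain_basis(h_p, d_p, res_vec = plane$normal, label = "optimized")
}

#' Fit the full optimized stain model of an image
#'
#' Convenience wrapper: OD transform, plane fit, and projection of the
#' reference vectors.
#'
#' @param image RGB image (H x W x 3, values in \[0, 255\]).
#' @param reference reference basis name or [stain_basis()] (default
#'   `"ruifrok"`).
#' @inheritParams fit_stain_plane
#' @return an object of class `fitted_stain_model`: list with
#'   `plane_basis`, `normal`, `basis` (the optimized [stain_basis()]),
#'   `reference`, `explained_fraction`, `n_pixels_used`.
#' @export
fit_stain_model <- function(image, reference = "ruifrok",
                            background_od_threshold = 0.15,
                            max_pixels = 200000L, seed = 1L) {
  if (is.character(reference)) reference <- reference_basis(reference)
  od <- rgb_to_od(image)
  plane <- fit_stain_plane(od, background_od_threshold, max_pixels, seed)
  basis <- optimize_basis(reference, plane)
  structure(list(
    plane_basis = plane$plane_basis,
    normal = plane$normal,
    basis = basis,
    reference = reference,
    explained_fraction = plane$explained_fraction,
    n_pixels_used = plane$n_pixels_used), class = "fitted_stain_model")
}

#' @export
print.fitted_stain_model <- function(x, ...) {
  cat("Fitted stain model:", x$n_pixels_used, "pixels,",
      sprintf("%.4f%%", 100 * x$explained_fraction),
      "of OD sum-of-squares in the stain plane\n")
  print(x$basis)
  invisible(x)
}

#' Color deconvolution of an RGB image
#'
#' Per pixel, solves `od = c_h * h + c_d * d + c_res * res` for the three
#' concentrations.  Raw (possibly negative) values are retained: they are
#' needed for an honest residual error and are clamped only when mapped to
#' color-map coordinates during re-staining.
#'
#' @param image RGB image (H x W x 3, values in \[0, 255\]) or an n x 3
#'   matrix of colors.
#' @param basis an invertible [stain_basis()].
#' @return an object of class `concentration_image`: list with per-pixel
#'   fields `h`, `d`, `res` (matrices, or vectors for matrix input), the
#'   `basis`, and `norm_lo`/`norm_hi` normalization anchors (unset until a
#'   map is extracted).
#' @export
deconvolve <- function(image, basis) {
  stopifnot(inherits(basis, "stain_basis"))
  od <- rgb_to_od(image)
  cm <- .as_color_matrix(od)
  conc <- cm$m %*% solve(unclass(basis))        # rows: (c_h, c_d, c_res)
  shape <- if (is.null(cm$dim)) NULL else cm$dim[1:2]
  reshape <- function(v) if (is.null(shape)) v else matrix(v, shape[1], shape[2])
  structure(list(
    h = reshape(conc[, 1]),
    d = reshape(conc[, 2]),
    res = reshape(conc[, 3]),
    basis = basis,
    norm_lo = NULL, norm_hi = NULL), class = "concentration_image")
}

#' Mean square error of the deconvolution residual channel
#'
#' @param conc a `concentration_image` from [deconvolve()].
#' @return mean over pixels of the squared residual concentration.
#' @export
residual_mse <- function(conc) {
  stopifnot(inherits(conc, "concentration_image"))
  mean(conc$res^2)
}

#' Re-compose an OD image from stain concentrations
#'
#' The linear-algebra inverse of [deconvolve()]; useful for checking that
#' the deconvolution is exact and for forward-simulating images.
#'
#' @param conc a `concentration_image`.
#' @return OD array/matrix of the original shape.
#' @export
recompose_od <- function(conc) {
  stopifnot(inherits(conc, "concentration_image"))
  V <- unclass(conc$basis)
  cm <- cbind(as.vector(conc$h), as.vector(conc$d), as.vector(conc$res))
  od <- cm %*% V
  if (is.matrix(conc$h)) array(od, c(dim(conc$h), 3L)) else od
}
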