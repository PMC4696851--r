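# Dichromacy simulation by LMS confusion-plane projection
# (Vienot/Brettel-style).  Colors are taken to linear RGB, then to LMS
# cone space (Hunt-Pointer-Estevez transform, D65-normalized so white is
# (1,1,1)); the missing cone's response is replaced by the value implied
# by a plane through the origin that contains the white axis and a
# device-gamut anchor far from the confusion axis (the sRGB blue primary
# for deuteranopia, the red primary for tritanopia).  Being a true
# projection, the simulation is exactly idempotent and leaves achromatic
# colors unchanged; all downstream uses are directional comparisons.

.M_HPE <- matrix(c(
   0.4002, 0.7076, -0.0808,
  -0.2263, 1.1653,  0.0457,
   0.0000, 0.0000,  0.9182), nrow = 3, byrow = TRUE)

.cvd_projection <- function(type) {
  M_lms <- .M_HPE %*% .M_RGB2XYZ           # linear RGB -> LMS
  white <- as.vector(M_lms %*% c(1, 1, 1))
  anchor <- switch(type,
    deuteranopia = as.vector(M_lms %*% c(0, 0, 1)),   # blue primary
    tritanopia   = as.vector(M_lms %*% c(1, 0, 0)))   # red primary
  miss <- switch(type, deuteranopia = 2L, tritanopia = 3L)
  keep <- setdiff(1:3, miss)
  A <- rbind(white[keep], anchor[keep])
  rhs <- c(white[miss], anchor[miss])
  coef <- solve(A, rhs)                     # missing = coef . kept
  P <- diag(3)
  P[miss, ] <- 0
  P[miss, keep] <- coef
  list(P = P, M_lms = M_lms, M_lms_inv = solve(M_lms))
}

#' Simulate dichromatic color vision
#'
#' Simulates the appearance of an image (or set of colors) to a
#' dichromatic observer lacking the M cone (deuteranopia) or the S cone
#' (tritanopia), by projecting LMS cone responses onto the dichromat's
#' confusion plane anchored at the white axis.  Out-of-gamut results are
#' clipped.
#'
#' @param image RGB image (H x W x 3), n x 3 matrix, or hex codes;
#'   values in \[0, 255\].
#' @param type `"deuteranopia"` or `"tritanopia"`.
#' @return simulated colors, same shape as the input (double,
#'   \[0, 255\]).
#' @export
simulate_dichromacy <- function(image, type = c("deuteranopia", "tritanopia")) {
  type <- match.arg(type)
  pr <- .cvd_projection(type)
  cm <- .as_color_matrix(image)
  v <- cm$m / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  lms <- lin %*% t(pr$M_lms)
  lms2 <- lms %*% t(pr$P)
  lin2 <- lms2 %*% t(pr$M_lms_inv)
  lin2 <- pmin(pmax(lin2, 0), 1)
  out <- 255 * ifelse(lin2 <= 0.0031308, 12.92 * lin2, 1.055 * lin2^(1 / 2.4) - 0.055)
  .restore_shape(out, cm$dim)
}

#' Contrast retention of color maps under dichromacy
#'
#' Simulates both maps for the given dichromacy type and returns, for
#' each, the ratio of the simulated to the original mean map contrast
#' ([contrast_profile()] mean).  A ratio near 1 means the map's
#' perceptual contrast survives the simulated deficiency.
#'
#' @param map_a,map_b two `bivariate_colormap`s with the same K.
#' @param type `"deuteranopia"` or `"tritanopia"`.
#' @return named numeric `c(a =, b =)` of retention ratios.
#' @export
cvd_robustness <- function(map_a, map_b, type = c("deuteranopia", "tritanopia")) {
  type <- match.arg(type)
  stopifnot(inherits(map_a, "bivariate_colormap"),
            inherits(map_b, "bivariate_colormap"),
            map_a$K == map_b$K)
  retention <- function(m) {
    before <- contrast_profile(m)$mean
    sim <- m
    sim$grid <- simulate_dichromacy(m$grid, type)
    after <- contrast_profile(sim)$mean
    after / before
  }
  c(a = retention(map_a), b = retention(map_b))
}
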