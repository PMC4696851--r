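# Shared fixtures and small helpers for the test suite.

# Small, fast synthetic H-DAB sample; noise-free unless asked otherwise.
tiny_ihc <- function(seed = 1L, noise_sd = 0.02, perturb_deg = 5,
                     width = 96L, height = 96L, n_objects = 6L) {
  generate_ihc(ihc_params(width = width, height = height,
                          n_objects = n_objects, radius_range = c(5, 12),
                          noise_sd = noise_sd, perturb_deg = perturb_deg,
                          seed = seed))
}

# A concentration_image built directly from known (d, h) fields, for tests
# that bypass deconvolution.
manual_conc <- function(d, h) {
  structure(list(h = h, d = d, res = d * 0,
                 basis = reference_basis("ruifrok"),
                 norm_lo = NULL, norm_hi = NULL),
            class = "concentration_image")
}

# CIELAB reference values computed with an independent implementation of
# the CIE formulas (scikit-image color.rgb2lab, sRGB/D65), frozen here.
LAB_ORACLE <- rbind(
  "#FFAD00" = c(76.7713, 19.7587, 80.1586),
  "#B58C70" = c(61.4392, 11.7092, 20.9446),
  "#5C5FA1" = c(42.8116, 16.3210, -36.1723),
  "#006EFF" = c(49.9396, 30.1210, -78.6748))
DE_BROWN_BLUE <- 60.25446   # delta-E #B58C70 vs #5C5FA1, same oracle

angle_deg <- function(a, b) {
  acos(pmin(1, abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2)))) * 180 / pi
}
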