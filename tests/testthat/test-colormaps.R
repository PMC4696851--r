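test_that("designed maps anchor their corners and are perceptually linear", {
  m <- design_map("#B58C70", "#5C5FA1", K = 16)   # gamut-clip-free pair
  expect_equal(m$clipped_fraction, 0)
  expect_equal(unname(m$grid[1, 1, ]), c(255, 255, 255), tolerance = 1e-6)
  expect_equal(unname(m$grid[16, 16, ]), c(0, 0, 0), tolerance = 1e-6)
  expect_equal(rgb_to_hex(m$grid[16, 1, ]), "#B58C70")
  expect_equal(rgb_to_hex(m$grid[1, 16, ]), "#5C5FA1")
  # equal Delta-E steps along every row and column
  lab <- rgb_to_lab(m$grid)
  for (i in 1:16) {
    row_steps <- sqrt(rowSums(diff(lab[i, , ])^2))
    col_steps <- sqrt(rowSums(diff(lab[, i, ])^2))
    expect_lt(diff(range(row_steps)), 1e-6)
    expect_lt(diff(range(col_steps)), 1e-6)
  }
})

test_that("swapping the two hues transposes a designed map", {
  a <- design_map("#FF0000", "#0093FF", K = 9)
  b <- design_map("#0093FF", "#FF0000", K = 9)
  expect_equal(a$grid, aperm(b$grid, c(2, 1, 3)), tolerance = 1e-9)
})

test_that("the map center obeys the bilinear midpoint identity", {
  m <- design_map("#B58C70", "#5C5FA1", K = 17)   # odd K: exact middle node
  corner_mean <- colMeans(rgb_to_lab(rbind(c(255, 255, 255), c(0, 0, 0),
                                           hex_to_rgb("#B58C70"),
                                           hex_to_rgb("#5C5FA1"))))
  expect_equal(unname(rgb_to_lab(m$grid[9, 9, ])[1, ]), unname(corner_mean),
               tolerance = 1e-6)
  expect_equal(unname(contrast_profile(m)$center), unname(corner_mean),
               tolerance = 1e-6)
})

test_that("contrast profiles report distance-to-center statistics", {
  # constant map: all distances zero
  m <- design_map("#808080", "#808080", K = 8)
  m$grid[] <- 128
  p <- contrast_profile(m)
  expect_equal(p$max, 0, tolerance = 1e-9)
  expect_equal(p$mean, 0, tolerance = 1e-9)
  # 2 x 2 map: closed form over the four corners
  corners <- c("#FFFFFF", "#000000", "#FF9600", "#00AAFF")
  m2 <- design_map("#FF9600", "#00AAFF", K = 2)
  lab_c <- rgb_to_lab(hex_to_rgb(corners))
  ctr <- colMeans(lab_c)
  expect_equal(contrast_profile(m2)$max,
               max(sqrt(rowSums(sweep(lab_c, 2, ctr)^2))), tolerance = 1e-6)
  # max for a designed map is attained at a corner
  m3 <- design_map("#006EFF", "#FFAD00", K = 24)
  p3 <- contrast_profile(m3)
  corner_idx <- rbind(c(1, 1), c(1, 24), c(24, 1), c(24, 24))
  expect_equal(p3$max, max(p3$distance_grid[corner_idx]), tolerance = 1e-9)
})

test_that("design rules flag bad corner sets and accept the blue/orange family", {
  expect_length(validate_design(c("#000000", "#FFFFFF", "#006EFF", "#FFAD00")), 0)
  v <- validate_design(c("#000000", "#FFFFFF", "#FF0000", "#00FF00"))
  expect_true(any(grepl("red and green", v)))
  expect_length(validate_design(c("#000000", "#FFFFFF", "#777777", "#999999")), 0)
})

test_that("surface area measures the CIELAB extent of a map", {
  m <- design_map("#808080", "#808080", K = 8)
  m$grid[] <- 128
  expect_equal(map_surface_area(m), 0, tolerance = 1e-9)
  # a planar Lab rectangle of known area (L = 50, a in [0,10], b in [0,20])
  K <- 5
  g <- expand.grid(a = seq(0, 10, length.out = K), b = seq(0, 20, length.out = K))
  rgbs <- lab_to_rgb(cbind(50, g$a, g$b))
  mp <- design_map("#808080", "#808080", K = K)
  mp$grid <- array(rgbs, c(K, K, 3L))
  expect_equal(map_surface_area(mp), 200, tolerance = 0.5)
  # the blue/orange replacement map spans more of CIELAB than the map
  # extracted from a standard-color synthetic H-DAB image
  s <- tiny_ihc(seed = 4, noise_sd = 0, perturb_deg = 0)
  conc <- deconvolve(s$image, fit_stain_model(s$image)$basis)
  extracted <- extract_map(s$image, conc, K = 24)
  expect_gt(map_surface_area(design_map("#006EFF", "#FFAD00", K = 24)),
            map_surface_area(extracted))
})

test_that("extracting a map from a densely sampled image recovers it", {
  src <- design_map("#B58C70", "#5C5FA1", K = 24)
  smp <- generate_from_map(src, 40000, mode = "grid")
  conc <- manual_conc(d = smp$u, h = smp$v)
  K <- 16
  ex <- extract_map(smp$image, conc, K = K)
  expect_true(all(ex$coverage))
  # compare observed bin colors with the source surface at the bin centers,
  # mapped through the percentile normalization the extractor applied
  uu <- (ex$coords * (ex$norm_hi["d"] - ex$norm_lo["d"])) + ex$norm_lo["d"]
  vv <- (ex$coords * (ex$norm_hi["h"] - ex$norm_lo["h"])) + ex$norm_lo["h"]
  ref <- eval_colormap(src, rep(uu, K), rep(vv, each = K))
  got <- matrix(ex$grid, ncol = 3)
  expect_lt(max(abs(got - ref)), 3)           # within 3 intensity steps
})

test_that("unobserved interior bins are filled between their neighbors", {
  src <- design_map("#FF0000", "#0093FF", K = 24)
  side <- 120
  g <- expand.grid(u = seq(0, 1, length.out = side), v = seq(0, 1, length.out = side))
  hole <- g$u > 0.35 & g$u < 0.65 & g$v > 0.35 & g$v < 0.65
  g <- g[!hole, ]
  cols <- eval_colormap(src, g$u, g$v)
  n <- nrow(g)
  img <- array(cols, c(n, 1, 3))
  conc <- manual_conc(d = matrix(g$u, n, 1), h = matrix(g$v, n, 1))
  ex <- extract_map(img, conc, K = 10)
  expect_true(any(!ex$coverage))
  lab_grid <- rgb_to_lab(ex$grid)
  obs_lab <- matrix(lab_grid, ncol = 3)[as.vector(ex$coverage), ]
  fill_lab <- matrix(lab_grid, ncol = 3)[!as.vector(ex$coverage), , drop = FALSE]
  for (ch in 1:3) {
    expect_gte(min(fill_lab[, ch]), min(obs_lab[, ch]) - 1e-6)
    expect_lte(max(fill_lab[, ch]), max(obs_lab[, ch]) + 1e-6)
  }
})

test_that("degenerate images cannot be mapped", {
  img <- array(200, c(10, 10, 3))
  conc <- manual_conc(d = matrix(0.5, 10, 10), h = matrix(0.5, 10, 10))
  expect_error(extract_map(img, conc), "degenerate")
})

test_that("color maps serialize to a PNG grid with a JSON sidecar", {
  m <- design_map("#006EFF", "#FFAD00", K = 24)
  png <- tempfile(fileext = ".png")
  side <- write_colormap(m, png)
  expect_true(file.exists(png))
  expect_true(file.exists(sub("png$", "json", png)))
  meta <- jsonlite::read_json(sub("png$", "json", png), simplifyVector = TRUE)
  expect_equal(meta$kind, "designed")
  expect_equal(meta$K, 24)
  expect_equal(meta$corners[1], "#FFFFFF")
})
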