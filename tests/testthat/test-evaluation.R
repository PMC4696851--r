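test_that("the phantom has 36 disjoint circles on a saturated-counterstain field", {
  p <- make_phantom()
  expect_equal(sort(unique(as.vector(p$labels))), 0:36)
  expect_true(all(diff(p$levels) > 0))
  # per-circle coordinates: (level, 1 - level); field at (0, 1)
  for (k in c(1L, 18L, 36L)) {
    expect_equal(unique(p$u[p$labels == k]), p$levels[k])
    expect_equal(unique(p$v[p$labels == k]), 1 - p$levels[k])
  }
  expect_equal(unique(p$u[p$labels == 0]), 0)
  expect_equal(unique(p$v[p$labels == 0]), 1)
  # total circle area matches 36 * pi r^2 up to rasterization
  frac <- mean(p$labels > 0)
  expect_equal(frac, 36 * pi * p$radius^2 / prod(dim(p$labels)), tolerance = 0.02)
  expect_error(make_phantom(levels = (1:10) / 10), "36")
  expect_error(make_phantom(radius = 40), "fit")
})

test_that("rendered phantoms have a homogeneous background and foreground-hue extreme", {
  p <- make_phantom()
  img <- apply_map_to_phantom(p, "#B58C70", "#5C5FA1")
  bgpx <- matrix(img, ncol = 3)[as.vector(p$labels) == 0, ]
  expect_lt(max(apply(bgpx, 2, function(x) diff(range(x)))), 1e-9)
  expect_equal(rgb_to_hex(bgpx[1, ]), "#5C5FA1")
  # the last circle (level 1) renders the pure-foreground corner
  fgpx <- matrix(img, ncol = 3)[as.vector(p$labels) == 36L, ]
  expect_equal(rgb_to_hex(fgpx[1, ]), "#B58C70")
})

test_that("phantom contrast matches the closed-form bilinear oracle in both orders", {
  p <- make_phantom()
  corners <- function(fg, bg) rgb_to_lab(rbind(hex_to_rgb("#FFFFFF"), hex_to_rgb(fg),
                                               hex_to_rgb(bg), hex_to_rgb("#000000")))
  oracle <- function(fg, bg) {
    lc <- corners(fg, bg)
    u <- p$levels; v <- 1 - u
    lab <- (1 - u) * (1 - v) %o% lc[1, ] + u * (1 - v) %o% lc[2, ] +
           (1 - u) * v %o% lc[3, ] + u * v %o% lc[4, ]
    d <- sqrt(rowSums(sweep(lab, 2, lc[3, ])^2))
    c(mean = mean(d), sd = sd(d))
  }
  for (pair in list(c("#B58C70", "#5C5FA1"), c("#5C5FA1", "#B58C70"))) {
    got <- phantom_contrast(p, pair[1], pair[2])
    expect_equal(got, oracle(pair[1], pair[2]), tolerance = 1e-4)
  }
})

test_that("phantom contrast is independent of canvas resolution", {
  a <- phantom_contrast(make_phantom(cell = 48L, radius = 16L), "#FF0000", "#0093FF")
  b <- phantom_contrast(make_phantom(cell = 24L, radius = 8L), "#FF0000", "#0093FF")
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("degenerate fg = bg pairs score far below distinct-hue pairs", {
  p <- make_phantom()
  same <- phantom_contrast(p, "#5C5FA1", "#5C5FA1")["mean"]
  distinct <- phantom_contrast(p, "#006EFF", "#FFAD00")["mean"]
  expect_lt(same, 0.5 * distinct)
})

test_that("the pairwise matrix is normalized to its best pair", {
  cols <- c("#FFFFFF", "#000000", "#006EFF", "#FFAD00", "#B58C70", "#5C5FA1")
  pm <- pairwise_matrix(cols)
  expect_equal(max(pm$mean_grid), 1)
  expect_true(all(pm$mean_grid >= 0 & pm$mean_grid <= 1))
  expect_true(all(diag(pm$mean_grid) == 0))
  expect_warning(pairwise_matrix(c(cols, "#FFFFFF")), "duplicate")
})

test_that("Otsu thresholding matches brute-force between-class variance maximization", {
  set.seed(10)
  x <- c(rnorm(4000, 0.25, 0.04), rnorm(1000, 0.75, 0.04))
  x <- pmin(pmax(x, 0), 1)
  ours <- otsu_threshold(x, probs = c(0, 1))
  # independent oracle: enumerate candidate cuts directly
  cand <- seq(0.05, 0.95, by = 0.001)
  bcv <- vapply(cand, function(t) {
    w0 <- mean(x < t)
    if (w0 == 0 || w0 == 1) return(0)
    w0 * (1 - w0) * (mean(x[x < t]) - mean(x[x >= t]))^2
  }, numeric(1))
  expect_equal(ours, cand[which.max(bcv)], tolerance = 0.01)
  expect_error(otsu_threshold(rep(1, 100)), "degenerate")
})

test_that("foreground masks recover DAB objects and guard degenerate cases", {
  s <- tiny_ihc(seed = 5, width = 128L, height = 128L)
  conc <- deconvolve(s$image, fit_stain_model(s$image)$basis)
  mask <- foreground_mask(conc, min_object_px = 16L)
  truth <- s$true_d > 0
  dice <- 2 * sum(mask & truth) / (sum(mask) + sum(truth))
  expect_gt(dice, 0.9)
  # a single object below the size cutoff leaves an empty foreground
  s1 <- generate_ihc(ihc_params(width = 64L, height = 64L, n_objects = 1L,
                                radius_range = c(6, 7), noise_sd = 0, seed = 2L))
  conc1 <- deconvolve(s1$image, s1$true_basis)
  expect_error(foreground_mask(conc1, min_object_px = 500L), "empty foreground")
})

test_that("8-connectivity labeling separates diagonal from disjoint components", {
  m <- matrix(FALSE, 6, 6)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE          # diagonal touch: one component
  m[5, 5] <- TRUE                            # far away: another
  lab <- restainr:::.label_components(m)
  expect_equal(lab[1, 1], lab[2, 2])
  expect_false(lab[5, 5] == lab[1, 1])
  expect_equal(max(lab), 2L)
})

test_that("contrast improvement is zero on identity and antisymmetric as a ratio", {
  s <- tiny_ihc(seed = 5, width = 128L, height = 128L)
  conc <- deconvolve(s$image, fit_stain_model(s$image)$basis)
  mask <- foreground_mask(conc, min_object_px = 16L)
  same <- contrast_improvement(s$image, s$image, mask)
  expect_equal(same$improvement_pct, 0, tolerance = 1e-9)
  model <- fit_stain_model(s$image)
  res <- restain_image(s$image, model, design_map("#006EFF", "#FFAD00"),
                       anchors = extract_map(s$image, conc, K = 32))
  fwd <- contrast_improvement(s$image, res$image, mask)
  bwd <- contrast_improvement(res$image, s$image, mask)
  expect_equal(log(fwd$contrast_after / fwd$contrast_before),
               -log(bwd$contrast_after / bwd$contrast_before), tolerance = 1e-9)
  expect_error(contrast_improvement(s$image, s$image, mask & FALSE), "degenerate")
})

test_that("the packaged phantom color list has 15 colors with provenance", {
  pc <- phantom_colors()
  expect_equal(nrow(pc), 15)
  expect_true(all(c("#B58C70", "#5C5FA1", "#006EFF", "#FFAD00") %in% pc$hex))
  expect_true(any(grepl("synthetic", pc$provenance)))
})
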