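# Cardinal-spline smoothing and RSML round-trip.

test_that("cardinal splines reproduce straight lines and interpolate control points", {
  path <- cbind(seq(0, 100, by = 1), rep(20, 101))
  sc <- fit_spline(path, spacing = 20)
  expect_true(all(abs(sc$samples[, 2] - 20) < 1e-6))
  # noisy curved path: spline passes through every control point
  set.seed(2)
  t <- seq(0, 1, length.out = 80)
  path2 <- cbind(100 * t + rnorm(80, 0, 0.4), 50 * t^2 + rnorm(80, 0, 0.4))
  sc2 <- fit_spline(path2, spacing = 15, sample_spacing = 0.5)
  for (i in seq_len(nrow(sc2$control_points))) {
    d <- min(sqrt(rowSums(sweep(sc2$samples, 2,
                                sc2$control_points[i, ])^2)))
    expect_lt(d, 0.05)
  }
  expect_error(fit_spline(cbind(1, 1)), "degenerate")
})

test_that("spline smoothing does not increase deviation from a known centerline", {
  # staircase discretization of a straight line
  true_y <- function(x) 0.5 * x + 10
  x <- 0:80
  stair <- cbind(x, round(true_y(x)))
  sc <- fit_spline(stair, spacing = 12, sample_spacing = 1)
  dev_raw <- mean(abs(stair[, 2] - true_y(stair[, 1])))
  dev_spline <- mean(abs(sc$samples[, 2] - true_y(sc$samples[, 1])))
  expect_lte(dev_spline, dev_raw + 1e-9)
})

test_that("spline arc length stays within 2% of the polyline arc length", {
  # paths at the pipeline operating scale (the default control spacing is
  # chosen to resolve the geometry of paths at these resolutions)
  for (seed in c(4, 9)) {
    p <- architecture_params("fibrous", image_size = 512L, root_width = 8,
                             n_first_order = c(3L, 4L),
                             laterals_per_root = c(1L, 2L), rng_seed = seed)
    rs <- generate_architecture(p)
    for (rt in rs$plants[[1]]$roots) {
      sc <- fit_spline(rt$points, sample_spacing = 1)
      l_poly <- rootarch:::polyline_length(rt$points)
      l_spline <- rootarch:::polyline_length(sc$samples)
      expect_lt(abs(l_spline - l_poly) / l_poly, 0.02)
    }
  }
})

test_that("RSML write/read round trip preserves topology and geometry", {
  p <- tiny_taproot_params(seed = 8L, n_plants = 2L)
  rs <- generate_architecture(p)
  path <- tempfile(fileext = ".rsml")
  write_rsml(rs, path)
  back <- read_rsml(path)
  expect_length(back$plants, 2)
  for (i in 1:2) {
    o_ord <- sort(vapply(rs$plants[[i]]$roots, `[[`, integer(1), "order"))
    b_ord <- sort(vapply(back$plants[[i]]$roots, `[[`, integer(1), "order"))
    expect_equal(o_ord, b_ord)
    expect_equal(back$plants[[i]]$seed, rs$plants[[i]]$seed, tolerance = 1e-6)
  }
  # polylines identical to 1e-6 (match roots by order + first point)
  for (i in 1:2) {
    for (rt in rs$plants[[i]]$roots) {
      match_found <- any(vapply(back$plants[[i]]$roots, function(b)
        b$order == rt$order && nrow(b$points) == nrow(rt$points) &&
          max(abs(b$points - rt$points)) < 1e-6, logical(1)))
      expect_true(match_found)
    }
  }
})

test_that("laterals are nested under their parent root elements", {
  p <- tiny_taproot_params(seed = 2L, n_plants = 2L)
  rs <- generate_architecture(p)
  path <- tempfile(fileext = ".rsml")
  write_rsml(rs, path)
  doc <- xml2::read_xml(path)
  plants <- xml2::xml_find_all(doc, "./scene/plant")
  expect_length(plants, 2)
  for (i in 1:2) {
    top <- xml2::xml_find_all(plants[[i]], "./root")
    expect_length(top, 1)  # taproot: one first-order root
    kids <- xml2::xml_find_all(top[[1]], "./root")
    n2 <- sum(vapply(rs$plants[[i]]$roots, function(r) r$order == 2L,
                     logical(1)))
    expect_length(kids, n2)
    # spline annotation present alongside the polyline
    expect_gte(length(xml2::xml_find_all(
      top[[1]], "./annotations/annotation[@name='spline']/point")), 2)
  }
})

test_that("an empty system writes valid RSML with zero plants", {
  rs <- structure(list(plants = list(), image_size = c(64, 64),
                       style = "fibrous"), class = "root_system")
  path <- tempfile(fileext = ".rsml")
  write_rsml(rs, path)
  doc <- xml2::read_xml(path)
  expect_length(xml2::xml_find_all(doc, "./scene/plant"), 0)
  expect_length(read_rsml(path)$plants, 0)
})

test_that("a hand-written minimal RSML file parses to one 3-point root", {
  path <- system.file("extdata", "minimal_synthetic.rsml",
                      package = "rootarch")
  expect_true(nzchar(path))
  rs <- read_rsml(path)
  expect_length(rs$plants, 1)
  expect_length(rs$plants[[1]]$roots, 1)
  rt <- rs$plants[[1]]$roots[[1]]
  expect_equal(rt$order, 1L)
  expect_equal(nrow(rt$points), 3)
  expect_equal(rt$points[1, ], c(10, 5))
})

test_that("roots nested three levels deep are rejected", {
  txt <- paste0(
    "<rsml><metadata/><scene><plant id='1'>",
    "<root id='1'><geometry><polyline>",
    "<point x='0' y='0'/><point x='0' y='10'/></polyline></geometry>",
    "<root id='1.1'><geometry><polyline>",
    "<point x='0' y='5'/><point x='5' y='8'/></polyline></geometry>",
    "<root id='1.1.1'><geometry><polyline>",
    "<point x='2' y='6'/><point x='4' y='9'/></polyline></geometry></root>",
    "</root></root></plant></scene></rsml>")
  path <- tempfile(fileext = ".rsml")
  writeLines(txt, path)
  expect_error(read_rsml(path), "nested")
})

test_that("mask PNG export is binary, deterministic and count-preserving", {
  p <- tiny_fibrous_params(seed = 5L)
  rs <- generate_architecture(p)
  maps <- render_class_masks(rs, c(256, 256), stroke_width = 6)
  pre <- file.path(tempdir(), "masks_a")
  write_masks(maps, pre)
  m1 <- png::readPNG(paste0(pre, "_order1.png"))
  expect_true(all(m1 %in% c(0, 1)))
  expect_equal(sum(m1), sum(maps[, , 2]))
  pre2 <- file.path(tempdir(), "masks_b")
  write_masks(maps, pre2)
  expect_identical(readBin(paste0(pre, "_order1.png"), "raw", 1e6),
                   readBin(paste0(pre2, "_order1.png"), "raw", 1e6))
})
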