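test_that("LSCV criterion matches the double-loop oracle and is minimised", {
  withr::with_seed(2, {
    xy <- cbind(rnorm(60, 0, 10), rnorm(60, 0, 10))
    b <- lscv_bandwidth(xy)
    # closed-form criterion equals the O(n^2) oracle on a scan
    for (h in c(1, 3, 7)) {
      got <- b$trace$criterion[which.min(abs(b$trace$h - h))]
      expect_equal(oracle_lscv(xy, b$trace$h[which.min(abs(b$trace$h - h))]),
                   got, tolerance = 1e-10)
    }
    # minimiser property against the search endpoints
    ends <- range(b$trace$h)
    crit_at <- function(h) oracle_lscv(xy, h)
    expect_lte(crit_at(b$h), crit_at(ends[1]) + 1e-12)
    expect_lte(crit_at(b$h), crit_at(ends[2]) + 1e-12)
    # within a factor 2 of the reference bandwidth for Gaussian data
    expect_gt(b$h, b$h_ref / 2)
    expect_lt(b$h, b$h_ref * 2)
  })
})

test_that("LSCV bandwidth is scale-equivariant", {
  withr::with_seed(6, {
    xy <- cbind(rnorm(80, 0, 5), rnorm(80, 0, 5))
    h1 <- lscv_bandwidth(xy)$h
    h3 <- lscv_bandwidth(xy * 3)$h
    expect_lt(abs(h3 / h1 - 3) / 3, 0.02)
  })
  expect_error(lscv_bandwidth(cbind(rep(1, 20), rep(2, 20))), "distinct points")
})

test_that("kernel UD matches the naive double-loop oracle and conserves mass", {
  withr::with_seed(4, {
    xy <- cbind(rnorm(40, 0, 6), rnorm(40, 0, 6))
    ud <- kde_ud(xy, h = 2, cell_km = 2)
    expect_equal(sum(ud$z) * ud$cell_km^2, 1, tolerance = 1e-6)
    # un-normalised oracle comparison on the same grid (<= 1e-10)
    z0 <- oracle_kde(xy, 2, ud$x, ud$y)
    z0 <- z0 / (sum(z0) * ud$cell_km^2)
    expect_lt(max(abs(ud$z - z0)), 1e-10)
  })
})

test_that("degenerate and symmetric UDs behave as expected", {
  ud1 <- kde_ud(cbind(3.2, -1.7), h = 1, cell_km = 0.5)
  peak <- which(ud1$z == max(ud1$z), arr.ind = TRUE)
  expect_lt(abs(ud1$x[peak[1]] - 3.2), 0.5)
  expect_lt(abs(ud1$y[peak[2]] + 1.7), 0.5)
  expect_equal(sum(ud1$z) * 0.25, 1, tolerance = 1e-6)
  # two distant points, small h: two equal modes with half the mass each
  ud2 <- kde_ud(rbind(c(-20, 0), c(20, 0)), h = 1, cell_km = 1)
  left <- ud2$x < 0
  expect_equal(sum(ud2$z[left, ]) * 1, 0.5, tolerance = 0.01)
  expect_error(kde_ud(matrix(numeric(0), 0, 2), 1), "no points")
  expect_error(kde_ud(cbind(0, 0), h = 0), "positive")
})

test_that("probability contours have the right mass and are nested", {
  withr::with_seed(9, {
    xy <- cbind(rnorm(400, 0, 10), rnorm(400, 0, 10))
    ud <- kde_ud(xy, h = 3, cell_km = 1)
    pc95 <- probability_contour(ud, 95)
    expect_gte(pc95$mass, 0.95)
    expect_lte(pc95$mass, 0.96)
    pc50 <- probability_contour(ud, 50)
    # nesting: every 50% cell is also a 95% cell
    k50 <- paste(pc50$cells$x, pc50$cells$y)
    k95 <- paste(pc95$cells$x, pc95$cells$y)
    expect_true(all(k50 %in% k95))
    tbl <- probability_contours(ud, c(25, 50, 75, 95))
    expect_false(is.unsorted(tbl$area_km2))
    expect_false(is.unsorted(tbl$mass))
    # near-100% contour covers nearly the whole support
    pc_all <- probability_contour(ud, 99.9)
    expect_gt(pc_all$mass, 0.999)
    expect_error(probability_contour(ud, 0), "level")
  })
})

test_that("central points: identical points collapse, geometric <= arithmetic", {
  xy <- matrix(rep(c(5, 7), each = 20), ncol = 2)
  ud <- kde_ud(xy, h = 1, cell_km = 0.5)
  cp <- central_points(xy, ud)
  expect_equal(cp$x, c(5, 5), tolerance = 0.3)
  expect_equal(cp$y, c(7, 7), tolerance = 0.3)
  withr::with_seed(13, {
    pts <- cbind(runif(50, 1, 40), runif(50, 1, 40))
    # AM-GM on strictly positive coordinates
    expect_lte(exp(mean(log(pts[, 1]))), mean(pts[, 1]))
    ud2 <- kde_ud(pts, h = 4, cell_km = 1)
    cp2 <- central_points(pts, ud2)
    gm <- cp2[cp2$which == "geometric_mean", ]
    expect_lte(gm$x, mean(pts[, 1]) + 1e-9)
    expect_lte(gm$y, mean(pts[, 2]) + 1e-9)
  })
})

test_that("centre of mass of a symmetric UD sits at the centroid", {
  withr::with_seed(23, {
    xy <- cbind(rnorm(500, 10, 5), rnorm(500, -4, 5))
    ud <- kde_ud(xy, h = 2, cell_km = 1)
    cp <- central_points(xy, ud)
    com <- cp[cp$which == "center_of_mass", ]
    expect_lt(abs(com$x - 10), 1)
    expect_lt(abs(com$y + 4), 1)
  })
})

test_that("estuary polygon: square recovery, convex limit, offshore extent", {
  g <- as.matrix(expand.grid(x = seq(0, 10, 1), y = seq(0, 10, 1)))
  ep <- estuary_polygon(g, alpha_km = 3)
  expect_equal(ep$area_km2, 100, tolerance = 0.01)
  expect_equal(ep$method, "alpha")
  # alpha -> Inf reduces to the convex hull
  withr::with_seed(17, {
    pts <- cbind(runif(60, 0, 30), runif(60, 0, 60))
    epc <- estuary_polygon(pts, alpha_km = Inf)
    hull <- pts[grDevices::chull(pts), ]
    hull_area <- abs(sum(hull[, 1] * c(hull[-1, 2], hull[1, 2]) -
                           c(hull[-1, 1], hull[1, 1]) * hull[, 2])) / 2
    expect_equal(epc$area_km2, hull_area, tolerance = 1e-9)
    expect_equal(epc$method, "convex")
    expect_equal(epc$offshore_km, max(pts[, 2]))
  })
  expect_error(estuary_polygon(cbind(1:5, 2 * (1:5))), "collinear")
})

test_that("synthetic occupancy spanning the funnel reports ~60 km offshore", {
  withr::with_seed(27, {
    # occupancy filling the funnel fixture out to its 60 km extent
    y <- runif(400, 0, 60)
    x <- runif(400, -1, 1) * y * tan(35 * pi / 180) * 0.9
    ep <- estuary_polygon(cbind(x, y), alpha_km = 20)
    expect_lt(abs(ep$offshore_km - 60), 3)
  })
})
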