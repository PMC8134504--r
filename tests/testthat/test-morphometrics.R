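# morphometric readouts: boundary/area, extension, skeleton, tessellation

test_that("boundary area is exact for a filled square", {
  m <- matrix(FALSE, 120, 120); m[11:110, 11:110] <- TRUE
  ba <- tree_boundary_and_area(m, pixel_size_um = 10)
  expect_equal(ba$area_um2, 1e6, tolerance = 0.02)  # 1 mm^2
  # at shrink 1 the polygon area equals the pixel count exactly
  ba1 <- tree_boundary_and_area(m, 10, shrink_factor = 1)
  expect_equal(ba1$area_um2, sum(m) * 100)
})

test_that("a C-shaped mask keeps its concavity at the default shrink", {
  m <- matrix(FALSE, 120, 120)
  disk <- make_disk(c(120, 120), c(60, 60), 40) & !make_disk(c(120, 120), c(60, 60), 22)
  m <- disk
  m[45:75, 60:120] <- FALSE  # cut a wide opening: a C
  ba <- tree_boundary_and_area(m, 1)
  hull <- tree_boundary_and_area(m, 1, shrink_factor = 0)
  expect_lt(ba$area_um2, hull$area_um2)
  expect_equal(ba$area_um2, sum(m), tolerance = 0.05)
})

test_that("shrink 0 reproduces the convex hull on a convex disk", {
  m <- make_disk(c(120, 120), c(60, 60), 45)
  h <- tree_boundary_and_area(m, 1, shrink_factor = 0)
  t <- tree_boundary_and_area(m, 1, shrink_factor = 1)
  # half-pixel staircase corners make the hull a sliver wider than the
  # tight contour on a raster disk
  expect_equal(h$area_um2, t$area_um2, tolerance = 0.025)
  expect_error(tree_boundary_and_area(matrix(FALSE, 5, 5), 1), "empty")
  m2 <- matrix(FALSE, 5, 5); m2[2, 2] <- TRUE
  expect_error(tree_boundary_and_area(m2, 1), "at least 3")
})

test_that("ductal extension is the exhaustive vertex maximum", {
  b <- boundary_polygon(rbind(c(0, 0), c(3, 4), c(0, 4)), 1)
  e <- ductal_extension(b, c(0, 0), 1)
  expect_equal(e$extension_um, 5)              # the 3-4-5 triangle
  expect_equal(e$leading_edge_px, c(3, 4))
  # nipple on a circle: extension is the diameter
  th <- seq(0, 2 * pi, length.out = 400)[-400]
  circ <- cbind(50 + 40 * sin(th), 50 + 40 * cos(th))
  ec <- ductal_extension(boundary_polygon(circ, 1), circ[1, ], 2.5)
  expect_equal(ec$extension_um, 2 * 40 * 2.5, tolerance = 0.01)
  # random polygon: equals brute force, and scales with pixel size
  set.seed(31)
  poly <- cbind(runif(20, 0, 100), runif(20, 0, 100))
  bp <- boundary_polygon(poly, 1)
  nip <- c(3, 7)
  brute <- max(sqrt((poly[, 1] - nip[1])^2 + (poly[, 2] - nip[2])^2))
  expect_equal(ductal_extension(bp, nip, 1)$extension_um, brute)
  expect_equal(ductal_extension(bp, nip, 10.5)$extension_um, brute * 10.5)
})

test_that("extension is monotone under adding a farther vertex", {
  set.seed(8)
  poly <- cbind(runif(12, 0, 50), runif(12, 0, 50))
  nip <- c(0, 0)
  e1 <- ductal_extension(boundary_polygon(poly, 1), nip, 1)$extension_um
  e2 <- ductal_extension(boundary_polygon(rbind(poly, c(90, 90)), 1), nip,
                         1)$extension_um
  expect_gte(e2, e1)
})

test_that("skeleton analysis counts forks, not thinning artefacts", {
  # straight line: no branch points, two endpoints
  line <- matrix(FALSE, 40, 40); line[20, 5:35] <- TRUE
  skg <- skeleton_branch_analysis(line, prune_px = 0)
  expect_equal(nrow(skg$branchpoints_px), 0)
  expect_equal(nrow(skg$endpoints_px), 2)
  # Y: exactly one merged branch point
  y <- matrix(FALSE, 60, 60)
  y[30:55, 29:31] <- TRUE
  for (i in 0:20) { y[30 - i, (29:31) - i] <- TRUE; y[30 - i, (29:31) + i] <- TRUE }
  skg <- skeleton_branch_analysis(y)
  expect_equal(nrow(skg$branchpoints_px), 1)
  expect_error(skeleton_branch_analysis(matrix(FALSE, 4, 4)), "empty")
})

test_that("generator forks are recovered and exclusions remove them", {
  wm <- generate_wholemount(tree_gen_params(seed = 2, noise_sd = 0))
  skg <- skeleton_branch_analysis(wm$truth$tree_mask)
  expect_equal(nrow(skg$branchpoints_px), 7)
  # every truth fork has a recovered branch point nearby; the skeleton
  # junction sits up to (half duct width) / tan(half opening angle) beyond
  # the geometric fork centre, ~ 3 / tan(13.5 deg) ~ 13 px at the deepest,
  # narrowest forks
  for (i in seq_len(nrow(wm$truth$branchpoints_px))) {
    f <- wm$truth$branchpoints_px[i, ]
    d <- sqrt(min((skg$branchpoints_px[, 1] - f[1])^2 +
                  (skg$branchpoints_px[, 2] - f[2])^2))
    expect_lt(d, 16)
  }
  # excluding one merged branch point drops the count by one
  skg2 <- skeleton_branch_analysis(wm$truth$tree_mask,
                                   exclusions = skg$branchpoints_px[1, , drop = FALSE])
  expect_equal(nrow(skg2$branchpoints_px), 6)
})

test_that("Voronoi cells clipped to the boundary are exact", {
  square <- boundary_polygon(rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0)), 1)
  # one site: the whole polygon
  v1 <- dirichlet_areas(rbind(c(0.3, 0.4)), square, 1)
  expect_equal(v1$areas_um2, 1)
  expect_true(is.na(v1$cv))
  # two mirror-symmetric sites: equal halves
  v2 <- dirichlet_areas(rbind(c(0.5, 0.25), c(0.5, 0.75)), square, 1)
  expect_equal(v2$areas_um2, c(0.5, 0.5), tolerance = 1e-9)
  expect_error(dirichlet_areas(rbind(c(0.5, 0.5), c(0.5, 0.5)), square, 1),
               "duplicate")
  expect_error(dirichlet_areas(rbind(c(2, 2)), square, 1), "inside")
})

test_that("clipped Voronoi areas match the nearest-site grid oracle", {
  square <- boundary_polygon(rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0)), 1)
  set.seed(12)
  sites <- cbind(runif(5, 0.1, 0.9), runif(5, 0.1, 0.9))
  v <- dirichlet_areas(sites, square, 1)
  # 2000 x 2000 midpoint grid, assign each cell to its nearest site
  n <- 2000
  g <- (seq_len(n) - 0.5) / n
  counts <- integer(5)
  for (chunk in split(seq_len(n), ceiling(seq_len(n) / 250))) {
    R <- matrix(g[chunk], length(chunk), n)
    C <- matrix(g, length(chunk), n, byrow = TRUE)
    dbest <- matrix(Inf, length(chunk), n); ibest <- matrix(0L, length(chunk), n)
    for (s in 1:5) {
      d <- (R - sites[s, 1])^2 + (C - sites[s, 2])^2
      upd <- d < dbest
      dbest[upd] <- d[upd]; ibest[upd] <- s
    }
    counts <- counts + tabulate(ibest, 5)
  }
  oracle <- counts / n^2
  expect_equal(v$areas_um2, oracle, tolerance = 0.02)
  expect_equal(sum(v$areas_um2), 1, tolerance = 0.005)
  # each site lies inside its own cell
  for (s in 1:5) {
    inside <- mammoquant:::points_in_polygon(sites[s, , drop = FALSE],
                                             v$cells[[s]])
    expect_true(inside)
  }
})

test_that("Voronoi areas sum to the boundary area on real tree shapes", {
  wm <- generate_wholemount(tree_gen_params(seed = 3))
  seg <- tree_segmentation(wm$truth$tree_mask, wm$truth$nipple_px, 10.5)
  rec <- measure_gland(seg)
  expect_equal(sum(rec$voronoi_areas_um2[[1]]), rec$area_um2,
               tolerance = 0.005)
  expect_equal(rec$n_primary_branches, length(rec$voronoi_areas_um2[[1]]))
})

test_that("signed lymph-node distance follows the sign convention and is rigid", {
  b <- boundary_polygon(rbind(c(0, 0), c(0, 300), c(1, 150), c(1, 0)), 1)
  expect_equal(ln_signed_distance(c(0, 200), c(0, 0), b, 1), 100)
  b2 <- boundary_polygon(rbind(c(0, 0), c(0, 150), c(1, 75), c(1, 0)), 1)
  expect_equal(ln_signed_distance(c(0, 200), c(0, 0), b2, 1), -50)
  expect_null(ln_signed_distance(NULL, c(0, 0), b, 1))
  # rotation invariance at 37 degrees
  th <- 37 * pi / 180
  Rm <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  rot <- function(p) as.numeric(Rm %*% p)
  vr <- t(apply(b$vertices, 1, rot))
  d0 <- ln_signed_distance(c(0, 200), c(0, 0), b, 1)
  d1 <- ln_signed_distance(rot(c(0, 200)), rot(c(0, 0)),
                           boundary_polygon(vr, 1), 1)
  expect_equal(d1, d0, tolerance = 1e-6 * abs(d0))
})

test_that("measure_gland is deterministic and complete", {
  wm <- generate_wholemount(tree_gen_params(seed = 4, noise_sd = 0,
                                            ln_center_px = c(120, 340)))
  seg <- segment_tree(wm$image, wm$truth$nipple_px)
  r1 <- measure_gland(seg)
  r2 <- measure_gland(seg)
  expect_equal(r1, r2, ignore_attr = TRUE)
  # noiseless: extension and area within 2% of truth
  expect_lt(abs(r1$area_um2 / wm$truth$true_area_um2 - 1), 0.02)
  expect_lt(abs(r1$extension_um / wm$truth$true_extension_um - 1), 0.02)
  expect_false(is.na(r1$ln_signed_distance_um))
  # micrometre quantities scale with the pixel size
  seg2 <- seg; seg2$pixel_size_um <- 21
  r3 <- measure_gland(seg2)
  expect_equal(r3$area_um2 / r1$area_um2, 4)
  expect_equal(r3$extension_um / r1$extension_um, 2)
  expect_equal(r3$ln_signed_distance_um / r1$ln_signed_distance_um, 2)
})

test_that("a branchless duct yields an empty tessellation", {
  line <- matrix(FALSE, 60, 60); line[30, 5:55] <- TRUE; line[29, 5:55] <- TRUE
  seg <- tree_segmentation(line, c(30, 5), 10.5)
  rec <- measure_gland(seg)
  expect_equal(rec$n_primary_branches, 0)
  expect_length(rec$voronoi_areas_um2[[1]], 0)
  expect_true(is.na(rec$voronoi_cv))
  expect_true(is.na(rec$ln_signed_distance_um))
})
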