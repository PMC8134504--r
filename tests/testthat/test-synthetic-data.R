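# synthetic-data generators: determinism, truth consistency, calibration

test_that("whole-mount generation is deterministic and validates its inputs", {
  p <- tree_gen_params(seed = 4, n_bifurcations = 3)
  a <- generate_wholemount(p)
  b <- generate_wholemount(p)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth, b$truth)

  expect_error(tree_gen_params(tree_intensity = 200, stroma_intensity = 100),
               "strictly below")
  expect_error(tree_gen_params(ln_center_px = c(50, 50), ln_intensity = 100,
                               tree_intensity = 60), "strictly below")
  # a tree that cannot fit names the offending segment
  expect_error(generate_wholemount(
    tree_gen_params(image_size_px = c(64, 64), segment_length_px = 80)),
    "segment")
})

test_that("an unbranched tree is a single duct with no branch points", {
  wm <- generate_wholemount(tree_gen_params(n_bifurcations = 0, seed = 2))
  expect_null(wm$truth$branchpoints_px)
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(wm$truth$tree_mask * 1)))
  expect_equal(max(lab), 1)
})

test_that("true extension equals the exhaustive scan over all mask pixels", {
  wm <- generate_wholemount(tree_gen_params(seed = 9))
  t <- wm$truth
  pts <- which(t$tree_mask, arr.ind = TRUE)
  brute <- sqrt(max((pts[, 1] - t$nipple_px[1])^2 + (pts[, 2] - t$nipple_px[2])^2)) *
    wm$image$pixel_size_um
  expect_equal(t$true_extension_um, brute, tolerance = 1e-12)
  # truth area is the mask pixel count
  expect_equal(t$true_area_um2, sum(t$tree_mask) * wm$image$pixel_size_um^2)
  # recorded fork centres lie on the rendered tree
  bp <- round(t$branchpoints_px)
  expect_true(all(t$tree_mask[bp]))
})

test_that("whole-mount scenes round-trip through TIFF + JSON", {
  dir <- withr::local_tempdir()
  wm <- generate_wholemount(tree_gen_params(seed = 3, n_bifurcations = 1))
  write_wholemount(wm, dir)
  img <- read_raster_tiff(file.path(dir, "wholemount.tif"),
                          wm$image$pixel_size_um)
  expect_equal(img$pixels, wm$image$pixels, ignore_attr = TRUE)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_equal(truth$true_area_um2, wm$truth$true_area_um2)
})

test_that("cyst time-lapse truth follows the inclusive lifetime convention", {
  tl <- generate_cyst_timelapse(cyst_gen_params(
    protrusion_specs = list(list(length_px = 25, width_px = 8,
                                 birth_frame = 2, death_frame = 6)),
    n_frames = 10, frame_interval_h = 0.5, seed = 1))
  expect_equal(tl$truth$lifetime_h, 2.5)
  present <- vapply(tl$frames, function(f) length(f$protrusion_masks) > 0, logical(1))
  expect_equal(which(present) - 1L, 2:6)

  expect_error(cyst_gen_params(n_frames = 0), "n_frames")
  expect_error(cyst_gen_params(protrusion_specs = list(
    list(length_px = 10, width_px = 4, birth_frame = 3, death_frame = 1))),
    "birth_frame")
})

test_that("compartment intensities follow the configured ratio", {
  # ratio 1, no noise: protrusion mean equals body mean exactly
  tl0 <- generate_cyst_timelapse(cyst_gen_params(compartment_ratio = 1,
                                                 noise_sd = 0, seed = 1))
  sc <- tl0$frames[[1]]
  expect_equal(mean(sc$channels$signal[sc$protrusion_masks[[1]]]),
               mean(sc$channels$signal[sc$body_mask]))
  # ratio 1.8 with noise 0.05 x base: empirical ratio within +/- 0.05
  tl <- generate_cyst_timelapse(cyst_gen_params(compartment_ratio = 1.8,
                                                noise_sd = 5, seed = 7))
  sc <- tl$frames[[1]]
  r <- mean(sc$channels$signal[sc$protrusion_masks[[1]]]) /
    mean(sc$channels$signal[sc$body_mask])
  expect_lt(abs(r - 1.8), 0.05)
  # determinism
  tl2 <- generate_cyst_timelapse(cyst_gen_params(compartment_ratio = 1.8,
                                                 noise_sd = 5, seed = 7))
  expect_identical(tl$frames[[1]]$channels$signal, tl2$frames[[1]]$channels$signal)
})

test_that("abundance generator controls zeros, effects and validation", {
  g0 <- generate_abundance_matrix(abundance_gen_params(n_proteins = 200,
                                                       dropout_prob = 0, seed = 1))
  expect_false(any(g0$matrix$values == 0))
  g <- generate_abundance_matrix(abundance_gen_params(n_proteins = 200,
                                                      dropout_prob = 0.1, seed = 1))
  expect_true(any(g$matrix$values == 0))
  expect_identical(g$matrix$original_zero, g$matrix$values == 0)
  expect_true(all(g$matrix$values[!g$matrix$original_zero] > 0))

  expect_error(abundance_gen_params(dropout_prob = 1), "dropout_prob")
  expect_error(abundance_gen_params(
    groups = list(c("a", 5), c("b", 1)),
    planted_effects = list(list(1, c("a", "b"), 2))), "fewer than 2")
  expect_error(abundance_gen_params(
    planted_effects = list(list(1, c("wt4wk", "wt5wk"), -2))), "fold_change")
})

test_that("null matrices give uniform Welch p-values", {
  g <- generate_abundance_matrix(abundance_gen_params(
    n_proteins = 2000, groups = list(c("a", 5), c("b", 5)),
    dropout_prob = 0, seed = 11))
  d <- differential(impute_zeros(g$matrix), "a", "b")
  expect_gt(stats::ks.test(d$p_value, "punif")$p.value, 0.01)
})

test_that("planted 4-fold effects are recovered as log2 ratios near 2", {
  l2 <- vapply(1:200, function(s) {
    g <- generate_abundance_matrix(abundance_gen_params(
      n_proteins = 40, groups = list(c("a", 5), c("b", 5)), dropout_prob = 0,
      planted_effects = list(list(7, c("a", "b"), 4)), seed = s))
    d <- differential(impute_zeros(g$matrix), "b", "a")
    d$log2_ratio[d$protein_id == "protein_0007"]
  }, numeric(1))
  expect_lt(abs(mean(l2) - 2), 0.1)
})

test_that("abundance matrices round-trip through TSV + group JSON", {
  dir <- withr::local_tempdir()
  g <- generate_abundance_matrix(abundance_gen_params(n_proteins = 25, seed = 5))
  path <- file.path(dir, "abund.tsv")
  write_abundance_tsv(g$matrix, path)
  m2 <- read_abundance_tsv(path)
  expect_equal(m2$values, g$matrix$values, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(m2$group_labels, g$matrix$group_labels)
})
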