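#' Segmentation configuration for whole-mount scans
#'
#' Tunable parameters of the fixed preprocessing chain. Gamma 0.45 is the
#' conventional contrast aid for carmine whole mounts; the background is
#' estimated with a wide Gaussian (SD 20 px at 10.5 um/px, i.e. ~200 um,
#' much wider than a duct) and subtracted. CLAHE tile and clip defaults are
#' chosen for the ~10.5 um/px whole-mount scale. The cleanup stage
#' (closing, small-object removal, nipple-component selection) is a
#' reproducible stand-in for ad-hoc manual mask editing.
#'
#' @param gamma gamma exponent in (0, 1]; applied to the PCA grayscale
#'   (set to 1 to disable).
#' @param clahe_clip CLAHE clip limit.
#' @param clahe_tile_px CLAHE tile edge in pixels.
#' @param background_sigma_px SD of the Gaussian background estimate.
#' @param min_object_px connected components smaller than this are removed.
#' @param closing_radius_px radius of the morphological closing disk.
#' @return A `segmentation_config` list.
#' @export
segmentation_config <- function(gamma = 0.45, clahe_clip = 2.0,
                                clahe_tile_px = 64L, background_sigma_px = 20,
                                min_object_px = 64L, closing_radius_px = 2L) {
  stopifnot_scalar_num(gamma, "gamma", positive = TRUE)
  if (gamma > 1) abort("`gamma` must be in (0, 1]")
  stopifnot_scalar_num(clahe_clip, "clahe_clip", positive = TRUE)
  stopifnot_scalar_num(background_sigma_px, "background_sigma_px", positive = TRUE)
  structure(list(gamma = gamma, clahe_clip = clahe_clip,
                 clahe_tile_px = as.integer(clahe_tile_px),
                 background_sigma_px = background_sigma_px,
                 min_object_px = as.integer(min_object_px),
                 closing_radius_px = as.integer(closing_radius_px)),
            class = "segmentation_config")
}

#' PCA grayscale conversion
#'
#' Projects mean-centred RGB pixels onto the first principal component of
#' the pixel-wise 3x3 RGB covariance — the maximum-variance grey axis of the
#' stain. The component sign is oriented so the projection correlates
#' positively with Rec.709 luminance (0.2126 R + 0.7152 G + 0.0722 B), so
#' dark carmine epithelium stays dark; the result is min-max rescaled to
#' [0, 1]. Because centring, projection and rescaling compose to an affine
#' map followed by normalization, the output is invariant to positive
#' affine transforms of the input channels.
#'
#' @param img an RGB [raster_image()].
#' @return A scalar [raster_image()] with values in [0, 1].
#' @export
pca_grayscale <- function(img) {
  if (!is_rgb(img)) abort("`img` must be an RGB raster_image")
  d <- dim(img$pixels)
  X <- matrix(img$pixels, d[1] * d[2], 3L)
  cv <- stats::cov(X)
  if (all(abs(cv) < .Machine$double.eps * 100))
    abort("degenerate input: constant image has no principal component")
  e <- eigen(cv, symmetric = TRUE)
  v <- e$vectors[, 1]
  score <- as.vector(scale(X, center = TRUE, scale = FALSE) %*% v)
  lum <- X %*% c(0.2126, 0.7152, 0.0722)
  if (stats::sd(lum) > 0) {
    r <- stats::cor(score, lum)
    if (!is.na(r) && r < 0) score <- -score
  }
  rng <- range(score)
  if (diff(rng) == 0) abort("degenerate input: projection is constant")
  score <- (score - rng[1]) / diff(rng)
  raster_image(matrix(score, d[1], d[2]), img$pixel_size_um)
}

# reflective padding of a matrix by `pad` pixels on each side
pad_reflect <- function(m, pad) {
  n <- nrow(m); c <- ncol(m)
  ri <- c(rev(seq_len(min(pad, n))), seq_len(n), n + 1 - rev(seq_len(min(pad, n))))
  ci <- c(rev(seq_len(min(pad, c))), seq_len(c), c + 1 - rev(seq_len(min(pad, c))))
  m[ri, ci]
}

gaussian_blur <- function(m, sigma) {
  pad <- ceiling(3 * sigma) + 1L
  big <- pad_reflect(m, pad)
  bl <- EBImage::imageData(EBImage::gblur(EBImage::Image(big), sigma))
  bl[(pad + 1):(pad + nrow(m)), (pad + 1):(pad + ncol(m))]
}

#' Wide-Gaussian background subtraction
#'
#' Estimates the smooth background of a scalar image as a Gaussian blur
#' (reflective boundary handling) and subtracts it. With a sigma much wider
#' than the structures of interest this flattens illumination and staining
#' gradients while leaving thin ducts intact. Not idempotent: applying it
#' twice keeps removing low-frequency content.
#'
#' @param img scalar [raster_image()] (or bare matrix).
#' @param sigma_px Gaussian SD in pixels (> 0).
#' @return Same type as `img`, the background-subtracted image (may contain
#'   negative values).
#' @export
subtract_background <- function(img, sigma_px) {
  stopifnot_scalar_num(sigma_px, "sigma_px", positive = TRUE)
  m <- if (inherits(img, "raster_image")) img$pixels else img
  if (!is.matrix(m)) abort("`img` must be a scalar image")
  out <- m - gaussian_blur(m, sigma_px)
  if (inherits(img, "raster_image")) raster_image(out, img$pixel_size_um) else out
}

#' Otsu threshold of an intensity histogram
#'
#' Returns the cut maximizing the between-class variance; ties are broken by
#' the lowest qualifying threshold. The threshold `t` separates bins
#' `1..t` (lower class) from `t+1..L` (upper class) and is reported as the
#' upper edge value of bin `t` on the `bin_values` scale.
#'
#' @param counts histogram counts (one per bin).
#' @param bin_values value associated with each bin; default `0:(L-1)`.
#' @return The threshold, a value from `bin_values`.
#' @export
otsu_threshold <- function(counts, bin_values = seq_along(counts) - 1) {
  if (length(counts) != length(bin_values))
    abort("`counts` and `bin_values` must have the same length")
  nz <- counts > 0
  if (sum(nz) < 2L) abort("degenerate histogram: need at least 2 nonempty bins")
  w <- counts / sum(counts)
  mu <- cumsum(w * bin_values)
  om <- cumsum(w)
  mu_t <- mu[length(mu)]
  L <- length(counts)
  t_idx <- seq_len(L - 1L)
  valid <- om[t_idx] > 0 & om[t_idx] < 1
  sb <- rep(-Inf, L - 1L)
  sb[valid] <- (mu_t * om[t_idx][valid] - mu[t_idx][valid])^2 /
    (om[t_idx][valid] * (1 - om[t_idx][valid]))
  best <- which(sb == max(sb))[1]
  bin_values[best]
}

#' Multilevel Otsu thresholds by dynamic programming
#'
#' Optimal partition of a histogram into `k` classes minimizing the total
#' within-class weighted variance (equivalently maximizing between-class
#' variance), found exactly by dynamic programming over bin prefix sums.
#'
#' @param counts histogram counts.
#' @param k number of classes (>= 2).
#' @param bin_values value per bin.
#' @return `k - 1` thresholds (upper edges of the lower `k - 1` classes).
#' @export
otsu_multilevel <- function(counts, k, bin_values = seq_along(counts) - 1) {
  L <- length(counts)
  if (sum(counts > 0) < k) abort("histogram has fewer nonempty bins than classes")
  w <- counts / sum(counts)
  cw <- c(0, cumsum(w))
  cwx <- c(0, cumsum(w * bin_values))
  cwx2 <- c(0, cumsum(w * bin_values^2))
  # sse[i, j]: within-class weighted SSE of bins i..j
  sse <- function(i, j) {
    ww <- cw[j + 1] - cw[i]
    if (ww <= 0) return(0)
    sx <- cwx[j + 1] - cwx[i]
    (cwx2[j + 1] - cwx2[i]) - sx^2 / ww
  }
  # D[c, j]: best SSE of bins 1..j split into c classes; A: argmin last cut
  D <- matrix(Inf, k, L)
  A <- matrix(0L, k, L)
  for (j in 1:L) D[1, j] <- sse(1, j)
  for (cl in 2:k) {
    for (j in cl:L) {
      best <- Inf; arg <- 0L
      for (t in (cl - 1):(j - 1)) {
        v <- D[cl - 1, t] + sse(t + 1, j)
        if (v < best - 1e-15) { best <- v; arg <- t }
      }
      D[cl, j] <- best; A[cl, j] <- arg
    }
  }
  cuts <- integer(k - 1)
  j <- L
  for (cl in k:2) { cuts[cl - 1] <- A[cl, j]; j <- A[cl, j] }
  bin_values[cuts]
}

# 256-bin histogram of a [0,1]-rescaled image; returns counts and bin values
# on the original intensity scale
image_histogram <- function(m, bins = 256L) {
  rng <- range(m)
  if (diff(rng) == 0) return(list(counts = c(length(m)), values = rng[1]))
  idx <- pmin(bins - 1L, floor((m - rng[1]) / diff(rng) * bins))
  counts <- tabulate(idx + 1L, nbins = bins)
  values <- rng[1] + (seq_len(bins) - 0.5) / bins * diff(rng)
  list(counts = counts, values = values)
}

#' Tree segmentation result
#'
#' @param tree_mask logical matrix covering the epithelial tree.
#' @param nipple_px (row, col) of the tree origin, snapped to the mask.
#' @param pixel_size_um physical pixel size.
#' @param ln_mask,ln_centroid_px lymph-node mask and centroid, or `NULL`.
#' @export
tree_segmentation <- function(tree_mask, nipple_px, pixel_size_um,
                              ln_mask = NULL, ln_centroid_px = NULL) {
  stopifnot(is.matrix(tree_mask))
  if (!is.null(ln_mask) && any(ln_mask & tree_mask))
    abort("lymph-node mask must be disjoint from the tree mask")
  structure(list(tree_mask = tree_mask, nipple_px = as_point(nipple_px, "nipple_px"),
                 pixel_size_um = pixel_size_um, ln_mask = ln_mask,
                 ln_centroid_px = as_point(ln_centroid_px, "ln_centroid_px")),
            class = "tree_segmentation")
}

#' Segment the epithelial tree from an RGB whole-mount scan
#'
#' The fixed chain: PCA grayscale, gamma adjustment, CLAHE contrast
#' enhancement, wide-Gaussian background subtraction, Otsu binarization
#' (the darker class after PCA luminance orientation is the carmine-stained
#' epithelium), morphological closing, small-object removal, and selection
#' of the connected component nearest the user-supplied nipple. The nipple
#' is a required input — the tree origin is visually determined on the
#' scan, not auto-detected.
#'
#' @param img RGB [raster_image()].
#' @param nipple_px (row, col) of the tree origin; must lie in the image.
#' @param cfg a [segmentation_config()].
#' @param find_ln also attempt lymph-node segmentation (default TRUE).
#' @param ln_expected_area_px,ln_area_tol_px expected lymph-node size and
#'   tolerance, forwarded to [segment_lymph_node()].
#' @return A [tree_segmentation()].
#' @export
segment_tree <- function(img, nipple_px, cfg = segmentation_config(),
                         find_ln = TRUE,
                         ln_expected_area_px = NULL, ln_area_tol_px = NULL) {
  if (!is_rgb(img)) abort("`img` must be an RGB raster_image")
  nipple_px <- as_point(nipple_px, "nipple_px")
  d <- dim(img$pixels)
  if (nipple_px[1] < 1 || nipple_px[1] > d[1] || nipple_px[2] < 1 || nipple_px[2] > d[2])
    abort("`nipple_px` must lie inside the image")

  g <- pca_grayscale(img)$pixels
  gg <- g^cfg$gamma
  nx <- max(2L, ceiling(nrow(gg) / cfg$clahe_tile_px))
  ny <- max(2L, ceiling(ncol(gg) / cfg$clahe_tile_px))
  ce <- EBImage::imageData(EBImage::clahe(EBImage::Image(gg), nx = nx, ny = ny,
                                          limit = cfg$clahe_clip))
  sub <- ce - gaussian_blur(ce, cfg$background_sigma_px)

  h <- image_histogram(sub)
  if (length(h$counts) < 2L) abort("no foreground: image is constant after preprocessing")
  thr <- otsu_threshold(h$counts, h$values)
  fg <- sub <= thr  # epithelium is the dark class after luminance orientation

  if (cfg$closing_radius_px > 0) {
    brush <- EBImage::makeBrush(2L * cfg$closing_radius_px + 1L, "disc")
    fg <- EBImage::imageData(EBImage::closing(EBImage::Image(fg * 1), brush)) > 0.5
  }
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(fg * 1)))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= cfg$min_object_px)
  if (length(keep) == 0L) abort("no foreground: every component was below `min_object_px`")
  # component nearest the nipple
  best <- NULL; bestd <- Inf
  for (k in keep) {
    pts <- mask_coords(lab == k)
    dk <- min(dist2_to(pts, nipple_px))
    if (dk < bestd) { bestd <- dk; best <- k }
  }
  tree_mask <- lab == best
  pts <- mask_coords(tree_mask)
  nip <- pts[which.min(dist2_to(pts, nipple_px)), ]

  ln <- if (find_ln)
    segment_lymph_node(raster_image(g, img$pixel_size_um), tree_mask,
                       expected_area_px = ln_expected_area_px,
                       area_tol_px = ln_area_tol_px)
  else NULL
  tree_segmentation(tree_mask, as.numeric(nip), img$pixel_size_um,
                    ln_mask = ln$ln_mask, ln_centroid_px = ln$ln_centroid_px)
}

#' Segment the lymph node as the darkest compact blob
#'
#' The lymph node is typically the darkest feature of a whole mount. The
#' search loops over multilevel Otsu partitions with k = 2..6 classes; for
#' each k the connected components of the darkest class lying outside the
#' tree mask are scored by `solidity * exp(-(area - expected)^2 / (2 tol^2))`
#' — compactness weighted by closeness to the expected size. The first
#' component whose score exceeds `accept_score` is returned; otherwise the
#' best-scoring candidate overall; otherwise the node is reported absent
#' (a valid outcome, e.g. when the node is outside the scan).
#'
#' @param img scalar [raster_image()] — the PCA grayscale image.
#' @param tree_mask logical matrix of the segmented tree.
#' @param expected_area_px expected node area; default `pi * 28^2`.
#' @param area_tol_px SD of the size weighting; default `expected / 2`.
#' @param accept_score early-accept score threshold.
#' @param min_area_px candidates smaller than this are ignored.
#' @return List with `ln_mask` and `ln_centroid_px`, or `NULL` when absent.
#' @export
segment_lymph_node <- function(img, tree_mask, expected_area_px = NULL,
                               area_tol_px = NULL, accept_score = 0.5,
                               min_area_px = 25L) {
  m <- if (inherits(img, "raster_image")) img$pixels else img
  if (is.null(expected_area_px)) expected_area_px <- pi * 28^2
  if (is.null(area_tol_px)) area_tol_px <- expected_area_px / 2
  h <- image_histogram(m)
  if (length(h$counts) < 2L) return(NULL)
  best <- NULL; best_score <- 0
  for (k in 2:6) {
    if (sum(h$counts > 0) < k) break
    th <- tryCatch(otsu_multilevel(h$counts, k, h$values), error = function(e) NULL)
    if (is.null(th)) next
    dark <- (m <= th[1]) & !tree_mask
    if (!any(dark)) next
    lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(dark * 1)))
    sizes <- tabulate(lab[lab > 0])
    for (cc in which(sizes >= min_area_px)) {
      pts <- mask_coords(lab == cc)
      sol <- component_solidity(pts)
      score <- sol * exp(-(nrow(pts) - expected_area_px)^2 / (2 * area_tol_px^2))
      if (score > best_score) {
        best_score <- score
        best <- list(ln_mask = lab == cc,
                     ln_centroid_px = c(mean(pts[, 1]), mean(pts[, 2])),
                     score = score, k = k)
      }
      if (score > accept_score)
        return(best)
    }
  }
  if (!is.null(best) && best_score > 1e-4) best else NULL
}

# pixel count over convex-hull area (with half-boundary correction)
component_solidity <- function(pts) {
  if (nrow(pts) < 3L) return(1)
  hull <- grDevices::chull(pts[, 2], pts[, 1])
  hv <- pts[hull, , drop = FALSE]
  a <- polygon_area(hv)
  if (a <= 0) return(1)
  # hull through pixel centres: add ~perimeter/2 to approximate pixel support
  per <- sum(sqrt(rowSums((hv - hv[c(2:nrow(hv), 1), , drop = FALSE])^2)))
  min(1, nrow(pts) / (a + per / 2 + 1))
}

#' Write segmentation outputs (mask TIFF + metadata JSON)
#' @param seg a [tree_segmentation()].
#' @param dir output directory.
#' @param cfg the [segmentation_config()] used (echoed into the JSON).
#' @export
write_segmentation <- function(seg, dir, cfg = segmentation_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mask_tiff(seg$tree_mask, file.path(dir, "tree_mask.tif"), seg$pixel_size_um)
  if (!is.null(seg$ln_mask))
    write_mask_tiff(seg$ln_mask, file.path(dir, "ln_mask.tif"), seg$pixel_size_um)
  meta <- list(nipple_px = seg$nipple_px, pixel_size_um = seg$pixel_size_um,
               ln_centroid_px = seg$ln_centroid_px, config = unclass(cfg))
  jsonlite::write_json(meta, file.path(dir, "segmentation.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
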