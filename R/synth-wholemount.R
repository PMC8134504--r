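#' Parameters for the synthetic whole-mount generator
#'
#' Describes a carmine-stained whole-mount-like scene: a dark bifurcating
#' epithelial tree growing from a nipple origin across a lighter, noisy
#' stromal background, optionally with one darker lymph-node blob. The
#' defaults emulate a pubertal gland scanned at 2400 dpi (10.5 um pixels):
#' the epithelium is the dark feature, the lymph node darker still.
#'
#' @param image_size_px integer (rows, cols) canvas size.
#' @param pixel_size_um physical pixel size in micrometres.
#' @param nipple_px (row, col) of the tree origin; default left-centre.
#' @param n_bifurcations total number of bifurcation events (fork points).
#' @param segment_length_px mean length of one duct segment between forks.
#' @param branch_angle_deg full opening angle between sister branches at the
#'   first fork.
#' @param angle_decay multiplicative shrinkage of the opening angle per
#'   bifurcation generation. The decaying fan keeps subtrees from growing
#'   into each other, so the rendered tree stays free of self-overlap and
#'   the recorded fork centres remain exact ground truth.
#' @param duct_width_px rendered duct thickness.
#' @param tree_intensity,stroma_intensity,ln_intensity 8-bit grey levels;
#'   the tree must be darker than the stroma and the lymph node darker than
#'   the tree when present.
#' @param noise_sd standard deviation of additive Gaussian pixel noise
#'   (applied per channel, then clipped to 0-255).
#' @param ln_center_px (row, col) lymph-node centre, or `NULL` for no node.
#' @param ln_radius_px lymph-node radius.
#' @param seed RNG seed; generation is bit-reproducible given the seed.
#' @return A validated `tree_gen_params` list.
#' @export
tree_gen_params <- function(image_size_px = c(448L, 448L),
                            pixel_size_um = 10.5,
                            nipple_px = NULL,
                            n_bifurcations = 7L,
                            segment_length_px = 55,
                            branch_angle_deg = 55,
                            angle_decay = 0.7,
                            duct_width_px = 6,
                            tree_intensity = 60,
                            stroma_intensity = 200,
                            noise_sd = 10,
                            ln_center_px = NULL,
                            ln_radius_px = 28,
                            ln_intensity = 30,
                            seed = 1L) {
  image_size_px <- as.integer(image_size_px)
  if (length(image_size_px) != 2L || any(image_size_px < 32L))
    abort("`image_size_px` must be two integers >= 32")
  if (is.null(nipple_px)) nipple_px <- c(round(image_size_px[1] / 2), 24)
  nipple_px <- as_point(nipple_px, "nipple_px")
  stopifnot_scalar_num(pixel_size_um, "pixel_size_um", positive = TRUE)
  stopifnot_scalar_num(segment_length_px, "segment_length_px", positive = TRUE)
  stopifnot_scalar_num(duct_width_px, "duct_width_px", positive = TRUE)
  stopifnot_scalar_num(noise_sd, "noise_sd", nonneg = TRUE)
  n_bifurcations <- as.integer(n_bifurcations)
  if (n_bifurcations < 0L) abort("`n_bifurcations` must be >= 0")
  if (!(tree_intensity < stroma_intensity))
    abort("`tree_intensity` must be strictly below `stroma_intensity`")
  ln_center_px <- as_point(ln_center_px, "ln_center_px")
  if (!is.null(ln_center_px) && !(ln_intensity < tree_intensity))
    abort("`ln_intensity` must be strictly below `tree_intensity` when a lymph node is drawn")
  structure(list(image_size_px = image_size_px, pixel_size_um = pixel_size_um,
                 nipple_px = nipple_px, n_bifurcations = n_bifurcations,
                 segment_length_px = segment_length_px,
                 branch_angle_deg = branch_angle_deg,
                 angle_decay = angle_decay,
                 duct_width_px = duct_width_px, tree_intensity = tree_intensity,
                 stroma_intensity = stroma_intensity, noise_sd = noise_sd,
                 ln_center_px = ln_center_px, ln_radius_px = ln_radius_px,
                 ln_intensity = ln_intensity, seed = as.integer(seed)),
            class = "tree_gen_params")
}

# stamp a thick line segment (capsule) into a logical mask
stamp_segment <- function(mask, p0, p1, half_width) {
  rmin <- max(1L, floor(min(p0[1], p1[1]) - half_width - 1))
  rmax <- min(nrow(mask), ceiling(max(p0[1], p1[1]) + half_width + 1))
  cmin <- max(1L, floor(min(p0[2], p1[2]) - half_width - 1))
  cmax <- min(ncol(mask), ceiling(max(p0[2], p1[2]) + half_width + 1))
  rr <- rmin:rmax; cc <- cmin:cmax
  R <- matrix(rr, length(rr), length(cc))
  C <- matrix(cc, length(rr), length(cc), byrow = TRUE)
  d <- p1 - p0
  len2 <- sum(d^2)
  if (len2 == 0) {
    dist2 <- (R - p0[1])^2 + (C - p0[2])^2
  } else {
    t <- pmin(1, pmax(0, ((R - p0[1]) * d[1] + (C - p0[2]) * d[2]) / len2))
    dist2 <- (R - (p0[1] + t * d[1]))^2 + (C - (p0[2] + t * d[2]))^2
  }
  mask[rr, cc] <- mask[rr, cc] | (dist2 <= half_width^2)
  mask
}

disk_mask <- function(dim, center, radius) {
  R <- matrix(seq_len(dim[1]), dim[1], dim[2])
  C <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  (R - center[1])^2 + (C - center[2])^2 <= radius^2
}

#' Generate a synthetic whole-mount scene with exact ground truth
#'
#' Grows a bifurcating epithelial tree by a recursive random walk with
#' jittered branch angles, renders it as a dark structure on a lighter noisy
#' stroma (plus an optional darker lymph-node disk), and returns both the
#' RGB image and a ground-truth record measured on the rendered mask itself:
#' the binary tree mask, the recorded fork centres, the tree area
#' (mask pixel count x pixel area) and the ductal extension (largest
#' Euclidean distance from the nipple to a mask boundary pixel).
#'
#' Generation is deterministic for a given seed. If any duct segment would
#' leave the canvas, generation fails naming the offending segment.
#'
#' @param params a [tree_gen_params()] object.
#' @return A list with elements `image` (a [raster_image()], RGB, 0-255) and
#'   `truth` (list: `tree_mask`, `branchpoints_px`, `nipple_px`,
#'   `ln_centroid_px`, `true_area_um2`, `true_extension_um`).
#' @examples
#' wm <- generate_wholemount(tree_gen_params(n_bifurcations = 3, seed = 7))
#' wm$truth$true_area_um2
#' @export
generate_wholemount <- function(params) {
  stopifnot(inherits(params, "tree_gen_params"))
  p <- params
  with_seed(p$seed, {
    dimpx <- p$image_size_px
    mask <- matrix(FALSE, dimpx[1], dimpx[2])
    half_w <- p$duct_width_px / 2
    # initial direction: from the nipple towards the canvas centre
    ctr <- c(dimpx[1] / 2, dimpx[2] / 2)
    dir0 <- ctr - p$nipple_px
    if (all(dir0 == 0)) dir0 <- c(0, 1)
    ang0 <- atan2(dir0[1], dir0[2])

    segs <- list()
    grow <- function(from, angle) {
      len <- p$segment_length_px * stats::runif(1, 0.85, 1.15)
      to <- from + len * c(sin(angle), cos(angle))
      segs[[length(segs) + 1L]] <<- list(p0 = from, p1 = to)
      i <- length(segs)
      margin <- half_w + 1
      if (to[1] < 1 + margin || to[1] > dimpx[1] - margin ||
          to[2] < 1 + margin || to[2] > dimpx[2] - margin)
        abort(sprintf("generated tree exceeds canvas at segment %d (tip %.1f, %.1f)",
                      i, to[1], to[2]))
      list(pos = to, angle = angle)
    }

    # trunk, then breadth-first forking until the bifurcation budget is spent
    tip0 <- grow(p$nipple_px, ang0)
    tip0$depth <- 0L
    tips <- list(tip0)
    branchpoints <- NULL
    forks_done <- 0L
    half_open0 <- p$branch_angle_deg / 2 * pi / 180
    while (forks_done < p$n_bifurcations) {
      tip <- tips[[1L]]
      tips <- tips[-1L]
      branchpoints <- rbind(branchpoints, tip$pos)
      half_open <- half_open0 * p$angle_decay^tip$depth
      jit <- stats::runif(2, -0.12, 0.12) * half_open
      kids <- list(grow(tip$pos, tip$angle - half_open + jit[1]),
                   grow(tip$pos, tip$angle + half_open + jit[2]))
      for (k in seq_along(kids)) kids[[k]]$depth <- tip$depth + 1L
      tips <- c(tips, kids)
      forks_done <- forks_done + 1L
    }

    for (s in segs) mask <- stamp_segment(mask, s$p0, s$p1, half_w)

    # render: stroma base, lymph-node disk, tree on top, per-channel noise
    base <- matrix(p$stroma_intensity, dimpx[1], dimpx[2])
    ln_mask <- NULL; ln_centroid <- NULL
    if (!is.null(p$ln_center_px)) {
      ln_mask <- disk_mask(dimpx, p$ln_center_px, p$ln_radius_px)
      base[ln_mask] <- p$ln_intensity
      lnc <- mask_coords(ln_mask & !mask)
      ln_centroid <- c(mean(lnc[, 1]), mean(lnc[, 2]))
    }
    base[mask] <- p$tree_intensity
    # carmine-like channel weighting: epithelium dark red on a pink stroma
    wts <- c(1.00, 0.82, 0.90)
    px <- array(0, c(dimpx[1], dimpx[2], 3L))
    for (ch in 1:3) {
      layer <- base * wts[ch]
      if (p$noise_sd > 0)
        layer <- layer + matrix(stats::rnorm(length(base), 0, p$noise_sd),
                                dimpx[1], dimpx[2])
      px[, , ch] <- round(pmin(255, pmax(0, layer)))
    }

    truth <- list(
      tree_mask = mask,
      branchpoints_px = branchpoints,
      nipple_px = p$nipple_px,
      ln_centroid_px = ln_centroid,
      true_area_um2 = sum(mask) * p$pixel_size_um^2,
      true_extension_um = mask_extension_um(mask, p$nipple_px, p$pixel_size_um)
    )
    list(image = raster_image(px, p$pixel_size_um), truth = truth)
  })
}

# largest Euclidean distance from the nipple to a boundary pixel of the mask
mask_extension_um <- function(mask, nipple_px, pixel_size_um) {
  b <- boundary_pixels(mask)
  if (nrow(b) == 0L) return(0)
  sqrt(max(dist2_to(b, nipple_px))) * pixel_size_um
}

# mask pixels with at least one 4-neighbour outside the mask (or image edge)
boundary_pixels <- function(mask) {
  p <- matrix(FALSE, nrow(mask) + 2L, ncol(mask) + 2L)
  p[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  n <- nrow(p); c <- ncol(p)
  interior <- p[1:(n - 2), 2:(c - 1)] & p[3:n, 2:(c - 1)] &
              p[2:(n - 1), 1:(c - 2)] & p[2:(n - 1), 3:c]
  mask_coords(mask & !interior)
}

#' Write a generated whole-mount scene to disk
#'
#' The image goes to an 8-bit TIFF and the ground truth (without the bulky
#' mask, which is written as its own 0/255 TIFF) to JSON.
#'
#' @param wm result of [generate_wholemount()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_wholemount <- function(wm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_raster_tiff(wm$image, file.path(dir, "wholemount.tif"))
  write_mask_tiff(wm$truth$tree_mask, file.path(dir, "tree_mask.tif"),
                  wm$image$pixel_size_um)
  truth <- wm$truth
  truth$tree_mask <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
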