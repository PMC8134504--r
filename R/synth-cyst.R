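#' Parameters for the synthetic cyst / protrusion generator
#'
#' Describes a multicellular cyst (a disk-shaped body) with subcellular
#' protrusions extending radially into the surrounding matrix, as imaged in
#' 3D tubulogenesis assays. Each protrusion has a geometry and a lifetime
#' window; per-compartment mean intensities follow a configurable
#' protrusion-to-body ratio plus additive Gaussian noise, emulating e.g.
#' puromycin (SUnSET) or F-actin channels.
#'
#' @param image_size_px (rows, cols) canvas.
#' @param body_radius_px radius of the cyst body disk.
#' @param protrusion_specs list of protrusion descriptors, each a list/vector
#'   with `length_px`, `width_px`, `birth_frame`, `death_frame` (frames are
#'   0-based; a protrusion is present in frames `birth..death` inclusive).
#' @param compartment_ratio mean protrusion intensity divided by mean body
#'   intensity; must be > 0.
#' @param base_intensity mean body intensity (arbitrary fluorescence units).
#' @param outline_margin_um body signal is painted this far beyond the
#'   reported body mask, emulating the conservative hand-drawn outlines of
#'   real assays (the outline sits inside the cyst edge, so the
#'   quantification band just outside it still lies on cell signal). Must
#'   exceed the band width used for intensity ratios.
#' @param noise_sd additive Gaussian noise SD (clipped at 0).
#' @param frame_interval_h hours between consecutive frames.
#' @param n_frames number of frames (>= 1).
#' @param pixel_size_um physical pixel size.
#' @param seed RNG seed.
#' @return A validated `cyst_gen_params` list.
#' @export
cyst_gen_params <- function(image_size_px = c(192L, 192L),
                            body_radius_px = 45,
                            protrusion_specs = list(
                              list(length_px = 30, width_px = 8,
                                   birth_frame = 0L, death_frame = 0L)),
                            compartment_ratio = 1.8,
                            base_intensity = 100,
                            outline_margin_um = 12,
                            noise_sd = 5,
                            frame_interval_h = 0.5,
                            n_frames = 1L,
                            pixel_size_um = 0.65,
                            seed = 1L) {
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) abort("`n_frames` must be >= 1")
  stopifnot_scalar_num(compartment_ratio, "compartment_ratio", positive = TRUE)
  stopifnot_scalar_num(base_intensity, "base_intensity", positive = TRUE)
  stopifnot_scalar_num(noise_sd, "noise_sd", nonneg = TRUE)
  stopifnot_scalar_num(frame_interval_h, "frame_interval_h", positive = TRUE)
  stopifnot_scalar_num(pixel_size_um, "pixel_size_um", positive = TRUE)
  protrusion_specs <- lapply(protrusion_specs, function(s) {
    s <- as.list(s)
    for (f in c("length_px", "width_px", "birth_frame", "death_frame"))
      if (is.null(s[[f]])) abort(sprintf("protrusion spec missing `%s`", f))
    s$birth_frame <- as.integer(s$birth_frame)
    s$death_frame <- as.integer(s$death_frame)
    if (s$birth_frame > s$death_frame || s$death_frame >= n_frames ||
        s$birth_frame < 0L)
      abort("protrusion frames must satisfy 0 <= birth_frame <= death_frame < n_frames")
    s
  })
  structure(list(image_size_px = as.integer(image_size_px),
                 body_radius_px = body_radius_px,
                 protrusion_specs = protrusion_specs,
                 compartment_ratio = compartment_ratio,
                 base_intensity = base_intensity,
                 outline_margin_um = outline_margin_um, noise_sd = noise_sd,
                 frame_interval_h = frame_interval_h, n_frames = n_frames,
                 pixel_size_um = pixel_size_um, seed = as.integer(seed)),
            class = "cyst_gen_params")
}

#' Cyst scene container
#'
#' Bundles the per-frame data the protrusion quantification operates on:
#' named channel images, a body mask, a list of protrusion masks (disjoint
#' from the body and from each other) and the pixel size.
#'
#' @param channels named list of numeric matrices, all the same shape.
#' @param body_mask logical matrix.
#' @param protrusion_masks list of logical matrices (possibly empty).
#' @param pixel_size_um physical pixel size.
#' @export
cyst_scene <- function(channels, body_mask, protrusion_masks, pixel_size_um) {
  stopifnot(is.list(channels), length(channels) >= 1L, is.matrix(body_mask))
  d <- dim(body_mask)
  for (ch in channels) if (!identical(dim(ch), d))
    abort("all channels must match the body mask shape")
  for (pm in protrusion_masks) {
    if (!identical(dim(pm), d)) abort("protrusion masks must match the body mask shape")
    if (any(pm & body_mask)) abort("protrusion masks must be disjoint from the body mask")
  }
  structure(list(channels = channels, body_mask = body_mask,
                 protrusion_masks = protrusion_masks,
                 pixel_size_um = pixel_size_um),
            class = "cyst_scene")
}

#' Generate a synthetic cyst time-lapse with known protrusion dynamics
#'
#' Renders a disk-shaped cyst body with radial finger-like protrusions whose
#' presence windows, geometry and compartment intensity ratio are exactly
#' known. Each protrusion `p` appears in frames `[birth, death]` inclusive,
#' so its true lifetime is `(death - birth + 1) * frame_interval_h` — the
#' time the protrusion is visible.
#'
#' @param params a [cyst_gen_params()] object.
#' @return List with `frames` (list of [cyst_scene()]s; protrusion masks are
#'   named by protrusion id) and `truth`, a tibble with one row per
#'   protrusion: `protrusion_id`, `birth_frame`, `death_frame`, `lifetime_h`,
#'   `max_length_um`.
#' @examples
#' tl <- generate_cyst_timelapse(cyst_gen_params(n_frames = 4))
#' tl$truth
#' @export
generate_cyst_timelapse <- function(params) {
  stopifnot(inherits(params, "cyst_gen_params"))
  p <- params
  with_seed(p$seed, {
    dimpx <- p$image_size_px
    ctr <- dimpx / 2
    body <- disk_mask(dimpx, ctr, p$body_radius_px)
    # signal support: outline margin beyond the reported body mask
    paint <- disk_mask(dimpx, ctr,
                       p$body_radius_px + p$outline_margin_um / p$pixel_size_um)
    nprot <- length(p$protrusion_specs)
    # spread protrusions around the body at well-separated angles
    angles <- (seq_len(nprot) - 1) * 2 * pi / max(1L, nprot) + pi / 7
    prot_masks <- vector("list", nprot)
    for (i in seq_len(nprot)) {
      s <- p$protrusion_specs[[i]]
      u <- c(sin(angles[i]), cos(angles[i]))
      p0 <- ctr + u * (p$body_radius_px - 1)
      p1 <- ctr + u * (p$body_radius_px + s$length_px)
      m <- stamp_segment(matrix(FALSE, dimpx[1], dimpx[2]), p0, p1,
                         s$width_px / 2)
      prot_masks[[i]] <- m & !body
    }
    names(prot_masks) <- sprintf("p%d", seq_len(nprot))

    prot_level <- p$base_intensity * p$compartment_ratio
    frames <- vector("list", p$n_frames)
    for (f in seq_len(p$n_frames) - 1L) {
      img <- matrix(0, dimpx[1], dimpx[2])
      img[paint] <- p$base_intensity
      present <- which(vapply(p$protrusion_specs, function(s)
        f >= s$birth_frame && f <= s$death_frame, logical(1)))
      for (i in present) img[prot_masks[[i]]] <- prot_level
      if (p$noise_sd > 0)
        img <- pmax(img + matrix(stats::rnorm(length(img), 0, p$noise_sd),
                                 dimpx[1], dimpx[2]), 0)
      frames[[f + 1L]] <- cyst_scene(list(signal = img), body,
                                     prot_masks[present], p$pixel_size_um)
    }

    truth <- tibble::tibble(
      protrusion_id = names(prot_masks),
      birth_frame = vapply(p$protrusion_specs, `[[`, integer(1), "birth_frame"),
      death_frame = vapply(p$protrusion_specs, `[[`, integer(1), "death_frame"),
      lifetime_h = (death_frame - birth_frame + 1) * p$frame_interval_h,
      # measured on the rendered masks: farthest protrusion pixel from the
      # body (Euclidean), not the nominal spec length
      max_length_um = {
        dbody <- EBImage::imageData(EBImage::distmap(EBImage::Image((!body) * 1)))
        unname(vapply(prot_masks, function(pm)
          if (any(pm)) max(dbody[pm]) * p$pixel_size_um else 0, numeric(1)))
      }
    )
    list(frames = frames, truth = truth, frame_interval_h = p$frame_interval_h)
  })
}
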