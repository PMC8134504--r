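#' Background correction for fluorescence channels
#'
#' Subtracts a wide-Gaussian background estimate and clips at zero
#' (fluorescence is non-negative). Use on images with shading or uneven
#' illumination before computing intensity ratios.
#'
#' @param img scalar [raster_image()] or numeric matrix.
#' @param sigma_px Gaussian SD in pixels (default 50, wide relative to a
#'   cyst).
#' @return Corrected image, same type as `img`, with no negative values.
#' @export
correct_background <- function(img, sigma_px = 50) {
  out <- subtract_background(img, sigma_px)
  if (inherits(out, "raster_image")) out$pixels <- pmax(out$pixels, 0)
  else out <- pmax(out, 0)
  out
}

#' Peri-body band mask
#'
#' The ring of non-body pixels within `width_um` of the cyst body — the
#' "size-matched" comparison region used for localized-translation ratios.
#' Computed from the Euclidean distance transform to the body; protrusion
#' pixels are excluded.
#'
#' @param body_mask logical matrix.
#' @param width_um band width in micrometres (must map to >= 1 px).
#' @param pixel_size_um physical pixel size.
#' @param protrusion_masks optional list of protrusion masks to exclude.
#' @return Logical band mask.
#' @export
body_band <- function(body_mask, width_um = 10, pixel_size_um = 1,
                      protrusion_masks = NULL) {
  stopifnot_scalar_num(width_um, "width_um", positive = TRUE)
  width_px <- width_um / pixel_size_um
  if (width_px < 1) abort("band width is below one pixel at this pixel size")
  if (!any(body_mask)) abort("`body_mask` is empty")
  d <- EBImage::imageData(EBImage::distmap(EBImage::Image((!body_mask) * 1)))
  band <- !body_mask & d <= width_px
  if (!is.null(protrusion_masks))
    for (pm in protrusion_masks) band <- band & !pm
  band
}

# scene channel, optionally background-corrected
scene_channel <- function(scene, channel, bg_sigma = NULL) {
  stopifnot(inherits(scene, "cyst_scene"))
  img <- scene$channels[[channel]]
  if (is.null(img)) abort(sprintf("no channel named `%s` in the scene", channel))
  if (!is.null(bg_sigma)) img <- correct_background(img, bg_sigma)
  img
}

#' Localized translation ratio (protrusion over body band)
#'
#' The SUnSET-style readout of compartmentalized protein synthesis: mean
#' channel intensity over a protrusion mask divided by the mean over a
#' size-matched subregion of the peri-body band. The subregion is the set
#' of band pixels nearest the protrusion root (the protrusion pixel closest
#' to the body), grown until its pixel count matches the protrusion's, so
#' the comparison is local and equal-area. If the whole band is smaller
#' than the protrusion, the full band is used and a warning is issued.
#' Being a ratio of means of one channel, the value is invariant to global
#' multiplicative rescaling of that channel.
#'
#' @param scene a [cyst_scene()].
#' @param channel channel name (default `"signal"`).
#' @param protrusion_id index or name of the protrusion mask.
#' @param width_um band width (default 10 um).
#' @param bg_sigma optional Gaussian SD for background correction; `NULL`
#'   (default) uses the raw channel — appropriate for images without
#'   shading, including the synthetic scenes.
#' @return The intensity ratio (a single number).
#' @export
localized_translation_ratio <- function(scene, channel = "signal",
                                        protrusion_id = 1L, width_um = 10,
                                        bg_sigma = NULL) {
  img <- scene_channel(scene, channel, bg_sigma)
  pm <- scene$protrusion_masks[[protrusion_id]]
  if (is.null(pm) || !any(pm)) abort("protrusion mask is empty or missing")
  band <- body_band(scene$body_mask, width_um, scene$pixel_size_um,
                    scene$protrusion_masks)
  if (!any(band)) abort("peri-body band is empty")
  n_prot <- sum(pm)
  band_pts <- mask_coords(band)
  if (nrow(band_pts) < n_prot) {
    warn("band smaller than protrusion; using the whole band as reference")
    sub <- band_pts
  } else {
    # root: protrusion pixel nearest the body
    dbody <- EBImage::imageData(EBImage::distmap(EBImage::Image((!scene$body_mask) * 1)))
    prot_pts <- mask_coords(pm)
    root <- prot_pts[which.min(dbody[prot_pts]), ]
    sub <- band_pts[order(dist2_to(band_pts, root))[seq_len(n_prot)], , drop = FALSE]
  }
  mean(img[mask_coords(pm)]) / mean(img[sub])
}

#' Normalized region intensity
#'
#' Mean channel intensity of a region divided by the whole-cyst mean
#' (body plus all protrusions) — the per-cyst normalization used for
#' compartment comparisons of F-actin, paxillin or translation markers.
#' The whole cyst itself therefore scores exactly 1, and the value is
#' invariant to multiplicative rescaling of the channel.
#'
#' @param scene a [cyst_scene()].
#' @param channel channel name.
#' @param region `"body"`, `"protrusion"` (union of all), a protrusion
#'   index/name, or a logical mask.
#' @param bg_sigma optional background-correction SD (see
#'   [localized_translation_ratio()]).
#' @return The normalized intensity.
#' @export
normalized_region_intensity <- function(scene, channel = "signal",
                                        region = "protrusion", bg_sigma = NULL) {
  img <- scene_channel(scene, channel, bg_sigma)
  prot_union <- Reduce(`|`, scene$protrusion_masks,
                       matrix(FALSE, nrow(scene$body_mask), ncol(scene$body_mask)))
  whole <- scene$body_mask | prot_union
  rmask <- if (is.matrix(region)) {
    region
  } else if (identical(region, "body")) {
    scene$body_mask
  } else if (identical(region, "protrusion")) {
    prot_union
  } else if (identical(region, "cyst") || identical(region, "whole")) {
    whole
  } else {
    scene$protrusion_masks[[region]]
  }
  if (is.null(rmask) || !any(rmask)) abort("empty region")
  mean(img[rmask]) / mean(img[whole])
}

# geodesic distance, within body+protrusion, from the body to each
# protrusion pixel; chamfer propagation with 8-neighbour sqrt(2) steps
protrusion_geodesic_length <- function(body_mask, prot_mask, pixel_size_um) {
  allow <- body_mask | prot_mask
  d <- matrix(Inf, nrow(allow), ncol(allow))
  d[body_mask] <- 0
  steps <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                 dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  w <- ifelse(abs(steps[, 1]) + abs(steps[, 2]) == 2, sqrt(2), 1)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(steps))) {
      cand <- shift_mat_num(d, steps[k, 1], steps[k, 2], Inf) + w[k]
      upd <- allow & cand < d
      if (any(upd)) { d[upd] <- cand[upd]; changed <- TRUE }
    }
    if (!changed) break
  }
  v <- d[prot_mask]
  if (length(v) == 0L || all(!is.finite(v))) return(0)
  max(v[is.finite(v)]) * pixel_size_um
}

shift_mat_num <- function(m, dr, dc, fill) {
  R <- nrow(m); C <- ncol(m)
  out <- matrix(fill, R, C)
  rs <- max(1, 1 + dr):min(R, R + dr)
  cs <- max(1, 1 + dc):min(C, C + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Track protrusions across a time-lapse
#'
#' Greedy frame-to-frame linking of protrusion masks by
#' intersection-over-union: in each frame, candidate links between active
#' tracks and current masks are taken in decreasing IoU order and accepted
#' when IoU >= `min_iou`. Unmatched masks start new tracks; unmatched
#' tracks close (no gap bridging — a vanished protrusion has retracted).
#' Each track reports its lifetime, `n_frames_present * frame_interval_h`,
#' and its maximal length over the frames it spans, where length is the
#' largest geodesic distance (within body plus protrusion) from the body
#' boundary, so curved protrusions are measured along their extent.
#'
#' @param frames list of [cyst_scene()]s, temporally ordered and aligned.
#' @param frame_interval_h hours between frames.
#' @param min_iou linking threshold (default 0.3).
#' @return Tibble (class `mq_tracks`): `track_id`, `first_frame`,
#'   `last_frame` (0-based), `n_frames`, `lifetime_h`, `max_length_um`.
#' @export
track_protrusions <- function(frames, frame_interval_h, min_iou = 0.3) {
  stopifnot(length(frames) >= 1L)
  stopifnot_scalar_num(frame_interval_h, "frame_interval_h", positive = TRUE)
  tracks <- list()   # each: list(mask, first, last, n, max_len)
  active <- integer(0)
  for (f in seq_along(frames) - 1L) {
    sc <- frames[[f + 1L]]
    cur <- sc$protrusion_masks
    ncur <- length(cur)
    lens <- vapply(seq_len(ncur), function(i)
      protrusion_geodesic_length(sc$body_mask, cur[[i]], sc$pixel_size_um),
      numeric(1))
    assigned_cur <- rep(FALSE, ncur)
    matched_tr <- logical(length(active))
    if (length(active) > 0 && ncur > 0) {
      iou <- matrix(0, length(active), ncur)
      for (a in seq_along(active)) for (i in seq_len(ncur)) {
        inter <- sum(tracks[[active[a]]]$mask & cur[[i]])
        if (inter > 0)
          iou[a, i] <- inter / sum(tracks[[active[a]]]$mask | cur[[i]])
      }
      ord <- order(iou, decreasing = TRUE)
      for (k in ord) {
        if (iou[k] < min_iou) break
        a <- (k - 1) %% length(active) + 1
        i <- (k - 1) %/% length(active) + 1
        if (matched_tr[a] || assigned_cur[i]) next
        t <- tracks[[active[a]]]
        t$mask <- cur[[i]]; t$last <- f; t$n <- t$n + 1L
        t$max_len <- max(t$max_len, lens[i])
        tracks[[active[a]]] <- t
        matched_tr[a] <- TRUE; assigned_cur[i] <- TRUE
      }
    }
    active <- active[matched_tr]
    for (i in which(!assigned_cur)) {
      tracks[[length(tracks) + 1L]] <- list(mask = cur[[i]], first = f,
                                            last = f, n = 1L, max_len = lens[i])
      active <- c(active, length(tracks))
    }
  }
  out <- tibble::tibble(
    track_id = seq_along(tracks),
    first_frame = vapply(tracks, `[[`, integer(1), "first"),
    last_frame = vapply(tracks, `[[`, integer(1), "last"),
    n_frames = vapply(tracks, `[[`, integer(1), "n"),
    lifetime_h = n_frames * frame_interval_h,
    max_length_um = vapply(tracks, `[[`, numeric(1), "max_len")
  )
  class(out) <- c("mq_tracks", class(out))
  attr(out, "frame_interval_h") <- frame_interval_h
  out
}
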