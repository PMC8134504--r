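# Boundary polygons of binary masks.
#
# Contours are traced on the pixel-corner lattice (the "crack" boundary
# between foreground and background pixels), so the polygon of an untouched
# mask encloses exactly the mask's pixel squares: its shoelace area equals
# the pixel count, and every mask pixel centre lies strictly inside. This
# avoids the ~perimeter/2 area bias a centre-traced contour has on thin
# ducts.

#' Boundary polygon of an epithelial tree
#'
#' @param vertices ordered (row, col) vertex matrix (open ring).
#' @param shrink_factor tightness parameter in `[0, 1]` recorded with the
#'   polygon: 0 = convex hull, 1 = tightest pixel-exact contour.
#' @export
boundary_polygon <- function(vertices, shrink_factor) {
  stopifnot(is.matrix(vertices), ncol(vertices) == 2L, nrow(vertices) >= 3L)
  structure(list(vertices = vertices, shrink_factor = shrink_factor),
            class = "boundary_polygon")
}

#' @export
print.boundary_polygon <- function(x, ...) {
  cat(sprintf("<boundary_polygon> %d vertices, shrink_factor %.2f, area %.1f px^2\n",
              nrow(x$vertices), x$shrink_factor, polygon_area(x$vertices)))
  invisible(x)
}

# Trace the outer crack boundary of the largest 4-connected region of a
# logical mask. Directed edges keep the foreground on the left; at saddle
# corners (diagonally touching pixels) the traversal turns toward the
# current pixel, which splits pinches and keeps every loop simple. Returns
# an open (row, col) vertex ring with collinear runs merged.
trace_outer_boundary <- function(mask) {
  R <- nrow(mask); C <- ncol(mask)
  if (!any(mask)) abort("cannot trace an empty mask")
  p <- matrix(FALSE, R + 2L, C + 2L)
  p[2:(R + 1L), 2:(C + 1L)] <- mask
  ctr <- p[2:(R + 1L), 2:(C + 1L)]
  up    <- ctr & !p[1:R, 2:(C + 1L)]
  down  <- ctr & !p[3:(R + 2L), 2:(C + 1L)]
  left  <- ctr & !p[2:(R + 1L), 1:C]
  right <- ctr & !p[2:(R + 1L), 3:(C + 2L)]

  # corner (r - .5, c - .5) has integer key idx(r, c) with r, c in 1..R+1
  nkc <- C + 1L
  key <- function(r, c) (r - 1L) * nkc + c
  e_from <- integer(0); e_to <- integer(0); e_dr <- integer(0); e_dc <- integer(0)
  add <- function(coords, f_r, f_c, t_r, t_c, dr, dc) {
    if (nrow(coords) == 0L) return()
    e_from <<- c(e_from, key(coords[, 1] + f_r, coords[, 2] + f_c))
    e_to   <<- c(e_to,   key(coords[, 1] + t_r, coords[, 2] + t_c))
    e_dr <<- c(e_dr, rep.int(dr, nrow(coords)))
    e_dc <<- c(e_dc, rep.int(dc, nrow(coords)))
  }
  # bg above: top edge, left-to-right; bg below: bottom edge, right-to-left;
  # bg left: left edge, upward; bg right: right edge, downward
  add(mask_coords(up),    0L, 0L, 0L, 1L,  0L,  1L)
  add(mask_coords(down),  1L, 1L, 1L, 0L,  0L, -1L)
  add(mask_coords(left),  1L, 0L, 0L, 0L, -1L,  0L)
  add(mask_coords(right), 0L, 1L, 1L, 1L,  1L,  0L)

  ne <- length(e_from)
  out1 <- integer((R + 1L) * nkc); out2 <- integer((R + 1L) * nkc)
  for (i in seq_len(ne)) {
    k <- e_from[i]
    if (out1[k] == 0L) out1[k] <- i else out2[k] <- i
  }
  used <- logical(ne)
  best_ring <- NULL; best_area <- -1
  for (start in seq_len(ne)) {
    if (used[start]) next
    ring <- integer(0)
    i <- start
    repeat {
      used[i] <- TRUE
      ring <- c(ring, i)
      k <- e_to[i]
      c1 <- out1[k]; c2 <- out2[k]
      nxt <- 0L
      if (c2 != 0L) {
        # saddle: prefer the left turn (dc, -dr), which hugs the interior
        ldr <- e_dc[i]; ldc <- -e_dr[i]
        if (!used[c1] && e_dr[c1] == ldr && e_dc[c1] == ldc) nxt <- c1
        else if (!used[c2] && e_dr[c2] == ldr && e_dc[c2] == ldc) nxt <- c2
        else if (!used[c1]) nxt <- c1
        else if (!used[c2]) nxt <- c2
      } else if (c1 != 0L && !used[c1]) nxt <- c1
      if (nxt == 0L) break
      i <- nxt
    }
    kr <- (e_from[ring] - 1L) %/% nkc + 1L
    kc <- (e_from[ring] - 1L) %% nkc + 1L
    v <- cbind(row = kr - 0.5, col = kc - 0.5)
    a <- polygon_area(v)
    if (a > best_area) { best_area <- a; best_ring <- v }
  }
  simplify_ring(best_ring)
}

# drop vertices interior to collinear runs
simplify_ring <- function(v) {
  n <- nrow(v)
  if (n < 4L) return(v)
  prv <- v[c(n, 1:(n - 1)), , drop = FALSE]
  nxt <- v[c(2:n, 1), , drop = FALSE]
  cross <- (v[, 1] - prv[, 1]) * (nxt[, 2] - v[, 2]) -
           (v[, 2] - prv[, 2]) * (nxt[, 1] - v[, 1])
  keep <- abs(cross) > 1e-12
  if (sum(keep) < 3L) return(v)
  v[keep, , drop = FALSE]
}

#' Tree boundary polygon and area
#'
#' Computes a concave boundary hull of a binary tree mask and its enclosed
#' area. The `shrink_factor` maps to hull tightness: 1 traces the exact
#' pixel contour, 0 returns the convex hull, and intermediate values close
#' the mask with a disk of radius `r = ((1 - s) / s) * a` pixels before
#' tracing, where `a` is the duct half-caliber (the median interior
#' distance-transform value). Concavities narrower than the duct's own
#' thickness scale are thus smoothed away at the default `s = 0.5`, while
#' the hull still hugs the tree and its area stays close to the mask's
#' pixel area.
#'
#' @param mask logical matrix (nonempty, >= 3 pixels).
#' @param pixel_size_um physical pixel size.
#' @param shrink_factor tightness in `[0, 1]` (default 0.5).
#' @return List with `boundary` (a [boundary_polygon()]) and `area_um2`.
#' @examples
#' sq <- matrix(FALSE, 120, 120); sq[11:110, 11:110] <- TRUE
#' tree_boundary_and_area(sq, pixel_size_um = 10)$area_um2  # 1 mm^2
#' @export
tree_boundary_and_area <- function(mask, pixel_size_um, shrink_factor = 0.5) {
  if (!is.matrix(mask)) abort("`mask` must be a logical matrix")
  mask <- mask > 0
  if (!any(mask)) abort("`mask` is empty")
  if (sum(mask) < 3L) abort("`mask` must contain at least 3 pixels")
  stopifnot_scalar_num(pixel_size_um, "pixel_size_um", positive = TRUE)
  if (shrink_factor < 0 || shrink_factor > 1)
    abort("`shrink_factor` must be in [0, 1]")

  if (shrink_factor == 0) {
    ring <- trace_outer_boundary(mask)
    hull <- grDevices::chull(ring[, 2], ring[, 1])
    v <- ring[hull, , drop = FALSE]
    # chull returns clockwise in (x, y); order is irrelevant for area
  } else {
    work <- mask
    if (shrink_factor < 1) {
      dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(mask * 1)))
      a <- stats::median(dm[mask])
      r <- round(((1 - shrink_factor) / shrink_factor) * a)
      if (r >= 1) {
        # pad so dilation never clips at the canvas border
        pad <- as.integer(r) + 2L
        big <- matrix(FALSE, nrow(mask) + 2L * pad, ncol(mask) + 2L * pad)
        big[pad + seq_len(nrow(mask)), pad + seq_len(ncol(mask))] <- mask
        brush <- EBImage::makeBrush(2L * as.integer(r) + 1L, "disc")
        closed <- EBImage::imageData(EBImage::closing(EBImage::Image(big * 1), brush)) > 0.5
        work <- closed[pad + seq_len(nrow(mask)), pad + seq_len(ncol(mask))] | mask
      }
    }
    v <- trace_outer_boundary(work)
  }
  bp <- boundary_polygon(v, shrink_factor)
  list(boundary = bp, area_um2 = polygon_area(v) * pixel_size_um^2)
}

# Sutherland-Hodgman clip of a polygon by the half-plane {x : a . x <= b},
# with x = (row, col). Returns a vertex matrix (possibly with 0 rows).
clip_halfplane <- function(v, a, b) {
  n <- nrow(v)
  s <- as.vector(v %*% a) - b
  jj <- c(2:n, 1L)
  sj <- s[jj]
  crossing <- (s < 0 & sj > 0) | (s > 0 & sj < 0)
  t <- ifelse(crossing, s / (s - sj), 0)
  ir <- v[, 1] + t * (v[jj, 1] - v[, 1])
  ic <- v[, 2] + t * (v[jj, 2] - v[, 2])
  # emit, in edge order: the edge's start vertex when inside, then the
  # intersection point when the edge crosses the clip line
  pos <- c(2 * seq_len(n) - 1, 2 * seq_len(n))
  keep <- c(s <= 0, crossing)
  rows <- c(v[, 1], ir)[keep]
  cols <- c(v[, 2], ic)[keep]
  ord <- order(pos[keep])
  cbind(row = rows[ord], col = cols[ord])
}
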