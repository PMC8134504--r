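# internal helpers shared across modules

#' @importFrom rlang abort warn inform
NULL

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

stopifnot_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort(sprintf("`%s` must be a finite numeric scalar", name))
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0", name))
  if (nonneg && x < 0) abort(sprintf("`%s` must be >= 0", name))
  invisible(x)
}

as_point <- function(p, name = "point") {
  if (is.null(p)) return(NULL)
  p <- as.numeric(p)
  if (length(p) != 2L || any(!is.finite(p)))
    abort(sprintf("`%s` must be a length-2 (row, col) coordinate", name))
  p
}

# squared Euclidean distances from one point to rows of a 2-col matrix
dist2_to <- function(pts, p) (pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2

# coordinates (row, col) of TRUE entries of a logical matrix
mask_coords <- function(mask) {
  w <- which(mask)
  cbind(row = ((w - 1L) %% nrow(mask)) + 1L,
        col = ((w - 1L) %/% nrow(mask)) + 1L)
}

# logical matrix from coordinates
coords_to_mask <- function(coords, dim) {
  m <- matrix(FALSE, dim[1], dim[2])
  m[cbind(coords[, 1], coords[, 2])] <- TRUE
  m
}

# 8-neighbour count of TRUE cells, zero-padded borders
neighbor_count8 <- function(m) {
  p <- matrix(0L, nrow(m) + 2L, ncol(m) + 2L)
  p[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m * 1L
  n <- nrow(p); c <- ncol(p)
  s <- p[1:(n - 2), 1:(c - 2)] + p[1:(n - 2), 2:(c - 1)] + p[1:(n - 2), 3:c] +
       p[2:(n - 1), 1:(c - 2)] +                            p[2:(n - 1), 3:c] +
       p[3:n,       1:(c - 2)] + p[3:n,       2:(c - 1)] + p[3:n,       3:c]
  s
}

# shoelace area of a polygon given as (row, col) vertex matrix (open or closed)
polygon_area <- function(v) {
  n <- nrow(v)
  if (n < 3L) return(0)
  if (all(v[1, ] == v[n, ])) { v <- v[-n, , drop = FALSE]; n <- n - 1L }
  x <- v[, 2]; y <- v[, 1]
  j <- c(n, seq_len(n - 1L))
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# point-in-polygon for (row, col) points against a (row, col) polygon
points_in_polygon <- function(pts, poly) {
  if (all(poly[1, ] == poly[nrow(poly), ])) poly <- poly[-nrow(poly), , drop = FALSE]
  mgcv::in.out(cbind(poly[, 2], poly[, 1]), cbind(pts[, 2], pts[, 1]))
}
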