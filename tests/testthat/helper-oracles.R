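# independent brute-force oracles used across tests

# exhaustive Otsu: try every cut, maximize between-class variance,
# return the lowest maximizing bin value
brute_otsu <- function(counts, values = seq_along(counts) - 1) {
  n <- sum(counts)
  best <- -Inf; arg <- NA
  for (t in seq_len(length(counts) - 1)) {
    w0 <- sum(counts[1:t]) / n
    w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(counts[1:t] * values[1:t]) / sum(counts[1:t])
    m1 <- sum(counts[(t + 1):length(counts)] * values[(t + 1):length(counts)]) /
      sum(counts[(t + 1):length(counts)])
    sb <- w0 * w1 * (m0 - m1)^2
    if (sb > best + 1e-12) { best <- sb; arg <- values[t] }
  }
  arg
}

# step-up BH q-values computed from the definition
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  running <- Inf
  for (i in n:1) {
    running <- min(running, n * p[o[i]] / i)
    q[o[i]] <- min(1, running)
  }
  q
}

# plain UPGMA by repeated merging of the closest cluster pair,
# average distance over all inter-cluster point pairs
brute_upgma <- function(d) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  memberships <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA); bd <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      dd <- mean(dm[clusters[[i]], clusters[[j]]])
      if (dd < bd) { bd <- dd; best <- c(i, j) }
    }
    heights <- c(heights, bd)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    memberships[[length(memberships) + 1L]] <- sort(merged)
    clusters <- c(clusters[-best], list(merged))
  }
  list(heights = heights, memberships = memberships)
}

# disk mask helper for constructed scenes
make_disk <- function(dim, center, radius) {
  R <- matrix(seq_len(dim[1]), dim[1], dim[2])
  C <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  (R - center[1])^2 + (C - center[2])^2 <= radius^2
}

# a minimal two-group cyst scene built by hand: body disk at `body_val`,
# one protrusion finger at `prot_val`, zero background
make_two_level_scene <- function(body_val = 100, prot_val = 200,
                                 dim = c(120, 120)) {
  body <- make_disk(dim, dim / 2, 30)
  prot <- matrix(FALSE, dim[1], dim[2])
  prot[(dim[1] / 2 - 3):(dim[1] / 2 + 3), (dim[2] / 2 + 30):(dim[2] / 2 + 50)] <- TRUE
  prot <- prot & !body
  img <- matrix(body_val, dim[1], dim[2])  # band outside body carries body signal
  img[prot] <- prot_val
  cyst_scene(list(signal = img), body, list(p1 = prot), pixel_size_um = 1)
}

# Welch p-value recomputed from the closed form
brute_welch_p <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * pt(-abs(t), df)
}
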