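#' Half-minimum imputation of zero intensities
#'
#' Replaces every zero entry by half the global minimum of the strictly
#' positive entries, the standard floor for label-free MS intensities below
#' detection. The `original_zero` provenance flags are untouched, so later
#' filters still see the pre-imputation state. Idempotent.
#'
#' @param m an [abundance_matrix()].
#' @return The imputed [abundance_matrix()].
#' @export
impute_zeros <- function(m) {
  stopifnot(inherits(m, "abundance_matrix"))
  pos <- m$values[m$values > 0]
  if (length(pos) == 0L) abort("all-zero matrix: nothing to anchor the imputation")
  m$values[m$values == 0] <- min(pos) / 2
  m
}

#' Filter proteins by per-group original-zero count
#'
#' Drops any protein that initially (pre-imputation) had zero ion intensity
#' in more than `max_zeros_per_group` samples of any single group. Operates
#' strictly on the `original_zero` flags.
#'
#' @param m an [abundance_matrix()].
#' @param max_zeros_per_group maximum tolerated original zeros per group
#'   (default 2, i.e. a protein missing from 3+ of a 5-sample group goes).
#' @return The filtered [abundance_matrix()].
#' @export
filter_group_zeros <- function(m, max_zeros_per_group = 2L) {
  stopifnot(inherits(m, "abundance_matrix"))
  groups <- unique(m$group_labels)
  bad <- rep(FALSE, nrow(m$values))
  for (g in groups) {
    cols <- m$group_labels == g
    bad <- bad | rowSums(m$original_zero[, cols, drop = FALSE]) > max_zeros_per_group
  }
  subset_proteins(m, !bad)
}

subset_proteins <- function(m, keep) {
  m$values <- m$values[keep, , drop = FALSE]
  m$original_zero <- m$original_zero[keep, , drop = FALSE]
  m$protein_ids <- m$protein_ids[keep]
  m
}

#' Normalize to summed extracted-ion-chromatogram intensity
#'
#' Divides every value by its sample's (column's) total, converting ion
#' intensities to relative abundances; each column then sums to 1.
#'
#' @param m an [abundance_matrix()].
#' @return The normalized [abundance_matrix()].
#' @export
eic_normalize <- function(m) {
  stopifnot(inherits(m, "abundance_matrix"))
  cs <- colSums(m$values)
  if (any(cs <= 0)) abort("every sample must have a positive total intensity")
  m$values <- sweep(m$values, 2, cs, "/")
  m
}

#' Standard preprocessing chain: impute, filter, normalize
#'
#' @param m an [abundance_matrix()].
#' @param steps order of operations; defaults to impute, then the group-zero
#'   filter (on original zeros), then summed-EIC normalization.
#' @param max_zeros_per_group forwarded to [filter_group_zeros()].
#' @return The preprocessed [abundance_matrix()].
#' @export
preprocess_abundance <- function(m, steps = c("impute", "filter", "normalize"),
                                 max_zeros_per_group = 2L) {
  for (s in steps) {
    m <- switch(s,
      impute = impute_zeros(m),
      filter = filter_group_zeros(m, max_zeros_per_group),
      normalize = eic_normalize(m),
      abort(sprintf("unknown preprocessing step `%s`", s)))
  }
  m
}

# Welch two-tailed t-test on two numeric vectors; handles the degenerate
# zero-variance cases by convention (equal constants: p = 1; different
# constants: p = 0)
welch_p <- function(a, b) {
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = NA_real_, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = NA_real_, p = 0))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Differential abundance between two groups
#'
#' The screen's pairwise comparison: proteins observed (nonzero before
#' imputation) in fewer than `min_obs` of the pooled samples are excluded;
#' each remaining protein gets a two-tailed heteroscedastic (Welch) t-test,
#' a q-value computed from the p-value list, and a log2 ratio of group
#' means (post-imputation). Proteins uniquely observed in one group — all
#' original zeros in exactly one of the two groups — are assigned the
#' sentinel log2 ratio +10 (present only in `group_a`) or -10 (only in
#' `group_b`); other ratios are clamped to that range. A protein is called
#' significant when p < `alpha` and/or |log2 ratio| >= `log2_cut`
#' (2 corresponds to a 4-fold change).
#'
#' @param m an [abundance_matrix()] (impute first: see [impute_zeros()]).
#' @param group_a,group_b group labels to compare (a vs b).
#' @param min_obs minimum pooled observations (default 3, of the 10 samples
#'   in a 5 + 5 design).
#' @param alpha p-value cutoff for the significance call.
#' @param log2_cut absolute log2-ratio cutoff for the significance call.
#' @param q_method `"BH"` (Benjamini-Hochberg, default) or `"storey"`.
#' @return Tibble (class `mq_differential`): `protein_id`, `mean_a`,
#'   `mean_b`, `t_statistic`, `df`, `p_value`, `q_value`, `log2_ratio`,
#'   `unique_to`, `significant`.
#' @export
differential <- function(m, group_a, group_b, min_obs = 3L, alpha = 0.05,
                         log2_cut = 2, q_method = c("BH", "storey")) {
  stopifnot(inherits(m, "abundance_matrix"))
  q_method <- match.arg(q_method)
  ca <- m$group_labels == group_a
  cb <- m$group_labels == group_b
  if (sum(ca) < 2L || sum(cb) < 2L)
    abort("both groups need at least 2 samples")
  obs <- rowSums(!m$original_zero[, ca | cb, drop = FALSE])
  keep <- obs >= min_obs
  va <- m$values[keep, ca, drop = FALSE]
  vb <- m$values[keep, cb, drop = FALSE]
  oza <- m$original_zero[keep, ca, drop = FALSE]
  ozb <- m$original_zero[keep, cb, drop = FALSE]
  n <- sum(keep)
  t_stat <- df <- p <- numeric(n)
  for (i in seq_len(n)) {
    w <- welch_p(va[i, ], vb[i, ])
    t_stat[i] <- w$t; df[i] <- w$df; p[i] <- w$p
  }
  mean_a <- rowMeans(va); mean_b <- rowMeans(vb)
  only_a <- rowSums(!ozb) == 0 & rowSums(!oza) > 0
  only_b <- rowSums(!oza) == 0 & rowSums(!ozb) > 0
  l2 <- pmin(10, pmax(-10, log2(mean_a / mean_b)))
  l2[only_a] <- 10
  l2[only_b] <- -10
  out <- tibble::tibble(
    protein_id = m$protein_ids[keep],
    mean_a = mean_a, mean_b = mean_b,
    t_statistic = t_stat, df = df, p_value = p,
    q_value = qvalues(p, method = q_method),
    log2_ratio = l2,
    unique_to = dplyr::case_when(only_a ~ group_a, only_b ~ group_b,
                                 .default = NA_character_),
    significant = p_value < alpha | abs(log2_ratio) >= log2_cut
  )
  class(out) <- c("mq_differential", class(out))
  attr(out, "comparison") <- c(a = group_a, b = group_b)
  attr(out, "settings") <- list(min_obs = min_obs, alpha = alpha,
                                log2_cut = log2_cut, q_method = q_method,
                                n_excluded = sum(!keep))
  out
}

#' False-discovery-rate q-values
#'
#' Benjamini-Hochberg step-up q-values by default; optionally Storey's
#' estimate with the smoother-based pi0 (the proportion of true nulls),
#' which simply scales the BH values by pi0 <= 1.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @param method `"BH"` or `"storey"`.
#' @return q-values, monotone in the p-value ordering.
#' @export
qvalues <- function(p, method = c("BH", "storey")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1 | !is.finite(p))) abort("p-values must lie in [0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  if (method == "storey") {
    pi0 <- storey_pi0(p)
    q <- pmin(1, q * pi0)
  }
  q
}

# Storey's pi0 via the natural-spline smoother over a lambda grid
storey_pi0 <- function(p, lambdas = seq(0.05, 0.9, by = 0.05)) {
  if (length(p) < 20L) return(1)
  pi0l <- vapply(lambdas, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- stats::smooth.spline(lambdas, pi0l, df = 3)
  pi0 <- stats::predict(fit, x = max(lambdas))$y
  min(1, max(pi0, 1 / length(p)))
}

#' Unsupervised correlation clustering of sample profiles
#'
#' Hierarchical clustering of samples with the distance set to
#' 1 - Pearson correlation between protein profiles and average linkage
#' (UPGMA) between clusters — the configuration used for screen-profile
#' dendrograms. By default each protein is standardized (z-scored across
#' samples) first, the heat-map convention, so every protein contributes
#' equally instead of the few most abundant ones dominating the
#' correlation; zero-variance proteins are skipped by the standardization.
#'
#' @param m an [abundance_matrix()] (preprocess first).
#' @param standardize z-score each protein across samples before
#'   correlating (default TRUE).
#' @return An `hclust` object with sample IDs as labels and the group
#'   labels attached as attribute `"groups"`.
#' @export
correlation_cluster <- function(m, standardize = TRUE) {
  stopifnot(inherits(m, "abundance_matrix"))
  if (ncol(m$values) < 2L) abort("need at least 2 samples")
  v <- m$values
  if (standardize) {
    sds_p <- apply(v, 1, stats::sd)
    v <- v[sds_p > 0, , drop = FALSE]
    v <- t(scale(t(v)))
  }
  sds <- apply(v, 2, stats::sd)
  if (any(sds == 0))
    abort(sprintf("constant profile(s): %s (correlation undefined)",
                  paste(m$sample_ids[sds == 0], collapse = ", ")))
  d <- stats::as.dist(1 - stats::cor(v))
  hc <- stats::hclust(d, method = "average")
  hc$labels <- m$sample_ids
  attr(hc, "groups") <- stats::setNames(m$group_labels, m$sample_ids)
  hc
}

#' Export a dendrogram in Newick format
#' @param hc an `hclust`, e.g. from [correlation_cluster()].
#' @param path output file.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Random-forest developmental-stage classification
#'
#' Trains a bootstrap-aggregated ensemble of decision trees (5000 by
#' default) on reference-stage sample profiles and scores samples by the
#' fraction of trees voting for each training class — e.g. the probability
#' that a profile looks like a 4-week rather than a 5-week gland.
#' Deterministic for a fixed seed; out-of-bag accuracy is reported as the
#' internal error estimate.
#'
#' @param train an [abundance_matrix()] whose samples carry exactly 2 (or
#'   more) class labels, each with >= 2 samples.
#' @param score an [abundance_matrix()] with the same proteins; defaults to
#'   scoring the training matrix itself.
#' @param n_trees ensemble size (default 5000).
#' @param seed integer RNG seed.
#' @return An `mq_rf_report`: list with `scores` (tibble: sample_id, group,
#'   one probability column per class), `classes`, `n_trees`, `seed`,
#'   `oob_accuracy`.
#' @export
rf_stage_classify <- function(train, score = train, n_trees = 5000L, seed = 1L) {
  stopifnot(inherits(train, "abundance_matrix"), inherits(score, "abundance_matrix"))
  cls <- factor(train$group_labels)
  if (nlevels(cls) < 2L) abort("training data must contain at least 2 classes")
  if (any(table(cls) < 2L)) abort("every training class needs at least 2 samples")
  if (!identical(train$protein_ids, score$protein_ids)) {
    common <- intersect(train$protein_ids, score$protein_ids)
    if (length(common) < 2L) abort("train and score matrices share too few proteins")
    train <- subset_proteins(train, train$protein_ids %in% common)
    score <- subset_proteins(score, score$protein_ids %in% common)
  }
  x <- t(train$values)
  colnames(x) <- train$protein_ids
  fit <- with_seed(seed,
    randomForest::randomForest(x, cls, ntree = as.integer(n_trees)))
  xs <- t(score$values)
  colnames(xs) <- score$protein_ids
  probs <- stats::predict(fit, xs, type = "prob")
  scores <- tibble::tibble(sample_id = score$sample_ids,
                           group = score$group_labels)
  for (lv in levels(cls)) scores[[paste0("p_", lv)]] <- unname(probs[, lv])
  structure(list(scores = scores, classes = levels(cls),
                 n_trees = as.integer(n_trees), seed = as.integer(seed),
                 oob_accuracy = 1 - unname(fit$err.rate[n_trees, "OOB"])),
            class = "mq_rf_report")
}

#' @export
print.mq_rf_report <- function(x, ...) {
  cat(sprintf("<mq_rf_report> %d trees, classes: %s, OOB accuracy %.3f\n",
              x$n_trees, paste(x$classes, collapse = " / "), x$oob_accuracy))
  print(x$scores)
  invisible(x)
}

#' Group comparison tests used across the study's readouts
#'
#' Dispatches the appropriate design: one-way ANOVA with Tukey-Kramer
#' post-hoc pairwise comparisons (parametric, 3+ groups, unequal n
#' supported); two-sided Wilcoxon rank-sum (2 groups, exact when sample
#' sizes permit and no ties); or Kruskal-Wallis with tie correction
#' followed by Dunn's pairwise z-tests (3+ groups, nonparametric).
#'
#' @param data a data frame.
#' @param value,group column names (strings) of the response and grouping
#'   variable.
#' @param design `"anova_tukey"`, `"wilcoxon"` or `"kruskal_dunn"`.
#' @param p_adjust adjustment for Dunn's pairwise p-values (default
#'   `"holm"`; Tukey-Kramer p-values come already adjusted from the
#'   studentized range distribution).
#' @return List (class `mq_group_compare`) with `omnibus` (one-row tibble)
#'   and `pairwise` (tibble of pairwise comparisons, or `NULL` for the
#'   two-group Wilcoxon design).
#' @examples
#' d <- data.frame(y = c(1, 2, 3, 2, 3, 4, 5, 6, 7),
#'                 g = rep(c("a", "b", "c"), each = 3))
#' group_compare(d, "y", "g", design = "anova_tukey")$omnibus
#' @export
group_compare <- function(data, value, group,
                          design = c("anova_tukey", "wilcoxon", "kruskal_dunn"),
                          p_adjust = "holm") {
  design <- match.arg(design)
  y <- data[[value]]
  g <- factor(data[[group]])
  if (nlevels(g) < 2L) abort("need at least 2 groups")
  out <- switch(design,
    anova_tukey = compare_anova_tukey(y, g),
    wilcoxon = compare_wilcoxon(y, g),
    kruskal_dunn = compare_kruskal_dunn(y, g, p_adjust))
  structure(c(out, list(design = design)), class = "mq_group_compare")
}

compare_anova_tukey <- function(y, g) {
  if (any(tapply(y, g, length) < 2L)) abort("parametric design needs >= 2 per group")
  if (stats::var(y) == 0) {
    omnibus <- tibble::tibble(statistic = 0, df1 = nlevels(g) - 1L,
                              df2 = length(y) - nlevels(g), p_value = 1)
    return(list(omnibus = omnibus, pairwise = NULL))
  }
  fit <- stats::aov(y ~ g)
  an <- summary(fit)[[1]]
  omnibus <- tibble::tibble(statistic = an[1, "F value"],
                            df1 = an[1, "Df"], df2 = an[2, "Df"],
                            p_value = an[1, "Pr(>F)"])
  tk <- stats::TukeyHSD(fit)$g
  pairwise <- tibble::tibble(
    comparison = rownames(tk),
    estimate = tk[, "diff"],
    conf_low = tk[, "lwr"], conf_high = tk[, "upr"],
    p_adjusted = tk[, "p adj"]
  )
  list(omnibus = omnibus, pairwise = pairwise)
}

compare_wilcoxon <- function(y, g) {
  if (nlevels(g) != 2L) abort("the Wilcoxon design is for exactly 2 groups")
  lv <- levels(g)
  wt <- stats::wilcox.test(y[g == lv[1]], y[g == lv[2]],
                           alternative = "two.sided", exact = NULL)
  omnibus <- tibble::tibble(statistic = unname(wt$statistic),
                            df1 = NA_integer_, df2 = NA_integer_,
                            p_value = wt$p.value)
  list(omnibus = omnibus, pairwise = NULL)
}

compare_kruskal_dunn <- function(y, g, p_adjust) {
  kw <- stats::kruskal.test(y, g)
  omnibus <- tibble::tibble(statistic = unname(kw$statistic),
                            df1 = unname(kw$parameter), df2 = NA_integer_,
                            p_value = kw$p.value)
  # Dunn's z-tests on mean ranks with tie correction
  N <- length(y)
  rk <- rank(y)
  ties <- table(rk)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  lv <- levels(g)
  combs <- utils::combn(lv, 2)
  z <- p <- numeric(ncol(combs))
  for (k in seq_len(ncol(combs))) {
    i <- combs[1, k]; j <- combs[2, k]
    ni <- sum(g == i); nj <- sum(g == j)
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / ni + 1 / nj))
    z[k] <- (mean(rk[g == i]) - mean(rk[g == j])) / se
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  pairwise <- tibble::tibble(
    comparison = paste(combs[2, ], combs[1, ], sep = "-"),
    z = -z, p_value = p,
    p_adjusted = stats::p.adjust(p, method = p_adjust)
  )
  list(omnibus = omnibus, pairwise = pairwise)
}

#' @export
print.mq_group_compare <- function(x, ...) {
  cat(sprintf("<mq_group_compare> design: %s\n", x$design))
  print(x$omnibus)
  if (!is.null(x$pairwise)) print(x$pairwise)
  invisible(x)
}

#' Pluggable cluster-number hook
#'
#' Estimating the "optimal" number of clusters is outside the fitted
#' pipeline; this hook exposes a default average-silhouette criterion over
#' a dendrogram cut and accepts any replacement function
#' `(hclust, dist, k_range) -> k`.
#'
#' @param hc an `hclust` from [correlation_cluster()].
#' @param d the distance used to build it (recomputed from `hc` call if
#'   omitted is not possible, so pass it).
#' @param k_range candidate cluster counts.
#' @param method a function or `"silhouette"`.
#' @return The selected number of clusters.
#' @export
optimal_clusters <- function(hc, d, k_range = 2:6, method = "silhouette") {
  if (is.function(method)) return(method(hc, d, k_range))
  dm <- as.matrix(d)
  sil <- vapply(k_range, function(k) {
    cl <- stats::cutree(hc, k = k)
    if (length(unique(cl)) < 2L) return(-1)
    mean(vapply(seq_along(cl), function(i) {
      own <- cl == cl[i]; own[i] <- FALSE
      a <- if (any(own)) mean(dm[i, own]) else 0
      b <- min(vapply(setdiff(unique(cl), cl[i]), function(o)
        mean(dm[i, cl == o]), numeric(1)))
      if (max(a, b) == 0) 0 else (b - a) / max(a, b)
    }, numeric(1)))
  }, numeric(1))
  k_range[which.max(sil)]
}
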