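# proteomic screen statistics

toy_matrix <- function(values, groups, ...) {
  abundance_matrix(values, groups, ...)
}

test_that("zero imputation uses half the global positive minimum and is idempotent", {
  v <- rbind(c(10, 0, 40), c(20, 30, 0))
  m <- toy_matrix(v, c("a", "a", "b"))
  im <- impute_zeros(m)
  expect_equal(im$values[1, 2], 5)
  expect_equal(im$values[2, 3], 5)
  expect_identical(impute_zeros(im)$values, im$values)
  # provenance flags untouched
  expect_equal(im$original_zero, v == 0, ignore_attr = TRUE)
  # no zeros: unchanged
  m2 <- toy_matrix(v + 1, c("a", "a", "b"))
  expect_identical(impute_zeros(m2)$values, m2$values)
  expect_error(impute_zeros(toy_matrix(matrix(0, 2, 2), c("a", "b"))), "all-zero")
})

test_that("the group-zero filter uses pre-imputation zeros per group", {
  groups <- rep(c("a", "b"), each = 5)
  v <- matrix(100, 3, 10)
  v[1, 1:3] <- 0          # 3 zeros in group a: dropped
  v[2, c(1, 2, 6, 7)] <- 0 # 2 zeros in each group: kept
  m <- toy_matrix(v, groups)
  f <- filter_group_zeros(m)
  expect_setequal(f$protein_ids, c("protein_0002", "protein_0003"))
  # imputation first must not rescue the filtered protein
  f2 <- filter_group_zeros(impute_zeros(m))
  expect_identical(f2$protein_ids, f$protein_ids)
})

test_that("EIC normalization makes every sample sum to one", {
  v <- cbind(c(2, 3, 5), c(1, 1, 2))
  m <- eic_normalize(toy_matrix(v, c("a", "b")))
  expect_equal(m$values[, 1], c(0.2, 0.3, 0.5), ignore_attr = TRUE)
  expect_equal(unname(colSums(m$values)), c(1, 1), tolerance = 1e-12)
  one <- toy_matrix(matrix(c(7, 3), 1, 2), c("a", "b"))
  expect_equal(unname(eic_normalize(one)$values[1, ]), c(1, 1))
  zero_col <- toy_matrix(cbind(c(1, 2), c(0, 0)), c("a", "b"))
  expect_error(eic_normalize(zero_col), "positive total")
})

test_that("differential reproduces the closed-form Welch example", {
  v <- rbind(c(1, 2, 3, 2, 3, 4),
             c(5, 5, 5, 5, 5, 5))
  m <- toy_matrix(v, rep(c("a", "b"), each = 3))
  d <- differential(m, "a", "b", min_obs = 3)
  i <- which(d$protein_id == "protein_0001")
  expect_equal(d$t_statistic[i], -1.224745, tolerance = 1e-6)
  expect_equal(d$df[i], 4, tolerance = 1e-9)
  expect_equal(d$p_value[i], 0.2878641, tolerance = 1e-6)
  expect_equal(d$p_value[i], brute_welch_p(c(1, 2, 3), c(2, 3, 4)), tolerance = 1e-12)
  # identical constant groups: log2 0, p 1 by convention, not significant
  j <- which(d$protein_id == "protein_0002")
  expect_equal(d$log2_ratio[j], 0)
  expect_equal(d$p_value[j], 1)
  expect_false(d$significant[j])
})

test_that("uniquely observed proteins get the +/-10 sentinel", {
  v <- rbind(c(8, 9, 10, 0, 0, 0),
             c(0, 0, 0, 8, 9, 10),
             c(8, 9, 10, 9, 10, 11))
  m <- impute_zeros(toy_matrix(v, rep(c("a", "b"), each = 3)))
  d <- differential(m, "a", "b", min_obs = 3)
  expect_equal(d$log2_ratio[d$protein_id == "protein_0001"], 10)
  expect_equal(d$log2_ratio[d$protein_id == "protein_0002"], -10)
  expect_equal(d$unique_to[d$protein_id == "protein_0001"], "a")
  expect_true(all(abs(d$log2_ratio) <= 10))
  # the sentinel alone triggers the significance call
  expect_true(d$significant[d$protein_id == "protein_0001"])
})

test_that("the min_obs rule excludes sparsely observed proteins", {
  v <- rbind(c(8, 0, 0, 0, 0, 0, 0, 0, 0, 0),
             c(8, 9, 10, 9, 8, 9, 10, 9, 8, 9))
  m <- impute_zeros(toy_matrix(v, rep(c("a", "b"), each = 5)))
  d <- differential(m, "a", "b", min_obs = 3)
  expect_false("protein_0001" %in% d$protein_id)
  expect_equal(attr(d, "settings")$n_excluded, 1)
})

test_that("q-values match the brute-force BH computation", {
  expect_equal(qvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(qvalues(1), 1)
  expect_equal(qvalues(0.2), 0.2)
  expect_equal(qvalues(rep(1, 5)), rep(1, 5))
  set.seed(21)
  for (i in 1:20) {
    p <- runif(50)^2
    q <- qvalues(p)
    expect_equal(q, brute_bh(p), tolerance = 1e-12)
    expect_true(all(q[order(p)] == cummax(q[order(p)])))  # monotone
    expect_true(all(q >= p))
  }
  expect_error(qvalues(c(0.5, 1.2)), "0, 1")
  # Storey variant scales BH down by pi0 <= 1
  set.seed(22)
  p <- c(runif(300)^3, runif(700))
  expect_true(all(qvalues(p, "storey") <= qvalues(p, "BH") + 1e-12))
})

test_that("correlation clustering matches the brute-force UPGMA oracle", {
  set.seed(13)
  base <- rnorm(30, 10, 2)
  v <- cbind(s1 = base + rnorm(30, 0, .1), s2 = base + rnorm(30, 0, .1),
             s3 = -base + rnorm(30, 0, .1), s4 = rnorm(30, 10, 2))
  v <- pmax(v - min(v) + 1, 0.01)
  m <- toy_matrix(v, c("g1", "g1", "g2", "g2"))
  hc <- correlation_cluster(m, standardize = FALSE)
  oracle <- brute_upgma(stats::as.dist(1 - cor(v)))
  expect_equal(sort(hc$height), sort(oracle$heights), tolerance = 1e-10)
  # first merge joins the two near-identical profiles
  expect_setequal(oracle$memberships[[1]], c(1, 2))
  first_pair <- which(stats::cutree(hc, h = hc$height[1] + 1e-9) ==
                        stats::cutree(hc, h = hc$height[1] + 1e-9)[1])
  expect_setequal(first_pair, c(1, 2))
  # near-identical profiles merge near 0; anticorrelated pair near 2
  d <- 1 - cor(v)
  expect_lt(d[1, 2], 0.01)
  expect_gt(d[1, 3], 1.98)
  # constant profile: undefined correlation
  vc <- v; vc[, 4] <- 5
  expect_error(correlation_cluster(toy_matrix(vc, c("g1", "g1", "g2", "g2")),
                                   standardize = FALSE),
               "constant")
  # standardization equalizes protein weight: one dominant protein must not
  # mask a broad signature carried by the others
  set.seed(14)
  broad <- matrix(rnorm(40 * 6, 10, 0.2), 40, 6)
  broad[1:20, 4:6] <- broad[1:20, 4:6] + 3  # signature on half the proteins
  dominant <- c(1e5, 1.2e5, 0.9e5, 1.05e5, 1.1e5, 0.95e5)
  vv <- pmax(rbind(dominant, broad), 0.01)
  ms <- toy_matrix(vv, rep(c("x", "y"), each = 3))
  cls <- stats::cutree(correlation_cluster(ms), k = 2)
  expect_length(unique(cls[1:3]), 1)
  expect_length(unique(cls[4:6]), 1)
  expect_false(cls[1] == cls[4])
})

test_that("dendrograms export as Newick", {
  g <- generate_abundance_matrix(abundance_gen_params(n_proteins = 50, seed = 2))
  hc <- correlation_cluster(impute_zeros(g$matrix))
  path <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(hc, path)
  tr <- ape::read.tree(path)
  expect_setequal(tr$tip.label, g$matrix$sample_ids)
})

test_that("random forest separates planted classes and stays honest on noise", {
  set.seed(10)
  n_feat <- 50
  mu_a <- 50; mu_b <- 60  # class means 10 sd apart (unit feature sd)
  va <- matrix(rnorm(n_feat * 5, mu_a, 1), n_feat, 5)
  vb <- matrix(rnorm(n_feat * 5, mu_b, 1), n_feat, 5)
  train <- toy_matrix(cbind(va, vb), rep(c("early", "late"), each = 5))
  held <- toy_matrix(cbind(matrix(rnorm(n_feat * 3, mu_a, 1), n_feat, 3),
                           matrix(rnorm(n_feat * 3, mu_b, 1), n_feat, 3)),
                     rep(c("early", "late"), each = 3))
  rep1 <- rf_stage_classify(train, held, n_trees = 1000, seed = 5)
  expect_true(all(rep1$scores$p_early[1:3] > 0.9))
  expect_true(all(rep1$scores$p_late[4:6] > 0.9))
  # probabilities sum to one
  expect_equal(rep1$scores$p_early + rep1$scores$p_late, rep(1, 6))
  # determinism
  rep2 <- rf_stage_classify(train, held, n_trees = 1000, seed = 5)
  expect_identical(rep1$scores, rep2$scores)
  # pure-noise features with permuted labels: mean probability near 0.5
  null_means <- vapply(1:20, function(s) {
    v <- matrix(rnorm(n_feat * 10, 50, 1), n_feat, 10)
    tn <- toy_matrix(v, sample(rep(c("early", "late"), each = 5)))
    r <- rf_stage_classify(tn, n_trees = 500, seed = s)
    mean(r$scores$p_early)
  }, numeric(1))
  expect_lt(abs(mean(null_means) - 0.5), 0.15)
  expect_error(rf_stage_classify(toy_matrix(va, rep("a", 5))), "2 classes")
})

test_that("group comparison reproduces the hand-computed examples", {
  d <- data.frame(y = c(1, 2, 3, 2, 3, 4, 5, 6, 7),
                  g = rep(c("a", "b", "c"), each = 3))
  res <- group_compare(d, "y", "g", design = "anova_tukey")
  expect_equal(res$omnibus$statistic, 13, tolerance = 1e-9)
  expect_equal(res$omnibus$df1, 2)
  expect_equal(res$omnibus$df2, 6)
  expect_equal(res$omnibus$p_value, pf(13, 2, 6, lower.tail = FALSE),
               tolerance = 1e-9)
  expect_equal(res$omnibus$p_value, 0.00663, tolerance = 1e-2)
  expect_equal(nrow(res$pairwise), 3)
  # identical observations: F = 0, p = 1
  d0 <- data.frame(y = rep(5, 9), g = rep(c("a", "b", "c"), each = 3))
  res0 <- group_compare(d0, "y", "g", design = "anova_tukey")
  expect_equal(res0$omnibus$statistic, 0)
  expect_equal(res0$omnibus$p_value, 1)
  # Wilcoxon (1,2) vs (3,4): exact two-sided p = 1/3
  dw <- data.frame(y = c(1, 2, 3, 4), g = c("a", "a", "b", "b"))
  rw <- group_compare(dw, "y", "g", design = "wilcoxon")
  expect_equal(rw$omnibus$p_value, 1 / 3, tolerance = 1e-12)
})

test_that("Kruskal-Wallis plus Dunn agrees with the base test and z formula", {
  set.seed(17)
  d <- data.frame(y = c(rnorm(6), rnorm(6, 2), rnorm(6, 4)),
                  g = rep(c("a", "b", "c"), each = 6))
  res <- group_compare(d, "y", "g", design = "kruskal_dunn")
  kw <- kruskal.test(d$y, factor(d$g))
  expect_equal(res$omnibus$statistic, unname(kw$statistic))
  expect_equal(res$omnibus$p_value, kw$p.value)
  # hand-checked Dunn z for the a-b pair (no ties)
  rk <- rank(d$y); N <- 18
  se <- sqrt((N * (N + 1) / 12) * (1 / 6 + 1 / 6))
  z_ab <- (mean(rk[d$g == "b"]) - mean(rk[d$g == "a"])) / se
  expect_equal(res$pairwise$z[res$pairwise$comparison == "b-a"], z_ab,
               tolerance = 1e-10)
  expect_equal(nrow(res$pairwise), 3)
})

test_that("tidiers expose results in broom style", {
  g <- generate_abundance_matrix(abundance_gen_params(
    n_proteins = 60, groups = list(c("a", 5), c("b", 5)),
    planted_effects = list(list(3, c("a", "b"), 6)), seed = 2))
  d <- differential(impute_zeros(g$matrix), "b", "a")
  gl <- glance(d)
  expect_equal(gl$n_tested, nrow(d))
  expect_equal(gl$n_significant, sum(d$significant))
  expect_s3_class(tidy(g$matrix), "tbl_df")
  expect_equal(nrow(tidy(g$matrix)), 600)
  rf <- rf_stage_classify(impute_zeros(g$matrix), n_trees = 200, seed = 1)
  td <- tidy(rf)
  expect_true(all(c("sample_id", "class", "probability") %in% names(td)))
  expect_s3_class(autoplot(d), "ggplot")
  expect_s3_class(autoplot(rf), "ggplot")
})
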