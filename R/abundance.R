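#' Protein abundance matrices with sample groups and zero provenance
#'
#' Container for a label-free proteomics ion-intensity table: proteins in
#' rows, samples in columns, a group label per sample, and an
#' `original_zero` flag matrix recording which entries were zero *before*
#' any imputation. Downstream filters that reason about "initially had zero
#' intensity" always consult this flag, never the (possibly imputed) values.
#'
#' @param values numeric proteins x samples matrix, non-negative.
#' @param group_labels character/factor of length `ncol(values)`.
#' @param protein_ids,sample_ids row / column identifiers; defaults are
#'   taken from dimnames or generated.
#' @param original_zero logical matrix flagging pre-imputation zeros;
#'   defaults to `values == 0`.
#' @return An `abundance_matrix` object.
#' @export
abundance_matrix <- function(values, group_labels,
                             protein_ids = NULL, sample_ids = NULL,
                             original_zero = NULL) {
  values <- as.matrix(values)
  if (any(!is.finite(values)) || any(values < 0))
    abort("`values` must be finite and non-negative")
  if (length(group_labels) != ncol(values))
    abort("`group_labels` must have one entry per sample (column)")
  if (is.null(protein_ids))
    protein_ids <- rownames(values) %||% sprintf("protein_%04d", seq_len(nrow(values)))
  if (is.null(sample_ids))
    sample_ids <- colnames(values) %||% sprintf("sample_%02d", seq_len(ncol(values)))
  if (is.null(original_zero)) original_zero <- values == 0
  stopifnot(identical(dim(original_zero), dim(values)),
            length(protein_ids) == nrow(values),
            length(sample_ids) == ncol(values))
  dimnames(values) <- list(protein_ids, sample_ids)
  dimnames(original_zero) <- dimnames(values)
  structure(list(values = values,
                 protein_ids = as.character(protein_ids),
                 sample_ids = as.character(sample_ids),
                 group_labels = as.character(group_labels),
                 original_zero = original_zero),
            class = "abundance_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("<abundance_matrix> %d proteins x %d samples; groups: %s; %d original zeros\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$group_labels), collapse = ", "),
              sum(x$original_zero)))
  invisible(x)
}

#' @describeIn abundance_matrix long-format view: one row per
#'   protein x sample with value, group and the original-zero flag.
#' @param x an `abundance_matrix`.
#' @param ... unused.
#' @export
tidy.abundance_matrix <- function(x, ...) {
  tibble::tibble(
    protein_id = rep(x$protein_ids, times = ncol(x$values)),
    sample_id = rep(x$sample_ids, each = nrow(x$values)),
    group = rep(x$group_labels, each = nrow(x$values)),
    value = as.vector(x$values),
    original_zero = as.vector(x$original_zero)
  )
}

#' Parameters for the synthetic abundance generator
#'
#' Emulates a label-free MS screen: per-protein baseline intensities are
#' log-normal (baseline log-means spread across proteins, replicate noise
#' within protein), planted fold-changes perturb chosen proteins in chosen
#' groups, and a dropout process replaces entries by exact zeros, mimicking
#' proteins falling below detection. The default design is the study-style
#' 3 groups x 5 samples.
#'
#' @param n_proteins number of proteins.
#' @param groups list of `(label, n_samples)` pairs, e.g.
#'   `list(c("wt4wk", 5), c("wt5wk", 5), c("mut5wk", 5))`.
#' @param log_mean mean of per-protein baseline natural-log intensity.
#' @param protein_sd SD of baseline log intensity across proteins.
#' @param log_sd replicate-to-replicate SD on the natural-log scale
#'   (0.15, a ~15% CV, typical of label-free technical replicates; kept
#'   modest so that raw-scale Welch tests on null data stay calibrated at
#'   n = 5, a stated contract of this generator).
#' @param planted_effects list of `list(protein, group_pair, fold_change)`;
#'   the fold is applied multiplicatively to the *second* group of the pair
#'   (the first stays at baseline).
#' @param dropout_prob probability an entry is zeroed (in `[0, 1)`).
#' @param seed RNG seed.
#' @export
abundance_gen_params <- function(n_proteins = 800L,
                                 groups = list(c("wt4wk", 5), c("wt5wk", 5), c("mut5wk", 5)),
                                 log_mean = 18,
                                 protein_sd = 1.5,
                                 log_sd = 0.15,
                                 planted_effects = list(),
                                 dropout_prob = 0.05,
                                 seed = 1L) {
  n_proteins <- as.integer(n_proteins)
  if (n_proteins < 1L) abort("`n_proteins` must be >= 1")
  if (dropout_prob < 0 || dropout_prob >= 1)
    abort("`dropout_prob` must be in [0, 1)")
  groups <- lapply(groups, function(g) list(label = as.character(g[[1]]),
                                            n_samples = as.integer(g[[2]])))
  labels <- vapply(groups, `[[`, character(1), "label")
  planted_effects <- lapply(planted_effects, function(e) {
    e <- as.list(e)
    names(e) <- c("protein", "group_pair", "fold_change")[seq_along(e)]
    if (as.numeric(e$fold_change) <= 0) abort("`fold_change` must be > 0")
    if (!all(e$group_pair %in% labels))
      abort("planted effect refers to an unknown group label")
    tgt <- groups[[match(e$group_pair[2], labels)]]
    if (tgt$n_samples < 2L)
      abort("effects cannot be planted on a group with fewer than 2 samples")
    e
  })
  structure(list(n_proteins = n_proteins, groups = groups, log_mean = log_mean,
                 protein_sd = protein_sd, log_sd = log_sd,
                 planted_effects = planted_effects,
                 dropout_prob = dropout_prob, seed = as.integer(seed)),
            class = "abundance_gen_params")
}

#' Generate a synthetic zero-inflated log-normal abundance matrix
#'
#' @param params an [abundance_gen_params()] object.
#' @return List with `matrix` (an [abundance_matrix()]) and `truth`
#'   (tibble of planted effects: `protein_id`, `group_a`, `group_b`,
#'   `fold_change`, and `true_log2_ratio` = log2 fold of group_b over
#'   group_a).
#' @examples
#' g <- generate_abundance_matrix(abundance_gen_params(n_proteins = 50))
#' g$matrix
#' @export
generate_abundance_matrix <- function(params) {
  stopifnot(inherits(params, "abundance_gen_params"))
  p <- params
  with_seed(p$seed, {
    labels <- vapply(p$groups, `[[`, character(1), "label")
    ns <- vapply(p$groups, `[[`, integer(1), "n_samples")
    group_labels <- rep(labels, times = ns)
    n_s <- sum(ns)
    base_log <- stats::rnorm(p$n_proteins, p$log_mean, p$protein_sd)
    logv <- matrix(stats::rnorm(p$n_proteins * n_s, 0, p$log_sd),
                   p$n_proteins, n_s) + base_log
    for (e in p$planted_effects) {
      cols <- which(group_labels == e$group_pair[2])
      logv[e$protein, cols] <- logv[e$protein, cols] + log(as.numeric(e$fold_change))
    }
    values <- exp(logv)
    if (p$dropout_prob > 0) {
      drop <- matrix(stats::runif(length(values)) < p$dropout_prob,
                     p$n_proteins, n_s)
      values[drop] <- 0
    }
    m <- abundance_matrix(values, group_labels,
                          protein_ids = sprintf("protein_%04d", seq_len(p$n_proteins)),
                          sample_ids = sprintf("%s_r%d", group_labels,
                                               unlist(lapply(ns, seq_len))))
    truth <- tibble::tibble(
      protein_id = vapply(p$planted_effects, function(e)
        m$protein_ids[as.integer(e$protein)], character(1)),
      group_a = vapply(p$planted_effects, function(e) e$group_pair[1], character(1)),
      group_b = vapply(p$planted_effects, function(e) e$group_pair[2], character(1)),
      fold_change = vapply(p$planted_effects, function(e)
        as.numeric(e$fold_change), numeric(1)),
      true_log2_ratio = log2(fold_change)
    )
    list(matrix = m, truth = truth)
  })
}

#' Read and write abundance matrices as TSV plus a JSON group map
#'
#' The TSV has protein IDs in the first column and one column per sample;
#' the sidecar JSON maps sample IDs to group labels.
#'
#' @param m an [abundance_matrix()].
#' @param path TSV path; the JSON sidecar is `<path>.groups.json`.
#' @return `write_abundance_tsv()` returns `path` invisibly;
#'   `read_abundance_tsv()` returns an [abundance_matrix()].
#' @export
write_abundance_tsv <- function(m, path) {
  df <- data.frame(protein_id = m$protein_ids, m$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(as.list(stats::setNames(m$group_labels, m$sample_ids)),
                       paste0(path, ".groups.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_abundance_tsv
#' @export
read_abundance_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  groups <- jsonlite::read_json(paste0(path, ".groups.json"), simplifyVector = TRUE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  abundance_matrix(vals, group_labels = unlist(groups[colnames(vals)]),
                   protein_ids = df[[1]], sample_ids = colnames(vals))
}
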