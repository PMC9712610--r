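# Differential expression (dual-rule DEP caller), unsupervised clustering
# and PCA, and gene-set aggregate scores.

#' Call differentially expressed proteins between two populations
#'
#' Dual rule. Rule 1 (`fc_p`), for genes detected in both groups: linear
#' fold change of group means at least `fold` and two-sided Student's t
#' test on log10 copies below `alpha` (at least 2 detected replicates per
#' group). Rule 2 (`presence_cv`), for genes where a fold change or p-value
#' cannot be formed: detected in every replicate of one group with
#' coefficient of variation at most `cv_max`, and in zero replicates of the
#' other. All other genes are not called. No multiple-testing correction is
#' applied to the calls (the fold-change gate makes the caller
#' conservative); a BH-adjusted column is emitted for transparency.
#'
#' @param copies Sample-level `expr_mat` with unit `"copies_per_cell"`.
#' @param design Sample design for `copies`.
#' @param group_a,group_b Population labels (must differ).
#' @param fold Fold-change threshold; default 5.
#' @param alpha p-value threshold; default 0.05.
#' @param cv_max CV ceiling for the presence rule; default 0.6.
#' @return A tibble with `gene`, `mean_a`, `mean_b`, `fold_change`
#'   (linear, A over B), `p`, `p_bh`, `reason` (`fc_p` / `presence_cv`),
#'   `direction` (`up_in_a` / `up_in_b`), restricted to called genes.
#' @export
call_deps <- function(copies, design, group_a, group_b, fold = 5,
                      alpha = 0.05, cv_max = 0.6) {
  require_unit(copies, "copies_per_cell")
  if (identical(group_a, group_b)) abort("groups must differ.")
  sa <- design$sample[design$population == group_a]
  sb <- design$sample[design$population == group_b]
  if (length(sa) < 2 || length(sb) < 2) {
    abort("each group needs at least 2 replicates.")
  }
  m <- em_values(copies)
  A <- m[, sa, drop = FALSE]
  B <- m[, sb, drop = FALSE]
  na_det <- rowSums(!is.na(A)); nb_det <- rowSums(!is.na(B))
  mean_a <- rowMeans(A, na.rm = TRUE); mean_b <- rowMeans(B, na.rm = TRUE)

  rows <- purrr::map(seq_len(nrow(m)), function(i) {
    a <- A[i, ][!is.na(A[i, ])]
    b <- B[i, ][!is.na(B[i, ])]
    if (length(a) >= 2 && length(b) >= 2) {
      fc <- mean(a) / mean(b)
      if (sd(log10(a)) == 0 && sd(log10(b)) == 0) return(NULL)
      p <- t.test(log10(a), log10(b))$p.value
      if (max(fc, 1 / fc) >= fold && p < alpha) {
        return(tibble(gene = rownames(m)[i], mean_a = mean(a),
                      mean_b = mean(b), fold_change = fc, p = p,
                      reason = "fc_p",
                      direction = if (fc >= 1) "up_in_a" else "up_in_b"))
      }
      return(NULL)
    }
    # presence rule: all replicates in one group, none in the other
    if (length(a) == ncol(A) && length(b) == 0L) {
      cv <- sd(a) / mean(a)
      if (cv <= cv_max) {
        return(tibble(gene = rownames(m)[i], mean_a = mean(a),
                      mean_b = NA_real_, fold_change = NA_real_,
                      p = NA_real_, reason = "presence_cv",
                      direction = "up_in_a"))
      }
    }
    if (length(b) == ncol(B) && length(a) == 0L) {
      cv <- sd(b) / mean(b)
      if (cv <= cv_max) {
        return(tibble(gene = rownames(m)[i], mean_a = NA_real_,
                      mean_b = mean(b), fold_change = NA_real_,
                      p = NA_real_, reason = "presence_cv",
                      direction = "up_in_b"))
      }
    }
    NULL
  })
  out <- bind_rows(rows)
  if (!nrow(out)) {
    return(tibble(gene = character(), mean_a = numeric(), mean_b = numeric(),
                  fold_change = numeric(), p = numeric(), p_bh = numeric(),
                  reason = character(), direction = character()))
  }
  out$p_bh <- stats::p.adjust(out$p, "BH")
  out[c("gene", "mean_a", "mean_b", "fold_change", "p", "p_bh",
        "reason", "direction")]
}

# clustering/PCA contract: log10(x + 1), missing -> 0 (distances need
# complete vectors); never applied to testing
cluster_prep <- function(x) {
  m <- em_values(x)
  lm10 <- log10(m + 1)
  lm10[is.na(lm10)] <- 0
  lm10
}

#' Hierarchical clustering of samples
#'
#' Euclidean distance between sample columns of `log10(x + 1)` (missing
#' set to 0), complete-linkage agglomeration by default.
#'
#' @param x An `expr_mat` with at least 2 sample columns.
#' @param metric Distance metric passed to [stats::dist()]; default
#'   `"euclidean"`.
#' @param linkage Agglomeration method; default `"complete"`.
#' @param k Optional number of flat clusters to cut.
#' @return A list of class `sample_clustering`: `tree` (hclust),
#'   `distances` (dist), and `clusters` (named integer vector, if `k`).
#' @export
hierarchical_cluster <- function(x, metric = "euclidean",
                                 linkage = "complete", k = NULL) {
  stopifnot(is_expr_matrix(x))
  if (length(em_samples(x)) < 2) abort("need at least 2 samples to cluster.")
  prep <- cluster_prep(x)
  d <- dist(t(prep), method = metric)
  tree <- hclust(d, method = linkage)
  clusters <- if (!is.null(k)) cutree(tree, k = k) else NULL
  structure(list(tree = tree, distances = d, clusters = clusters),
            class = "sample_clustering")
}

#' PCA of samples
#'
#' Principal components of centred `log10(x + 1)` sample profiles (missing
#' set to 0). Coordinates are orthogonal and explained variances
#' non-increasing and summing to the total variance.
#'
#' @param x An `expr_mat` with at least 3 samples.
#' @return A list of class `sample_pca`: `coords` (tibble `sample`, `PC1`,
#'   `PC2`, ...), `var_explained` (fractions), `sdev`.
#' @export
pca_samples <- function(x) {
  stopifnot(is_expr_matrix(x))
  if (length(em_samples(x)) < 3) abort("need at least 3 samples for PCA.")
  prep <- cluster_prep(x)
  if (all(apply(prep, 1, sd) == 0)) abort("constant matrix; PCA undefined.")
  pc <- prcomp(t(prep), center = TRUE, scale. = FALSE)
  coords <- as_tibble(pc$x, rownames = "sample")
  structure(list(coords = coords,
                 var_explained = pc$sdev^2 / sum(pc$sdev^2),
                 sdev = pc$sdev),
            class = "sample_pca")
}

#' Aggregate gene-set score per sample
#'
#' Sum of copies over the detected members of a gene set, per sample
#' (e.g. total expression of chemokines and their receptors).
#'
#' @param x An `expr_mat`.
#' @param gene_set Character vector of member genes; must intersect the
#'   matrix rows.
#' @param design Optional sample design; if supplied, `population` is
#'   attached to the output.
#' @return A tibble with `sample`, `score` (and `population` when a design
#'   is given).
#' @export
geneset_score <- function(x, gene_set, design = NULL) {
  stopifnot(is_expr_matrix(x))
  members <- intersect(gene_set, em_genes(x))
  if (!length(members)) abort("gene set has no member in the matrix.")
  m <- em_values(x)[members, , drop = FALSE]
  out <- tibble(sample = colnames(m),
                score = unname(colSums(m, na.rm = TRUE)))
  if (!is.null(design)) {
    out <- left_join(out, design[c("sample", "population")], by = "sample")
  }
  out
}

#' Correlate two gene-set scores across population means
#'
#' Pearson correlation between the population-mean aggregate scores of two
#' gene sets (e.g. motility receptors vs pattern-recognition receptors
#' across paired resident/recruited populations).
#'
#' @inheritParams geneset_score
#' @param set_a,set_b Character vectors of member genes.
#' @param design Sample design mapping samples to populations.
#' @param populations Optional subset/order of populations; default all.
#' @return A list with `r` (Pearson correlation), `scores` (tibble
#'   `population`, `score_a`, `score_b`).
#' @export
geneset_cor <- function(x, set_a, set_b, design, populations = NULL) {
  sa <- geneset_score(x, set_a, design) %>%
    group_by(.data$population) %>%
    summarise(score_a = mean(.data$score), .groups = "drop")
  sb <- geneset_score(x, set_b, design) %>%
    group_by(.data$population) %>%
    summarise(score_b = mean(.data$score), .groups = "drop")
  sc <- inner_join(sa, sb, by = "population")
  if (!is.null(populations)) {
    sc <- sc[match(populations, sc$population), , drop = FALSE]
  }
  list(r = cor(sc$score_a, sc$score_b), scores = sc)
}
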