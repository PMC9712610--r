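# Hierarchical tissue -> cell crosstalk networks: tissue-specific ligands,
# ligand-receptor pairing, hypergeometric pathway-activation testing,
# TF -> target closure, and link counting.

#' Tissue-specific ligands
#'
#' A ligand is specific to a tissue when its expression there is at least
#' `fold` times its average level across all tissues (the focal tissue
#' included by default; non-detections count as 0 in the average). Ligands
#' absent from every tissue are skipped.
#'
#' @param tissue_matrix An `expr_mat` whose columns are tissues (any unit).
#' @param ligand_genes Character vector of ligand gene symbols.
#' @param fold Fold threshold; default 1.5.
#' @param include_self Include the focal tissue in the average (the
#'   default); `FALSE` for a leave-one-out average.
#' @return A tibble with `tissue`, `ligand`, `value`, `grand_mean`.
#' @export
tissue_specific_ligands <- function(tissue_matrix, ligand_genes, fold = 1.5,
                                    include_self = TRUE) {
  stopifnot(is_expr_matrix(tissue_matrix))
  if (length(em_samples(tissue_matrix)) < 2) abort("need at least 2 tissues.")
  m <- em_values(tissue_matrix)
  m[is.na(m)] <- 0
  lg <- intersect(ligand_genes, rownames(m))
  lg <- lg[rowSums(m[lg, , drop = FALSE]) > 0]
  tissues <- colnames(m)
  rows <- list()
  for (g in lg) {
    for (t in tissues) {
      ref <- if (include_self) m[g, ] else m[g, setdiff(tissues, t)]
      gm <- mean(ref)
      if (gm > 0 && m[g, t] >= fold * gm) {
        rows[[length(rows) + 1L]] <-
          tibble(tissue = t, ligand = g, value = m[g, t], grand_mean = gm)
      }
    }
  }
  out <- bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble(tissue = character(), ligand = character(),
                  value = numeric(), grand_mean = numeric())
  }
  out
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` items from a
#' universe of `N` containing `K` marked items.
#'
#' @param k Observed marked items among the draw.
#' @param K Marked items in the universe.
#' @param n Draw size.
#' @param N Universe size. Requires `0 <= k <= min(K, n) <= N`.
#' @return The upper-tail probability.
#' @examples
#' hypergeom_upper_tail(3, 4, 3, 10)  # 4/120
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || k > min(K, n) || K > N || n > N) {
    abort("inconsistent hypergeometric counts: need 0 <= k <= min(K, n) <= N.")
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Pathway activation for a tissue-cell pair
#'
#' A pathway is active when (a) it contains at least one receptor paired
#' with a tissue-specific ligand and detected in the cell, (b) it contains
#' at least one cell-type-specific TF, and (c) its intermediate nodes
#' (members minus ligand-tier genes) are enriched among the cell's detected
#' proteins: hypergeometric upper-tail p below `alpha`, with the cell's
#' quantified proteome as background `N`, `K` intermediates, `n` detected
#' proteins and `k` detected intermediates. Pathways with no intermediate
#' in the background are skipped with a message.
#'
#' @param pathways A `gene_sets` collection (e.g. [read_gmt()]).
#' @param detected Character vector of genes detected in the cell.
#' @param universe Character vector: all genes quantified in the cell (the
#'   background; `detected` must be a subset).
#' @param specific_tfs Character vector of cell-type-specific TFs.
#' @param receptors_hit Character vector of detected receptors paired with
#'   specific ligands.
#' @param ligand_genes Ligand-tier genes removed from pathway members when
#'   forming intermediates.
#' @param alpha Significance level on the raw p-value; default 0.05 (no
#'   multiple-testing correction; set `adjust = "BH"` to gate on adjusted
#'   p-values instead).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A tibble with `pathway`, `k`, `K`, `n`, `N`, `p`,
#'   `has_receptor`, `has_tf`, `active`.
#' @export
pathway_activation <- function(pathways, detected, universe, specific_tfs,
                               receptors_hit, ligand_genes = character(),
                               alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  detected <- intersect(detected, universe)
  N <- length(universe)
  n <- length(detected)
  rows <- purrr::map(names(pathways), function(nm) {
    members <- pathways[[nm]]
    inter <- setdiff(members, ligand_genes)
    K_set <- intersect(inter, universe)
    if (!length(K_set)) {
      inform(sprintf("pathway '%s' has no intermediate node in the background, skipped.",
                     nm))
      return(NULL)
    }
    k <- length(intersect(K_set, detected))
    tibble(pathway = nm, k = k, K = length(K_set), n = n, N = N,
           p = hypergeom_upper_tail(k, length(K_set), n, N),
           has_receptor = length(intersect(members, receptors_hit)) > 0,
           has_tf = length(intersect(members, specific_tfs)) > 0)
  })
  out <- bind_rows(rows)
  if (!nrow(out)) {
    return(tibble(pathway = character(), k = integer(), K = integer(),
                  n = integer(), N = integer(), p = numeric(),
                  has_receptor = logical(), has_tf = logical(),
                  active = logical()))
  }
  p_gate <- if (adjust == "BH") stats::p.adjust(out$p, "BH") else out$p
  out$active <- out$has_receptor & out$has_tf & p_gate < alpha
  out
}

#' Crosstalk-network parameters
#'
#' @param ligand_fold Tissue-specificity fold for ligands; default 1.5.
#' @param tf_fold Cell-specificity fold for TFs (vs. the average over all
#'   populations); default 1.5.
#' @param alpha Pathway-activation significance level; default 0.05.
#' @param min_detected Replicate detections required to call a gene
#'   detected in the cell; default 2.
#' @return A list of class `crosstalk_params`.
#' @export
crosstalk_params <- function(ligand_fold = 1.5, tf_fold = 1.5, alpha = 0.05,
                             min_detected = 2L) {
  structure(list(ligand_fold = ligand_fold, tf_fold = tf_fold,
                 alpha = alpha, min_detected = min_detected),
            class = "crosstalk_params")
}

# cell-type-specific genes by the fold-vs-average rule (NA -> 0)
fold_specific_genes <- function(pop_means, population, genes, fold) {
  m <- em_values(pop_means)
  m[is.na(m)] <- 0
  g <- intersect(genes, rownames(m))
  gm <- rowMeans(m[g, , drop = FALSE])
  val <- m[g, population]
  g[gm > 0 & val >= fold * gm]
}

#' Build the hierarchical crosstalk network for one tissue-cell pair
#'
#' Assembles the four-tier directed network tissue ligand -> cell receptor
#' -> TF (via an active pathway) -> target gene. Ligand->receptor edges
#' require a tissue-specific ligand paired (in `lr_pairs`) with a receptor
#' detected in the cell; receptor->TF edges require an active pathway (see
#' [pathway_activation()]) containing both; TF->target edges connect each
#' such TF to its regulon targets detected in the cell. The link count is
#' the number of edges.
#'
#' @param tissue_matrix `expr_mat` of tissue proteomes (columns = tissues).
#' @param cell_copies Sample-level `expr_mat` of cell populations with unit
#'   `"copies_per_cell"`.
#' @param cell_design Sample design for `cell_copies`.
#' @param tissue,population The pair to analyse.
#' @param lr_pairs Ligand-receptor tibble (`ligand`, `receptor`).
#' @param pathways A `gene_sets` collection.
#' @param regulons Regulon tibble (`tf`, `target`).
#' @param annotation Gene annotation (flags `is_ligand`, `is_receptor`,
#'   `is_tf`).
#' @param params A [crosstalk_params()].
#' @return A list of class `crosstalk_network`: `edges` (tibble `from`,
#'   `to`, `tier`, `pathway`, `p`), `nodes` (tibble `node`, `tier`),
#'   `pathways` (the activation table), `n_links`, `tissue`, `population`.
#'   No specific ligand yields an empty network, not an error.
#' @export
build_crosstalk_network <- function(tissue_matrix, cell_copies, cell_design,
                                    tissue, population, lr_pairs, pathways,
                                    regulons, annotation,
                                    params = crosstalk_params()) {
  stopifnot(inherits(params, "crosstalk_params"))
  require_unit(cell_copies, "copies_per_cell")
  ligand_genes <- annotation$gene[annotation$is_ligand]
  tf_genes <- annotation$gene[annotation$is_tf]

  tsl <- tissue_specific_ligands(tissue_matrix, ligand_genes,
                                 fold = params$ligand_fold)
  ligands_here <- tsl$ligand[tsl$tissue == tissue]

  det_counts <- detection_counts(cell_copies, cell_design)
  detected <- rownames(det_counts)[det_counts[, population] >= params$min_detected]
  universe <- em_genes(cell_copies)

  pm <- pool_replicates(cell_copies, cell_design)
  spec_tfs <- fold_specific_genes(pm, population, tf_genes, params$tf_fold)

  lr_hit <- lr_pairs[lr_pairs$ligand %in% ligands_here &
                     lr_pairs$receptor %in% detected, , drop = FALSE]
  receptors_hit <- unique(lr_hit$receptor)

  pw <- pathway_activation(pathways, detected, universe, spec_tfs,
                           receptors_hit, ligand_genes = ligand_genes,
                           alpha = params$alpha)

  edges <- list()
  if (nrow(lr_hit)) {
    edges[[1L]] <- tibble(from = lr_hit$ligand, to = lr_hit$receptor,
                          tier = "ligand_receptor", pathway = NA_character_,
                          p = NA_real_)
  }
  active <- pw[pw$active, , drop = FALSE]
  tf_nodes <- character()
  for (i in seq_len(nrow(active))) {
    nm <- active$pathway[i]
    members <- pathways[[nm]]
    recs <- intersect(receptors_hit, members)
    tfs <- intersect(spec_tfs, members)
    if (!length(recs) || !length(tfs)) next
    grid <- tidyr::expand_grid(from = recs, to = tfs)
    edges[[length(edges) + 1L]] <-
      tibble(from = grid$from, to = grid$to, tier = "receptor_tf",
             pathway = nm, p = active$p[i])
    tf_nodes <- union(tf_nodes, tfs)
  }
  for (tf in tf_nodes) {
    tg <- intersect(regulons$target[regulons$tf == tf], detected)
    if (length(tg)) {
      edges[[length(edges) + 1L]] <-
        tibble(from = tf, to = tg, tier = "tf_target",
               pathway = NA_character_, p = NA_real_)
    }
  }
  edges <- bind_rows(edges)
  if (!nrow(edges)) {
    edges <- tibble(from = character(), to = character(), tier = character(),
                    pathway = character(), p = numeric())
  }
  nodes <- bind_rows(
    tibble(node = unique(edges$from[edges$tier == "ligand_receptor"]),
           tier = "ligand"),
    tibble(node = unique(edges$to[edges$tier == "ligand_receptor"]),
           tier = "receptor"),
    tibble(node = unique(edges$to[edges$tier == "receptor_tf"]), tier = "tf"),
    tibble(node = unique(edges$to[edges$tier == "tf_target"]), tier = "target"))
  structure(list(edges = edges, nodes = nodes, pathways = pw,
                 n_links = nrow(edges), tissue = tissue,
                 population = population),
            class = "crosstalk_network")
}

#' @export
print.crosstalk_network <- function(x, ...) {
  cat(sprintf("# Crosstalk network %s -> %s: %d nodes, %d links\n",
              x$tissue, x$population, nrow(x$nodes), x$n_links))
  if (x$n_links) print(dplyr::count(x$edges, .data$tier))
  invisible(x)
}
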