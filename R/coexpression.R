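# Weighted co-expression module detection: soft-threshold selection by
# scale-free topology fit, topological-overlap similarity, average-linkage
# clustering with a static cut, module eigengenes, and module-trait /
# gene-significance / module-membership statistics.

# Shared preprocessing contract for the network stage: log10 transform with
# missing values kept explicit (correlations are pairwise-complete), genes
# present in too few samples or constant excluded.
wgcna_prep <- function(x, min_fraction_present = 0.25) {
  stopifnot(is_expr_matrix(x))
  m <- em_values(x)
  present <- rowMeans(!is.na(m))
  kept <- present >= min_fraction_present
  m <- m[kept, , drop = FALSE]
  lm10 <- log10(m)
  const <- apply(lm10, 1, sd, na.rm = TRUE) == 0
  const[is.na(const)] <- TRUE
  if (any(const)) {
    warn(sprintf("dropping %d constant gene row(s) from the network.",
                 sum(const)))
    lm10 <- lm10[!const, , drop = FALSE]
  }
  lm10
}

# pairwise-complete gene-gene correlation; residual NAs (no overlap) -> 0
wgcna_cor <- function(prep) {
  cc <- suppressWarnings(cor(t(prep), use = "pairwise.complete.obs"))
  cc[!is.finite(cc)] <- 0
  cc
}

adjacency_matrix <- function(prep, power, signed = FALSE) {
  cc <- wgcna_cor(prep)
  a <- if (signed) ((1 + cc) / 2)^power else abs(cc)^power
  diag(a) <- 0
  a
}

#' Pick the soft-threshold power
#'
#' For each candidate power, raise the absolute gene-gene correlation to
#' that power, compute per-gene connectivity `k_i = sum_j |cor_ij|^beta`,
#' and regress `log10 p(k)` on `log10 k` over connectivity bins. The signed
#' scale-free fit `R^2` (positive only when the slope is negative) decides:
#' the smallest candidate reaching `target_r2` is chosen, or the argmax with
#' a warning when none reaches it.
#'
#' @param x An `expr_mat` (copies per cell or any positive unit); values are
#'   log10-transformed, correlations are pairwise-complete over detected
#'   values, and genes present in under 25% of samples are excluded.
#' @param powers Candidate powers; default `1:20`.
#' @param target_r2 Scale-free fit target; default 0.85.
#' @param n_bins Connectivity histogram bins for the fit; default 10 (at
#'   least 8).
#' @param signed Use a signed network; default unsigned.
#' @return A list of class `soft_threshold` with elements `fits` (tibble:
#'   `power`, `r_squared`, `slope`, `mean_k`), `power` (chosen), and
#'   `reached_target`.
#' @export
pick_soft_threshold <- function(x, powers = 1:20, target_r2 = 0.85,
                                n_bins = 10L, signed = FALSE) {
  prep <- wgcna_prep(x)
  if (nrow(prep) < 50) abort("need at least 50 genes for the network stage.")
  if (ncol(prep) < 8) abort("need at least 8 samples for the network stage.")
  if (n_bins < 8) abort("use at least 8 connectivity bins.")
  cc <- wgcna_cor(prep)
  acc <- if (signed) (1 + cc) / 2 else abs(cc)
  diag(acc) <- 0
  fits <- purrr::map_dfr(powers, function(b) {
    k <- rowSums(acc^b)
    brk <- seq(min(k), max(k), length.out = n_bins + 1L)
    bin <- cut(k, brk, include.lowest = TRUE)
    pk <- tabulate(bin, nbins = n_bins) / length(k)
    km <- tapply(k, bin, mean)[levels(bin)]
    ok <- pk > 0 & !is.na(km) & km > 0
    if (sum(ok) < 3) {
      return(tibble(power = b, r_squared = NA_real_, slope = NA_real_,
                    mean_k = mean(k)))
    }
    fit <- stats::lm(log10(pk[ok]) ~ log10(km[ok]))
    slope <- unname(stats::coef(fit)[2L])
    r2 <- summary(fit)$r.squared
    tibble(power = b, r_squared = -sign(slope) * r2, slope = slope,
           mean_k = mean(k))
  })
  ok <- !is.na(fits$r_squared) & fits$r_squared >= target_r2
  if (any(ok)) {
    chosen <- fits$power[which(ok)[1L]]
    reached <- TRUE
  } else {
    warn(sprintf("no candidate power reaches scale-free R^2 = %.2f; using argmax.",
                 target_r2))
    chosen <- fits$power[which.max(fits$r_squared)]
    reached <- FALSE
  }
  structure(list(fits = fits, power = chosen, reached_target = reached,
                 target_r2 = target_r2),
            class = "soft_threshold")
}

#' @export
print.soft_threshold <- function(x, ...) {
  cat(sprintf("# Soft threshold: power %d (target R^2 %.2f %s)\n",
              x$power, x$target_r2,
              if (x$reached_target) "reached" else "NOT reached"))
  print(x$fits)
  invisible(x)
}

#' Topological overlap matrix
#'
#' `tom_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`, with
#' unit diagonal. Symmetric, values in `[0, 1]`.
#'
#' @param adjacency A symmetric adjacency matrix with zero diagonal.
#' @return The TOM similarity matrix.
#' @export
tom_similarity <- function(adjacency) {
  k <- rowSums(adjacency)
  num <- adjacency %*% adjacency + adjacency
  denom <- outer(k, k, pmin) + 1 - adjacency
  tom <- num / denom
  diag(tom) <- 1
  tom
}

#' Detect co-expression modules
#'
#' Builds the soft-thresholded (unsigned by default) adjacency, converts it
#' to topological-overlap dissimilarity `1 - TOM`, clusters genes by
#' average-linkage hierarchical clustering, and applies a static cut at a
#' fixed fraction of the dendrogram height. Clusters smaller than
#' `min_module_size` are merged into module 0 (unassigned); surviving
#' modules are renumbered by decreasing size.
#'
#' @inheritParams pick_soft_threshold
#' @param power Soft-threshold power (e.g. from [pick_soft_threshold()]).
#' @param min_module_size Minimum genes per module; default 30.
#' @param cut_fraction Static cut height as a fraction of the maximum merge
#'   height; default 0.995.
#' @return A list of class `module_assignment` with `assignment` (tibble:
#'   `gene`, `module`), `tree` (hclust), `power`, `n_modules`.
#' @export
detect_modules <- function(x, power, min_module_size = 30L,
                           cut_fraction = 0.995, signed = FALSE) {
  prep <- wgcna_prep(x)
  if (nrow(prep) < min_module_size) {
    return(structure(list(
      assignment = tibble(gene = rownames(prep), module = 0L),
      tree = NULL, power = power, n_modules = 0L),
      class = "module_assignment"))
  }
  a <- adjacency_matrix(prep, power, signed)
  tom <- tom_similarity(a)
  d <- 1 - tom
  tree <- hclust(stats::as.dist(d), method = "average")
  h <- cut_fraction * max(tree$height)
  raw <- cutree(tree, h = h)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_module_size]
  # a branch only counts as a module when it is internally tighter than
  # the cut that defined it: the loose background branch (mutually
  # uncorrelated genes coalescing just under the top of the tree) fails
  # this and stays unassigned, like WGCNA's grey module
  cohesive <- vapply(keep, function(cl) {
    idx <- which(raw == as.integer(cl))
    median(d[idx, idx][upper.tri(d[idx, idx])]) < h
  }, logical(1))
  keep <- keep[cohesive]
  module <- integer(length(raw))
  if (length(keep)) {
    keep <- keep[order(sizes[keep], decreasing = TRUE)]
    for (i in seq_along(keep)) module[raw == as.integer(keep[i])] <- i
  }
  structure(list(
    assignment = tibble(gene = rownames(prep), module = module),
    tree = tree, power = power, n_modules = length(keep)),
    class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  sz <- table(x$assignment$module[x$assignment$module > 0])
  cat(sprintf("# Module assignment: %d modules over %d genes (%d unassigned)\n",
              x$n_modules, nrow(x$assignment),
              sum(x$assignment$module == 0L)))
  if (length(sz)) {
    cat("  sizes:", paste(sz, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' member genes' standardized expression over samples, scaled to unit norm
#' and signed so the mean correlation with its members is positive. A
#' single-gene module's eigengene is that standardized gene.
#'
#' @inheritParams pick_soft_threshold
#' @param assignment A `module_assignment`.
#' @return A tibble with a `sample` column and one `ME<k>` column per
#'   module.
#' @export
module_eigengenes <- function(x, assignment) {
  stopifnot(inherits(assignment, "module_assignment"))
  prep <- wgcna_prep(x)
  asg <- assignment$assignment
  mods <- sort(unique(asg$module[asg$module > 0L]))
  out <- tibble(sample = colnames(prep))
  for (m in mods) {
    gs <- intersect(asg$gene[asg$module == m], rownames(prep))
    sub <- prep[gs, , drop = FALSE]
    z <- t(scale(t(sub)))
    z[!is.finite(z)] <- 0   # missing -> standardized mean
    e <- if (nrow(z) == 1L) drop(z) else svd(z, nu = 0, nv = 1)$v[, 1L]
    e <- e / sqrt(sum(e^2))
    if (mean(cor(e, t(sub), use = "pairwise.complete.obs"),
             na.rm = TRUE) < 0) e <- -e
    out[[paste0("ME", m)]] <- unname(e)
  }
  out
}

#' Module-trait statistics with GS/MM filtering
#'
#' Correlates each module eigengene with one indicator trait per population
#' (1 for that population's samples, 0 otherwise), matches each module to
#' its best-correlated population, and drops modules whose best correlation
#' falls below `cor_min`. For genes in surviving modules, gene significance
#' `GS = |cor(expression, matched trait)|` and module membership
#' `MM = |cor(expression, eigengene)|` are computed; genes passing both
#' `gs_min` and `mm_min` form the high-confidence list.
#'
#' @inheritParams module_eigengenes
#' @param design Sample design covering the matrix samples.
#' @param gs_min,mm_min,cor_min Filter cutoffs; defaults 0.6, 0.5, 0.5.
#' @return A list of class `module_stats`: `module_trait` (tibble `module`,
#'   `population`, `cor`, `kept`), `gene_stats` (tibble `gene`, `module`,
#'   `population`, `gs`, `mm`, `pass`), `high_confidence` (character).
#' @export
module_trait_stats <- function(x, assignment, design, gs_min = 0.6,
                               mm_min = 0.5, cor_min = 0.5) {
  stopifnot(inherits(assignment, "module_assignment"))
  prep <- wgcna_prep(x)
  design <- design[match(colnames(prep), design$sample), , drop = FALSE]
  pops <- unique(design$population)
  traits <- vapply(pops, function(p) as.numeric(design$population == p),
                   numeric(nrow(design)))
  if (any(apply(traits, 2, sd) == 0)) abort("degenerate population trait.")
  me <- module_eigengenes(x, assignment)
  mods <- as.integer(sub("^ME", "", setdiff(names(me), "sample")))
  mt <- purrr::map_dfr(mods, function(m) {
    cors <- drop(cor(me[[paste0("ME", m)]], traits))
    best <- which.max(cors)
    tibble(module = m, population = pops[best], cor = cors[best],
           kept = cors[best] >= cor_min)
  })
  asg <- assignment$assignment
  gene_stats <- purrr::map_dfr(mods[mt$kept], function(m) {
    gs_genes <- intersect(asg$gene[asg$module == m], rownames(prep))
    trait <- traits[, mt$population[mt$module == m]]
    e <- me[[paste0("ME", m)]]
    expr <- prep[gs_genes, , drop = FALSE]
    gs <- abs(drop(suppressWarnings(
      cor(t(expr), trait, use = "pairwise.complete.obs"))))
    mm <- abs(drop(suppressWarnings(
      cor(t(expr), e, use = "pairwise.complete.obs"))))
    tibble(gene = gs_genes, module = m,
           population = mt$population[mt$module == m],
           gs = unname(gs), mm = unname(mm),
           pass = gs >= gs_min & mm >= mm_min)
  })
  structure(list(module_trait = mt, gene_stats = gene_stats,
                 high_confidence = gene_stats$gene[gene_stats$pass],
                 gs_min = gs_min, mm_min = mm_min, cor_min = cor_min),
            class = "module_stats")
}

#' @export
print.module_stats <- function(x, ...) {
  cat(sprintf("# Module-trait stats: %d/%d modules kept, %d high-confidence genes\n",
              sum(x$module_trait$kept), nrow(x$module_trait),
              length(x$high_confidence)))
  print(x$module_trait)
  invisible(x)
}
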