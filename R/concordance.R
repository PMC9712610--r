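# Proteome-transcriptome concordance: missing-feature detection, the
# four-quadrant classification of never-detected genes, across-gene and
# gene-wise Spearman correlations. Gene-wise p-values at small n use the
# exact permutation null of Spearman's rho, computed once per n by dynamic
# programming and cached.

# -- exact Spearman permutation null ------------------------------------

.spearman_cache <- new.env(parent = emptyenv())

# Distribution of T = sum(i * pi(i)) over all permutations pi of 1..n,
# via a bitmask DP (feasible well past the n! enumeration limit).
# D = sum (i - pi(i))^2 = 2*sum(i^2) - 2T, rho = 1 - 6D / (n(n^2-1)).
spearman_null_distribution <- function(n) {
  key <- as.character(n)
  if (!is.null(.spearman_cache[[key]])) return(.spearman_cache[[key]])
  if (n < 2 || n > 14) abort("exact Spearman null supported for 2 <= n <= 14.")
  maxT <- sum((1:n)^2)
  nmask <- bitwShiftL(1L, n)
  popcount <- vapply(0:(nmask - 1L), function(m) {
    sum(bitwAnd(bitwShiftR(m, 0:(n - 1L)), 1L))
  }, integer(1))
  counts <- vector("list", nmask)
  counts[[1L]] <- c(1, numeric(maxT))
  for (mask in 1:(nmask - 1L)) {
    i <- popcount[mask + 1L]      # position being filled
    v <- numeric(maxT + 1L)
    for (j in 1:n) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(mask, bit) == 0L) next
      s <- i * j
      prev <- counts[[mask - bit + 1L]]
      idx <- seq_len(maxT + 1L - s)
      v[idx + s] <- v[idx + s] + prev[idx]
    }
    counts[[mask + 1L]] <- v
  }
  cnt <- counts[[nmask]]
  keep <- cnt > 0
  t_vals <- (0:maxT)[keep]
  d_vals <- 2 * sum((1:n)^2) - 2 * t_vals
  rho_vals <- 1 - 6 * d_vals / (n * (n^2 - 1))
  out <- list(rho = rho_vals, count = cnt[keep], total = factorial(n))
  .spearman_cache[[key]] <- out
  out
}

#' Exact two-sided permutation p-value for Spearman's rho
#'
#' For `n` untied observations the full permutation null of Spearman's rho
#' is computed exactly (all `n!` rank permutations, via dynamic programming)
#' and the two-sided tail probability `P(|rho_null| >= |rho|)` returned.
#' Large-sample approximations are poor at the atlas scale of ~12
#' populations; this gives the exact reference the `|r| > 0.57` operating
#' threshold is judged against.
#'
#' @param rho Observed Spearman correlation(s), in `[-1, 1]`.
#' @param n Number of paired observations (2 to 14, no ties assumed).
#' @return Numeric vector of two-sided p-values.
#' @examples
#' spearman_perm_pvalue(0.57, n = 12)
#' @export
spearman_perm_pvalue <- function(rho, n) {
  null <- spearman_null_distribution(n)
  vapply(rho, function(r) {
    sum(null$count[abs(null$rho) >= abs(r) - 1e-12]) / null$total
  }, numeric(1))
}

# -- missing features & quadrants ---------------------------------------

#' Detect missing proteins and missing transcripts
#'
#' A "missing protein" is a gene detected in at least one RNA sample but in
#' zero protein samples; a "missing transcript" is the symmetric case. A
#' gene absent as a row of a layer counts as never detected in that layer.
#'
#' @param protein,rna `expr_mat` objects for the two layers.
#' @return A list with character vectors `missing_protein` and
#'   `missing_transcript`.
#' @export
detect_missing_features <- function(protein, rna) {
  stopifnot(is_expr_matrix(protein), is_expr_matrix(rna))
  if (!length(intersect(em_genes(protein), em_genes(rna)))) {
    abort("protein and RNA layers share no genes.")
  }
  det_p <- rowSums(!is.na(em_values(protein))) > 0
  det_r <- rowSums(!is.na(em_values(rna))) > 0
  detected_p <- em_genes(protein)[det_p]
  detected_r <- em_genes(rna)[det_r]
  list(missing_protein = setdiff(detected_r, detected_p),
       missing_transcript = setdiff(detected_p, detected_r))
}

#' Four-quadrant classification of missing features
#'
#' For each gene of `genes`, compute its mean log10 expression over samples
#' where it is present in `source` (the *other* layer) and its
#' identification frequency (number of samples where present), then split on
#' two cutoffs: by default the median expression over the gene set and half
#' the number of samples. Ties (`>= cutoff`) count as "high". Regions:
#' R1 high expression / high frequency, R2 low/high, R3 low/low,
#' R4 high/low.
#'
#' @param genes Character vector of gene symbols (subset of `source` rows).
#'   An empty set returns an empty table.
#' @param source `expr_mat` of the layer in which the genes *are* detected.
#' @param expr_cutoff,freq_cutoff Numeric cutoffs; `NULL` (default) uses
#'   the median log10 expression and half the sample count.
#' @return A tibble with columns `gene`, `mean_log10_expr`, `frequency`,
#'   `region`.
#' @export
quadrant_classify <- function(genes, source, expr_cutoff = NULL,
                              freq_cutoff = NULL) {
  stopifnot(is_expr_matrix(source))
  if (!length(genes)) {
    return(tibble(gene = character(), mean_log10_expr = numeric(),
                  frequency = integer(), region = character()))
  }
  missing_rows <- setdiff(genes, em_genes(source))
  if (length(missing_rows)) {
    abort(sprintf("gene(s) not in source matrix: %s",
                  paste(head(missing_rows, 5), collapse = ", ")))
  }
  m <- em_values(source)[genes, , drop = FALSE]
  expr <- apply(m, 1, function(v) mean(log10(v[!is.na(v) & v > 0])))
  freq <- rowSums(!is.na(m))
  expr_cutoff <- expr_cutoff %||% median(expr, na.rm = TRUE)
  freq_cutoff <- freq_cutoff %||% (ncol(m) / 2)
  hi_e <- !is.na(expr) & expr >= expr_cutoff
  hi_f <- freq >= freq_cutoff
  region <- ifelse(hi_e & hi_f, "R1",
            ifelse(!hi_e & hi_f, "R2",
            ifelse(!hi_e & !hi_f, "R3", "R4")))
  tibble(gene = genes, mean_log10_expr = unname(expr),
         frequency = as.integer(unname(freq)), region = unname(region))
}

# -- correlations -------------------------------------------------------

#' Across-gene protein-RNA correlation per population
#'
#' Spearman correlation between log10 replicate-mean protein and mRNA
#' copies over genes co-present in a population. At least 10 co-quantified
#' genes are required.
#'
#' @param protein_copies,rna_copies `expr_mat` objects with unit
#'   `"copies_per_cell"` whose columns are populations (e.g. from
#'   [pool_replicates()]).
#' @param populations Populations to report; default all shared columns.
#' @return A tibble with `population`, `n_genes`, `rho`, `p`.
#' @export
across_gene_correlation <- function(protein_copies, rna_copies,
                                    populations = NULL) {
  require_unit(protein_copies, "copies_per_cell")
  require_unit(rna_copies, "copies_per_cell")
  p <- em_values(protein_copies)
  r <- em_values(rna_copies)
  pops <- populations %||% intersect(colnames(p), colnames(r))
  genes <- intersect(rownames(p), rownames(r))
  purrr::map_dfr(pops, function(pop) {
    x <- p[genes, pop]
    y <- r[genes, pop]
    ok <- !is.na(x) & !is.na(y) & x > 0 & y > 0
    if (sum(ok) < 10) {
      abort(sprintf("fewer than 10 co-present genes in population '%s'.", pop))
    }
    ct <- suppressWarnings(
      cor.test(log10(x[ok]), log10(y[ok]), method = "spearman"))
    tibble(population = pop, n_genes = sum(ok),
           rho = unname(ct$estimate), p = ct$p.value)
  })
}

#' Gene-wise RNA-to-protein correlation
#'
#' Per-gene Spearman correlation of replicate-mean protein vs mRNA copies
#' across populations, with an exact two-sided permutation p-value when the
#' number of populations is small (<= 14 and no rank ties; the asymptotic
#' t approximation is used otherwise). Genes are classed
#' `positive_significant` / `negative_significant` when `|rho|` exceeds
#' `r_threshold` and `p < alpha`, else `ns`. Genes co-quantified in fewer
#' than `min_populations` populations, or with a constant vector in either
#' layer, are excluded (a message reports the count).
#'
#' @inheritParams across_gene_correlation
#' @param r_threshold Correlation magnitude threshold; default 0.57.
#' @param alpha Significance level; default 0.05.
#' @param min_populations Coverage floor; default 5.
#' @return A tibble with `gene`, `n`, `rho`, `p`, `class`.
#' @export
genewise_correlation <- function(protein_copies, rna_copies,
                                 r_threshold = 0.57, alpha = 0.05,
                                 min_populations = 5L) {
  require_unit(protein_copies, "copies_per_cell")
  require_unit(rna_copies, "copies_per_cell")
  p <- em_values(protein_copies)
  r <- em_values(rna_copies)
  pops <- intersect(colnames(p), colnames(r))
  genes <- intersect(rownames(p), rownames(r))
  n_excluded <- 0L
  rows <- purrr::map(genes, function(g) {
    x <- p[g, pops]
    y <- r[g, pops]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (n < min_populations) {
      n_excluded <<- n_excluded + 1L
      return(NULL)
    }
    x <- x[ok]; y <- y[ok]
    if (sd(x) == 0 || sd(y) == 0) {
      n_excluded <<- n_excluded + 1L
      return(NULL)
    }
    rho <- cor(x, y, method = "spearman")
    ties <- anyDuplicated(x) || anyDuplicated(y)
    pval <- if (!ties && n <= 14) {
      spearman_perm_pvalue(rho, n)
    } else {
      suppressWarnings(cor.test(x, y, method = "spearman")$p.value)
    }
    tibble(gene = g, n = n, rho = rho, p = pval)
  })
  out <- bind_rows(rows)
  if (n_excluded > 0) {
    inform(sprintf("genewise_correlation: %d gene(s) excluded (coverage or constant vector).",
                   n_excluded))
  }
  if (!nrow(out)) {
    return(tibble(gene = character(), n = integer(), rho = numeric(),
                  p = numeric(), class = character()))
  }
  out$class <- ifelse(abs(out$rho) > r_threshold & out$p < alpha,
                      ifelse(out$rho > 0, "positive_significant",
                             "negative_significant"),
                      "ns")
  out
}
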