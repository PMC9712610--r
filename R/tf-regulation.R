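# Transcription-factor regulation: population-specific TF calling (5x
# median rule with optional module gating), the CSPS relative-entropy
# specificity score, and permutation-based cell-type-maintenance TF calls.

#' Call population-specific transcription factors
#'
#' A TF is specific to a population when its replicate-mean expression there
#' is at least `fold` times the median of its expression over the *other*
#' populations (leave-one-out; set `include_self = TRUE` to take the median
#' over all populations). Non-detections count as 0 in the median; the focal
#' mean requires detection in at least `min_detected` replicates. A TF
#' positive in the focal population with an all-zero background median is
#' specific; a TF at 0 against a 0 median is not. When `module_stats` is
#' supplied, the TF must additionally be a high-confidence member
#' (GS/MM-passing) of a module matched to that population.
#'
#' @param copies Sample-level `expr_mat` with unit `"copies_per_cell"`.
#' @param design Sample design for `copies`.
#' @param tf_genes Character vector of TF gene symbols (e.g. from the
#'   annotation's `is_tf` flag). TFs absent from the matrix are skipped with
#'   a message.
#' @param fold Specificity fold threshold; default 5.
#' @param module_stats Optional [module_trait_stats()] result for the
#'   module-membership gate.
#' @param include_self Include the focal population in the median.
#' @param min_detected Replicate-detection floor for the focal mean;
#'   default 2.
#' @return A tibble with `population`, `tf`, `mean_focal`, `median_others`.
#' @export
call_specific_tfs <- function(copies, design, tf_genes, fold = 5,
                              module_stats = NULL, include_self = FALSE,
                              min_detected = 2L) {
  require_unit(copies, "copies_per_cell")
  absent <- setdiff(tf_genes, em_genes(copies))
  if (length(absent)) {
    inform(sprintf("call_specific_tfs: %d TF(s) absent from the matrix, skipped.",
                   length(absent)))
  }
  tfs <- intersect(tf_genes, em_genes(copies))
  pm <- pool_replicates(copies, design, min_detected = min_detected)
  mval <- em_values(pm)[tfs, , drop = FALSE]
  mval0 <- mval
  mval0[is.na(mval0)] <- 0
  pops <- colnames(mval)
  rows <- list()
  for (tf in tfs) {
    for (c in pops) {
      focal <- mval[tf, c]
      if (is.na(focal) || focal <= 0) next
      ref <- if (include_self) mval0[tf, ] else mval0[tf, setdiff(pops, c)]
      med <- median(ref)
      ok <- if (med == 0) focal > 0 else focal >= fold * med
      if (ok) {
        rows[[length(rows) + 1L]] <-
          tibble(population = c, tf = tf, mean_focal = focal,
                 median_others = med)
      }
    }
  }
  out <- bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble(population = character(), tf = character(),
                  mean_focal = numeric(), median_others = numeric())
  }
  if (!is.null(module_stats)) {
    stopifnot(inherits(module_stats, "module_stats"))
    gs <- module_stats$gene_stats
    keep <- paste(gs$gene[gs$pass], gs$population[gs$pass])
    out <- out[paste(out$tf, out$population) %in% keep, , drop = FALSE]
  }
  out
}

#' Cell-specificity score (CSPS)
#'
#' Relative entropy (in bits) of a gene's fractional expression across
#' populations against the uniform null `q = 1/P`:
#' `CSPS = sum_j f_j log2(f_j / q)` with `0 * log(0) = 0`. The score is 0
#' for uniform expression and `log2(P)` for expression confined to a single
#' population.
#'
#' @param expression Non-negative expression vector over populations
#'   (`P >= 2`), e.g. replicate-mean copies; must not be all zero. `NA`
#'   counts as undetected (0).
#' @return A list of class `csps_result`: `f` (fractional expression), `q`,
#'   `csps` (bits), `n_populations`.
#' @examples
#' csps(c(5, rep(0, 11)))$csps    # log2(12) ~ 3.585
#' csps(rep(3, 12))$csps          # 0
#' @export
csps <- function(expression) {
  e <- as.numeric(expression)
  e[is.na(e)] <- 0
  if (length(e) < 2L) abort("CSPS needs at least 2 populations.")
  if (any(e < 0)) abort("negative expression in CSPS input.")
  if (all(e == 0)) abort("all-zero expression vector.")
  f <- e / sum(e)
  q <- 1 / length(e)
  # identical expression everywhere is uniform by definition: return an
  # exact 0 rather than the rounding residue of the normalization
  value <- if (all(e == e[1L])) 0 else {
    sum(ifelse(f > 0, f * log2(f / q), 0))
  }
  structure(list(f = f, q = q, csps = value,
                 n_populations = length(e)),
            class = "csps_result")
}

#' @export
print.csps_result <- function(x, ...) {
  cat(sprintf("# CSPS: %.4f bits over %d populations (max %.4f)\n",
              x$csps, x$n_populations, log2(x$n_populations)))
  invisible(x)
}

#' CSPS for every gene of a population-level matrix
#'
#' @param pop_means An `expr_mat` whose columns are populations (e.g. from
#'   [pool_replicates()]); `NA` counts as 0. All-zero genes get `NA`.
#' @return A tibble with `gene`, `csps`, `n_populations`.
#' @export
csps_scores <- function(pop_means) {
  stopifnot(is_expr_matrix(pop_means))
  m <- em_values(pop_means)
  m[is.na(m)] <- 0
  P <- ncol(m)
  tot <- rowSums(m)
  f <- m / tot
  terms <- ifelse(f > 0, f * log2(f * P), 0)
  val <- rowSums(terms)
  val[tot == 0] <- NA_real_
  tibble(gene = rownames(m), csps = unname(val), n_populations = P)
}

#' Call cell-type-maintenance TFs (ctmTFs)
#'
#' For each population-specific TF, score its regulon: per-gene z-scores of
#' log10 replicate-mean copies across populations, averaged over the TF's
#' detected target genes in the focal population. The observed score is
#' compared with `B` draws of equally many genes sampled uniformly without
#' replacement from all quantified proteins; the TF is called a ctmTF when
#' the observed score exceeds the maximum of all `B` null scores. An
#' empirical p-value `(1 + #{null >= observed}) / (B + 1)` is also reported.
#'
#' @param specific_tfs Tibble with `population`, `tf` (from
#'   [call_specific_tfs()]).
#' @param regulons Regulon tibble with `tf`, `target`.
#' @param copies Sample-level `expr_mat` with unit `"copies_per_cell"`.
#' @param design Sample design for `copies`.
#' @param B Number of null draws; default 1000.
#' @param seed Mandatory integer seed; the calls are reproducible given
#'   `(seed, B)`.
#' @param min_regulon Minimum detected targets; smaller regulons are
#'   skipped with a message.
#' @return A tibble with `tf`, `population`, `n_targets`, `observed`,
#'   `null_max`, `p`, `called`.
#' @export
call_ctmtfs <- function(specific_tfs, regulons, copies, design, B = 1000L,
                        seed, min_regulon = 3L) {
  if (missing(seed)) abort("`seed` is mandatory for ctmTF calling.")
  require_unit(copies, "copies_per_cell")
  if (B < 1) abort("B must be >= 1.")
  set.seed(seed)
  pm <- em_values(pool_replicates(copies, design))
  lx <- log10(pm)
  mu <- rowMeans(lx, na.rm = TRUE)
  sdv <- apply(lx, 1, sd, na.rm = TRUE)
  z <- (lx - mu) / sdv
  z[which(sdv == 0 | !is.finite(sdv)), ] <- NA_real_   # sd = 0 genes dropped
  rows <- purrr::pmap(specific_tfs[c("population", "tf")],
                      function(population, tf) {
    zc <- z[, population]
    pool <- which(!is.na(zc))
    targets <- intersect(regulons$target[regulons$tf == tf],
                         rownames(z)[pool])
    if (length(targets) < min_regulon) {
      inform(sprintf("ctmTF: regulon of %s has %d detected target(s) (< %d), skipped.",
                     tf, length(targets), min_regulon))
      return(NULL)
    }
    observed <- mean(zc[targets])
    null <- vapply(seq_len(B), function(b) {
      mean(zc[sample(pool, length(targets))])
    }, numeric(1))
    tibble(tf = tf, population = population,
           n_targets = length(targets), observed = observed,
           null_max = max(null),
           p = (1 + sum(null >= observed)) / (B + 1),
           called = observed > max(null))
  })
  out <- bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble(tf = character(), population = character(),
                  n_targets = integer(), observed = numeric(),
                  null_max = numeric(), p = numeric(), called = logical())
  }
  out
}
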