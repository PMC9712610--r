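# broom-style tidiers for the package's fitted/derived objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a soft-threshold report
#'
#' @param x A `soft_threshold`.
#' @param ... Unused.
#' @return The per-power fit tibble with a `chosen` flag.
#' @method tidy soft_threshold
#' @export
tidy.soft_threshold <- function(x, ...) {
  mutate(x$fits, chosen = .data$power == x$power)
}

#' @rdname tidy.soft_threshold
#' @method glance soft_threshold
#' @export
glance.soft_threshold <- function(x, ...) {
  tibble(power = x$power, target_r2 = x$target_r2,
         reached_target = x$reached_target,
         best_r2 = max(x$fits$r_squared, na.rm = TRUE))
}

#' Tidy a module assignment
#'
#' @param x A `module_assignment`.
#' @param ... Unused.
#' @return The gene/module tibble.
#' @method tidy module_assignment
#' @export
tidy.module_assignment <- function(x, ...) x$assignment

#' @rdname tidy.module_assignment
#' @method glance module_assignment
#' @export
glance.module_assignment <- function(x, ...) {
  asg <- x$assignment
  sz <- table(asg$module[asg$module > 0L])
  tibble(n_modules = x$n_modules, n_genes = nrow(asg),
         n_unassigned = sum(asg$module == 0L),
         min_size = if (length(sz)) min(sz) else NA_integer_,
         max_size = if (length(sz)) max(sz) else NA_integer_,
         power = x$power)
}

#' Tidy module-trait statistics
#'
#' @param x A `module_stats`.
#' @param ... Unused.
#' @return The per-gene GS/MM tibble.
#' @method tidy module_stats
#' @export
tidy.module_stats <- function(x, ...) x$gene_stats

#' @rdname tidy.module_stats
#' @method glance module_stats
#' @export
glance.module_stats <- function(x, ...) {
  tibble(n_modules_kept = sum(x$module_trait$kept),
         n_modules = nrow(x$module_trait),
         n_high_confidence = length(x$high_confidence),
         gs_min = x$gs_min, mm_min = x$mm_min, cor_min = x$cor_min)
}

#' Tidy a CSPS result
#'
#' @param x A `csps_result`.
#' @param ... Unused.
#' @return A tibble with one row per population: `population` index,
#'   `f` (fractional expression), `q`.
#' @method tidy csps_result
#' @export
tidy.csps_result <- function(x, ...) {
  tibble(population = seq_len(x$n_populations), f = x$f, q = x$q)
}

#' @rdname tidy.csps_result
#' @method glance csps_result
#' @export
glance.csps_result <- function(x, ...) {
  tibble(csps = x$csps, n_populations = x$n_populations,
         max_csps = log2(x$n_populations))
}

#' Tidy a sample PCA
#'
#' @param x A `sample_pca`.
#' @param ... Unused.
#' @return The sample-coordinate tibble.
#' @method tidy sample_pca
#' @export
tidy.sample_pca <- function(x, ...) x$coords

#' @rdname tidy.sample_pca
#' @method glance sample_pca
#' @export
glance.sample_pca <- function(x, ...) {
  tibble(n_components = length(x$var_explained),
         pc1_var = x$var_explained[1L],
         pc2_var = if (length(x$var_explained) > 1) x$var_explained[2L] else NA_real_)
}

#' Tidy a crosstalk network
#'
#' @param x A `crosstalk_network`.
#' @param ... Unused.
#' @return The edge tibble.
#' @method tidy crosstalk_network
#' @export
tidy.crosstalk_network <- function(x, ...) x$edges

#' @rdname tidy.crosstalk_network
#' @method glance crosstalk_network
#' @export
glance.crosstalk_network <- function(x, ...) {
  tibble(tissue = x$tissue, population = x$population,
         n_links = x$n_links, n_nodes = nrow(x$nodes),
         n_active_pathways = sum(x$pathways$active))
}
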