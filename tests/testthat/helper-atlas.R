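# Shared fixtures, built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# default study-condition atlas (12 pops x 3 reps, CV 0.2, logistic missingness)
default_bundle <- function() {
  cached("default", generate_atlas(atlas_config(seed = 11L)))
}

# noiseless, fully detected atlas for invertibility checks
noiseless_bundle <- function() {
  cached("noiseless",
         generate_atlas(atlas_config(seed = 21L, noise_cv = 0,
                                     detection = "complete")))
}

# replicate noise but complete detection: clustering-friendly conditions
complete_bundle <- function() {
  cached("complete",
         generate_atlas(atlas_config(seed = 12L, detection = "complete")))
}

# small, fast atlas for plumbing tests
small_bundle <- function() {
  cached("small",
         generate_atlas(atlas_config(
           seed = 31L, n_populations = 6L, n_genes = 400L, n_modules = 2L,
           module_size = 40L, n_ribosomal = 20L, n_tissues = 4L,
           n_decoy_tfs = 4L, pathway_intermediates = 10L)))
}

protein_copies_of <- function(bundle) {
  key <- paste0("copies_", rlang::hash(bundle$truth$config))
  cached(key, proteomic_ruler(bundle$protein_ibaq, bundle$annotation,
                              ruler_params(dna_mass_per_cell =
                                             bundle$truth$dna_mass_per_cell)))
}

protein_design_of <- function(bundle) {
  bundle$design[bundle$design$layer == "protein", , drop = FALSE]
}

# tiny expression matrix builder for hand toys
toy_matrix <- function(values, genes, samples, unit = "copies_per_cell") {
  m <- matrix(values, nrow = length(genes), byrow = TRUE,
              dimnames = list(genes, samples))
  as_expr_matrix(m, unit = unit)
}

# hand-constructed crosstalk inputs: one tissue-specific ligand, one
# detected receptor, one pathway carrying the receptor + a kupffer-specific
# TF + a detected intermediate, and a regulon with two detected targets
crosstalk_toy <- function() {
  tissues <- c("liver", "lung")
  tv <- rbind(L1 = c(100, 1))
  colnames(tv) <- tissues
  pops <- c("kupffer", "alveolar")
  samples <- as.vector(outer(pops, 1:2, paste, sep = "_r"))
  design <- tibble::tibble(sample = samples, population = rep(pops, 2),
                           replicate = rep(1:2, each = 2), layer = "protein",
                           tissue = NA_character_)
  cm <- rbind(
    R1  = c(1e4, 1e4, 1e4, 1e4),
    TF1 = c(1e5, 1e2, 1e5, 1e2),
    T1  = c(1e4, 1e4, 1e4, 1e4),
    T2  = c(1e4, 1e4, 1e4, 1e4),
    B1  = c(1e3, 1e3, 1e3, 1e3),
    B2  = c(NA,  1e3, NA,  1e3))
  bg <- matrix(rep(c(NA, 1e3, NA, 1e3), 30), nrow = 30, byrow = TRUE,
               dimnames = list(sprintf("BG%02d", 1:30), NULL))
  cm <- rbind(cm, bg)
  colnames(cm) <- samples
  list(
    tissue_matrix = as_expr_matrix(tv, "fot"),
    cell = as_expr_matrix(cm, "copies_per_cell"),
    cell_flat_tf = {
      cm2 <- cm; cm2["TF1", ] <- 1e3
      as_expr_matrix(cm2, "copies_per_cell")
    },
    design = design,
    lr = tibble::tibble(ligand = "L1", receptor = "R1", source = "toy"),
    annotation = tibble::tibble(
      gene = c("L1", rownames(cm)),
      molecular_weight = 3e4, theoretical_peptides = 10L,
      is_histone = FALSE, is_ribosomal = FALSE,
      is_tf = c("L1", rownames(cm)) == "TF1",
      is_ligand = c("L1", rownames(cm)) == "L1",
      is_receptor = c("L1", rownames(cm)) == "R1"),
    pathways = structure(list(sig = c("R1", "TF1", "T1")),
                         class = c("gene_sets", "list")),
    regulons = tibble::tibble(tf = "TF1", target = c("T1", "T2", "B2")))
}

# adjusted Rand index (independent of the clustering code under test)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_ind <- sum_a * sum_b / n
  (sum_ij - exp_ind) / ((sum_a + sum_b) / 2 - exp_ind)
}
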