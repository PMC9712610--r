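# Synthetic paired proteome/transcriptome atlas with planted ground truth.
# The generator emulates the study conditions every downstream stage is
# tested against: ~12 populations x 3 replicates, protein copies spanning
# ~7 and transcript copies ~5 orders of magnitude, a ~8000-fold mean
# protein/mRNA copy ratio, histones carrying exactly the DNA mass (so the
# proteomic ruler is invertible), ribosomal proteins with fixed
# stoichiometry, planted co-expression modules, population-specific TFs
# with activated regulons, tissue-specific ligands with matched receptors
# and active pathways, and an abundance-dependent logistic missingness
# mechanism acting independently per replicate.

#' Synthetic-atlas configuration
#'
#' All counts, effect sizes and noise levels of the generator. The defaults
#' are the study conditions of the atlas this package models: 12 populations
#' in biological triplicate, a 7-order protein and 5-order transcript
#' dynamic range, an 8000-fold mean protein/mRNA copy ratio, and replicate
#' noise of CV 0.2.
#'
#' @param n_populations,n_replicates Populations and replicates per layer.
#' @param n_genes Total gene universe size.
#' @param n_modules,module_size Planted co-expression modules (each assigned
#'   a home population in rotation) and genes per module.
#' @param module_shift Fold up-shift of module genes in the home population.
#' @param n_specific_tfs,regulon_size Planted specific TFs per population and
#'   target genes per regulon.
#' @param tf_shift,regulon_shift Fold up-shifts of the TF itself and of its
#'   targets in the home population.
#' @param n_decoy_tfs TFs with random, unshifted regulons (null behaviour).
#' @param protein_log10_range Range of baseline log10 protein copies
#'   (default `c(2, 9)`, seven orders of magnitude).
#' @param planted_log10_range Baseline range for planted (module, TF,
#'   regulon, receptor) genes; kept off the detection floor.
#' @param rna_log10_span Transcript dynamic range in log10 (default 5);
#'   transcript baselines compress the protein baselines onto this span.
#' @param protein_rna_ratio Mean protein/mRNA copy ratio (default 8000).
#' @param rna_scatter_log10 Per-gene-per-population log10 scatter of the
#'   transcript around the compressed protein baseline.
#' @param population_sigma_log10 Per-gene-per-population log10 jitter
#'   (biological variation unrelated to planted structure).
#' @param noise_cv Replicate-level coefficient of variation (lognormal).
#' @param detection `"logistic"` for abundance-dependent missingness or
#'   `"complete"` for none.
#' @param protein_detect_mid,protein_detect_slope,rna_detect_mid,rna_detect_slope
#'   Midpoint (log10 copies) and slope of the per-layer logistic detection
#'   curve.
#' @param n_histones Histone genes; together they carry exactly
#'   `dna_mass_per_cell` of protein mass in every population.
#' @param n_ribosomal Ribosomal-protein genes (fixed copy number across
#'   populations, 1:1 with ribosomes).
#' @param ribosome_copies Ribosome count per cell.
#' @param dna_mass_per_cell DNA mass per cell in grams (diploid mouse).
#' @param n_tissues,ligands_per_tissue Tissue panel for the crosstalk tier;
#'   each tissue gets this many specific ligands with matched receptors.
#' @param ligand_shift Fold up-shift of a tissue's ligands in that tissue.
#' @param pathway_intermediates Intermediate genes per planted pathway.
#' @param seed Integer seed; fully determines the output.
#' @return A list of class `atlas_config`.
#' @export
atlas_config <- function(n_populations = 12L, n_replicates = 3L,
                         n_genes = 2000L,
                         n_modules = 8L, module_size = 60L,
                         module_shift = 4,
                         n_specific_tfs = 1L, regulon_size = 20L,
                         tf_shift = 10, regulon_shift = 5,
                         n_decoy_tfs = 10L,
                         protein_log10_range = c(2, 9),
                         planted_log10_range = c(4, 8),
                         rna_log10_span = 5,
                         protein_rna_ratio = 8000,
                         rna_scatter_log10 = 0.15,
                         population_sigma_log10 = 0,
                         noise_cv = 0.2,
                         detection = c("logistic", "complete"),
                         protein_detect_mid = 3.5,
                         protein_detect_slope = 1.2,
                         rna_detect_mid = 0.0,
                         rna_detect_slope = 1.2,
                         n_histones = 10L, n_ribosomal = 80L,
                         ribosome_copies = 3e6,
                         dna_mass_per_cell = 5.5e-12,
                         n_tissues = 8L, ligands_per_tissue = 3L,
                         ligand_shift = 8,
                         pathway_intermediates = 40L,
                         seed = 1L) {
  detection <- match.arg(detection)
  cfg <- as.list(environment())
  counts <- c("n_populations", "n_replicates", "n_genes", "n_modules",
              "module_size", "n_specific_tfs", "regulon_size", "n_histones",
              "n_ribosomal", "n_tissues", "ligands_per_tissue",
              "pathway_intermediates")
  for (nm in counts) check_scalar_pos(cfg[[nm]], nm)
  planted <- n_histones + n_ribosomal + n_modules * module_size +
    n_populations * n_specific_tfs * (1L + regulon_size) + n_decoy_tfs +
    2L * n_tissues * ligands_per_tissue
  if (planted > n_genes) {
    abort(sprintf("config plants %d genes but n_genes = %d.", planted, n_genes))
  }
  if (n_tissues > n_populations) {
    abort("n_tissues must not exceed n_populations (tissues pair with populations).")
  }
  structure(cfg, class = "atlas_config")
}

# lognormal replicate noise with mean 1 and coefficient of variation cv
rln_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

detect_prob <- function(log10_x, mid, slope) {
  if (!is.finite(slope)) return(as.numeric(log10_x >= mid))
  plogis(slope * (log10_x - mid))
}

#' Generate a synthetic paired atlas
#'
#' Draws the full bundle of inputs the pipeline consumes - protein intensity
#' and iBAQ matrices, an FPKM matrix, the sample design, gene annotation,
#' regulon table, pathway collection, ligand-receptor pairs and a tissue
#' proteome - together with the planted `GroundTruth` (true copy numbers,
#' module membership, specific and maintenance TFs, tissue ligands, active
#' pathways). The seed in the config fully determines the output.
#'
#' Generation model, per gene g and population c (all on log10 copies):
#' baseline `b_g` uniform over the configured range; planted up-shifts
#' (module / TF / regulon genes in their home population) are multiplicative;
#' transcript baselines are the protein baselines compressed to the
#' transcript span minus `log10(ratio)`, plus lognormal scatter; replicate
#' values multiply the truth by lognormal noise of the configured CV; each
#' replicate value is observed with logistic probability in log10 abundance.
#' Intensity is `copies * MW` times one arbitrary scale per sample; iBAQ
#' divides by the theoretical peptide count (tied proportionally to MW so
#' iBAQ is exactly molar); FPKM is molar-proportional with one arbitrary
#' scale per sample.
#'
#' @param config An [atlas_config()].
#' @return A list of class `atlas_bundle` with elements `protein_intensity`,
#'   `protein_ibaq`, `rna_fpkm` (expr_mat), `design`, `annotation`,
#'   `regulons`, `pathways`, `lr_pairs`, `tissue_fot`, and `truth`.
#' @export
generate_atlas <- function(config = atlas_config()) {
  stopifnot(inherits(config, "atlas_config"))
  cf <- config
  set.seed(cf$seed)
  P <- cf$n_populations; R <- cf$n_replicates; G <- cf$n_genes
  pops <- sprintf("pop%02d", seq_len(P))
  genes <- sprintf("G%04d", seq_len(G))

  # ---- carve up the gene universe -------------------------------------
  idx <- seq_len(G)
  take <- function(n) { out <- idx[seq_len(n)]; idx <<- idx[-seq_len(n)]; out }
  i_hist <- take(cf$n_histones)
  i_ribo <- take(cf$n_ribosomal)
  i_mod  <- matrix(take(cf$n_modules * cf$module_size), ncol = cf$n_modules)
  n_tf   <- P * cf$n_specific_tfs
  i_tf   <- take(n_tf)
  i_reg  <- matrix(take(n_tf * cf$regulon_size), ncol = n_tf)
  i_dtf  <- take(cf$n_decoy_tfs)
  n_lig  <- cf$n_tissues * cf$ligands_per_tissue
  i_lig  <- matrix(take(n_lig), ncol = cf$n_tissues)
  i_rec  <- matrix(take(n_lig), ncol = cf$n_tissues)
  i_bg   <- idx

  module_home <- ((seq_len(cf$n_modules) - 1L) %% P) + 1L
  tf_home <- rep(seq_len(P), each = cf$n_specific_tfs)

  # ---- annotation -----------------------------------------------------
  tp <- pmax(3L, round(10^rnorm(G, mean = 1.3, sd = 0.25)))
  tp[i_hist] <- 6L
  mw <- tp * 2000            # peptide count tied to MW: iBAQ exactly molar
  annotation <- tibble(
    gene = genes,
    molecular_weight = mw,
    theoretical_peptides = as.integer(tp),
    is_histone = seq_len(G) %in% i_hist,
    is_ribosomal = seq_len(G) %in% i_ribo,
    is_tf = seq_len(G) %in% c(i_tf, i_dtf),
    is_ligand = seq_len(G) %in% i_lig,
    is_receptor = seq_len(G) %in% i_rec)

  # ---- true copy numbers (gene x population, log10) -------------------
  lo <- cf$protein_log10_range[1]; hi <- cf$protein_log10_range[2]
  base <- runif(G, lo, hi)
  planted_idx <- c(as.vector(i_mod), i_tf, as.vector(i_reg))
  base[planted_idx] <- runif(length(planted_idx),
                             cf$planted_log10_range[1],
                             cf$planted_log10_range[2])
  # planted receptors are the paired cell's surface markers: abundant
  # enough that the crosstalk ground truth is not erased by dropout
  base[as.vector(i_rec)] <- runif(length(i_rec),
                                  max(6, cf$planted_log10_range[1]),
                                  cf$planted_log10_range[2])
  lp <- matrix(base, G, P) +
    matrix(rnorm(G * P, 0, cf$population_sigma_log10), G, P)
  # planted up-shifts
  for (m in seq_len(cf$n_modules)) {
    lp[i_mod[, m], module_home[m]] <-
      lp[i_mod[, m], module_home[m]] + log10(cf$module_shift)
  }
  for (k in seq_len(n_tf)) {
    lp[i_tf[k], tf_home[k]] <- lp[i_tf[k], tf_home[k]] + log10(cf$tf_shift)
    lp[i_reg[, k], tf_home[k]] <-
      lp[i_reg[, k], tf_home[k]] + log10(cf$regulon_shift)
  }
  # fixed-stoichiometry anchors override everything else
  hist_copies <- cf$dna_mass_per_cell / cf$n_histones * AVOGADRO / mw[i_hist]
  lp[i_hist, ] <- matrix(log10(hist_copies), cf$n_histones, P)
  ribo_copies <- cf$ribosome_copies * 10^rnorm(cf$n_ribosomal, 0, 0.1)
  lp[i_ribo, ] <- matrix(log10(ribo_copies), cf$n_ribosomal, P)

  # transcripts: compress the protein log-scale onto the rna span, shift
  # down by log10(ratio), add scatter; planted shifts act on both layers
  span_p <- hi - lo
  mid_p <- (hi + lo) / 2
  compress <- cf$rna_log10_span / span_p
  lr_ <- (lp - mid_p) * compress + mid_p - log10(cf$protein_rna_ratio) +
    matrix(rnorm(G * P, 0, cf$rna_scatter_log10), G, P)
  prot_true <- 10^lp
  rna_true <- 10^lr_
  dimnames(prot_true) <- dimnames(rna_true) <- list(genes, pops)

  # ---- replicate-level observed matrices ------------------------------
  pro_samples <- as.vector(outer(pops, seq_len(R),
                                 function(p, r) sprintf("pro_%s_r%d", p, r)))
  rna_samples <- as.vector(outer(pops, seq_len(R),
                                 function(p, r) sprintf("rna_%s_r%d", p, r)))
  pop_of <- rep(pops, times = R)

  draw_layer <- function(true_mat, mid, slope) {
    ns <- P * R
    out <- matrix(NA_real_, G, ns)
    for (j in seq_len(ns)) {
      x <- true_mat[, pop_of[j]] * rln_cv(G, cf$noise_cv)
      keep <- if (cf$detection == "complete") rep(TRUE, G) else {
        runif(G) < detect_prob(log10(x), mid, slope)
      }
      out[keep, j] <- x[keep]
    }
    out
  }
  prot_obs <- draw_layer(prot_true, cf$protein_detect_mid, cf$protein_detect_slope)
  rna_obs <- draw_layer(rna_true, cf$rna_detect_mid, cf$rna_detect_slope)
  dimnames(prot_obs) <- list(genes, pro_samples)
  dimnames(rna_obs) <- list(genes, rna_samples)

  # intensity = copies * MW up to one arbitrary scale per sample
  pro_scale <- 10^runif(P * R, -1, 1)
  intensity <- sweep(prot_obs * mw, 2, pro_scale, "*")
  ibaq <- intensity / tp
  # fpkm: molar-proportional with one arbitrary scale per sample
  rna_tot <- colSums(rna_obs, na.rm = TRUE)
  fpkm <- sweep(rna_obs, 2, 1e6 * 10^runif(P * R, -0.2, 0.2) / rna_tot, "*")

  design <- bind_rows(
    tibble(sample = pro_samples, population = pop_of,
           replicate = rep(seq_len(R), each = P), layer = "protein",
           tissue = NA_character_),
    tibble(sample = rna_samples, population = pop_of,
           replicate = rep(seq_len(R), each = P), layer = "rna",
           tissue = NA_character_))
  design <- design %>% arrange(.data$layer, match(.data$population, pops),
                               .data$replicate)

  # ---- regulons -------------------------------------------------------
  tf_names <- genes[i_tf]
  regulons <- bind_rows(
    purrr::map_dfr(seq_len(n_tf), function(k) {
      tibble(tf = tf_names[k], target = genes[i_reg[, k]])
    }),
    purrr::map_dfr(seq_len(cf$n_decoy_tfs), function(k) {
      tibble(tf = genes[i_dtf[k]],
             target = genes[sample(i_bg, cf$regulon_size)])
    }))

  # ---- tissue panel, ligand-receptor pairs, pathways ------------------
  tissues <- sprintf("tissue%02d", seq_len(cf$n_tissues))
  # tissue proteome: ligands + receptors + a background slice
  tiss_genes_idx <- c(as.vector(i_lig), as.vector(i_rec),
                      i_bg[seq_len(min(300L, length(i_bg)))])
  tg <- genes[tiss_genes_idx]
  # per-gene baseline shared across tissues (tissue proteomes measure the
  # same proteins); mild tissue-to-tissue scatter, then the planted shift
  tis_base <- runif(length(tg), 2, 6)
  tmat <- 10^(matrix(tis_base, length(tg), cf$n_tissues) +
                matrix(rnorm(length(tg) * cf$n_tissues, 0, 0.1),
                       length(tg), cf$n_tissues))
  dimnames(tmat) <- list(tg, tissues)
  for (t in seq_len(cf$n_tissues)) {
    lg <- genes[i_lig[, t]]
    tmat[lg, t] <- tmat[lg, t] * cf$ligand_shift
  }
  tissue_fot <- em_replace(sweep(tmat, 2, colSums(tmat), "/") * 1e7, "fot")

  lr_pairs <- purrr::map_dfr(seq_len(cf$n_tissues), function(t) {
    tibble(ligand = genes[i_lig[, t]], receptor = genes[i_rec[, t]],
           source = "synthetic")
  })

  # pathways: per tissue one active (receptor + matched specific TF +
  # detected intermediates) and one decoy (no specific TF)
  paired_pop <- seq_len(cf$n_tissues)      # tissue t pairs with population t
  hi_bg <- i_bg[base[i_bg] >= 6]           # reliably detected intermediates
  if (length(hi_bg) < cf$pathway_intermediates) hi_bg <- i_bg
  sets <- list(); descs <- character()
  active_rows <- list()
  for (t in seq_len(cf$n_tissues)) {
    tfk <- which(tf_home == paired_pop[t])[1L]
    inter <- genes[sample(hi_bg, cf$pathway_intermediates)]
    nm <- sprintf("PW_%s_active", tissues[t])
    sets[[nm]] <- c(genes[i_rec[1L, t]], tf_names[tfk], inter)
    descs[nm] <- sprintf("planted active pathway for %s", tissues[t])
    active_rows[[t]] <- tibble(tissue = tissues[t],
                               population = pops[paired_pop[t]],
                               pathway = nm)
    dm <- sprintf("PW_%s_decoy", tissues[t])
    inter2 <- genes[sample(i_bg, cf$pathway_intermediates)]
    sets[[dm]] <- c(genes[i_rec[2L %% nrow(i_rec) + 1L, t]], inter2)
    descs[dm] <- sprintf("decoy pathway for %s (no specific TF)", tissues[t])
  }
  pathways <- structure(sets, descriptions = descs,
                        class = c("gene_sets", "list"))

  truth <- list(
    protein_copies = prot_true,
    rna_copies = rna_true,
    modules = bind_rows(
      purrr::map_dfr(seq_len(cf$n_modules), function(m) {
        tibble(gene = genes[i_mod[, m]], module = m,
               population = pops[module_home[m]])
      }),
      tibble(gene = genes[-as.vector(i_mod)], module = 0L,
             population = NA_character_)),
    # co-expression ground truth: everything sharing a planted
    # population-specific profile (module genes plus the same
    # population's specific TF and its regulon targets) forms one group
    coexpression = {
      grp <- integer(G)
      for (m in seq_len(cf$n_modules)) grp[i_mod[, m]] <- module_home[m]
      for (k in seq_len(n_tf)) grp[c(i_tf[k], i_reg[, k])] <- tf_home[k]
      tibble(gene = genes, group = grp,
             population = ifelse(grp > 0, pops[pmax(grp, 1L)], NA_character_))
    },
    specific_tfs = tibble(population = pops[tf_home], tf = tf_names),
    ctmtfs = tibble(population = pops[tf_home], tf = tf_names),
    tissue_ligands = purrr::map_dfr(seq_len(cf$n_tissues), function(t) {
      tibble(tissue = tissues[t], ligand = genes[i_lig[, t]])
    }),
    active_pathways = bind_rows(active_rows),
    paired_population = tibble(tissue = tissues, population = pops[paired_pop]),
    dna_mass_per_cell = cf$dna_mass_per_cell,
    config = cf)

  structure(list(
    protein_intensity = em_replace(intensity, "intensity"),
    protein_ibaq = em_replace(ibaq, "ibaq"),
    rna_fpkm = em_replace(fpkm, "fpkm"),
    design = design,
    annotation = annotation,
    regulons = regulons,
    pathways = pathways,
    lr_pairs = lr_pairs,
    tissue_fot = tissue_fot,
    truth = truth), class = "atlas_bundle")
}

#' Write a generated bundle to a fixture directory
#'
#' All tables are written in the package's TSV/GMT formats, alongside a
#' `manifest.yaml` recording the seed and a hash of the configuration.
#'
#' @param bundle An `atlas_bundle` from [generate_atlas()].
#' @param dir Output directory; must be empty unless `force = TRUE`.
#' @param force Overwrite a non-empty directory.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(bundle, dir, force = FALSE) {
  stopifnot(inherits(bundle, "atlas_bundle"))
  if (dir.exists(dir) && length(list.files(dir)) && !force) {
    abort(sprintf("directory '%s' is not empty (use force = TRUE).", dir))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(dir, ...)
  write_expression_matrix(bundle$protein_intensity, fp("protein_intensity.tsv"))
  write_expression_matrix(bundle$protein_ibaq, fp("protein_ibaq.tsv"))
  write_expression_matrix(bundle$rna_fpkm, fp("rna_fpkm.tsv"))
  write_expression_matrix(bundle$tissue_fot, fp("tissue_fot.tsv"))
  readr::write_tsv(bundle$design, fp("design.tsv"), progress = FALSE)
  readr::write_tsv(bundle$annotation, fp("annotation.tsv"), progress = FALSE)
  readr::write_tsv(bundle$regulons, fp("regulons.tsv"), progress = FALSE)
  readr::write_tsv(bundle$lr_pairs, fp("lr_pairs.tsv"), progress = FALSE)
  write_gmt(bundle$pathways, fp("pathways.gmt"))
  tr <- bundle$truth
  write_expression_matrix(em_replace(tr$protein_copies, "copies_per_cell"),
                          fp("truth_protein_copies.tsv"))
  write_expression_matrix(em_replace(tr$rna_copies, "copies_per_cell"),
                          fp("truth_rna_copies.tsv"))
  readr::write_tsv(tr$modules, fp("truth_modules.tsv"), progress = FALSE)
  readr::write_tsv(tr$specific_tfs, fp("truth_specific_tfs.tsv"), progress = FALSE)
  cfg <- tr$config
  yaml::write_yaml(list(
    seed = cfg$seed,
    config_hash = rlang::hash(unclass(cfg)),
    units = list(protein_intensity = "intensity", protein_ibaq = "ibaq",
                 rna_fpkm = "fpkm", tissue_fot = "fot")),
    fp("manifest.yaml"))
  invisible(dir)
}
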