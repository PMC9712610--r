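# independent digestion oracle: walk the chain, cut after K/R unless the
# next residue is P, count fragments with length in [7, 30]
digest_oracle <- function(seq) {
  aa <- strsplit(seq, "")[[1]]
  frags <- character()
  cur <- ""
  for (i in seq_along(aa)) {
    cur <- paste0(cur, aa[i])
    nxt <- if (i < length(aa)) aa[i + 1] else ""
    if (aa[i] %in% c("K", "R") && nxt != "P") {
      frags <- c(frags, cur)
      cur <- ""
    }
  }
  if (nzchar(cur)) frags <- c(frags, cur)
  sum(nchar(frags) >= 7 & nchar(frags) <= 30)
}

test_that("theoretical peptide counting follows the Keil rule and length window", {
  expect_equal(count_theoretical_peptides("ACDEFGHILM"), 1L)
  expect_equal(count_theoretical_peptides("AAAAKAAAAAAR"), 1L)
  # no cleavage before proline: single 15-mer fragment
  expect_equal(count_theoretical_peptides("AAAAAAKPAAAAAAR"), 1L)
  expect_error(count_theoretical_peptides(""), "empty")
  err <- tryCatch(count_theoretical_peptides("ACDXFG"), error = identity)
  expect_match(conditionMessage(err), "position 4")

  set.seed(42)
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:50) {
    s <- paste(sample(alphabet, sample(10:200, 1), replace = TRUE),
               collapse = "")
    expect_equal(count_theoretical_peptides(s), digest_oracle(s), info = s)
  }
})

test_that("iBAQ divides intensity by peptide count and flags missing counts", {
  x <- toy_matrix(c(1000, 500, 30, NA), genes = c("a", "b"),
                  samples = c("s1", "s2"), unit = "intensity")
  ann <- tibble::tibble(gene = c("a", "b"), theoretical_peptides = c(10L, 1L))
  ib <- compute_ibaq(x, ann)
  expect_equal(em_unit(ib), "ibaq")
  expect_equal(em_values(ib)["a", "s1"], 100)
  expect_equal(em_values(ib)["b", "s1"], 30)   # count 1: identity
  expect_true(is.na(em_values(ib)["b", "s2"]))

  ann0 <- tibble::tibble(gene = c("a", "b"), theoretical_peptides = c(10L, 0L))
  expect_error(compute_ibaq(x, ann0), "b")
})

test_that("FOT normalizes each sample column to 1e7", {
  x <- toy_matrix(c(3, NA, 1, 5), genes = c("a", "b"),
                  samples = c("s1", "s2"), unit = "ibaq")
  fot <- compute_fot(x)
  expect_equal(em_values(fot)["a", "s1"], 7.5e6)
  expect_equal(em_values(fot)["b", "s1"], 2.5e6)
  expect_equal(em_values(fot)["b", "s2"], 1e7)  # single present protein
  expect_equal(colSums(em_values(fot), na.rm = TRUE),
               c(s1 = 1e7, s2 = 1e7))
  allna <- toy_matrix(c(NA, 1, NA, 2), genes = c("a", "b"),
                      samples = c("s1", "s2"), unit = "ibaq")
  expect_error(compute_fot(allna), "s1")
})

test_that("proteomic ruler matches the single-histone arithmetic oracle", {
  # sole histone, MW 15 kg/mol, m_DNA 6e-12 g: copies = m*N_A/MW
  x <- toy_matrix(c(2e5, 4e5), genes = c("H1x", "Prot1"),
                  samples = "s1", unit = "intensity")
  ann <- tibble::tibble(gene = c("H1x", "Prot1"),
                        molecular_weight = c(15000, 50000),
                        is_histone = c(TRUE, FALSE))
  cp <- proteomic_ruler(x, ann, ruler_params(dna_mass_per_cell = 6e-12,
                                             signal_kind = "mass_proportional"))
  expect_equal(em_values(cp)["H1x", "s1"], 6e-12 * 6.02214076e23 / 15000,
               tolerance = 1e-12)
  # second protein carries twice the histone mass share at MW 50 kg/mol
  expect_equal(em_values(cp)["Prot1", "s1"],
               (6e-12 * 4e5 / 2e5) * 6.02214076e23 / 50000,
               tolerance = 1e-12)
})

test_that("ruler errors name samples without histones and genes without MW", {
  x <- toy_matrix(c(NA, 1e5, 3e5, 4e5), genes = c("H1x", "Prot1"),
                  samples = c("s1", "s2"), unit = "intensity")
  ann <- tibble::tibble(gene = c("H1x", "Prot1"),
                        molecular_weight = c(15000, 50000),
                        is_histone = c(TRUE, FALSE))
  err <- tryCatch(
    proteomic_ruler(x, ann, ruler_params(signal_kind = "mass_proportional")),
    error = identity)
  expect_match(conditionMessage(err), "s1")
  ann$molecular_weight[2] <- NA
  expect_error(
    proteomic_ruler(x, ann, ruler_params(signal_kind = "mass_proportional")),
    "Prot1")
})

test_that("ruler is invariant to per-sample global scaling of the signal", {
  b <- noiseless_bundle()
  base <- proteomic_ruler(b$protein_ibaq, b$annotation)
  set.seed(99)
  for (i in 1:10) {
    scl <- 10^runif(length(em_samples(b$protein_ibaq)), -2, 2)
    scaled <- as_expr_matrix(sweep(em_values(b$protein_ibaq), 2, scl, "*"),
                             "ibaq")
    cp <- proteomic_ruler(scaled, b$annotation)
    expect_equal(em_values(cp), em_values(base), tolerance = 1e-12)
  }
})

test_that("ruler inverts the generator in the noiseless limit, both signal kinds", {
  b <- noiseless_bundle()
  tru <- b$truth$protein_copies
  pop <- b$design$population[match(em_samples(b$protein_ibaq),
                                   b$design$sample)]
  params <- ruler_params(dna_mass_per_cell = b$truth$dna_mass_per_cell)
  for (sig in list(list(m = b$protein_ibaq, kind = "mole_proportional"),
                   list(m = b$protein_intensity, kind = "mass_proportional"))) {
    p <- ruler_params(dna_mass_per_cell = b$truth$dna_mass_per_cell,
                      signal_kind = sig$kind)
    est <- em_values(proteomic_ruler(sig$m, b$annotation, p))
    rel <- abs(est - tru[, pop]) / tru[, pop]
    expect_lt(median(rel, na.rm = TRUE), 1e-6)
  }
  # histone mass identity to 1e-9 relative
  est <- em_values(proteomic_ruler(b$protein_ibaq, b$annotation, params))
  ann <- b$annotation
  hg <- ann$gene[ann$is_histone]
  mwv <- stats::setNames(ann$molecular_weight, ann$gene)
  ident <- colSums(est[hg, ] * mwv[hg]) / 6.02214076e23
  expect_true(all(abs(ident - b$truth$dna_mass_per_cell) /
                    b$truth$dna_mass_per_cell < 1e-9))
})

test_that("iBAQ- and intensity-anchored copies agree when counts track MW", {
  # generator ties theoretical peptides to MW, so agreement is exact
  b <- noiseless_bundle()
  p1 <- proteomic_ruler(b$protein_ibaq, b$annotation,
                        ruler_params(signal_kind = "mole_proportional"))
  p2 <- proteomic_ruler(b$protein_intensity, b$annotation,
                        ruler_params(signal_kind = "mass_proportional"))
  expect_equal(em_values(p1), em_values(p2), tolerance = 1e-9)
  # and on a noisy fixture the log-log correlation stays high
  bn <- default_bundle()
  q1 <- log10(em_values(proteomic_ruler(bn$protein_ibaq, bn$annotation)))
  q2 <- log10(em_values(proteomic_ruler(
    bn$protein_intensity, bn$annotation,
    ruler_params(signal_kind = "mass_proportional"))))
  ok <- stats::complete.cases(cbind(as.vector(q1), as.vector(q2)))
  expect_gt(cor(as.vector(q1)[ok], as.vector(q2)[ok]), 0.9)
})

test_that("RNA ruler conserves the mRNA pool and is scale invariant", {
  b <- noiseless_bundle()
  d <- b$design
  prot <- protein_copies_of(b)
  pm_prot <- pool_replicates(prot, d[d$layer == "protein", ])
  pm_fpkm <- pool_replicates(b$rna_fpkm, d[d$layer == "rna", ])
  rc <- rna_ruler(pm_fpkm, pm_prot, b$annotation)
  n_mrna <- attr(rc, "n_mrna")
  expect_equal(colSums(em_values(rc), na.rm = TRUE), n_mrna)
  # doubling every FPKM changes nothing
  doubled <- as_expr_matrix(em_values(pm_fpkm) * 2, "fpkm")
  rc2 <- rna_ruler(doubled, pm_prot, b$annotation)
  expect_equal(em_values(rc2), em_values(rc), tolerance = 1e-12)
  # rank preservation against the generator's true transcript copies
  for (p in colnames(em_values(rc))[1:3]) {
    est <- em_values(rc)[, p]
    tru <- b$truth$rna_copies[names(est), p]
    ok <- !is.na(est)
    expect_equal(cor(est[ok], tru[ok], method = "spearman"), 1)
  }
  expect_error(rna_ruler(pm_fpkm, pm_prot, b$annotation,
                         min_ribosomal = 1e4), "ribosomal")
})
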