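# exhaustive combinatorial oracle for the hypergeometric upper tail
hyper_oracle <- function(k, K, n, N) {
  universe <- seq_len(N)
  marked <- seq_len(K)
  draws <- utils::combn(N, n)
  hits <- apply(draws, 2, function(d) sum(d %in% marked))
  mean(hits >= k)
}

test_that("hypergeometric upper tail equals exhaustive enumeration for N <= 12", {
  expect_equal(hypergeom_upper_tail(3, 4, 3, 10), 4 / 120, tolerance = 1e-12)
  for (N in c(5, 8, 12)) {
    for (K in c(0, 2, N %/% 2, N)) {
      for (n in c(1, N %/% 2, N)) {
        for (k in 0:min(K, n)) {
          expect_equal(hypergeom_upper_tail(k, K, n, N),
                       hyper_oracle(k, K, n, N), tolerance = 1e-12,
                       info = sprintf("k=%d K=%d n=%d N=%d", k, K, n, N))
        }
      }
    }
  }
  expect_equal(hypergeom_upper_tail(0, 4, 3, 10), 1)
  expect_equal(hypergeom_upper_tail(5, 5, 5, 5), 1)   # forced outcome
  expect_error(hypergeom_upper_tail(4, 3, 4, 10), "inconsistent")
})

test_that("tissue-specific ligand calls match hand evaluation", {
  tissues <- sprintf("t%d", 1:8)
  vals <- rbind(
    lig_single  = c(10, rep(0, 7)),     # ratio 8 -> specific in t1
    lig_uniform = rep(5, 8),            # ratio 1 -> nowhere
    lig_exact   = c(3, rep(1.8, 7)),    # mean 1.95, 3/1.95 = 1.54 -> specific
    lig_below   = c(2, rep(1.8, 7)),    # ratio ~1.1 -> nowhere
    lig_absent  = rep(NA_real_, 8))     # skipped
  colnames(vals) <- tissues
  x <- as_expr_matrix(vals, "fot")
  res <- tissue_specific_ligands(x, rownames(vals))
  expect_setequal(res$ligand[res$tissue == "t1"], c("lig_single", "lig_exact"))
  expect_false("lig_uniform" %in% res$ligand)
  expect_false("lig_below" %in% res$ligand)
  expect_false("lig_absent" %in% res$ligand)
})

test_that("pathway activation gates on receptors, TFs, and enrichment", {
  universe <- sprintf("g%02d", 1:40)
  detected <- universe[1:20]
  sets <- structure(list(
    full = c("R1", universe[1:10]),       # receptor + enriched intermediates
    no_tf = c("R2", universe[1:10]),      # enriched but gated out by TF rule
    sparse = c("R1", universe[31:40])),   # receptor+TF but undetected nodes
    class = c("gene_sets", "list"))
  sets$full <- c(sets$full, "TF1")
  sets$sparse <- c(sets$sparse, "TF1")
  res <- pathway_activation(sets, detected, universe,
                            specific_tfs = "TF1", receptors_hit = c("R1", "R2"))
  full <- res[res$pathway == "full", ]
  # closed-form oracle: all 10 intermediates among the 20 detected of 40
  p_closed <- sum(vapply(10:10, function(j) {
    choose(10, j) * choose(30, 20 - j) / choose(40, 20)
  }, numeric(1)))
  expect_equal(full$p, p_closed, tolerance = 1e-12)
  expect_true(full$active)
  expect_false(res$active[res$pathway == "no_tf"])    # gating rule
  expect_false(res$active[res$pathway == "sparse"])
})

test_that("the hand-constructed crosstalk toy yields exactly 4 edges", {
  # 1 ligand -> 1 receptor -> 1 active pathway TF -> 2 detected targets
  toy <- crosstalk_toy()
  net <- build_crosstalk_network(toy$tissue_matrix, toy$cell, toy$design,
                                 "liver", "kupffer", toy$lr, toy$pathways,
                                 toy$regulons, toy$annotation)
  expect_equal(net$n_links, 4L)
  expect_equal(sort(table(net$edges$tier), decreasing = TRUE),
               sort(table(c("ligand_receptor", "receptor_tf",
                            "tf_target", "tf_target")), decreasing = TRUE))
  # B2 is not detected in kupffer, so it is not a target node
  expect_false("B2" %in% net$edges$to)
  # tier closure: every edge is reachable from a ligand
  reach <- "L1"
  for (tier in c("ligand_receptor", "receptor_tf", "tf_target")) {
    e <- net$edges[net$edges$tier == tier, ]
    expect_true(all(e$from %in% reach))
    reach <- union(reach, e$to)
  }

  # flattening the TF removes the receptor->TF tier and downstream edges
  net2 <- build_crosstalk_network(toy$tissue_matrix, toy$cell_flat_tf,
                                  toy$design, "liver", "kupffer", toy$lr,
                                  toy$pathways, toy$regulons, toy$annotation)
  expect_equal(net2$n_links, 1L)
  expect_equal(net2$edges$tier, "ligand_receptor")

  # link counts are invariant to row order of the prior tables
  set.seed(24)
  net3 <- build_crosstalk_network(
    toy$tissue_matrix, toy$cell, toy$design, "liver", "kupffer",
    toy$lr[sample(nrow(toy$lr)), ], toy$pathways,
    toy$regulons[sample(nrow(toy$regulons)), ], toy$annotation)
  expect_equal(net3$n_links, net$n_links)
})

test_that("planted active pathways are recovered from the atlas", {
  b <- default_bundle()
  prot <- protein_copies_of(b)
  d <- protein_design_of(b)
  ap <- b$truth$active_pathways
  for (i in seq_len(min(3, nrow(ap)))) {
    net <- build_crosstalk_network(
      b$tissue_fot, prot, d, ap$tissue[i], ap$population[i],
      b$lr_pairs, b$pathways, b$regulons, b$annotation)
    act <- net$pathways$pathway[net$pathways$active]
    expect_true(ap$pathway[i] %in% act)
    # planted decoys (no specific TF) are never active
    expect_false(any(grepl("decoy", act)))
    expect_gt(net$n_links, 0)
  }
})

test_that("matched tissue-cell pairs carry more links than mismatched pairs", {
  b <- default_bundle()
  prot <- protein_copies_of(b)
  d <- protein_design_of(b)
  ap <- b$truth$active_pathways[1:3, ]
  matched <- vapply(seq_len(nrow(ap)), function(i) {
    build_crosstalk_network(b$tissue_fot, prot, d, ap$tissue[i],
                            ap$population[i], b$lr_pairs, b$pathways,
                            b$regulons, b$annotation)$n_links
  }, numeric(1))
  # pair each tissue with a population that has no planted pathway for it
  far_pops <- c("pop09", "pop10", "pop11")
  mismatched <- vapply(seq_len(nrow(ap)), function(i) {
    build_crosstalk_network(b$tissue_fot, prot, d, ap$tissue[i],
                            far_pops[i], b$lr_pairs, b$pathways,
                            b$regulons, b$annotation)$n_links
  }, numeric(1))
  expect_gt(mean(matched), mean(mismatched))
})
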