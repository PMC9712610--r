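make_block_matrix <- function(seed = 8L, n_per_block = 100L, n_samples = 40L,
                              r_within = 0.8) {
  set.seed(seed)
  lat1 <- rnorm(n_samples)
  lat2 <- rnorm(n_samples)
  lam <- sqrt(r_within)
  g <- function(latent) {
    t(vapply(seq_len(n_per_block), function(i) {
      lam * latent + sqrt(1 - lam^2) * rnorm(n_samples)
    }, numeric(n_samples)))
  }
  m <- rbind(g(lat1), g(lat2))
  dimnames(m) <- list(sprintf("g%03d", seq_len(2 * n_per_block)),
                      sprintf("s%02d", seq_len(n_samples)))
  as_expr_matrix(10^(m + 6), "copies_per_cell")
}

test_that("two planted correlation blocks are recovered exactly", {
  x <- make_block_matrix()
  ma <- detect_modules(x, power = 6)
  asg <- tidy(ma)
  expect_equal(ma$n_modules, 2L)
  truth <- rep(1:2, each = 100)
  expect_gte(adjusted_rand(asg$module, truth), 0.99)
  # order invariance: permuting gene rows permutes the assignment identically
  set.seed(9)
  perm <- sample(nrow(x))
  xp <- as_expr_matrix(em_values(x)[perm, ], "copies_per_cell")
  map <- tidy(detect_modules(xp, power = 6))
  merged <- dplyr::inner_join(asg, map, by = "gene")
  # module ids may be relabelled, membership must not change
  expect_equal(adjusted_rand(merged$module.x, merged$module.y), 1)
})

test_that("TOM is symmetric, in [0, 1], with unit diagonal and tight duplicates", {
  x <- make_block_matrix(seed = 10, n_per_block = 30, n_samples = 30)
  prep <- macatlas:::wgcna_prep(x)
  a <- macatlas:::adjacency_matrix(prep, 6)
  tom <- tom_similarity(a)
  expect_equal(tom, t(tom))
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  expect_equal(unname(diag(tom)), rep(1, nrow(tom)))
  # an exactly duplicated gene pair has near-maximal overlap
  m <- em_values(x)
  m <- rbind(m, dup1 = m[1, ], dup2 = m[1, ])
  a2 <- macatlas:::adjacency_matrix(
    macatlas:::wgcna_prep(as_expr_matrix(m, "copies_per_cell")), 6)
  tom2 <- tom_similarity(a2)
  off_diag <- tom2[upper.tri(tom2)]
  expect_gte(tom2["dup1", "dup2"], quantile(off_diag, 0.99))
})

test_that("assignment is invariant to per-gene affine rescaling of log values", {
  x <- make_block_matrix(seed = 12, n_per_block = 40, n_samples = 30)
  base <- tidy(detect_modules(x, power = 6))
  set.seed(13)
  m <- em_values(x)
  a <- runif(nrow(m), 0.5, 2)
  b <- runif(nrow(m), -2, 2)
  scaled <- 10^(sweep(sweep(log10(m), 1, a, "*"), 1, b, "+"))
  resc <- tidy(detect_modules(as_expr_matrix(scaled, "copies_per_cell"),
                              power = 6))
  merged <- dplyr::inner_join(base, resc, by = "gene")
  expect_equal(adjusted_rand(merged$module.x, merged$module.y), 1)
})

test_that("soft-threshold selection finds scale-free structure and warns otherwise", {
  # single-factor loading model with power-law connectivity
  set.seed(14)
  n <- 400; ns <- 100
  rho <- runif(n, 0.05, 0.95)
  f <- rnorm(ns)
  m <- t(vapply(rho, function(r) r * f + sqrt(1 - r^2) * rnorm(ns),
                numeric(ns)))
  dimnames(m) <- list(sprintf("g%03d", 1:n), sprintf("s%02d", 1:ns))
  x <- as_expr_matrix(10^(m + 6), "copies_per_cell")
  st <- pick_soft_threshold(x, powers = 1:12, target_r2 = 0.8)
  expect_true(st$reached_target)
  expect_gte(max(st$fits$r_squared, na.rm = TRUE), 0.8)

  # independent Gaussian genes: no power reaches the target
  set.seed(15)
  m2 <- matrix(rnorm(300 * 40), 300, 40,
               dimnames = list(sprintf("h%03d", 1:300), sprintf("s%02d", 1:40)))
  x2 <- as_expr_matrix(10^(m2 + 6), "copies_per_cell")
  expect_warning(st2 <- pick_soft_threshold(x2, powers = c(2, 4, 6)),
                 "argmax")
  expect_false(st2$reached_target)

  # single candidate: that power is chosen and the report is complete
  st3 <- suppressWarnings(pick_soft_threshold(x, powers = 7))
  expect_equal(st3$power, 7)
  expect_equal(nrow(st3$fits), 1L)
})

test_that("eigengenes summarize their modules with the sign contract", {
  x <- make_block_matrix(seed = 16, n_per_block = 50, n_samples = 30,
                         r_within = 0.95)
  ma <- detect_modules(x, power = 6)
  me <- module_eigengenes(x, ma)
  expect_equal(me$sample, em_samples(x))
  prep <- macatlas:::wgcna_prep(x)
  asg <- tidy(ma)
  for (m in seq_len(ma$n_modules)) {
    e <- me[[paste0("ME", m)]]
    expect_equal(sum(e^2), 1)
    members <- asg$gene[asg$module == m]
    mm <- abs(cor(e, t(prep[members, ])))
    expect_gt(min(mm), 0.9)
    # positive mean correlation with members (sign contract)
    expect_gt(mean(cor(e, t(prep[members, ]))), 0)
  }
})

test_that("module recovery on the default atlas meets the planted structure", {
  b <- default_bundle()
  prot <- protein_copies_of(b)
  ma <- detect_modules(prot, power = 12)
  cx <- b$truth$coexpression
  j <- dplyr::inner_join(tidy(ma), cx, by = "gene")
  expect_gte(adjusted_rand(j$module, j$group), 0.8)
  # eigengene of each found module tracks its planted population profile
  st <- module_trait_stats(prot, ma, protein_design_of(b))
  expect_true(all(st$module_trait$cor[st$module_trait$kept] > 0.9))
  gs <- tidy(st)
  planted <- b$truth$modules$gene[b$truth$modules$module > 0]
  expect_gte(mean(planted %in% gs$gene[gs$pass]), 0.9)
})

test_that("module-trait statistics behave on a noiseless planted module", {
  # module expressed only in population A: moduleTraitCor = 1
  pops <- rep(c("A", "B", "C"), each = 3)
  samples <- sprintf("s%d", 1:9)
  base <- matrix(1e4, 60, 9, dimnames = list(sprintf("g%02d", 1:60), samples))
  base[1:40, pops == "A"] <- 1e6
  set.seed(17)
  noise <- matrix(10^rnorm(60 * 9, 0, 0.02), 60, 9)
  x <- as_expr_matrix(base * noise, "copies_per_cell")
  d <- tibble::tibble(sample = samples, population = pops,
                      replicate = rep(1:3, 3), layer = "protein",
                      tissue = NA_character_)
  ma <- detect_modules(x, power = 6, min_module_size = 10)
  st <- module_trait_stats(x, ma, d)
  top <- st$module_trait[st$module_trait$kept, ]
  expect_true(any(top$population == "A" & top$cor > 0.99))
  expect_error(module_trait_stats(x, ma, dplyr::mutate(d, population = "A")),
               "degenerate")
})

test_that("tiny inputs collapse to the unassigned module", {
  x <- make_block_matrix(seed = 18, n_per_block = 5, n_samples = 10)
  ma <- detect_modules(x, power = 6, min_module_size = 30)
  expect_equal(ma$n_modules, 0L)
  expect_true(all(tidy(ma)$module == 0L))
})
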