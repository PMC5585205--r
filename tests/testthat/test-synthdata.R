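test_that("sim_config validates its inputs", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_genes = 0), "positive integers")
  expect_error(sim_config(cluster_effect = Inf), "finite")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(biclique_dims = c(1, 3)), "biclique_dims")
  expect_error(sim_config(star_size = 2), "star_size")
  expect_error(sim_config(n_genes = 20, cluster_size = 10), "exceed")
})

test_that("generators are byte-identical under a fixed seed", {
  cfg <- sim_config(n_genes = 40, n_samples_per_cell = 3, seed = 7)
  e1 <- gen_expression(cfg); e2 <- gen_expression(cfg)
  expect_identical(e1$expr$values, e2$expr$values)
  expect_identical(e1$truth$cluster_membership, e2$truth$cluster_membership)
  i1 <- gen_interactome(cfg); i2 <- gen_interactome(cfg)
  expect_identical(i1$net$edges, i2$net$edges)
  g1 <- gen_genotypes(cfg); g2 <- gen_genotypes(cfg)
  expect_identical(g1$geno$counts, g2$geno$counts)
  expect_identical(g1$pheno, g2$pheno)
  a1 <- gen_annotations(cfg, i1$truth); a2 <- gen_annotations(cfg, i2$truth)
  expect_identical(a1$gmt, a2$gmt)
  # a different seed changes the draw
  e3 <- gen_expression(sim_config(n_genes = 40, n_samples_per_cell = 3, seed = 8))
  expect_false(identical(e1$expr$values, e3$expr$values))
})

test_that("with zero cluster effect the two conditions are exchangeable", {
  # factorial treatment p-values behave like a level-alpha test on null data
  ps <- unlist(lapply(1:10, function(s) {
    g <- gen_expression(sim_config(n_genes = 60, n_samples_per_cell = 3,
                                   cluster_effect = 0, seed = 100 + s))
    fit_factorial(g$expr)$p_treatment
  }))
  rate <- mean(ps < 0.05)
  # 600 genes x ~independent tests; binomial 3*SE band around alpha
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / length(ps)) + 0.01)
})

test_that("planted precision translates into rank-detectable partial correlations", {
  # closed-form oracle: true pcor = -omega_ij / sqrt(omega_ii omega_jj)
  g <- gen_expression(sim_config(n_genes = 30, n_samples_per_cell = 4,
                                 precision_offdiag = 0.4, cluster_effect = 0,
                                 seed = 11))
  tp <- true_partial_correlations(g$omega)
  idx <- cbind(match(g$truth$planted_edges[, 1], g$expr$genes),
               match(g$truth$planted_edges[, 2], g$expr$genes))
  expect_true(all(abs(tp[idx]) > 0.05))
  off <- abs(tp[upper.tri(tp)])
  planted_mag <- abs(tp[idx])
  # every planted entry is nonzero, all others are exactly zero in truth
  expect_equal(sum(off > 1e-12), nrow(idx))
  expect_true(min(planted_mag) > max(off[rank(-off) > nrow(idx)]))
})

test_that("sample covariance converges to the inverse precision matrix", {
  cfg <- sim_config(n_genes = 10, n_samples_per_cell = 625,
                    cluster_effect = 0, precision_offdiag = 0.3, seed = 3)
  g <- gen_expression(cfg)          # 5000 samples
  S_true <- solve(g$omega)
  S_hat <- stats::cov(t(g$expr$values))
  n <- ncol(g$expr$values)
  se <- sqrt((outer(diag(S_true), diag(S_true)) + S_true^2) / n)
  expect_true(all(abs(S_hat - S_true) <= 3 * se + 1e-8))
})

test_that("interactome carries the planted star, biclique and degree sequence", {
  cfg <- sim_config(star_size = 5, biclique_dims = c(3, 3),
                    n_background_ppi_nodes = 60, seed = 2)
  gi <- gen_interactome(cfg)
  g <- as_igraph(gi$net)
  deg <- igraph::degree(g)
  expect_equal(unname(deg["STAR_HUB"]), 5)
  leaves <- setdiff(gi$truth$planted_modules$star, "STAR_HUB")
  expect_true(all(deg[leaves] == 1))
  # biclique 3x3 -> 9 internal edges
  bic <- gi$truth$planted_modules$biclique
  sub <- igraph::induced_subgraph(g, bic)
  expect_equal(igraph::ecount(sub), 9L)
  # configuration-model background matches the prescribed degree sequence
  bg_deg <- deg[names(gi$truth$background_degrees)]
  expect_identical(unname(bg_deg), unname(as.numeric(gi$truth$background_degrees)))
  # modules are disjoint
  expect_length(intersect(gi$truth$planted_modules$star, bic), 0)
  expect_error(gen_interactome(sim_config(star_size = 30,
                                          n_background_ppi_nodes = 20)),
               "node budget")
})

test_that("annotation categories are enriched in their planted modules", {
  cfg <- sim_config(seed = 4)
  gi <- gen_interactome(cfg)
  an <- gen_annotations(cfg, gi$truth)
  universe <- unique(c(unlist(gi$truth$planted_modules),
                       sprintf("BG%04d", seq_len(cfg$n_background_ppi_nodes))))
  for (m in names(gi$truth$planted_modules)) {
    cat_name <- paste0("CAT_", toupper(m))
    mod <- gi$truth$planted_modules[[m]]
    k <- length(intersect(an$gmt[[cat_name]], mod))
    p <- hypergeom_tail(k, length(an$gmt[[cat_name]]), length(mod),
                        length(universe))
    expect_lt(p, 1e-4)
  }
  # full coverage, no padding: category equals the module exactly
  cfg_full <- sim_config(annotation_q = 1, seed = 4)
  an_full <- gen_annotations(cfg_full, gi$truth, universe = universe,
                             n_null_sets = 0)
  # drop the padding half: category contains the whole module
  expect_true(all(gi$truth$planted_modules$star %in% an_full$gmt$CAT_STAR))
})

test_that("genotype generator respects Hardy-Weinberg and plants its effects", {
  g <- gen_genotypes(sim_config(n_subjects = 400, n_snps = 10,
                                maf_range = c(0.25, 0.25), seed = 5))
  emp <- g$geno$maf
  se <- sqrt(0.25 * 0.75 / (2 * 400))
  expect_true(all(abs(emp - 0.25) <= 3 * se))
  expect_true(all(g$geno$counts %in% 0:2))
  expect_false(g$truth$causal_snp$id == g$truth$eqtl_snp$id)
  # with beta = 0 the phenotype association p-values are uniform
  ps <- vapply(1:100, function(s) {
    gg <- gen_genotypes(sim_config(n_subjects = 80, n_snps = 4,
                                   causal_beta = 0, seed = 300 + s))
    snp_association(gg$pheno, gg$geno$counts[, gg$truth$causal_snp$id],
                    coding = "additive")$p
  }, 1.0)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
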