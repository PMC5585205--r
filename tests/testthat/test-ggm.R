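test_that("shrink_correlation behaves at the corners", {
  # orthogonal standardized columns: R ~ I and R* ~ I
  X <- cbind(rep(c(1, -1), 8), rep(c(1, 1, -1, -1), 4), rep(c(1, -1, -1, 1), 4))
  sh <- shrink_correlation(X)
  expect_equal(sh$R, diag(3), tolerance = 1e-12)
  # abundant samples, strong correlation: lambda near zero
  set.seed(1)
  z <- stats::rnorm(2000)
  X2 <- cbind(z + stats::rnorm(2000, sd = 0.3),
              z + stats::rnorm(2000, sd = 0.3),
              -z + stats::rnorm(2000, sd = 0.3))
  expect_lt(shrink_correlation(X2)$lambda, 0.05)
  # p > n: still positive definite
  set.seed(2)
  X3 <- matrix(stats::rnorm(10 * 30), 10, 30)
  sh3 <- shrink_correlation(X3)
  expect_gt(min(eigen(sh3$R, symmetric = TRUE, only.values = TRUE)$values), 0)
  # constant column is named in the error
  X4 <- cbind(a = stats::rnorm(5), b = rep(2, 5))
  expect_error(shrink_correlation(X4), "b")
  expect_error(shrink_correlation(matrix(1:4, 2, 2)), ">= 3 samples")
})

test_that("partial correlations match the closed-form precision oracle", {
  omega <- matrix(c(2, 1, 0, 1, 2, 1, 0, 1, 2), 3, 3)
  R <- stats::cov2cor(solve(omega))
  P <- partial_correlations(R)
  expect_equal(P[1, 2], -0.5, tolerance = 1e-12)
  expect_equal(P[1, 3], 0, tolerance = 1e-12)
  expect_equal(P[2, 3], -0.5, tolerance = 1e-12)
  expect_equal(partial_correlations(diag(4)), diag(4))
  # symmetry and unit diagonal on a random SPD input
  set.seed(3)
  A <- crossprod(matrix(stats::rnorm(49), 7, 7)) + diag(7)
  Pr <- partial_correlations(stats::cov2cor(A))
  expect_equal(Pr, t(Pr))
  expect_equal(diag(Pr), rep(1, 7))
  expect_error(partial_correlations(matrix(c(1, 1, 1, 1), 2, 2)), "singular")
})

test_that("local fdr is calibrated on null data and monotone in |r|", {
  set.seed(4)
  X <- matrix(stats::rnorm(40 * 50), 40, 50)
  P <- partial_correlations(shrink_correlation(X)$R)
  fit <- fit_local_fdr(P[upper.tri(P)])
  expect_gte(fit$eta0, 0.95)
  expect_gt(fit$kappa, 3)
  r <- P[upper.tri(P)]
  ord <- order(abs(r))
  expect_true(all(diff(fit$lfdr[ord]) <= 1e-12))
  expect_error(fit_local_fdr(stats::runif(50, -0.5, 0.5)), ">= 100")
  expect_error(fit_local_fdr(c(rep(0.2, 120), 1)), "inside")
})

test_that("planted edges receive lower local fdr than null pairs", {
  lower <- vapply(1:5, function(s) {
    g <- gen_expression(sim_config(n_genes = 40, n_samples_per_cell = 20,
                                   precision_offdiag = 0.4, cluster_effect = 0,
                                   seed = 400 + s))
    P <- partial_correlations(shrink_correlation(t(g$expr$values))$R)
    dimnames(P) <- list(g$expr$genes, g$expr$genes)
    fit <- fit_local_fdr(P[upper.tri(P)])
    ut <- which(upper.tri(P), arr.ind = TRUE)
    keys <- paste(g$expr$genes[ut[, 1]], g$expr$genes[ut[, 2]])
    planted <- paste(g$truth$planted_edges[, 1], g$truth$planted_edges[, 2])
    mean(fit$lfdr[keys %in% planted]) < mean(fit$lfdr[!keys %in% planted])
  }, TRUE)
  expect_true(all(lower))
})

test_that("build_network respects the threshold monotonically", {
  g <- gen_expression(sim_config(n_genes = 30, n_samples_per_cell = 10,
                                 precision_offdiag = 0.4, cluster_effect = 0,
                                 seed = 8))
  nets <- lapply(c(1e-13, 1e-2, 0.5, 1),
                 function(th) build_network(g$expr$genes, g$expr, threshold = th))
  sizes <- vapply(nets, function(n) nrow(n$edges), 1L)
  expect_true(all(diff(sizes) >= 0))
  # threshold 1 keeps every pair: complete graph
  expect_equal(sizes[4], choose(30, 2))
  # edge sets are nested
  key <- function(n) paste(n$edges$gene_a, n$edges$gene_b)
  expect_true(all(key(nets[[2]]) %in% key(nets[[3]])))
  expect_error(build_network(g$expr$genes[1:2], g$expr), ">= 3 genes")
  expect_error(build_network(c(g$expr$genes[1:5], "nope"), g$expr), "absent")
})

test_that("independent data yield an empty network at stringent thresholds", {
  set.seed(9)
  vals <- matrix(stats::rnorm(50 * 40), 50, 40)
  meta <- data.frame(sample = sprintf("s%02d", 1:40),
                     condition = rep(c("IL1B", "PBS"), 20),
                     timepoint = rep(c("P1", "P5", "P10", "P45"), each = 10),
                     replicate = rep(1:5, 8), stringsAsFactors = FALSE)
  dimnames(vals) <- list(sprintf("g%02d", 1:50), meta$sample)
  ex <- structure(list(values = vals, genes = rownames(vals),
                       samples = meta$sample, metadata = meta),
                  class = "expression_matrix")
  nw <- build_network(ex$genes, ex, threshold = 1e-13)
  expect_equal(nrow(nw$edges), 0L)
  expect_length(nw$nodes, 50)
})

test_that("every planted graph model yields a valid precision and plants edges", {
  for (model in c("scale-free", "small-world", "hub-star")) {
    g <- gen_expression(sim_config(n_genes = 40, n_samples_per_cell = 2,
                                   network_model = model, seed = 2))
    expect_gt(nrow(g$truth$planted_edges), 0)
    ev <- eigen(g$omega, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
})

test_that("a planted hub-star structure puts the hub at the top of the degree
           ranking of the recovered network", {
  ok <- vapply(1:5, function(s) {
    g <- gen_expression(sim_config(n_genes = 50, n_samples_per_cell = 10,
                                   precision_offdiag = 0.4,
                                   network_model = "hub-star",
                                   cluster_effect = 0, seed = 700 + s))
    nw <- build_network(g$expr$genes, g$expr, threshold = 1e-2)
    deg <- igraph::degree(as_igraph(nw))
    hub_true <- names(which.max(table(as.vector(g$truth$planted_edges))))
    names(which.max(deg)) == hub_true
  }, TRUE)
  expect_true(all(ok))
})

test_that("the shrinkage pcor estimate is consistent on a strong structure", {
  # ring precision with strong entries: lambda vanishes as n grows and the
  # estimate approaches the closed form entrywise
  n_genes <- 10
  edges <- cbind(seq_len(n_genes), c(seq_len(n_genes)[-1], 1))
  edges <- t(apply(edges, 1, sort))
  omega <- matrix(0, n_genes, n_genes)
  omega[edges] <- 0.45; omega <- omega + t(omega)
  diag(omega) <- 1 + rowSums(abs(omega)) + 0.1
  truth <- true_partial_correlations(omega)
  set.seed(10)
  X <- MASS::mvrnorm(5000, rep(0, n_genes), solve(omega))
  sh <- shrink_correlation(X)
  P <- partial_correlations(sh$R)
  expect_lt(sh$lambda, 0.02)
  expect_lt(mean(abs(P - truth)), 0.02)
  # each entry within its ~1/sqrt(n) sampling band
  expect_lt(max(abs(P - truth)), 3.5 / sqrt(nrow(X)))
})

test_that("ggm_network methods print and summarise", {
  g <- gen_expression(sim_config(n_genes = 20, n_samples_per_cell = 5,
                                 cluster_effect = 0, seed = 12))
  nw <- build_network(g$expr$genes, g$expr, threshold = 0.5,
                      response_label = "IL1B")
  expect_output(print(nw), "IL1B")
  s <- summary(nw)
  expect_equal(s$n_nodes, 20)
  expect_s3_class(as_igraph(nw), "igraph")
})
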