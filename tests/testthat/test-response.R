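test_that("welch_test handles regular and degenerate inputs", {
  expect_equal(welch_test(c(1, 2, 3), c(1, 2, 3))[c("t", "p")],
               list(t = 0, p = 1))
  d <- welch_test(c(0, 0), c(5, 5))
  expect_true(d$degenerate)
  expect_equal(d$p, 0)
  r <- welch_test(c(1, 2, 4), c(8, 9, 11))
  ref <- stats::t.test(c(1, 2, 4), c(8, 9, 11))
  expect_equal(r$t, unname(ref$statistic))
  expect_equal(r$p, ref$p.value)
  expect_error(welch_test(1, c(1, 2)), ">= 2")
})

test_that("welch_test rejection rate is calibrated at alpha = 0.05", {
  set.seed(1)
  x <- matrix(stats::rnorm(10000 * 10), 10000, 10)
  w <- powerggm:::row_welch(x, rep(c(TRUE, FALSE), each = 5))
  rate <- mean(w$p < 0.05)
  expect_gte(rate, 0.04)
  expect_lte(rate, 0.06)
})

test_that("row_welch agrees with welch_test per row", {
  set.seed(2)
  x <- matrix(stats::rnorm(20 * 9), 20, 9)
  treated <- c(rep(TRUE, 4), rep(FALSE, 5))
  w <- powerggm:::row_welch(x, treated)
  for (i in c(1, 7, 20)) {
    ref <- welch_test(x[i, treated], x[i, !treated])
    expect_equal(w$t[i], ref$t)
    expect_equal(w$p[i], ref$p)
  }
})

test_that("bh_adjust applies the step-up rule and preserves order", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(1), 1)
  p <- c(0.002, 0.9, 0.04, 0.3, 0.011)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  # permutation equivariance
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(bh_adjust(p[perm]), q[perm])
  # monotone in sorted-p order
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  # NA propagates and is excluded from the test count
  qn <- bh_adjust(c(0.025, NA, 0.05))
  expect_true(is.na(qn[2]))
  expect_equal(qn[c(1, 3)], stats::p.adjust(c(0.025, 0.05), "BH"))
  expect_error(bh_adjust(c(-0.1, 0.5)), "\\[0, 1\\]")
})

make_expr <- function(vals, conds, tps, reps = NULL) {
  n <- length(conds)
  if (is.null(reps)) reps <- stats::ave(seq_len(n), paste(conds, tps),
                                        FUN = seq_along)
  meta <- data.frame(sample = sprintf("s%02d", seq_len(n)), condition = conds,
                     timepoint = tps, replicate = reps,
                     stringsAsFactors = FALSE)
  colnames(vals) <- meta$sample
  rownames(vals) <- sprintf("g%02d", seq_len(nrow(vals)))
  structure(list(values = vals, genes = rownames(vals),
                 samples = meta$sample, metadata = meta),
            class = "expression_matrix")
}

test_that("fit_factorial matches per-gene anova and flags zero variance", {
  g <- gen_expression(sim_config(n_genes = 25, n_samples_per_cell = 3,
                                 cluster_effect = 1, seed = 5))
  # plant a constant gene
  g$expr$values[1, ] <- 7
  ct <- fit_factorial(g$expr)
  expect_equal(ct$p_treatment[1], 1)
  expect_equal(ct$p_time[1], 1)
  expect_equal(ct$p_interaction[1], 1)
  meta <- g$expr$metadata
  cond <- factor(meta$condition)
  time <- factor(meta$timepoint, levels = unique(meta$timepoint))
  for (i in c(2, 10, 25)) {
    ref <- stats::anova(stats::lm(g$expr$values[i, ] ~ cond * time))[["Pr(>F)"]]
    expect_equal(ct$p_treatment[i], ref[1], tolerance = 1e-12)
    expect_equal(ct$p_time[i], ref[2], tolerance = 1e-12)
    expect_equal(ct$p_interaction[i], ref[3], tolerance = 1e-12)
  }
  expect_true(all(ct$q_treatment >= ct$p_treatment, na.rm = TRUE))
})

test_that("fit_factorial fails listing empty design cells", {
  g <- gen_expression(sim_config(n_genes = 10, n_samples_per_cell = 2, seed = 1))
  keep <- !(g$expr$metadata$condition == "IL1B" &
              g$expr$metadata$timepoint == "P5")
  ex <- g$expr
  ex$values <- ex$values[, keep]
  ex$metadata <- ex$metadata[keep, ]
  ex$samples <- ex$samples[keep]
  expect_error(fit_factorial(ex), "IL1B:P5")
})

test_that("factorial treatment F equals squared pooled t on a 2x2-free design", {
  # single timepoint pair, no interaction: F(treatment) == t^2
  set.seed(9)
  vals <- matrix(stats::rnorm(5 * 12), 5, 12)
  ex <- make_expr(vals, conds = rep(c("IL1B", "PBS"), each = 6),
                  tps = rep(rep(c("P1", "P5"), each = 3), 2))
  ct <- fit_factorial(ex)
  for (i in 1:5) {
    fit <- stats::lm(vals[i, ] ~ factor(ex$metadata$condition) +
                       factor(ex$metadata$timepoint))
    tstat <- summary(fit)$coefficients[2, 3]
    # treatment F from the additive fit equals t^2
    a <- stats::anova(fit)
    expect_equal(a[["F value"]][1] / tstat^2, 1, tolerance = 1e-8)
  }
})

test_that("cluster_responses recovers planted clusters and is antisymmetric", {
  g <- gen_expression(sim_config(n_genes = 100, cluster_effect = 1.5, seed = 21))
  cl <- cluster_responses(g$expr)
  tr <- g$truth$cluster_membership
  up1 <- names(tr)[tr == "up_P1"]
  c1 <- cl[cl$timepoint == "P1", ]
  expect_gt(mean(c1$label[match(up1, c1$gene)] == "up"), 0.6)
  # flipping the treated condition swaps up and down exactly
  cl_flip <- cluster_responses(g$expr, treated = "PBS")
  expect_identical(cl_flip$label[cl$label == "up"],
                   rep("down", sum(cl$label == "up")))
  expect_identical(cl_flip$label[cl$label == "down"],
                   rep("up", sum(cl$label == "down")))
  expect_identical(cl_flip$label[cl$label == "none"],
                   rep("none", sum(cl$label == "none")))
  expect_equal(cl_flip$z, -cl$z)
})

test_that("cluster_responses handles degenerate inputs", {
  # identical difference for every gene: z = 0, labels none
  vals <- matrix(rep(c(5, 5, 3, 3), times = 4), 4, 4, byrow = TRUE) +
    seq_len(4)                       # gene-specific baselines, common diff = 2
  ex <- make_expr(vals, conds = c("IL1B", "IL1B", "PBS", "PBS"),
                  tps = rep("P1", 4))
  cl <- cluster_responses(ex)
  expect_true(all(cl$z == 0))
  expect_true(all(cl$label == "none"))
  # single gene: cross-gene SD undefined
  ex1 <- make_expr(vals[1, , drop = FALSE], conds = c("IL1B", "IL1B", "PBS", "PBS"),
                   tps = rep("P1", 4))
  expect_error(cluster_responses(ex1), ">= 2 genes")
})

test_that("select_response_genes respects the q cutoff and cap", {
  g <- gen_expression(sim_config(n_genes = 100, cluster_effect = 2, seed = 31))
  ct <- fit_factorial(g$expr)
  sel <- select_response_genes(ct, "interaction", q_max = 0.05, cap = 10)
  expect_lte(length(sel), 10)
  qs <- ct$q_interaction[match(sel, ct$gene)]
  expect_true(all(qs <= 0.05))
  sel_all <- select_response_genes(ct, "interaction", q_max = 0.05, cap = 1e6)
  expect_equal(length(sel_all), sum(ct$q_interaction <= 0.05, na.rm = TRUE))
})
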