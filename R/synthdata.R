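#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generators: a two-condition
#' (IL1B vs PBS vehicle) by four-time-point factorial expression design with
#' planted up/down response clusters, a sparse-precision Gaussian graphical
#' model for the co-expression structure, a background interactome with one
#' planted star module and one planted biclique module, gene-set/TF-target
#' annotations enriched in the planted modules, and a genotype panel with one
#' causal SNP for a scalar phenotype and one cis-eQTL.
#'
#' @param n_genes number of genes on the expression array.
#' @param n_samples_per_cell replicates per condition x time-point cell.
#'   The default (12) gives >90% power for a two-sample t-test on a 1.5
#'   log2-unit shift at genome-wide Benjamini-Hochberg thresholds.
#' @param timepoints ordered time-point labels (postnatal days).
#' @param conditions two condition labels; the first is treated as "treated"
#'   when planting cluster shifts.
#' @param cluster_effect log2-scale mean shift planted into response-cluster
#'   genes at their assigned time point.
#' @param cluster_size genes per planted cluster (four clusters are planted:
#'   up/down at each of the first two time points).
#' @param network_model planted conditional-dependence graph for the
#'   expression precision matrix: preferential-attachment scale-free,
#'   Watts-Strogatz small-world, or a single hub-and-spokes star.
#' @param precision_offdiag magnitude of planted off-diagonal precision
#'   entries (sign random per edge).
#' @param n_background_ppi_nodes proteins in the interactome background
#'   (excludes the two planted modules).
#' @param star_size number of leaves of the planted star module (>= 3).
#' @param biclique_dims integer pair: side sizes of the planted complete
#'   bipartite module (each >= 2).
#' @param n_snps SNPs in the genotype panel (>= 2).
#' @param n_subjects genotyped subjects with a scalar phenotype.
#' @param causal_beta phenotype effect of carrying the minor allele at the
#'   causal SNP (presence coding).
#' @param eqtl_gamma expression shift per minor-allele count at the eQTL SNP.
#' @param maf_range minor-allele-frequency interval, inside (0, 0.5].
#' @param annotation_q fraction of each planted module covered by its
#'   enriched annotation category.
#' @param tf_overlap fraction of the star module covered by the planted
#'   transcription-factor target set.
#' @param seed integer seed; all generator randomness derives from it through
#'   per-stage streams, so a fixed seed reproduces every output byte.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 200,
                       n_samples_per_cell = 12,
                       timepoints = c("P1", "P5", "P10", "P45"),
                       conditions = c("IL1B", "PBS"),
                       cluster_effect = 1.0,
                       cluster_size = max(1L, n_genes %/% 10L),
                       network_model = c("scale-free", "small-world", "hub-star"),
                       precision_offdiag = 0.3,
                       n_background_ppi_nodes = 200,
                       star_size = 10,
                       biclique_dims = c(6, 6),
                       n_snps = 20,
                       n_subjects = 271,
                       causal_beta = 0.8,
                       eqtl_gamma = 1.0,
                       maf_range = c(0.1, 0.4),
                       annotation_q = 0.8,
                       tf_overlap = 0.6,
                       seed = 1L) {
  network_model <- match.arg(network_model)
  counts <- c(n_genes = n_genes, n_samples_per_cell = n_samples_per_cell,
              n_background_ppi_nodes = n_background_ppi_nodes,
              star_size = star_size, n_snps = n_snps, n_subjects = n_subjects,
              cluster_size = cluster_size)
  if (any(counts <= 0) || any(counts != round(counts)))
    stop("all counts must be positive integers; offending: ",
         paste(names(counts)[counts <= 0 | counts != round(counts)], collapse = ", "))
  if (!is.finite(cluster_effect)) stop("cluster_effect must be finite")
  if (length(biclique_dims) != 2 || any(biclique_dims < 2))
    stop("biclique_dims must be two counts, each >= 2")
  if (star_size < 3) stop("star_size must be >= 3")
  if (n_snps < 2) stop("n_snps must be >= 2")
  if (length(maf_range) != 2 || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop("maf_range must lie inside (0, 0.5]")
  if (length(timepoints) < 2) stop("need at least two timepoints")
  if (length(conditions) != 2) stop("exactly two conditions required")
  if (4 * cluster_size > n_genes)
    stop("four clusters of size ", cluster_size, " exceed n_genes")
  if (annotation_q <= 0 || annotation_q > 1) stop("annotation_q must be in (0,1]")
  if (tf_overlap <= 0 || tf_overlap > 1) stop("tf_overlap must be in (0,1]")
  if (precision_offdiag < 0) stop("precision_offdiag must be >= 0")
  cfg <- list(n_genes = as.integer(n_genes),
              n_samples_per_cell = as.integer(n_samples_per_cell),
              timepoints = as.character(timepoints),
              conditions = as.character(conditions),
              cluster_effect = cluster_effect,
              cluster_size = as.integer(cluster_size),
              network_model = network_model,
              precision_offdiag = precision_offdiag,
              n_background_ppi_nodes = as.integer(n_background_ppi_nodes),
              star_size = as.integer(star_size),
              biclique_dims = as.integer(biclique_dims),
              n_snps = as.integer(n_snps),
              n_subjects = as.integer(n_subjects),
              causal_beta = causal_beta,
              eqtl_gamma = eqtl_gamma,
              maf_range = as.numeric(maf_range),
              annotation_q = annotation_q,
              tf_overlap = tf_overlap,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  expression: %d genes x (%d cond x %d time x %d reps), cluster effect %.2f\n",
              x$n_genes, length(x$conditions), length(x$timepoints),
              x$n_samples_per_cell, x$cluster_effect))
  cat(sprintf("  precision graph: %s, off-diagonal %.2f\n",
              x$network_model, x$precision_offdiag))
  cat(sprintf("  interactome: star K(1,%d) + biclique %dx%d + %d background nodes\n",
              x$star_size, x$biclique_dims[1], x$biclique_dims[2],
              x$n_background_ppi_nodes))
  cat(sprintf("  genetics: %d subjects x %d SNPs, beta=%.2f, gamma=%.2f, MAF in [%.2f,%.2f]\n",
              x$n_subjects, x$n_snps, x$causal_beta, x$eqtl_gamma,
              x$maf_range[1], x$maf_range[2]))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# Derive a deterministic sub-seed for a named generator stream, keeping it
# inside the 32-bit integer range R requires.
stream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

# Evaluate expr under a named RNG stream without disturbing the caller's RNG.
with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stream_seed(seed, stream))
  expr
}

empty_truth <- function() {
  structure(list(planted_edges = NULL, cluster_membership = NULL,
                 planted_modules = NULL, hub = NULL,
                 enriched_categories = NULL, tf_set = NULL,
                 causal_snp = NULL, eqtl_snp = NULL),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic ground truth\n")
  if (!is.null(x$planted_edges))
    cat(sprintf("  %d planted precision edges\n", nrow(x$planted_edges)))
  if (!is.null(x$cluster_membership)) {
    tb <- table(x$cluster_membership)
    cat("  clusters:", paste(names(tb), tb, sep = "=", collapse = " "), "\n")
  }
  if (!is.null(x$planted_modules))
    cat("  modules:", paste(names(x$planted_modules),
                            lengths(x$planted_modules), sep = "=", collapse = " "),
        if (!is.null(x$hub)) sprintf("(hub %s)", x$hub), "\n")
  if (!is.null(x$causal_snp))
    cat(sprintf("  causal SNP %s (beta=%.2f), eQTL SNP %s (gamma=%.2f)\n",
                x$causal_snp$id, x$causal_snp$beta, x$eqtl_snp$id, x$eqtl_snp$gamma))
  invisible(x)
}

# Planted conditional-dependence graph as a 2-column index matrix.
planted_graph_edges <- function(cfg) {
  n <- cfg$n_genes
  g <- switch(cfg$network_model,
    "scale-free"  = igraph::sample_pa(n, m = 1, directed = FALSE),
    "small-world" = igraph::sample_smallworld(1, n, nei = 2, p = 0.05),
    "hub-star"    = igraph::make_star(min(n, max(4L, n %/% 10L) + 1L),
                                      mode = "undirected", center = 1) +
                    (n - min(n, max(4L, n %/% 10L) + 1L)))
  em <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(em) <- "integer"
  em[em[, 1] > em[, 2], ] <- em[em[, 1] > em[, 2], c(2, 1)]
  em
}

# Build the planted precision matrix: unit diagonal inflated to strict
# diagonal dominance (1 + row-sum of |off-diagonals| + 0.1), off-diagonals
# +/- precision_offdiag on planted edges.
build_precision <- function(n, edges, offdiag) {
  omega <- matrix(0, n, n)
  if (nrow(edges) > 0) {
    sgn <- sample(c(-1, 1), nrow(edges), replace = TRUE)
    for (k in seq_len(nrow(edges))) {
      i <- edges[k, 1]; j <- edges[k, 2]
      omega[i, j] <- omega[j, i] <- sgn[k] * offdiag
    }
  }
  diag(omega) <- 1 + rowSums(abs(omega)) + 0.1
  ev <- min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0)
    stop("planted precision matrix is not positive definite (min eigenvalue ",
         signif(ev, 4), "); refusing to rescale silently")
  omega
}

#' Closed-form partial correlations of a precision matrix
#'
#' The population partial correlation implied by a precision matrix Omega is
#' -omega_ij / sqrt(omega_ii * omega_jj); used as the analytic oracle for the
#' sample estimates.
#'
#' @param omega symmetric positive-definite precision matrix.
#' @return matrix of partial correlations with unit diagonal.
#' @export
true_partial_correlations <- function(omega) {
  d <- sqrt(diag(omega))
  p <- -omega / tcrossprod(d)
  diag(p) <- 1
  p
}

#' Generate a factorial expression matrix with planted structure
#'
#' Draws samples from a multivariate normal whose precision matrix carries the
#' planted conditional-dependence graph, then adds condition x time mean
#' shifts of +/- `cluster_effect` to the four planted response clusters
#' (up/down at each of the first two time points, mimicking an immediate and
#' an early inflammatory wave). Gene-wise baselines are uniform on [6, 12] to
#' mimic log2 intensities.
#'
#' @param cfg a [sim_config()].
#' @return list with `expr` (an `expression_matrix`: `values` genes x samples,
#'   `genes`, `samples`, `metadata`), `truth` (a `synthetic_truth` recording
#'   planted edges, cluster membership and the precision matrix) and `omega`.
#' @export
gen_expression <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_stream(cfg$seed, "expression", {
    n <- cfg$n_genes
    genes <- sprintf("G%04d", seq_len(n))
    edges <- planted_graph_edges(cfg)
    omega <- build_precision(n, edges, cfg$precision_offdiag)
    sigma <- solve(omega)

    meta <- expand.grid(replicate = seq_len(cfg$n_samples_per_cell),
                        timepoint = cfg$timepoints,
                        condition = cfg$conditions,
                        stringsAsFactors = FALSE)
    meta$sample <- sprintf("S%03d_%s_%s_r%02d", seq_len(nrow(meta)),
                           meta$condition, meta$timepoint, meta$replicate)
    meta <- meta[, c("sample", "condition", "timepoint", "replicate")]

    vals <- t(MASS::mvrnorm(nrow(meta), mu = rep(0, n), Sigma = sigma))
    baseline <- runif(n, 6, 12)
    vals <- vals + baseline

    membership <- rep("null", n)
    k <- cfg$cluster_size
    labs <- c(paste0("up_", cfg$timepoints[1]), paste0("down_", cfg$timepoints[1]),
              paste0("up_", cfg$timepoints[2]), paste0("down_", cfg$timepoints[2]))
    idx <- sample.int(n, 4 * k)
    for (c_i in seq_along(labs)) {
      g_i <- idx[((c_i - 1) * k + 1):(c_i * k)]
      membership[g_i] <- labs[c_i]
      tp <- sub("^(up|down)_", "", labs[c_i])
      sgn <- if (startsWith(labs[c_i], "up")) 1 else -1
      treated <- meta$condition == cfg$conditions[1] & meta$timepoint == tp
      vals[g_i, treated] <- vals[g_i, treated] + sgn * cfg$cluster_effect
    }

    dimnames(vals) <- list(genes, meta$sample)
    expr <- structure(list(values = vals, genes = genes, samples = meta$sample,
                           metadata = meta), class = "expression_matrix")
    truth <- empty_truth()
    truth$planted_edges <- cbind(gene_a = genes[edges[, 1]],
                                 gene_b = genes[edges[, 2]])
    truth$cluster_membership <- stats::setNames(membership, genes)
    list(expr = expr, truth = truth, omega = omega)
  })
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples\n",
              length(x$genes), length(x$samples)))
  tb <- table(x$metadata$condition, x$metadata$timepoint)
  print(tb)
  invisible(x)
}

#' Generate a background interactome with planted modules
#'
#' The interactome is the disjoint union of a star K(1, star_size), a complete
#' bipartite module K(a, b), and a configuration-model background with a
#' prescribed sparse degree sequence (degrees 1-3; self-loops and multi-edges
#' rejected). Edge confidences are uniform on (0.5, 0.99]. The background is
#' deliberately free of dense motifs so the planted modules are the only
#' large coherent structures.
#'
#' @param cfg a [sim_config()].
#' @return list with `net` (an `interactome`: edge data frame
#'   `protein_a, protein_b, confidence`) and `truth` recording module
#'   membership and the star hub.
#' @export
gen_interactome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  a <- cfg$biclique_dims[1]; b <- cfg$biclique_dims[2]
  if (cfg$star_size + 1 > cfg$n_background_ppi_nodes ||
      a + b > cfg$n_background_ppi_nodes)
    stop("requested modules larger than the background node budget")
  with_stream(cfg$seed, "interactome", {
    hub <- "STAR_HUB"
    leaves <- sprintf("STAR_L%02d", seq_len(cfg$star_size))
    side_a <- sprintf("BICL_A%02d", seq_len(a))
    side_b <- sprintf("BICL_B%02d", seq_len(b))
    bg <- sprintf("BG%04d", seq_len(cfg$n_background_ppi_nodes))

    star_e <- cbind(hub, leaves)
    bicl_e <- cbind(rep(side_a, each = b), rep(side_b, times = a))

    degs <- sample(c(1L, 2L, 3L), cfg$n_background_ppi_nodes,
                   replace = TRUE, prob = c(0.6, 0.3, 0.1))
    if (sum(degs) %% 2L == 1L) degs[1] <- degs[1] + 1L
    gbg <- igraph::sample_degseq(degs, method = "configuration.simple")
    igraph::V(gbg)$name <- bg
    bg_e <- igraph::as_edgelist(gbg)

    edges <- rbind(star_e, bicl_e, bg_e)
    colnames(edges) <- c("protein_a", "protein_b")
    net <- data.frame(protein_a = edges[, 1], protein_b = edges[, 2],
                      confidence = round(runif(nrow(edges), 0.5, 0.99), 3),
                      stringsAsFactors = FALSE)
    net <- as_interactome(net)
    truth <- empty_truth()
    truth$planted_modules <- list(star = c(hub, leaves),
                                  biclique = c(side_a, side_b))
    truth$hub <- hub
    truth$background_degrees <- stats::setNames(degs, bg)
    list(net = net, truth = truth)
  })
}

#' Generate annotation gene sets enriched in the planted modules
#'
#' One category per planted interactome module, containing a fraction
#' `annotation_q` of its members plus an equal number of background proteins;
#' one transcription-factor target set overlapping the star module at
#' fraction `tf_overlap`; plus unenriched random categories as ballast.
#'
#' @param cfg a [sim_config()].
#' @param truth a `synthetic_truth` carrying `planted_modules` (from
#'   [gen_interactome()]).
#' @param universe optional character vector of all proteins; defaults to the
#'   union of module members and background ids implied by `cfg`.
#' @param n_padding background proteins added to each planted category
#'   (default: the module size, so the category is about half module).
#' @param n_null_sets number of random, unenriched categories to add.
#' @return list with `gmt` (named list of categories), `tf_gmt` (named list of
#'   TF target sets) and `truth` updated with `enriched_categories`/`tf_set`.
#' @export
gen_annotations <- function(cfg, truth, universe = NULL, n_padding = NULL,
                            n_null_sets = 5) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "synthetic_truth"))
  if (is.null(truth$planted_modules)) stop("truth carries no planted modules")
  if (is.null(universe))
    universe <- unique(c(unlist(truth$planted_modules),
                         sprintf("BG%04d", seq_len(cfg$n_background_ppi_nodes))))
  with_stream(cfg$seed, "annotations", {
    gmt <- list(); enriched <- character(0)
    for (m in names(truth$planted_modules)) {
      mod <- truth$planted_modules[[m]]
      if (length(mod) == 0) { warning("empty module ", m, "; skipped"); next }
      n_in <- max(1L, round(cfg$annotation_q * length(mod)))
      pool <- setdiff(universe, mod)
      n_pad <- if (is.null(n_padding)) length(mod) else n_padding
      pad <- if (n_pad > 0) sample(pool, min(length(pool), n_pad)) else character(0)
      gmt[[paste0("CAT_", toupper(m))]] <- c(sample(mod, n_in), pad)
      enriched[paste0("CAT_", toupper(m))] <- m
    }
    for (i in seq_len(n_null_sets))
      gmt[[sprintf("CAT_NULL%02d", i)]] <- sample(universe, min(15, length(universe)))
    star <- truth$planted_modules$star
    n_tf <- max(1L, round(cfg$tf_overlap * length(star)))
    tf <- c(sample(star, n_tf),
            sample(setdiff(universe, star), min(10, length(setdiff(universe, star)))))
    tf_gmt <- list(TF1_targets = tf)
    truth$enriched_categories <- enriched
    truth$tf_set <- list(tf = "TF1_targets", module = "star")
    list(gmt = gmt, tf_gmt = tf_gmt, truth = truth)
  })
}

#' Generate genotypes, a scalar phenotype and a cis-eQTL expression vector
#'
#' Genotypes are minor-allele counts drawn Binomial(2, MAF) per SNP under
#' Hardy-Weinberg equilibrium with per-SNP MAF uniform on `maf_range`. The
#' phenotype (a white-matter microstructure surrogate) is
#' `causal_beta * presence(minor allele at the causal SNP) + N(0, 1)`;
#' the expression vector is `eqtl_gamma * allele count at the eQTL SNP +
#' N(0, 1)`. The causal and eQTL SNPs are distinct, recorded in the truth,
#' and planted at loci where their group comparisons are testable: the
#' causal SNP has at least 3 carriers and 3 non-carriers, the eQTL SNP at
#' least 5 homozygous-minor subjects (falling back to the best available
#' locus for small panels).
#'
#' @param cfg a [sim_config()].
#' @return list with `geno` (a `genotype_table`), `pheno` (named numeric),
#'   `expr_vector` (named numeric) and `truth`.
#' @export
gen_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_stream(cfg$seed, "genotypes", {
    n <- cfg$n_subjects; s <- cfg$n_snps
    subjects <- sprintf("SUBJ%04d", seq_len(n))
    snps <- sprintf("rs%05d", seq_len(s))
    mafs <- runif(s, cfg$maf_range[1], cfg$maf_range[2])
    counts <- vapply(mafs, function(m) rbinom(n, 2L, m), integer(n))
    dimnames(counts) <- list(subjects, snps)
    hom <- colSums(counts == 2)
    eligible_eqtl <- snps[hom >= 5]
    if (length(eligible_eqtl) == 0) eligible_eqtl <- snps[which.max(hom)]
    eqtl <- eligible_eqtl[sample.int(length(eligible_eqtl), 1)]
    carriers <- colSums(counts >= 1)
    eligible_causal <- setdiff(snps[carriers >= 3 & n - carriers >= 3], eqtl)
    if (length(eligible_causal) == 0) eligible_causal <- setdiff(snps, eqtl)
    causal <- eligible_causal[sample.int(length(eligible_causal), 1)]
    presence <- as.numeric(counts[, causal] >= 1)
    pheno <- stats::setNames(cfg$causal_beta * presence + rnorm(n), subjects)
    expr_vec <- stats::setNames(cfg$eqtl_gamma * counts[, eqtl] + rnorm(n), subjects)
    truth <- empty_truth()
    truth$causal_snp <- list(id = causal, beta = cfg$causal_beta)
    truth$eqtl_snp <- list(id = eqtl, gamma = cfg$eqtl_gamma)
    truth$maf <- stats::setNames(mafs, snps)
    list(geno = genotype_table(counts), pheno = pheno,
         expr_vector = expr_vec, truth = truth)
  })
}

#' Generate the full synthetic input bundle
#'
#' Convenience wrapper running every generator off one configuration and
#' merging the recorded ground truths.
#'
#' @param cfg a [sim_config()].
#' @return list with `expr`, `omega`, `net`, `gmt`, `tf_gmt`, `geno`, `pheno`,
#'   `expr_vector` and a merged `truth`.
#' @export
gen_all <- function(cfg) {
  e <- gen_expression(cfg)
  i <- gen_interactome(cfg)
  a <- gen_annotations(cfg, i$truth)
  g <- gen_genotypes(cfg)
  truth <- a$truth
  truth$planted_edges <- e$truth$planted_edges
  truth$cluster_membership <- e$truth$cluster_membership
  truth$causal_snp <- g$truth$causal_snp
  truth$eqtl_snp <- g$truth$eqtl_snp
  truth$maf <- g$truth$maf
  list(expr = e$expr, omega = e$omega, net = i$net, gmt = a$gmt,
       tf_gmt = a$tf_gmt, geno = g$geno, pheno = g$pheno,
       expr_vector = g$expr_vector, truth = truth)
}
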