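#' Construct a genotype table
#'
#' @param counts subject x SNP matrix of minor-allele counts (0/1/2, NA for
#'   missing), with subject row names and SNP column names.
#' @return object of class `genotype_table` with per-SNP `maf` (folded to
#'   <= 0.5), `flipped` flags and `call_rate`.
#' @export
genotype_table <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry subject row names and SNP column names")
  bad <- !(counts %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("genotype counts must be 0, 1, 2 or NA")
  storage.mode(counts) <- "integer"
  mafs <- lapply(seq_len(ncol(counts)), function(j) maf(counts[, j]))
  structure(list(counts = counts,
                 subjects = rownames(counts), snps = colnames(counts),
                 maf = stats::setNames(vapply(mafs, as.numeric, 1.0), colnames(counts)),
                 flipped = stats::setNames(
                   vapply(mafs, function(m) isTRUE(attr(m, "flipped")), TRUE),
                   colnames(counts)),
                 call_rate = colMeans(!is.na(counts))),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d subjects x %d SNPs; MAF %.3f-%.3f; call rate >= %.3f\n",
              length(x$subjects), length(x$snps),
              min(x$maf), max(x$maf), min(x$call_rate)))
  invisible(x)
}

#' Minor-allele frequency of a count vector
#'
#' Sum of counts over twice the number of non-missing genotypes, folded to
#' <= 0.5; a fold records an allele flip in the `"flipped"` attribute.
#'
#' @param counts vector of minor-allele counts (0/1/2/NA), >= 1 non-missing.
#' @return frequency in [0, 0.5] with attribute `flipped`.
#' @export
maf <- function(counts) {
  counts <- counts[!is.na(counts)]
  if (length(counts) == 0) stop("no non-missing genotypes")
  f <- sum(counts) / (2 * length(counts))
  flipped <- f > 0.5
  if (flipped) f <- 1 - f
  structure(f, flipped = flipped)
}

#' Genotype quality-control filter
#'
#' Removes SNPs with minor-allele frequency below `maf_min` or genotyping
#' call rate below `call_min`.
#'
#' @param gt a `genotype_table`.
#' @param maf_min minimum MAF (default 0.05).
#' @param call_min minimum call rate (default 0.99).
#' @return filtered `genotype_table` with attribute `qc_report` (counts of
#'   SNPs removed by each filter).
#' @export
qc_filter <- function(gt, maf_min = 0.05, call_min = 0.99) {
  stopifnot(inherits(gt, "genotype_table"))
  fail_maf <- gt$maf < maf_min
  fail_call <- gt$call_rate < call_min
  keep <- !(fail_maf | fail_call)
  if (!any(keep)) stop("no SNPs pass QC")
  out <- genotype_table(gt$counts[, keep, drop = FALSE])
  attr(out, "qc_report") <- list(n_input = length(keep),
                                 n_fail_maf = sum(fail_maf),
                                 n_fail_call = sum(fail_call),
                                 n_kept = sum(keep))
  out
}

#' Minor-allele presence (dominant) coding
#'
#' 1 when at least one minor allele is carried, 0 otherwise; NA propagates.
#'
#' @param counts vector of minor-allele counts.
#' @return integer vector of 0/1 (NA preserved).
#' @export
presence_coding <- function(counts) {
  out <- as.integer(counts >= 1)
  out
}

#' Covariate balance between two subject groups
#'
#' Per covariate: Welch t-test for numeric covariates, Fisher's exact test
#' for two-level covariates; Benjamini-Hochberg adjustment across
#' covariates. Used to check that carriers and non-carriers of a minor
#' allele do not differ in clinical features.
#'
#' @param pheno_table data frame of covariates (rows = subjects).
#' @param group logical or 0/1 vector, one entry per subject.
#' @return data frame: covariate, test, p, q.
#' @export
group_covariate_tests <- function(pheno_table, group) {
  group <- as.logical(group)
  if (!any(group) || !any(!group)) stop("both groups must be non-empty")
  res <- lapply(names(pheno_table), function(v) {
    x <- pheno_table[[v]]
    if (is.numeric(x) && length(unique(stats::na.omit(x))) > 2) {
      wt <- welch_test(x[group], x[!group])
      data.frame(covariate = v, test = "welch", p = wt$p)
    } else {
      tb <- table(factor(group, c(FALSE, TRUE)), x)
      p <- if (ncol(tb) < 2) 1 else stats::fisher.test(tb)$p.value
      data.frame(covariate = v, test = "fisher", p = p)
    }
  })
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p)
  out
}

code_genotype <- function(counts, coding = c("presence", "additive")) {
  coding <- match.arg(coding)
  if (coding == "presence") presence_coding(counts) else as.numeric(counts)
}

#' Single-SNP association with a scalar phenotype
#'
#' Ordinary least squares of the phenotype on the coded genotype (general
#' linear model), two-sided t-test on the genotype coefficient. Presence
#' coding groups subjects by carrying >= 1 minor allele; additive coding
#' uses the allele count. Missing genotypes or phenotypes are dropped
#' pairwise.
#'
#' @param pheno numeric phenotype vector.
#' @param geno_vector minor-allele counts, same length/order as `pheno`.
#' @param coding `"presence"` or `"additive"`.
#' @param covariates optional data frame of covariates entered additively.
#' @return list with `beta`, `t`, `p`, `n`.
#' @export
snp_association <- function(pheno, geno_vector, coding = c("presence", "additive"),
                            covariates = NULL) {
  coding <- match.arg(coding)
  g <- code_genotype(geno_vector, coding)
  ok <- !is.na(g) & !is.na(pheno)
  g <- g[ok]; y <- pheno[ok]
  if (length(unique(g)) < 2) stop("genotype is constant; no association testable")
  if (coding == "presence" && min(table(g)) < 3)
    stop("need >= 3 subjects per genotype group under presence coding")
  dat <- data.frame(y = y, g = g)
  form <- y ~ g
  if (!is.null(covariates)) {
    cov_ok <- covariates[ok, , drop = FALSE]
    dat <- cbind(dat, cov_ok)
    form <- stats::reformulate(c("g", names(cov_ok)), response = "y")
  }
  fit <- stats::lm(form, data = dat)
  cf <- summary(fit)$coefficients["g", ]
  list(beta = unname(cf[1]), t = unname(cf[3]), p = unname(cf[4]),
       n = length(y))
}

# Per-SNP two-sided OLS slope p-values of y on each column of G (additive
# coding, no covariates), via the correlation-t identity. Y may be a matrix
# of phenotype columns (one p per SNP per column).
ols_pvals_matrix <- function(G, Y) {
  n <- nrow(G)
  Gs <- scale(G); Ys <- scale(Y)
  r <- crossprod(Gs, Ys) / (n - 1)
  r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE)
}

#' Self-contained SNP-set association by phenotype permutation
#'
#' Joint association of a SNP set with a phenotype. The set statistic is the
#' sum over SNPs of -log10 of the additive-coding single-SNP association
#' p-values; the self-contained null distribution is obtained by permuting
#' the phenotype across subjects, leaving the genotype correlation structure
#' intact. The empirical p-value is `(1 + #{null >= observed}) / (1 + n_perm)`.
#'
#' @param pheno numeric phenotype, one entry per subject of `gt`.
#' @param gt a `genotype_table` (after QC).
#' @param snp_set character vector of SNP ids within `gt`.
#' @param n_perm number of phenotype permutations.
#' @param seed RNG seed.
#' @return list with `statistic`, `p`, `per_snp_p`, `n_perm`, `seed`.
#' @export
geneset_joint_association <- function(pheno, gt, snp_set, n_perm = 1000, seed = 1) {
  stopifnot(inherits(gt, "genotype_table"))
  snp_set <- intersect(unique(snp_set), gt$snps)
  if (length(snp_set) == 0) stop("SNP set is empty after matching to the table")
  G <- gt$counts[, snp_set, drop = FALSE]
  ok <- stats::complete.cases(G) & !is.na(pheno)
  G <- G[ok, , drop = FALSE]; y <- pheno[ok]
  keep <- apply(G, 2, function(g) length(unique(g)) > 1)
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " constant SNP(s) from the set")
    G <- G[, keep, drop = FALSE]
  }
  if (ncol(G) == 0) stop("no variable SNPs left in the set")
  storage.mode(G) <- "double"
  obs_p <- ols_pvals_matrix(G, matrix(y))
  stat <- sum(-log10(pmax(obs_p, 1e-300)))
  with_stream(seed, "snp_set_permutation", {
    Yp <- replicate(n_perm, sample(y))
    null_p <- ols_pvals_matrix(G, Yp)
    null_stat <- colSums(-log10(pmax(null_p, 1e-300)))
    list(statistic = stat,
         p = (1 + sum(null_stat >= stat)) / (1 + n_perm),
         per_snp_p = stats::setNames(as.numeric(obs_p), colnames(G)),
         n_perm = n_perm, seed = seed)
  })
}

#' Genotype-group eQTL test
#'
#' Compares expression between subjects homozygous for the minor allele
#' (count 2) and all others (counts 0/1) with a two-sided Student t-test
#' (pooled variance).
#'
#' @param expr_vector numeric expression values, one per subject.
#' @param counts minor-allele counts, same order.
#' @return list with `t`, `p`, `group_means` (hom-minor, rest), `n` per
#'   group.
#' @export
eqtl_group_test <- function(expr_vector, counts) {
  ok <- !is.na(counts) & !is.na(expr_vector)
  x <- expr_vector[ok]; g <- counts[ok] == 2
  n2 <- sum(g); n01 <- sum(!g)
  if (n2 < 2 || n01 < 2)
    stop(sprintf("need >= 2 subjects per group (hom-minor: %d, rest: %d)", n2, n01))
  ht <- stats::t.test(x[g], x[!g], var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       group_means = c(hom_minor = mean(x[g]), rest = mean(x[!g])),
       n = c(hom_minor = n2, rest = n01))
}
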