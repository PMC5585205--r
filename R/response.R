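#' Welch two-sample t-test with degenerate-variance handling
#'
#' Welch statistic with Satterthwaite degrees of freedom and two-sided p.
#' When both group variances are zero the test is decided by the means:
#' equal means give t = 0, p = 1; unequal means give p = 0 and the result is
#' flagged degenerate (the statistic is infinite).
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return list with `t`, `p`, `df`, `degenerate`.
#' @export
welch_test <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs >= 2 finite values")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, p = 1, df = NA_real_, degenerate = FALSE))
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0, df = NA_real_,
                degenerate = TRUE))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), degenerate = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with monotonicity enforcement, preserving input order. Missing
#' values propagate and are excluded from the number of tests.
#'
#' @param p numeric vector of p-values in [0, 1] (NA allowed).
#' @return vector of q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

# Vectorised Welch test of treated vs control columns for every row of a
# matrix; returns data frame of t, df, p, with the double-degenerate rows
# resolved as in welch_test().
row_welch <- function(x, treated) {
  a <- x[, treated, drop = FALSE]; b <- x[, !treated, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  zero <- se2 == 0
  if (any(zero)) {
    eq <- zero & (ma == mb)
    t[eq] <- 0; p[eq] <- 1; df[eq] <- NA
    ne <- zero & (ma != mb)
    t[ne] <- sign(ma[ne] - mb[ne]) * Inf; p[ne] <- 0; df[ne] <- NA
  }
  data.frame(diff = ma - mb, t = t, df = df, p = p, degenerate = zero & (ma != mb))
}

#' Per-gene two-way factorial analysis of variance
#'
#' Fits, gene by gene, the fixed-effects model
#' `expression ~ condition * timepoint` by least squares and reports the
#' F-test p-value for each of the three responses: treatment (IL1B), time
#' (Development) and their interaction. Benjamini-Hochberg adjustment is
#' applied within each response across genes. All genes share one model
#' matrix, so the sums of squares are taken from a single multi-response
#' least-squares fit; on the balanced factorial design the sequential and
#' marginal decompositions coincide.
#'
#' Genes with zero variance (or otherwise undefined F statistics) are
#' reported with p = 1, i.e. flagged non-significant rather than dropped.
#'
#' @param expr an `expression_matrix`.
#' @return data frame of class `contrast_result`: per gene, F and p for
#'   `treatment`, `time`, `interaction`, plus BH q-values.
#' @export
fit_factorial <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  meta <- expr$metadata
  cells <- table(meta$condition, meta$timepoint)
  if (any(cells == 0)) {
    miss <- which(cells == 0, arr.ind = TRUE)
    stop("empty design cells: ",
         paste(rownames(cells)[miss[, 1]], colnames(cells)[miss[, 2]],
               sep = ":", collapse = ", "))
  }
  if (any(cells < 2)) stop("need >= 2 replicates per condition x timepoint cell")
  cond <- factor(meta$condition)
  time <- factor(meta$timepoint, levels = unique(meta$timepoint))
  Y <- t(expr$values)   # samples x genes
  fit <- stats::lm(Y ~ cond * time)
  asn <- attr(stats::model.matrix(~ cond * time), "assign")
  asn <- asn[fit$qr$pivot]   # effects rows follow the (pivoted) QR order
  eff <- fit$effects
  n <- nrow(Y); pcols <- length(asn)
  rss <- colSums(eff[(pcols + 1):n, , drop = FALSE]^2)
  df_res <- n - pcols
  constant <- apply(Y, 2, stats::var) == 0   # flat genes: non-significant
  out <- data.frame(gene = expr$genes, stringsAsFactors = FALSE)
  terms <- c(treatment = 1L, time = 2L, interaction = 3L)
  for (nm in names(terms)) {
    rows <- which(asn == terms[[nm]])
    ss <- colSums(eff[rows, , drop = FALSE]^2)
    f <- (ss / length(rows)) / (rss / df_res)
    p <- stats::pf(f, length(rows), df_res, lower.tail = FALSE)
    p[!is.finite(p) | constant] <- 1
    f[constant] <- 0
    out[[paste0("F_", nm)]] <- f
    out[[paste0("p_", nm)]] <- p
  }
  for (nm in names(terms))
    out[[paste0("q_", nm)]] <- bh_adjust(out[[paste0("p_", nm)]])
  class(out) <- c("contrast_result", "data.frame")
  out
}

#' Per-time-point up/down response clusters
#'
#' For each time point, the per-gene treated-minus-control mean difference is
#' standardized across genes (subtract the gene-wise-difference mean, divide
#' by its SD) to give a Z-score; a Welch test compares the two conditions per
#' gene; and BH adjustment is applied across genes within the time point.
#' A gene is labeled `up` when z > `z_hi`, Welch p < `alpha` and q <= `fdr`;
#' `down` symmetrically below `z_lo`; otherwise `none`.
#'
#' @param expr an `expression_matrix` with both conditions at each time point.
#' @param treated condition label treated as the stimulus (default: first
#'   condition level in the metadata, e.g. IL1B).
#' @param z_hi,z_lo Z-score thresholds for up/down labels.
#' @param alpha nominal Welch p threshold.
#' @param fdr BH q threshold.
#' @return data frame of class `response_clusters`: gene, timepoint, diff, z,
#'   welch_p, welch_q, label.
#' @export
cluster_responses <- function(expr, treated = NULL,
                              z_hi = 1, z_lo = -1, alpha = 0.05, fdr = 0.10) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (length(expr$genes) < 2) stop("need >= 2 genes to standardize differences")
  meta <- expr$metadata
  if (is.null(treated)) treated <- meta$condition[1]
  if (!treated %in% meta$condition) stop("treated condition not found: ", treated)
  res <- list()
  for (tp in unique(meta$timepoint)) {
    sel <- meta$timepoint == tp
    grp <- meta$condition[sel] == treated
    if (!any(grp) || !all(c(TRUE, FALSE) %in% grp))
      stop("both conditions required at timepoint ", tp)
    w <- row_welch(expr$values[, sel, drop = FALSE], grp)
    sd_d <- stats::sd(w$diff)
    if (!is.finite(sd_d) || sd_d == 0) {
      z <- rep(0, nrow(w))
    } else z <- (w$diff - mean(w$diff)) / sd_d
    q <- bh_adjust(w$p)
    label <- rep("none", nrow(w))
    label[z > z_hi & w$p < alpha & q <= fdr] <- "up"
    label[z < z_lo & w$p < alpha & q <= fdr] <- "down"
    res[[tp]] <- data.frame(gene = expr$genes, timepoint = tp, diff = w$diff,
                            z = z, welch_p = w$p, welch_q = q, label = label,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("response_clusters", "data.frame")
  out
}

#' @export
print.response_clusters <- function(x, ...) {
  tb <- table(x$timepoint, x$label)
  cat("Response clusters (genes per label by timepoint):\n")
  print(tb)
  invisible(x)
}

#' Select genes feeding a downstream network
#'
#' Genes with BH q <= `q_max` within the given response, capped at the top
#' `cap` by F-statistic magnitude.
#'
#' @param contrasts a `contrast_result` from [fit_factorial()].
#' @param response one of `"treatment"`, `"time"`, `"interaction"`.
#' @param q_max BH q cutoff.
#' @param cap maximum number of genes returned.
#' @return character vector of gene ids.
#' @export
select_response_genes <- function(contrasts, response = c("treatment", "time", "interaction"),
                                  q_max = 0.05, cap = 500) {
  response <- match.arg(response)
  q <- contrasts[[paste0("q_", response)]]
  f <- contrasts[[paste0("F_", response)]]
  keep <- which(!is.na(q) & q <= q_max)
  keep <- keep[order(f[keep], decreasing = TRUE)]
  contrasts$gene[utils::head(keep, cap)]
}
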