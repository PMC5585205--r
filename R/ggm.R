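#' Shrinkage estimate of the correlation matrix
#'
#' Schafer-Strimmer shrinkage towards the identity: `R* = lambda I +
#' (1 - lambda) R` with `R` the sample correlation matrix and `lambda` the
#' analytic variance-minimizing intensity, the sum of estimated sampling
#' variances of the off-diagonal r_ij divided by the sum of their squares,
#' clipped to [0, 1]. Any positive `lambda` makes `R*` positive definite even
#' when genes outnumber samples.
#'
#' @param X numeric matrix, samples x genes (>= 3 samples).
#' @return list with `R` (shrunk correlation matrix) and `lambda`.
#' @export
shrink_correlation <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 3) stop("need >= 3 samples")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    nm <- colnames(X)[sds == 0]
    if (is.null(nm)) nm <- which(sds == 0)
    stop("constant column(s): ", paste(nm, collapse = ", "))
  }
  Xs <- scale(X)                      # unit (n-1)-denominator variance
  R <- crossprod(Xs) / (n - 1)
  # var-hat of r_ij: w_kij = x_ki x_kj; var = n/(n-1)^3 * sum_k (w_kij - wbar)^2
  sw <- crossprod(Xs)                 # sum_k w_kij = (n-1) r_ij
  sw2 <- crossprod(Xs^2)              # sum_k w_kij^2
  varr <- n / (n - 1)^3 * (sw2 - sw^2 / n)
  off <- upper.tri(R)
  denom <- sum(R[off]^2)
  lambda <- if (denom == 0) 1 else min(1, max(0, sum(varr[off]) / denom))
  Rs <- (1 - lambda) * R
  diag(Rs) <- 1
  list(R = Rs, lambda = lambda)
}

#' Partial correlations from a correlation matrix
#'
#' Inverts the (positive definite) correlation matrix and standardizes:
#' `p_ij = -omega_ij / sqrt(omega_ii omega_jj)`, diagonal set to 1.
#'
#' @param R positive-definite correlation (or covariance) matrix.
#' @return matrix of partial correlations.
#' @export
partial_correlations <- function(R) {
  ch <- tryCatch(chol(R), error = function(e)
    stop("correlation matrix is singular or not positive definite"))
  omega <- chol2inv(ch)
  true_partial_correlations(omega)
}

# Log-density of the null distribution of correlations:
# f0(r; kappa) = (1 - r^2)^((kappa - 3)/2) / Beta(1/2, (kappa - 1)/2).
dcor0_log <- function(r, kappa)
  (kappa - 3) / 2 * log1p(-r^2) - lbeta(0.5, (kappa - 1) / 2)

# Two-sided null p-value: under f0, r^2 ~ Beta(1/2, (kappa-1)/2).
pcor0_tail <- function(r, kappa)
  stats::pbeta(r^2, 0.5, (kappa - 1) / 2, lower.tail = FALSE)

# Least concave majorant of the empirical CDF of p in [0,1]; returns the
# Grenander (monotone non-increasing) density evaluated at each p.
grenander_density <- function(p) {
  n <- length(p)
  ord <- order(p)
  x <- c(0, p[ord], 1)
  y <- c(0, seq_len(n) / n, 1)
  # upper concave hull by monotone chain on (x, y)
  hx <- numeric(n + 2); hy <- numeric(n + 2); m <- 0L
  for (i in seq_along(x)) {
    while (m >= 2L) {
      cr <- (hx[m] - hx[m - 1]) * (y[i] - hy[m - 1]) -
            (hy[m] - hy[m - 1]) * (x[i] - hx[m - 1])
      if (cr >= 0) m <- m - 1L else break
    }
    m <- m + 1L
    hx[m] <- x[i]; hy[m] <- y[i]
  }
  hx <- hx[seq_len(m)]; hy <- hy[seq_len(m)]
  slopes <- diff(hy) / diff(hx)
  dens_sorted <- slopes[findInterval(p[ord], hx, rightmost.closed = TRUE,
                                     left.open = TRUE)]
  dens <- numeric(n)
  dens[ord] <- dens_sorted
  list(density = dens, min_slope = min(slopes), knots = hx, slopes = slopes)
}

#' Empirical-null local false discovery rate for partial correlations
#'
#' Fits the two-component mixture `f(r) = eta0 f0(r; kappa) +
#' (1 - eta0) fA(r)` where the null density is
#' `f0(r; kappa) = (1 - r^2)^((kappa - 3)/2) / B(1/2, (kappa - 1)/2)`
#' (`kappa > 3`). `kappa` is estimated by censored maximum likelihood
#' (observations beyond the `censor_q` quantile of |r| contribute only their
#' null tail probability, which makes the fit robust to the alternative);
#' the mixture density is estimated nonparametrically through the Grenander
#' (monotone) density of the null p-values, whose terminal slope estimates
#' `eta0`. The local fdr is `eta0 f0 / f = eta0 / g(p)`, capped at 1, and is
#' monotone non-increasing in |r|.
#'
#' @param pcors numeric vector of off-diagonal partial correlations in
#'   (-1, 1); at least 100 values.
#' @param censor_q quantile of |r| above which observations are censored when
#'   fitting `kappa`.
#' @return list with `eta0`, `kappa`, `lfdr` (per input value, input order)
#'   and `p` (two-sided null p-values).
#' @export
fit_local_fdr <- function(pcors, censor_q = 0.75) {
  r <- as.numeric(pcors)
  if (length(r) < 100) stop("need >= 100 partial correlations")
  if (any(!is.finite(r)) || any(abs(r) >= 1))
    stop("partial correlations must lie strictly inside (-1, 1)")
  ar <- abs(r)
  r0 <- stats::quantile(ar, censor_q, names = FALSE)
  if (r0 == 0) r0 <- max(ar[ar > 0], 1e-12)
  inside <- ar <= r0
  n_out <- sum(!inside)
  negll <- function(lk) {
    kappa <- 3 + exp(lk)
    ll <- sum(dcor0_log(r[inside], kappa))
    if (n_out > 0) ll <- ll + n_out * log(max(pcor0_tail(r0, kappa), 1e-300))
    -ll
  }
  opt <- stats::optimize(negll, interval = c(log(1e-2), log(1e7)))
  if (!is.finite(opt$objective))
    stop("local-fdr null fit failed to converge (censored likelihood not finite)")
  kappa <- 3 + exp(opt$minimum)
  p <- pcor0_tail(r, kappa)
  gren <- grenander_density(p)
  # censored-ML null proportion: observed central mass over its null
  # probability under the fitted kappa
  p0_inside <- 1 - pcor0_tail(r0, kappa)
  eta0 <- min(1, max(mean(inside) / max(p0_inside, 1e-12), 1e-8))
  lfdr <- pmin(1, eta0 / pmax(gren$density, 1e-300))
  list(eta0 = eta0, kappa = kappa, lfdr = lfdr, p = p)
}

#' Build a graphical Gaussian co-expression network
#'
#' Pipeline over a gene set: shrinkage correlation, joint partial
#' correlations from the full inverse, empirical-null local fdr, and edge
#' retention at `local_fdr <= threshold`. Isolated nodes stay in the node
#' list. The default threshold is the stringent cutoff used at full study
#' scale; small designs cannot reach it, so exploratory analyses typically
#' pass `threshold = 1e-2`.
#'
#' @param gene_set character vector of genes (>= 3), a subset of the
#'   expression matrix rows.
#' @param expr an `expression_matrix`.
#' @param threshold local fdr cutoff for retaining an edge.
#' @param response_label optional label (IL1B, Development, Interaction).
#' @return object of class `ggm_network`: `nodes`, `edges` (data frame
#'   `gene_a, gene_b, pcor, local_fdr`), `eta0`, `kappa`, `lambda`,
#'   `threshold`, `response_label`, and `pcor_matrix`.
#' @export
build_network <- function(gene_set, expr, threshold = 1e-13,
                          response_label = NA_character_) {
  stopifnot(inherits(expr, "expression_matrix"))
  gene_set <- unique(as.character(gene_set))
  if (length(gene_set) < 3) stop("need >= 3 genes to build a network")
  miss <- setdiff(gene_set, expr$genes)
  if (length(miss) > 0)
    stop("genes absent from expression matrix: ",
         paste(utils::head(miss, 5), collapse = ", "))
  X <- t(expr$values[gene_set, , drop = FALSE])
  sh <- shrink_correlation(X)
  P <- partial_correlations(sh$R)
  ut <- which(upper.tri(P), arr.ind = TRUE)
  vals <- P[upper.tri(P)]
  fit <- fit_local_fdr(vals)
  keep <- fit$lfdr <= threshold
  edges <- data.frame(gene_a = gene_set[ut[keep, 1]],
                      gene_b = gene_set[ut[keep, 2]],
                      pcor = vals[keep],
                      local_fdr = fit$lfdr[keep],
                      stringsAsFactors = FALSE)
  structure(list(nodes = gene_set, edges = edges, eta0 = fit$eta0,
                 kappa = fit$kappa, lambda = sh$lambda,
                 threshold = threshold, response_label = response_label,
                 pcor_matrix = P),
            class = "ggm_network")
}

#' @export
print.ggm_network <- function(x, ...) {
  cat(sprintf("ggm_network%s: %d nodes, %d edges (local fdr <= %g)\n",
              if (is.na(x$response_label)) "" else paste0(" [", x$response_label, "]"),
              length(x$nodes), nrow(x$edges), x$threshold))
  cat(sprintf("  shrinkage lambda = %.3f, eta0 = %.3f, kappa = %.1f\n",
              x$lambda, x$eta0, x$kappa))
  invisible(x)
}

#' @export
summary.ggm_network <- function(object, ...) {
  g <- as_igraph(object)
  deg <- igraph::degree(g)
  out <- list(n_nodes = length(object$nodes), n_edges = nrow(object$edges),
              mean_degree = mean(deg), max_degree = if (length(deg)) max(deg) else 0,
              eta0 = object$eta0, kappa = object$kappa, lambda = object$lambda)
  class(out) <- "summary.ggm_network"
  out
}

#' @export
print.summary.ggm_network <- function(x, ...) {
  cat(sprintf("GGM network: %d nodes, %d edges; mean degree %.2f, max %d\n",
              x$n_nodes, x$n_edges, x$mean_degree, x$max_degree))
  cat(sprintf("  eta0 = %.3f, kappa = %.1f, lambda = %.3f\n",
              x$eta0, x$kappa, x$lambda))
  invisible(x)
}

#' Convert a network-like object to igraph
#'
#' @param x a `ggm_network` or `interactome`.
#' @param ... unused.
#' @return an undirected igraph graph including isolated nodes.
#' @export
as_igraph <- function(x, ...) UseMethod("as_igraph")

#' @export
as_igraph.ggm_network <- function(x, ...)
  igraph::graph_from_data_frame(x$edges[, c("gene_a", "gene_b")],
                                directed = FALSE,
                                vertices = data.frame(name = x$nodes))

#' @export
plot.ggm_network <- function(x, ...) {
  g <- as_igraph(x)
  igraph::plot.igraph(g, vertex.size = 4, vertex.label.cex = 0.5, ...)
  invisible(x)
}
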