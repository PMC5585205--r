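# Coerce edge-list data frames / matrices / igraph objects to a simple
# undirected igraph graph.
as_simple_graph <- function(g, nodes = NULL) {
  if (igraph::is_igraph(g)) {
    gg <- g
  } else if (inherits(g, "interactome")) {
    gg <- as_igraph(g)
  } else {
    el <- as.matrix(g)[, 1:2, drop = FALSE]
    storage.mode(el) <- "character"
    verts <- unique(c(as.vector(el), nodes))
    gg <- igraph::graph_from_edgelist(el, directed = FALSE)
    if (length(setdiff(verts, igraph::V(gg)$name)) > 0)
      gg <- gg + setdiff(verts, igraph::V(gg)$name)
  }
  igraph::simplify(igraph::as_undirected(gg))
}

#' Average local clustering coefficient
#'
#' Mean over all nodes of 2 x triangles / (deg (deg - 1)); nodes of degree
#' < 2 contribute 0.
#'
#' @param g an igraph graph, `interactome`, or 2-column edge list.
#' @return scalar in [0, 1].
#' @export
clustering_coefficient <- function(g) {
  g <- as_simple_graph(g)
  if (igraph::vcount(g) == 0) stop("empty graph")
  loc <- igraph::transitivity(g, type = "local", isolates = "zero")
  loc[!is.finite(loc)] <- 0
  mean(loc)
}

# Mean shortest path length on the largest connected component.
largest_component_apl <- function(g) {
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == big))
  if (igraph::vcount(sub) < 2) return(NA_real_)
  igraph::mean_distance(sub)
}

#' Small-world sigma
#'
#' `sigma = (C / C_rand) / (L / L_rand)` where C is the average local
#' clustering coefficient, L the mean shortest path on the largest connected
#' component, and the random reference is the mean over `n_rand`
#' Erdos-Renyi G(n, m) graphs with the same node and edge counts.
#' Disconnected replicates contribute the L of their largest component (a
#' `flagged_disconnected` attribute counts them).
#'
#' @param g graph (see [clustering_coefficient()]); its largest component is
#'   used if disconnected.
#' @param n_rand number of random reference graphs.
#' @param seed RNG seed for the reference ensemble.
#' @return sigma (scalar) with attributes `C`, `L`, `C_rand`, `L_rand`,
#'   `flagged_disconnected`.
#' @export
smallworld_sigma <- function(g, n_rand = 100, seed = 1) {
  g <- as_simple_graph(g)
  comp <- igraph::components(g)
  if (comp$no > 1) {
    big <- which.max(comp$csize)
    g <- igraph::induced_subgraph(g, which(comp$membership == big))
  }
  n <- igraph::vcount(g); m <- igraph::ecount(g)
  if (n < 10) stop("need >= 10 nodes in the largest component")
  C <- clustering_coefficient(g)
  L <- largest_component_apl(g)
  with_stream(seed, "smallworld", {
    Cr <- numeric(n_rand); Lr <- numeric(n_rand); flagged <- 0L
    for (i in seq_len(n_rand)) {
      rg <- igraph::sample_gnm(n, m)
      Cr[i] <- clustering_coefficient(rg)
      if (igraph::components(rg)$no > 1) flagged <- flagged + 1L
      Lr[i] <- largest_component_apl(rg)
    }
    sigma <- (C / mean(Cr)) / (L / mean(Lr))
    attr(sigma, "C") <- C; attr(sigma, "L") <- L
    attr(sigma, "C_rand") <- mean(Cr); attr(sigma, "L_rand") <- mean(Lr)
    attr(sigma, "flagged_disconnected") <- flagged
    sigma
  })
}

#' Continuous-approximation MLE of the power-law degree exponent
#'
#' `gamma = 1 + n / sum(log(k_i / (kmin - 0.5)))` over degrees >= kmin
#' (the Clauset-Shalizi-Newman continuous approximation for discrete data
#' at fixed kmin). Degenerate inputs where every degree equals kmin carry no
#' tail information and raise an error.
#'
#' @param degrees integer vector of node degrees.
#' @param kmin minimum degree included in the fit.
#' @return scalar exponent estimate (> 1).
#' @export
powerlaw_gamma_mle <- function(degrees, kmin = 1) {
  k <- degrees[degrees >= kmin]
  if (length(k) < 10) stop("need >= 10 degrees >= kmin")
  if (all(k == kmin))
    stop("all degrees equal kmin; exponent not identifiable")
  1 + length(k) / sum(log(k / (kmin - 0.5)))
}

#' Degree classes for hiveplot axes
#'
#' Partition nodes into low / mid / high degree bands: degree < `lo`,
#' `lo` <= degree <= `hi`, degree > `hi`.
#'
#' @param g graph (see [clustering_coefficient()]).
#' @param lo,hi band boundaries (defaults 30 and 80).
#' @return named character vector node -> class.
#' @export
degree_classes <- function(g, lo = 30, hi = 80) {
  g <- as_simple_graph(g)
  deg <- igraph::degree(g)
  cls <- ifelse(deg < lo, "low", ifelse(deg <= hi, "mid", "high"))
  stats::setNames(cls, igraph::V(g)$name)
}

#' Topology profile of a network
#'
#' Collects the topological quantities used to contrast the co-expression
#' networks: size, degree summaries, average local clustering, mean shortest
#' path on the largest component, small-world sigma, the power-law degree
#' exponent (NA when not identifiable), and hiveplot degree classes.
#'
#' @param g graph (`ggm_network`, `interactome`, igraph, or edge list).
#' @param n_rand,seed passed to [smallworld_sigma()]; `n_rand = 0` skips it.
#' @param lo,hi passed to [degree_classes()].
#' @return object of class `topology_summary`.
#' @export
topology_summary <- function(g, n_rand = 100, seed = 1, lo = 30, hi = 80) {
  if (inherits(g, "ggm_network")) g <- as_igraph(g)
  g <- as_simple_graph(g)
  deg <- igraph::degree(g)
  sigma <- if (n_rand > 0 && igraph::vcount(g) >= 10 && igraph::ecount(g) > 0)
    tryCatch(as.numeric(smallworld_sigma(g, n_rand, seed)),
             error = function(e) NA_real_) else NA_real_
  gamma <- tryCatch(powerlaw_gamma_mle(deg[deg >= 1]),
                    error = function(e) NA_real_)
  out <- list(n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g),
              mean_degree = if (length(deg)) mean(deg) else 0,
              max_degree = if (length(deg)) max(deg) else 0,
              global_clustering = if (igraph::vcount(g)) clustering_coefficient(g) else NA,
              avg_path_length = largest_component_apl(g),
              smallworld_sigma = sigma, gamma = gamma,
              degree_classes = degree_classes(g, lo, hi))
  class(out) <- "topology_summary"
  out
}

#' @export
print.topology_summary <- function(x, ...) {
  cat(sprintf("Topology: %d nodes, %d edges; mean degree %.2f (max %d)\n",
              x$n_nodes, x$n_edges, x$mean_degree, x$max_degree))
  cat(sprintf("  clustering C = %.3f, path length L = %.2f, sigma = %s, gamma = %s\n",
              x$global_clustering, x$avg_path_length,
              ifelse(is.na(x$smallworld_sigma), "NA", sprintf("%.2f", x$smallworld_sigma)),
              ifelse(is.na(x$gamma), "NA", sprintf("%.2f", x$gamma))))
  tb <- table(factor(x$degree_classes, levels = c("low", "mid", "high")))
  cat("  degree classes:", paste(names(tb), tb, sep = "=", collapse = " "), "\n")
  invisible(x)
}
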