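#' Construct an interactome object
#'
#' @param edges data frame with columns `protein_a`, `protein_b`,
#'   `confidence` (in (0, 1]); parallel edges and self-loops are rejected.
#' @return object of class `interactome`.
#' @export
as_interactome <- function(edges) {
  stopifnot(is.data.frame(edges),
            all(c("protein_a", "protein_b", "confidence") %in% names(edges)))
  if (any(!is.finite(edges$confidence) | edges$confidence <= 0 |
          edges$confidence > 1))
    stop("confidence values must lie in (0, 1]")
  if (any(edges$protein_a == edges$protein_b)) stop("self-interactions not allowed")
  keys <- paste(pmin(edges$protein_a, edges$protein_b),
                pmax(edges$protein_a, edges$protein_b), sep = "\r")
  if (anyDuplicated(keys)) stop("duplicate interactions in edge list")
  structure(list(edges = edges), class = "interactome")
}

#' @export
as_igraph.interactome <- function(x, ...)
  igraph::graph_from_data_frame(x$edges, directed = FALSE)

#' @export
print.interactome <- function(x, ...) {
  g <- as_igraph(x)
  cat(sprintf("interactome: %d proteins, %d interactions (mean degree %.2f)\n",
              igraph::vcount(g), igraph::ecount(g),
              mean(igraph::degree(g))))
  invisible(x)
}

#' Direct interaction network of a query gene set
#'
#' Induced subgraph of the interactome on the query proteins; query members
#' absent from the interactome are dropped with a warning.
#'
#' @param query character vector of protein/gene ids.
#' @param net an `interactome`.
#' @return igraph subgraph on `query` intersected with the interactome.
#' @export
direct_network <- function(query, net) {
  stopifnot(inherits(net, "interactome"))
  g <- as_igraph(net)
  present <- intersect(query, igraph::V(g)$name)
  if (length(present) < length(unique(query)))
    warning(length(unique(query)) - length(present),
            " query gene(s) absent from the interactome; dropped")
  igraph::induced_subgraph(g, present)
}

# log2 degree bin index.
degree_bin <- function(deg) floor(log2(pmax(deg, 1)))

#' Degree-matched permutation test of subnetwork connectivity
#'
#' Empirical significance of the direct interactions among a query set
#' within a background interactome. Null draws replace each query protein by
#' a protein sampled uniformly (without replacement within a draw) from its
#' logarithmic (base-2) degree bin; bins too small for the required
#' multiplicity are widened to neighboring bins with a warning. Two
#' statistics are recomputed per draw: the number of direct edges and the
#' mean direct degree of the drawn set. Empirical p-values use the
#' add-one estimator `(1 + #{null >= observed}) / (1 + n_perm)`, so they are
#' never zero.
#'
#' @param query character vector of protein ids (>= 2 present in `net`).
#' @param net an `interactome`.
#' @param n_perm number of null draws.
#' @param seed RNG seed.
#' @return object of class `connectivity_result`: `n_direct_edges`,
#'   `mean_direct_degree`, `empirical_p_edges`, `empirical_p_degree`,
#'   `n_perm`, `seed`, `null_edges` (the null distribution).
#' @export
ppi_permutation_test <- function(query, net, n_perm = 1000, seed = 1) {
  stopifnot(inherits(net, "interactome"))
  g <- as_igraph(net)
  nodes <- igraph::V(g)$name
  query <- intersect(unique(query), nodes)
  if (length(query) < 2) stop("need >= 2 query proteins present in the interactome")
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE)) > 0
  deg <- rowSums(A)
  bins <- degree_bin(deg)
  qidx <- match(query, nodes)
  qbins <- bins[qidx]
  need <- table(qbins)
  bin_members <- split(seq_along(nodes), bins)
  pools <- list(); widened <- FALSE
  for (b in names(need)) {
    pool <- bin_members[[b]]
    width <- 0L
    while (length(pool) < need[[b]]) {
      width <- width + 1L
      sel <- as.character((as.integer(b) - width):(as.integer(b) + width))
      pool <- unique(unlist(bin_members[intersect(sel, names(bin_members))]))
      widened <- TRUE
      if (width > length(bin_members)) break
    }
    pools[[b]] <- pool
  }
  if (widened)
    warning("some degree bins were smaller than the required multiplicity; widened")
  obs_edges <- sum(A[qidx, qidx]) / 2
  obs_deg <- obs_edges * 2 / length(qidx)
  with_stream(seed, "ppi_permutation", {
    null_edges <- numeric(n_perm)
    for (i in seq_len(n_perm)) {
      draw <- unlist(lapply(names(need), function(b)
        pools[[b]][sample.int(length(pools[[b]]), need[[b]])]))
      null_edges[i] <- sum(A[draw, draw]) / 2
    }
    null_deg <- null_edges * 2 / length(qidx)
    res <- list(n_direct_edges = obs_edges,
                mean_direct_degree = obs_deg,
                empirical_p_edges = (1 + sum(null_edges >= obs_edges)) / (1 + n_perm),
                empirical_p_degree = (1 + sum(null_deg >= obs_deg)) / (1 + n_perm),
                n_perm = n_perm, seed = seed, null_edges = null_edges)
    class(res) <- "connectivity_result"
    res
  })
}

#' @export
print.connectivity_result <- function(x, ...) {
  cat(sprintf("Direct network: %d edges, mean direct degree %.2f\n",
              x$n_direct_edges, x$mean_direct_degree))
  cat(sprintf("  empirical p (edges) = %.4g, p (degree) = %.4g  [%d permutations]\n",
              x$empirical_p_edges, x$empirical_p_degree, x$n_perm))
  invisible(x)
}

#' Edge replication against a reference interactome
#'
#' Counts how many of the supplied edges are present in an independent
#' reference network (order within an edge is ignored).
#'
#' @param edge_list 2-column matrix or data frame of protein pairs.
#' @param reference_net an `interactome`.
#' @return list with `k` (replicated), `n` (total), `fraction`.
#' @export
replicate_edges <- function(edge_list, reference_net) {
  stopifnot(inherits(reference_net, "interactome"))
  el <- as.matrix(edge_list)[, 1:2, drop = FALSE]
  if (nrow(el) == 0) stop("empty edge list")
  keys <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "\r")
  ref <- reference_net$edges
  rkeys <- paste(pmin(ref$protein_a, ref$protein_b),
                 pmax(ref$protein_a, ref$protein_b), sep = "\r")
  k <- sum(keys %in% rkeys)
  list(k = k, n = nrow(el), fraction = k / nrow(el))
}
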