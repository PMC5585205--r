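# --- power graph decomposition and super-power-node (SPN) detection -------
#
# A power graph re-expresses a simple graph through power nodes (sets of
# nodes) and power edges: a power edge (U, V) with U, V disjoint abstracts
# the full biclique between U and V; a clique edge (U, U) abstracts the
# clique inside U. The decomposition here is strict: every base edge is
# abstracted by exactly one power edge, so expansion recovers the original
# edge set exactly (losslessness).

set_key <- function(members) paste(sort(members), collapse = "\r")

# All internal-node member sets (size >= 2) of an hclust tree.
hclust_cut_sets <- function(hc, labels) {
  m <- hc$merge
  sets <- vector("list", nrow(m))
  for (k in seq_len(nrow(m))) {
    pick <- function(x) if (x < 0) -x else sets[[x]]
    sets[[k]] <- c(pick(m[k, 1]), pick(m[k, 2]))
  }
  lapply(sets, function(ix) sort(labels[ix]))
}

# Average-linkage clustering of nodes under Jaccard similarity of
# neighborhoods; returns the dendrogram cut-sets (a laminar family).
jaccard_linkage_sets <- function(A, labels, closed = FALSE) {
  n <- nrow(A)
  if (n < 2) return(list())
  N <- A * 1
  if (closed) diag(N) <- 1
  inter <- tcrossprod(N)
  sz <- rowSums(N)
  uni <- outer(sz, sz, "+") - inter
  J <- ifelse(uni > 0, inter / uni, 0)
  hc <- stats::hclust(stats::as.dist(1 - J), method = "average")
  hclust_cut_sets(hc, labels)
}

#' Candidate power nodes
#'
#' Average-linkage hierarchical clustering of nodes under Jaccard similarity
#' of neighborhoods, run twice: open neighborhoods N(v) (captures biclique
#' sides and star leaf sets) and closed neighborhoods N(v) u {v} (captures
#' cliques). Every dendrogram cut-set of size >= 2 is emitted; the family is
#' laminar within each run, and the union is deduplicated.
#'
#' @param g graph (igraph, `interactome`, or 2-column edge list).
#' @return list of character vectors (sorted member sets).
#' @export
candidate_power_nodes <- function(g) {
  g <- as_simple_graph(g)
  labels <- igraph::V(g)$name
  if (is.null(labels)) {
    labels <- as.character(seq_len(igraph::vcount(g)))
    igraph::V(g)$name <- labels
  }
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE)) > 0
  sets <- c(jaccard_linkage_sets(A, labels, closed = FALSE),
            jaccard_linkage_sets(A, labels, closed = TRUE))
  sets[!duplicated(vapply(sets, set_key, ""))]
}

# Laminar compatibility of a new index set with an accepted family.
laminar_ok <- function(s, family) {
  for (t in family) {
    ov <- length(intersect(s, t))
    if (ov > 0 && ov != length(s) && ov != length(t)) return(FALSE)
  }
  TRUE
}

#' Greedy lossless power-graph decomposition
#'
#' Repeatedly selects the candidate pair (U, V) — disjoint sets (biclique),
#' a set with one of its common neighbors (star), or U = V (clique) — whose
#' required base edges are all present and all currently uncovered,
#' maximizing the number of edges abstracted (at least 2 to count). Ties are
#' broken by smaller |U| + |V|, then by the lexicographically smallest member
#' set. Power nodes accepted into the decomposition must remain laminar
#' (pairwise nested or disjoint). Remaining uncovered edges are emitted as
#' singleton-singleton power edges, so the decomposition is always lossless.
#'
#' @param g graph (igraph, `interactome`, or 2-column edge list).
#' @param candidates optional candidate family (list of character vectors);
#'   defaults to [candidate_power_nodes()]. Singletons are implicit.
#' @return object of class `power_graph`: `base_nodes`, `base_degrees`,
#'   `power_nodes` (named list of the size->=2 sets used), `power_edges`
#'   (list of `u`, `v`, `abstracts`), `n_base_edges`.
#' @export
decompose_power_graph <- function(g, candidates = NULL) {
  g <- as_simple_graph(g)
  if (is.null(igraph::V(g)$name))
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  labels <- sort(igraph::V(g)$name)
  g <- igraph::permute(g, match(igraph::V(g)$name, labels))
  n <- length(labels)
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE)) > 0
  dimnames(A) <- list(labels, labels)
  deg <- rowSums(A)
  if (is.null(candidates)) candidates <- candidate_power_nodes(g)

  cand <- lapply(candidates, function(s) sort(match(s, labels)))
  if (any(vapply(cand, function(s) anyNA(s), TRUE)))
    stop("candidate sets contain nodes absent from the graph")
  # laminarity of the supplied family is enforced at selection time; each
  # clustering run is laminar by construction
  keep <- vapply(cand, function(s) length(s) >= 2 && length(s) <= max(deg) + 1,
                 TRUE)
  cand <- cand[keep]
  cand <- cand[!duplicated(vapply(cand, paste, "", collapse = ","))]

  pair_u <- list(); pair_v <- list(); gain <- integer(0); size <- integer(0)
  key <- character(0)
  add_pair <- function(U, V, gn) {
    pair_u[[length(pair_u) + 1]] <<- U
    pair_v[[length(pair_v) + 1]] <<- V
    gain[length(gain) + 1] <<- gn
    size[length(size) + 1] <<- length(U) + length(V)
    key[length(key) + 1] <<- set_key(labels[union(U, V)])
  }
  for (i in seq_along(cand)) {
    U <- cand[[i]]; su <- length(U)
    # clique edge (U, U)
    if (su >= 3 && min(deg[U]) >= su - 1) {
      sub <- A[U, U]
      if (all(sub[upper.tri(sub)])) add_pair(U, U, su * (su - 1) / 2)
    }
    # star edges (common neighbor singleton, U)
    common <- which(colSums(A[U, , drop = FALSE]) == su)
    common <- setdiff(common, U)
    for (v in common) add_pair(v, U, su)
    # biclique edges with later candidate sets
    if (i < length(cand)) for (j in (i + 1):length(cand)) {
      V <- cand[[j]]; sv <- length(V)
      if (length(intersect(U, V)) > 0) next
      if (min(deg[U]) < sv || min(deg[V]) < su) next
      if (all(A[U, V])) add_pair(U, V, su * sv)
    }
  }

  covered <- matrix(FALSE, n, n)
  accepted <- list()
  family <- list()
  if (length(gain) > 0) {
    ord <- order(-gain, size, key, method = "radix")
    for (k in ord) {
      U <- pair_u[[k]]; V <- pair_v[[k]]
      if (identical(U, V)) {
        sub <- covered[U, U]
        if (any(sub[upper.tri(sub)])) next
      } else if (any(covered[U, V])) next
      if (!laminar_ok(U, family) || !laminar_ok(V, family)) next
      if (identical(U, V)) {
        prs <- t(utils::combn(U, 2))
      } else {
        prs <- cbind(rep(U, times = length(V)), rep(V, each = length(U)))
        prs <- cbind(pmin(prs[, 1], prs[, 2]), pmax(prs[, 1], prs[, 2]))
      }
      covered[prs] <- TRUE
      covered[prs[, c(2, 1), drop = FALSE]] <- TRUE
      if (length(U) >= 2 && !any(vapply(family, identical, TRUE, y = U)))
        family[[length(family) + 1]] <- U
      if (length(V) >= 2 && !identical(U, V) &&
          !any(vapply(family, identical, TRUE, y = V)))
        family[[length(family) + 1]] <- V
      accepted[[length(accepted) + 1]] <-
        list(u = labels[U], v = labels[V],
             abstracts = cbind(labels[prs[, 1]], labels[prs[, 2]]))
    }
  }
  # leftover edges as singleton-singleton power edges
  left <- which(A & !covered & upper.tri(A), arr.ind = TRUE)
  if (nrow(left) > 0) {
    left <- left[order(left[, 1], left[, 2]), , drop = FALSE]
    for (k in seq_len(nrow(left)))
      accepted[[length(accepted) + 1]] <-
        list(u = labels[left[k, 1]], v = labels[left[k, 2]],
             abstracts = cbind(labels[left[k, 1]], labels[left[k, 2]]))
  }
  pn <- family[order(vapply(family, min, 1L))]
  pn <- stats::setNames(lapply(pn, function(s) labels[s]),
                        if (length(pn)) paste0("PN", seq_along(pn)) else character(0))
  structure(list(base_nodes = labels,
                 base_degrees = stats::setNames(as.integer(deg), labels),
                 power_nodes = pn, power_edges = accepted,
                 n_base_edges = sum(A) / 2),
            class = "power_graph")
}

#' @export
print.power_graph <- function(x, ...) {
  cat(sprintf("power_graph: %d base nodes, %d base edges -> %d power edges (%.2fx reduction)\n",
              length(x$base_nodes), x$n_base_edges, length(x$power_edges),
              if (length(x$power_edges)) x$n_base_edges / length(x$power_edges) else NA))
  cat(sprintf("  %d power nodes of size >= 2\n", length(x$power_nodes)))
  invisible(x)
}

#' Expand a power graph back to its base edge set
#'
#' Union of the abstracted pairs over all power edges; fails if any base edge
#' is abstracted more than once (which would violate the strict
#' decomposition).
#'
#' @param pg a `power_graph`.
#' @return 2-column character matrix of base edges (columns sorted within
#'   rows, rows in lexicographic order).
#' @export
expand_power_graph <- function(pg) {
  stopifnot(inherits(pg, "power_graph"))
  if (length(pg$power_edges) == 0)
    return(matrix(character(0), 0, 2))
  allp <- do.call(rbind, lapply(pg$power_edges, `[[`, "abstracts"))
  a <- pmin(allp[, 1], allp[, 2]); b <- pmax(allp[, 1], allp[, 2])
  keys <- paste(a, b, sep = "\r")
  if (anyDuplicated(keys))
    stop("overlapping abstractions: some base edge abstracted twice")
  ord <- order(a, b)
  cbind(a, b)[ord, , drop = FALSE]
}

#' Compression achieved by a power-graph decomposition
#'
#' @param pg a `power_graph` with at least one base edge.
#' @return base edges per power edge (>= 1).
#' @export
edge_reduction <- function(pg) {
  stopifnot(inherits(pg, "power_graph"))
  if (pg$n_base_edges < 1) stop("graph has no base edges")
  pg$n_base_edges / length(pg$power_edges)
}

#' Detect super-power nodes (SPNs)
#'
#' An SPN is a set of power nodes that form a connected graph: the meta-graph
#' has one vertex per power node of size >= 2 plus every singleton incident
#' to such a power node via a power edge, and one meta-edge per power edge
#' joining its two endpoint power nodes. Connected components with at least
#' `min_power_nodes` power nodes and at least `min_proteins` member proteins
#' are reported as SPNs, sorted by member-protein count (largest first) and
#' labeled SPN1, SPN2, ... The protein-count floor separates the main
#' coherent modules from incidental two-edge star fragments. Each SPN's hub
#' is its member protein of maximal base-graph degree.
#'
#' @param pg a `power_graph`.
#' @param min_power_nodes minimum power nodes per SPN.
#' @param min_proteins minimum member proteins per SPN.
#' @return object of class `spn_list`: list of `spn` objects with `label`,
#'   `member_power_nodes`, `member_proteins`, `hub`.
#' @export
find_spns <- function(pg, min_power_nodes = 2, min_proteins = 5) {
  stopifnot(inherits(pg, "power_graph"))
  verts <- character(0); medges <- NULL
  for (pe in pg$power_edges) {
    if (length(pe$u) < 2 && length(pe$v) < 2) next  # singleton-singleton
    ku <- set_key(pe$u); kv <- set_key(pe$v)
    verts <- c(verts, ku, kv)
    medges <- rbind(medges, c(ku, kv))
  }
  if (is.null(medges))
    return(structure(list(), class = "spn_list"))
  verts <- unique(verts)
  mg <- igraph::graph_from_data_frame(as.data.frame(medges),
                                      directed = FALSE,
                                      vertices = data.frame(name = verts))
  mg <- igraph::simplify(mg)
  comp <- igraph::components(mg)
  spns <- list()
  for (ci in seq_len(comp$no)) {
    keys <- verts[comp$membership == ci]
    pns <- lapply(keys, function(k) strsplit(k, "\r", fixed = TRUE)[[1]])
    prot <- sort(unique(unlist(pns)))
    if (length(pns) < min_power_nodes || length(prot) < min_proteins) next
    degs <- pg$base_degrees[prot]
    hub <- prot[order(-degs, prot)][1]
    spns[[length(spns) + 1]] <- list(member_power_nodes = pns,
                                     member_proteins = prot, hub = hub)
  }
  if (length(spns) > 0) {
    spns <- spns[order(-vapply(spns, function(s) length(s$member_proteins), 1L))]
    for (i in seq_along(spns)) {
      spns[[i]]$label <- paste0("SPN", i)
      class(spns[[i]]) <- "spn"
    }
  }
  structure(spns, class = "spn_list")
}

#' @export
print.spn_list <- function(x, ...) {
  if (length(x) == 0) { cat("No SPNs detected\n"); return(invisible(x)) }
  for (s in x)
    cat(sprintf("%s: %d power nodes, %d proteins, hub = %s\n",
                s$label, length(s$member_power_nodes),
                length(s$member_proteins), s$hub))
  invisible(x)
}

#' @export
print.spn <- function(x, ...) {
  cat(sprintf("%s: %d proteins (hub %s)\n  %s\n", x$label,
              length(x$member_proteins), x$hub,
              paste(x$member_proteins, collapse = ", ")))
  invisible(x)
}
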