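# Independent oracles and small fixtures used across the suite.

# Exhaustive-greedy power-graph oracle: at every step enumerate ALL node
# subsets (not just clustering candidates), pick the fully-connected,
# fully-uncovered pair abstracting the most edges (>= 2), with the same
# tie-breaking and laminarity rule as the implementation. Returns the number
# of power edges (including singleton-singleton leftovers). Tiny graphs only.
oracle_power_edges <- function(A, labels) {
  n <- nrow(A)
  subsets <- lapply(seq_len(2^n - 1),
                    function(m) which(bitwAnd(m, 2^(seq_len(n) - 1)) > 0))
  covered <- matrix(FALSE, n, n)
  family <- list()
  n_pe <- 0L
  lam_ok <- function(s) all(vapply(family, function(t) {
    ov <- length(intersect(s, t))
    ov == 0 || ov == length(s) || ov == length(t)
  }, TRUE))
  repeat {
    best <- NULL
    for (U in subsets) for (V in subsets) {
      su <- length(U); sv <- length(V)
      if (su > sv) next
      if (identical(U, V)) {
        if (su < 3) next
        need <- A[U, U]
        if (!all(need[upper.tri(need)])) next
        cv <- covered[U, U]
        if (any(cv[upper.tri(cv)])) next
        gain <- su * (su - 1) / 2
      } else {
        if (length(intersect(U, V)) > 0) next
        if (su * sv < 2) next
        if (!all(A[U, V])) next
        if (any(covered[U, V])) next
        gain <- su * sv
      }
      key <- paste(sort(labels[union(U, V)]), collapse = "\r")
      better <- is.null(best) || gain > best$gain ||
        (gain == best$gain && (su + sv < best$size ||
          (su + sv == best$size && key < best$key)))
      if (better && lam_ok(U) && lam_ok(V))
        best <- list(U = U, V = V, gain = gain, size = su + sv, key = key)
    }
    if (is.null(best)) break
    U <- best$U; V <- best$V
    prs <- if (identical(U, V)) t(utils::combn(U, 2)) else
      cbind(rep(U, times = length(V)), rep(V, each = length(U)))
    prs <- cbind(pmin(prs[, 1], prs[, 2]), pmax(prs[, 1], prs[, 2]))
    covered[prs] <- TRUE
    covered[prs[, c(2, 1), drop = FALSE]] <- TRUE
    if (length(U) >= 2) family[[length(family) + 1]] <- U
    if (length(V) >= 2 && !identical(U, V)) family[[length(family) + 1]] <- V
    n_pe <- n_pe + 1L
  }
  n_pe + sum(A[upper.tri(A)] & !covered[upper.tri(covered)])
}

# Hypergeometric upper tail by explicit binomial-coefficient summation
# (independent of phyper).
oracle_hyper_tail <- function(k, K, n, N) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Adjacency matrix of a named edge list.
adj_from_edges <- function(el, nodes = NULL) {
  nodes <- sort(unique(c(as.vector(el), nodes)))
  A <- matrix(FALSE, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  A[cbind(el[, 1], el[, 2])] <- TRUE
  A[cbind(el[, 2], el[, 1])] <- TRUE
  A
}

# Canonical "a|b" edge keys of a 2-column edge matrix.
edge_keys <- function(el)
  sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "|"))

# Small named graphs used repeatedly.
k33_edges <- function()
  cbind(rep(c("a", "b", "c"), each = 3), rep(c("d", "e", "f"), times = 3))
star_edges <- function(n_leaves = 5)
  cbind("hub", sprintf("leaf%02d", seq_len(n_leaves)))
triangle_edges <- function()
  cbind(c("a", "a", "b"), c("b", "c", "c"))

# Random G(n, p) edge list with stable node names.
gnp_edges <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(stats::runif(n * n) < p, n, n)
  A[lower.tri(A, diag = TRUE)] <- FALSE
  el <- which(A, arr.ind = TRUE)
  cbind(sprintf("v%03d", el[, 1]), sprintf("v%03d", el[, 2]))
}

# Randomized (tie-broken) permutation PIT: exactly Uniform(0,1) under the
# null for an exchangeable discrete statistic.
randomized_pit <- function(obs, null_stats) {
  (sum(null_stats > obs) + stats::runif(1) * (1 + sum(null_stats == obs))) /
    (length(null_stats) + 1)
}
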