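#' Hypergeometric upper-tail probability
#'
#' P(X >= k) where X ~ Hypergeometric(N, K, n): the over-representation
#' p-value for observing k category members in a query of size n drawn from
#' a universe of N genes of which K belong to the category. Computed exactly
#' in log space by [stats::phyper()].
#'
#' @param k overlap count.
#' @param K category size in the universe.
#' @param n query size.
#' @param N universe size.
#' @return upper-tail probability in (0, 1].
#' @export
hypergeom_tail <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || k > min(K, n) || K > N || n > N)
    stop("inconsistent counts: need 0 <= k <= min(K, n) <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric enrichment of a query set against a gene-set collection
#'
#' One-sided over-representation test per category with Benjamini-Hochberg
#' adjustment across categories. Categories are intersected with the
#' universe first; categories empty after intersection are dropped with a
#' warning.
#'
#' @param query character vector of genes, a subset of `universe`.
#' @param gmt named list of character vectors (categories).
#' @param universe character vector of all genes under consideration;
#'   defaults to the union of the collection and the query.
#' @param alpha_adj adjusted-p significance threshold for the flag.
#' @return data frame of class `enrichment_table`: category, k, K, n, N, p,
#'   q, significant.
#' @export
enrich_table <- function(query, gmt, universe = NULL, alpha_adj = 0.01) {
  query <- unique(query)
  if (is.null(universe)) universe <- unique(c(unlist(gmt), query))
  universe <- unique(universe)
  if (!all(query %in% universe)) stop("query must be a subset of the universe")
  sets <- lapply(gmt, intersect, universe)
  empty <- lengths(sets) == 0
  if (any(empty)) {
    warning("dropping ", sum(empty), " categor(ies) empty after intersection: ",
            paste(utils::head(names(sets)[empty], 5), collapse = ", "))
    sets <- sets[!empty]
  }
  N <- length(universe); n <- length(query)
  out <- data.frame(category = names(sets),
                    k = vapply(sets, function(s) length(intersect(s, query)), 1L),
                    K = lengths(sets), n = n, N = N,
                    row.names = NULL, stringsAsFactors = FALSE)
  out$p <- mapply(hypergeom_tail, out$k, out$K, out$n, out$N)
  out$q <- bh_adjust(out$p)
  out$significant <- out$q <= alpha_adj
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Transcription-factor target-set enrichment
#'
#' [enrich_table()] specialised to TF target sets tested against a module,
#' flagged at nominal/adjusted alpha 0.05 (one row per TF).
#'
#' @param tf_targets named list of TF target sets.
#' @param module character vector of module members (the query).
#' @param universe character vector of all genes.
#' @param alpha_adj significance threshold.
#' @return an `enrichment_table`.
#' @export
tf_target_enrichment <- function(tf_targets, module, universe = NULL,
                                 alpha_adj = 0.05) {
  enrich_table(module, tf_targets, universe, alpha_adj = alpha_adj)
}

#' Multi-set overlap test
#'
#' Significance of the common intersection of two or more gene sets within a
#' universe. For two sets the exact hypergeometric tail on the overlap is
#' used; for three or more, a Monte-Carlo test resampling each set uniformly
#' at its observed size and counting replicates whose full intersection
#' reaches the observed one, with the add-one estimator
#' `p = (1 + b) / (1 + n_mc)`.
#'
#' @param sets list of >= 2 character vectors, all subsets of `universe`.
#' @param universe character vector.
#' @param n_mc Monte-Carlo replicates (>= 3 sets).
#' @param seed RNG seed.
#' @return list with `observed` (size of the common intersection), `p`,
#'   `method`, `n_mc` (NA for the exact case).
#' @export
multiset_overlap_test <- function(sets, universe, n_mc = 10000, seed = 1) {
  if (length(sets) < 2) stop("need >= 2 sets")
  sets <- lapply(sets, unique)
  if (any(!unlist(sets) %in% universe))
    stop("all sets must be subsets of the universe")
  if (any(lengths(sets) > length(universe)))
    stop("set larger than the universe")
  obs <- length(Reduce(intersect, sets))
  if (length(sets) == 2) {
    p <- hypergeom_tail(obs, length(sets[[1]]), length(sets[[2]]),
                        length(universe))
    return(list(observed = obs, p = p, method = "hypergeometric", n_mc = NA))
  }
  if (obs == 0)
    return(list(observed = 0, p = 1, method = "monte-carlo", n_mc = n_mc))
  with_stream(seed, "multiset_overlap", {
    b <- 0L
    for (i in seq_len(n_mc)) {
      draw <- lapply(lengths(sets), function(m) sample(universe, m))
      if (length(Reduce(intersect, draw)) >= obs) b <- b + 1L
    }
    list(observed = obs, p = (1 + b) / (1 + n_mc), method = "monte-carlo",
         n_mc = n_mc)
  })
}

# Consensus disorder-promoting residues (Dunker and colleagues).
DISORDER_RESIDUES <- c("A", "R", "G", "Q", "S", "P", "E", "K")

#' Disorder-promoting amino-acid enrichment between two protein groups
#'
#' Per protein, the fraction of residues belonging to the consensus
#' disorder-promoting set {A, R, G, Q, S, P, E, K}; a two-sided Student
#' t-test (pooled variance) compares the two groups.
#'
#' @param sequences named character vector of amino-acid sequences, or a
#'   FASTA file path (read with seqinr).
#' @param set_a,set_b character vectors of sequence ids (each >= 2).
#' @return list with `t`, `p`, `mean_a`, `mean_b`, `fractions` (named, all
#'   proteins used).
#' @export
disorder_enrichment <- function(sequences, set_a, set_b) {
  if (length(sequences) == 1 && file.exists(sequences))
    sequences <- read_fasta(sequences)
  if (length(set_a) < 2 || length(set_b) < 2)
    stop("each group needs >= 2 proteins")
  ids <- c(set_a, set_b)
  miss <- setdiff(ids, names(sequences))
  if (length(miss) > 0)
    stop("sequences missing for: ", paste(utils::head(miss, 5), collapse = ", "))
  if (any(nchar(sequences[ids]) == 0)) stop("empty sequence(s) present")
  frac <- vapply(sequences[ids], function(s) {
    aa <- strsplit(toupper(s), "")[[1]]
    mean(aa %in% DISORDER_RESIDUES)
  }, 1.0)
  fa <- frac[set_a]; fb <- frac[set_b]
  if (stats::var(fa) + stats::var(fb) == 0) {
    t <- if (mean(fa) == mean(fb)) 0 else sign(mean(fa) - mean(fb)) * Inf
    p <- if (t == 0) 1 else 0
  } else {
    ht <- stats::t.test(fa, fb, var.equal = TRUE)
    t <- unname(ht$statistic); p <- ht$p.value
  }
  list(t = t, p = p, mean_a = mean(fa), mean_b = mean(fb), fractions = frac)
}
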