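test_that("candidate power nodes find biclique sides, star leaves and cliques", {
  cands <- candidate_power_nodes(k33_edges())
  keys <- vapply(cands, paste, "", collapse = ",")
  expect_true("a,b,c" %in% keys)
  expect_true("d,e,f" %in% keys)
  # star: all leaves share an identical open neighborhood
  cands2 <- candidate_power_nodes(star_edges(5))
  keys2 <- vapply(cands2, paste, "", collapse = ",")
  expect_true(paste(sprintf("leaf%02d", 1:5), collapse = ",") %in% keys2)
  # triangle: closed neighborhoods identical -> the clique is a candidate
  cands3 <- candidate_power_nodes(triangle_edges())
  expect_true("a,b,c" %in% vapply(cands3, paste, "", collapse = ","))
})

test_that("each clustering run yields a laminar family", {
  el <- gnp_edges(25, 0.2, seed = 11)
  g <- powerggm:::as_simple_graph(el)
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE)) > 0
  labels <- igraph::V(g)$name
  for (closed in c(FALSE, TRUE)) {
    fam <- powerggm:::jaccard_linkage_sets(A, labels, closed = closed)
    for (i in seq_along(fam)) for (j in seq_len(i - 1)) {
      ov <- length(intersect(fam[[i]], fam[[j]]))
      expect_true(ov == 0 || ov == length(fam[[i]]) || ov == length(fam[[j]]))
    }
  }
})

test_that("decomposition matches the exhaustive greedy oracle on worked cases", {
  cases <- list(k33 = list(el = k33_edges(), m = 9),
                star = list(el = star_edges(5), m = 5),
                triangle = list(el = triangle_edges(), m = 3))
  for (nm in names(cases)) {
    el <- cases[[nm]]$el
    pg <- decompose_power_graph(el)
    A <- adj_from_edges(el)
    expect_equal(length(pg$power_edges),
                 oracle_power_edges(A, rownames(A)), info = nm)
    expect_equal(edge_reduction(pg), cases[[nm]]$m, info = nm)
    expect_equal(nrow(expand_power_graph(pg)), cases[[nm]]$m, info = nm)
  }
  # K33: a single biclique power edge abstracting all 9 edges
  pg <- decompose_power_graph(k33_edges())
  expect_length(pg$power_edges, 1)
  expect_setequal(pg$power_edges[[1]]$u, c("a", "b", "c"))
  expect_setequal(pg$power_edges[[1]]$v, c("d", "e", "f"))
  # star: ({hub}, {leaves})
  pgs <- decompose_power_graph(star_edges(5))
  sides <- list(pgs$power_edges[[1]]$u, pgs$power_edges[[1]]$v)
  expect_true(any(vapply(sides, identical, TRUE, y = "hub")))
  # triangle: clique power edge (U, U)
  pgt <- decompose_power_graph(triangle_edges())
  expect_identical(pgt$power_edges[[1]]$u, pgt$power_edges[[1]]$v)
})

test_that("expansion is the exact inverse of decomposition", {
  for (s in 1:25) {
    el <- gnp_edges(30, 0.2, seed = s)
    pg <- decompose_power_graph(el)
    expect_identical(edge_keys(expand_power_graph(pg)), edge_keys(el))
    expect_gte(edge_reduction(pg), 1)
  }
})

test_that("power nodes stay laminar and edges are abstracted exactly once", {
  el <- gnp_edges(40, 0.25, seed = 77)
  pg <- decompose_power_graph(el)
  fam <- pg$power_nodes
  for (i in seq_along(fam)) for (j in seq_len(i - 1)) {
    ov <- length(intersect(fam[[i]], fam[[j]]))
    expect_true(ov == 0 || ov == length(fam[[i]]) || ov == length(fam[[j]]))
  }
  # expand_power_graph() errors on double abstraction; here it must succeed
  expect_silent(expand_power_graph(pg))
  # and a doctored power graph with a duplicated abstraction fails
  pg_bad <- pg
  pg_bad$power_edges <- c(pg_bad$power_edges, pg_bad$power_edges[1])
  expect_error(expand_power_graph(pg_bad), "twice")
})

test_that("edge cases: empty graph, single edge", {
  pg1 <- decompose_power_graph(cbind("x", "y"))
  expect_equal(edge_reduction(pg1), 1.0)
  expect_equal(nrow(expand_power_graph(pg1)), 1)
  g0 <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(g0)$name <- c("a", "b", "c")
  pg0 <- decompose_power_graph(g0)
  expect_length(pg0$power_edges, 0)
  expect_equal(nrow(expand_power_graph(pg0)), 0)
  expect_error(edge_reduction(pg0), "no base edges")
})

test_that("SPNs: planted star and biclique are found with the right hubs", {
  cfg <- sim_config(star_size = 8, biclique_dims = c(5, 5),
                    n_background_ppi_nodes = 120, seed = 42)
  gi <- gen_interactome(cfg)
  pg <- decompose_power_graph(gi$net)
  spns <- find_spns(pg)
  expect_length(spns, 2)
  star_spn <- Filter(function(s) gi$truth$hub %in% s$member_proteins, spns)
  expect_length(star_spn, 1)
  expect_equal(star_spn[[1]]$hub, gi$truth$hub)
  expect_setequal(star_spn[[1]]$member_proteins, gi$truth$planted_modules$star)
  bic_spn <- Filter(function(s) !gi$truth$hub %in% s$member_proteins, spns)
  expect_setequal(bic_spn[[1]]$member_proteins,
                  gi$truth$planted_modules$biclique)
  # SPN protein sets are disjoint across disjoint components
  expect_length(intersect(spns[[1]]$member_proteins,
                          spns[[2]]$member_proteins), 0)
  # labels sorted by size
  expect_equal(spns[[1]]$label, "SPN1")
  expect_gte(length(spns[[1]]$member_proteins),
             length(spns[[2]]$member_proteins))
})

test_that("graphs without qualifying power edges have no SPNs", {
  # a perfect matching: every edge is singleton-singleton
  el <- cbind(sprintf("m%02d", 1:4), sprintf("n%02d", 1:4))
  spns <- find_spns(decompose_power_graph(el))
  expect_length(spns, 0)
})

test_that("power graph JSON round-trips losslessly", {
  el <- gnp_edges(20, 0.25, seed = 13)
  pg <- decompose_power_graph(el)
  path <- tempfile(fileext = ".json")
  write_power_graph(pg, path)
  pg2 <- read_power_graph(path)
  expect_identical(edge_keys(expand_power_graph(pg2)),
                   edge_keys(expand_power_graph(pg)))
  expect_equal(pg2$n_base_edges, pg$n_base_edges)
  unlink(path)
})
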