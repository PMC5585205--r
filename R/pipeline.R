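# --- pipeline orchestration ------------------------------------------------

PIPELINE_STAGES <- c("simulate", "respond", "ggm", "topology", "powergraph",
                     "ppi", "enrich", "genetics")

STAGE_DEPS <- list(simulate = character(0),
                   respond = "simulate",
                   ggm = c("simulate", "respond"),
                   topology = "ggm",
                   powergraph = "simulate",
                   ppi = c("simulate", "powergraph"),
                   enrich = c("simulate", "powergraph"),
                   genetics = "simulate")

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra) > 0)
    stop("unknown ", where, " key(s): ", paste(extra, collapse = ", "))
}

#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]: stage toggles and the
#' per-stage parameters, mirroring each stage's defaults. Unknown keys are
#' rejected.
#'
#' @param sim list of arguments for [sim_config()] (the `seed` there is
#'   overridden by the global `seed`).
#' @param stages character vector of enabled stages, in any order; each
#'   enabled stage requires its upstream dependencies.
#' @param response list: `z_hi`, `z_lo`, `alpha`, `fdr` for
#'   [cluster_responses()]; `q_max`, `cap` for [select_response_genes()].
#' @param ggm list: `threshold` (local fdr edge cutoff; the desk-scale
#'   default 1e-2 rather than the full-study 1e-13).
#' @param topology list: `n_rand` random reference graphs for sigma.
#' @param ppi list: `n_perm` permutations.
#' @param genetics list: `n_perm`, `maf_min`, `call_min`, `set_size`.
#' @param seed global integer seed; every stage derives its stream from it.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = list(), stages = PIPELINE_STAGES,
                            response = list(), ggm = list(), topology = list(),
                            ppi = list(), genetics = list(), seed = 1L) {
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  for (s in stages) {
    missing_deps <- setdiff(STAGE_DEPS[[s]], stages)
    if (length(missing_deps) > 0)
      stop("stage '", s, "' requires disabled stage(s): ",
           paste(missing_deps, collapse = ", "))
  }
  response <- utils::modifyList(list(z_hi = 1, z_lo = -1, alpha = 0.05,
                                     fdr = 0.10, q_max = 0.05, cap = 500),
                                response)
  check_keys(response, c("z_hi", "z_lo", "alpha", "fdr", "q_max", "cap"),
             "response")
  ggm <- utils::modifyList(list(threshold = 1e-2), ggm)
  check_keys(ggm, "threshold", "ggm")
  topology <- utils::modifyList(list(n_rand = 50), topology)
  check_keys(topology, "n_rand", "topology")
  ppi <- utils::modifyList(list(n_perm = 1000), ppi)
  check_keys(ppi, "n_perm", "ppi")
  genetics <- utils::modifyList(list(n_perm = 1000, maf_min = 0.05,
                                     call_min = 0.99, set_size = 5),
                                genetics)
  check_keys(genetics, c("n_perm", "maf_min", "call_min", "set_size"),
             "genetics")
  sim$seed <- as.integer(seed)
  cfg <- list(sim = do.call(sim_config, sim), stages = stages,
              response = response, ggm = ggm, topology = topology,
              ppi = ppi, genetics = genetics, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys mirror the arguments of
#'   [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  obj <- yaml::read_yaml(path)
  check_keys(obj, c("sim", "stages", "response", "ggm", "topology", "ppi",
                    "genetics", "seed"), "configuration")
  do.call(pipeline_config, obj)
}

#' Write SPNs as a TSV (spn_label, protein, is_hub)
#'
#' @param spns an `spn_list`.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_spns <- function(spns, path) {
  rows <- lapply(spns, function(s)
    data.frame(spn_label = s$label, protein = s$member_proteins,
               is_hub = as.integer(s$member_proteins == s$hub),
               stringsAsFactors = FALSE))
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(spn_label = character(0), protein = character(0),
               is_hub = integer(0))
  write_tsv_strict(df, path)
}

# Rank-based AUC of scores for a 0/1 label vector.
rank_auc <- function(scores, positive) {
  r <- rank(scores)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Planted-edge recovery AUC
#'
#' Ranks all gene pairs by |partial correlation| and computes the area under
#' the ROC curve for recovering the planted conditional-dependence edges.
#'
#' @param pcor_matrix estimated partial correlation matrix with gene
#'   dimnames.
#' @param planted_edges 2-column matrix of planted gene pairs.
#' @return AUC in [0, 1].
#' @export
planted_edge_auc <- function(pcor_matrix, planted_edges) {
  genes <- rownames(pcor_matrix)
  ut <- which(upper.tri(pcor_matrix), arr.ind = TRUE)
  keys <- paste(pmin(genes[ut[, 1]], genes[ut[, 2]]),
                pmax(genes[ut[, 1]], genes[ut[, 2]]), sep = "\r")
  planted <- paste(pmin(planted_edges[, 1], planted_edges[, 2]),
                   pmax(planted_edges[, 1], planted_edges[, 2]), sep = "\r")
  rank_auc(abs(pcor_matrix[upper.tri(pcor_matrix)]), keys %in% planted)
}

#' Run the full analysis pipeline on simulated data
#'
#' Executes the enabled stages in dependency order — simulate, respond
#' (factorial contrasts + response clusters), ggm (one network per
#' response), topology, powergraph + SPN detection, ppi connectivity,
#' enrichment, genetics — writing every artifact plus a `report.json` and a
#' `manifest.json` (parameters, seed, md5 content hashes) under `out_dir`.
#' Since the ground truth of the simulation is recorded, the report also
#' carries recovery metrics: was the planted hub recovered, the planted-edge
#' AUC, the rank of the planted annotation category, and cluster
#' recall/false-positive rates. A stage failure halts the run naming the
#' stage; artifacts already written are retained.
#'
#' @param config a `pipeline_config`.
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return the report, invisibly (a nested list, also written as JSON).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[powerggm] ", ...)
  artifacts <- character(0)
  report <- list(seed = config$seed, stages = config$stages)
  stage <- "setup"
  run_stage <- function(name, fun) {
    stage <<- name
    tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  keep <- function(path) artifacts <<- c(artifacts, path)

  sim <- NULL
  if ("simulate" %in% config$stages) run_stage("simulate", function() {
    say("simulate: generating inputs (seed ", config$seed, ")")
    sim <<- gen_all(config$sim)
    write_expression(sim$expr, file.path(out_dir, "expression.tsv"),
                     file.path(out_dir, "metadata.tsv"))
    write_interactome(sim$net, file.path(out_dir, "interactome.tsv"))
    write_gmt(sim$gmt, file.path(out_dir, "annotations.gmt"))
    write_gmt(sim$tf_gmt, file.path(out_dir, "tf_targets.gmt"))
    write_genotypes(sim$geno, file.path(out_dir, "genotypes.tsv"))
    write_phenotype(sim$pheno, file.path(out_dir, "phenotype.tsv"))
    jsonlite::write_json(
      list(cluster_membership = as.list(sim$truth$cluster_membership),
           planted_modules = sim$truth$planted_modules,
           hub = sim$truth$hub,
           causal_snp = sim$truth$causal_snp, eqtl_snp = sim$truth$eqtl_snp),
      file.path(out_dir, "truth.json"), auto_unbox = TRUE, pretty = TRUE)
    for (f in c("expression.tsv", "metadata.tsv", "interactome.tsv",
                "annotations.gmt", "tf_targets.gmt", "genotypes.tsv",
                "phenotype.tsv", "truth.json"))
      keep(file.path(out_dir, f))
  })

  contrasts <- NULL; clusters <- NULL
  if ("respond" %in% config$stages) run_stage("respond", function() {
    say("respond: factorial contrasts and response clusters")
    contrasts <<- fit_factorial(sim$expr)
    rp <- config$response
    clusters <<- cluster_responses(sim$expr, z_hi = rp$z_hi, z_lo = rp$z_lo,
                                   alpha = rp$alpha, fdr = rp$fdr)
    write_tsv_strict(contrasts, file.path(out_dir, "contrasts.tsv"))
    write_tsv_strict(clusters, file.path(out_dir, "clusters.tsv"))
    keep(file.path(out_dir, "contrasts.tsv"))
    keep(file.path(out_dir, "clusters.tsv"))
    tb <- table(clusters$timepoint, clusters$label)
    report$clusters_per_timepoint <<-
      lapply(stats::setNames(rownames(tb), rownames(tb)),
             function(r) as.list(stats::setNames(as.integer(tb[r, ]), colnames(tb))))
    truth_cl <- sim$truth$cluster_membership
    tp1 <- config$sim$timepoints[1]
    up1 <- names(truth_cl)[truth_cl == paste0("up_", tp1)]
    nulls <- names(truth_cl)[truth_cl == "null"]
    cl1 <- clusters[clusters$timepoint == tp1, ]
    report$recovery$cluster_recall_up_P1 <<-
      mean(cl1$label[match(up1, cl1$gene)] == "up")
    any_label <- clusters$label != "none"
    report$recovery$cluster_null_fpr <<-
      mean(vapply(nulls, function(g) any(any_label[clusters$gene == g]), TRUE))
  })

  networks <- list()
  if ("ggm" %in% config$stages) run_stage("ggm", function() {
    labels <- c(treatment = "IL1B", time = "Development",
                interaction = "Interaction")
    for (resp in names(labels)) {
      genes <- select_response_genes(contrasts, resp,
                                     q_max = config$response$q_max,
                                     cap = config$response$cap)
      if (length(genes) < 15) {  # < 15 genes -> < 100 gene pairs: local fdr unfittable
        say("ggm: only ", length(genes), " genes selected for ",
            labels[[resp]], "; network skipped")
        next
      }
      say("ggm: ", labels[[resp]], " network on ", length(genes), " genes")
      net <- build_network(genes, sim$expr, threshold = config$ggm$threshold,
                           response_label = labels[[resp]])
      networks[[labels[[resp]]]] <<- net
      base <- file.path(out_dir, paste0("network_", tolower(labels[[resp]])))
      write_ggm_network(net, paste0(base, "_edges.tsv"),
                        paste0(base, "_nodes.tsv"))
      keep(paste0(base, "_edges.tsv")); keep(paste0(base, "_nodes.tsv"))
    }
    report$networks <<- lapply(networks, function(nw)
      list(n_nodes = length(nw$nodes), n_edges = nrow(nw$edges),
           eta0 = nw$eta0, kappa = nw$kappa, lambda = nw$lambda))
    if (!is.null(sim$truth$planted_edges)) {
      full <- shrink_correlation(t(sim$expr$values))
      P <- partial_correlations(full$R)
      dimnames(P) <- list(sim$expr$genes, sim$expr$genes)
      report$recovery$planted_edge_auc <<-
        planted_edge_auc(P, sim$truth$planted_edges)
    }
  })

  if ("topology" %in% config$stages) run_stage("topology", function() {
    say("topology: profiling ", length(networks), " network(s)")
    report$topology <<- lapply(networks, function(nw) {
      ts <- topology_summary(nw, n_rand = config$topology$n_rand,
                             seed = config$seed)
      cls <- table(factor(ts$degree_classes, c("low", "mid", "high")))
      list(n_nodes = ts$n_nodes, n_edges = ts$n_edges,
           mean_degree = ts$mean_degree, max_degree = ts$max_degree,
           clustering = ts$global_clustering,
           avg_path_length = ts$avg_path_length,
           smallworld_sigma = ts$smallworld_sigma, gamma = ts$gamma,
           degree_classes = as.list(stats::setNames(as.integer(cls), names(cls))))
    })
  })

  pg <- NULL; spns <- NULL
  if ("powergraph" %in% config$stages) run_stage("powergraph", function() {
    say("powergraph: decomposing the interactome")
    pg <<- decompose_power_graph(sim$net)
    spns <<- find_spns(pg)
    write_power_graph(pg, file.path(out_dir, "power_graph.json"))
    write_spns(spns, file.path(out_dir, "spns.tsv"))
    keep(file.path(out_dir, "power_graph.json"))
    keep(file.path(out_dir, "spns.tsv"))
    report$power_graph <<- list(n_base_edges = pg$n_base_edges,
                                n_power_edges = length(pg$power_edges),
                                edge_reduction = edge_reduction(pg))
    report$spns <<- lapply(spns, function(s)
      list(label = s$label, n_power_nodes = length(s$member_power_nodes),
           n_proteins = length(s$member_proteins), hub = s$hub))
    if (!is.null(sim$truth$hub)) {
      star_spn <- Filter(function(s) sim$truth$hub %in% s$member_proteins,
                         spns)
      report$recovery$hub_recovered <<-
        length(star_spn) == 1 && star_spn[[1]]$hub == sim$truth$hub
      report$recovery$n_spns <<- length(spns)
    }
  })

  if ("ppi" %in% config$stages) run_stage("ppi", function() {
    if (length(spns) == 0) { say("ppi: no SPNs; skipped"); return(invisible()) }
    say("ppi: permutation connectivity of each SPN")
    report$connectivity <<- lapply(spns, function(s) {
      cr <- ppi_permutation_test(s$member_proteins, sim$net,
                                 n_perm = config$ppi$n_perm,
                                 seed = config$seed)
      list(label = s$label, n_direct_edges = cr$n_direct_edges,
           mean_direct_degree = cr$mean_direct_degree,
           p_edges = cr$empirical_p_edges, p_degree = cr$empirical_p_degree)
    })
  })

  if ("enrich" %in% config$stages) run_stage("enrich", function() {
    if (length(spns) == 0) { say("enrich: no SPNs; skipped"); return(invisible()) }
    say("enrich: SPN annotation and TF-target enrichment")
    universe <- pg$base_nodes
    report$enrichment <<- lapply(spns, function(s) {
      et <- enrich_table(s$member_proteins, sim$gmt, universe)
      tf <- tf_target_enrichment(sim$tf_gmt, s$member_proteins, universe)
      list(label = s$label,
           top_category = et$category[1], top_p = et$p[1], top_q = et$q[1],
           n_significant = sum(et$significant),
           tf_top = tf$category[1], tf_p = tf$p[1])
    })
    star_cat <- names(sim$truth$enriched_categories)[
      sim$truth$enriched_categories == "star"]
    star_spn <- Filter(function(s) sim$truth$hub %in% s$member_proteins, spns)
    if (length(star_spn) == 1 && length(star_cat) == 1) {
      et <- enrich_table(star_spn[[1]]$member_proteins, sim$gmt, universe)
      report$recovery$planted_category_rank <<-
        match(star_cat, et$category)
    }
    if (length(spns) >= 2) {
      ov <- multiset_overlap_test(list(spns[[1]]$member_proteins,
                                       spns[[2]]$member_proteins),
                                  universe)
      report$spn_overlap <<- list(observed = ov$observed, p = ov$p)
    }
  })

  if ("genetics" %in% config$stages) run_stage("genetics", function() {
    say("genetics: QC, association, SNP-set and eQTL tests")
    gp <- config$genetics
    gt <- qc_filter(sim$geno, maf_min = gp$maf_min, call_min = gp$call_min)
    causal <- sim$truth$causal_snp$id
    eqtl <- sim$truth$eqtl_snp$id
    assoc <- snp_association(sim$pheno, gt$counts[, causal], "presence")
    others <- setdiff(gt$snps, causal)
    snp_set <- c(causal, utils::head(others, max(0, gp$set_size - 1)))
    setp <- geneset_joint_association(sim$pheno, gt, snp_set,
                                      n_perm = gp$n_perm, seed = config$seed)
    eq <- eqtl_group_test(sim$expr_vector, gt$counts[, eqtl])
    report$genetics <<- list(
      qc = attr(gt, "qc_report"),
      causal_snp = list(id = causal, beta = assoc$beta, t = assoc$t,
                        p = assoc$p),
      snp_set = list(snps = snp_set, statistic = setp$statistic, p = setp$p),
      eqtl = list(id = eqtl, t = eq$t, p = eq$p,
                  group_means = as.list(eq$group_means)))
  })

  stage <- "report"
  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null", na = "null")
  keep(report_path)
  manifest <- list(package = "powerggm",
                   version = as.character(utils::packageVersion("powerggm")),
                   seed = config$seed,
                   parameters = unclass(config)[c("response", "ggm", "topology",
                                                  "ppi", "genetics")],
                   sim = unclass(config$sim),
                   files = as.list(stats::setNames(tools::md5sum(sort(artifacts)),
                                                   basename(sort(artifacts)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("done: ", length(artifacts), " artifacts in ", out_dir)
  invisible(report)
}
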