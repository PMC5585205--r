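# --- format suite ----------------------------------------------------------
# Strict dialects: tab-separated, UTF-8, '#' comment lines, "NA" for missing.
# Every writer/reader pair round-trips exactly.

read_tsv_strict <- function(path, ...) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

write_tsv_strict <- function(df, path, row_names_col = NULL) {
  if (!is.null(row_names_col)) {
    df <- cbind(stats::setNames(data.frame(rownames(df),
                                           stringsAsFactors = FALSE),
                                row_names_col),
                as.data.frame(df, check.names = FALSE))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA")
  invisible(path)
}

#' Write / read an expression matrix with sample metadata
#'
#' Expression values as a gene x sample TSV (first column `gene`), metadata
#' as a TSV with columns `sample`, `condition`, `timepoint`, `replicate`.
#'
#' @param expr an `expression_matrix`.
#' @param path expression TSV path.
#' @param meta_path metadata TSV path.
#' @return (read) an `expression_matrix`; (write) the path, invisibly.
#' @export
write_expression <- function(expr, path, meta_path) {
  stopifnot(inherits(expr, "expression_matrix"))
  write_tsv_strict(as.data.frame(expr$values, check.names = FALSE), path,
                   row_names_col = "gene")
  write_tsv_strict(expr$metadata, meta_path)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path, meta_path) {
  tab <- read_tsv_strict(path)
  meta <- read_tsv_strict(meta_path)
  need <- c("sample", "condition", "timepoint", "replicate")
  if (!all(need %in% names(meta)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  genes <- tab[[1]]
  if (anyDuplicated(genes)) stop("duplicate gene ids in expression table")
  vals <- as.matrix(tab[, -1, drop = FALSE])
  rownames(vals) <- genes
  if (!identical(sort(colnames(vals)), sort(meta$sample)))
    stop("expression columns and metadata samples disagree")
  meta <- meta[match(colnames(vals), meta$sample), ]
  rownames(meta) <- NULL
  structure(list(values = vals, genes = genes, samples = colnames(vals),
                 metadata = meta), class = "expression_matrix")
}

#' Write / read an interactome edge list
#'
#' TSV with columns `protein_a`, `protein_b`, `confidence` (in (0, 1]).
#'
#' @param net an `interactome`.
#' @param path file path.
#' @return (read) an `interactome`; (write) the path, invisibly.
#' @export
write_interactome <- function(net, path) {
  stopifnot(inherits(net, "interactome"))
  write_tsv_strict(net$edges, path)
}

#' @rdname write_interactome
#' @export
read_interactome <- function(path) {
  df <- read_tsv_strict(path)
  need <- c("protein_a", "protein_b", "confidence")
  if (!all(need %in% names(df)))
    stop("interactome TSV must have columns: ", paste(need, collapse = ", "))
  as_interactome(df[, need])
}

#' Write / read gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated members.
#' Duplicate genes within a set are removed with a warning on read.
#'
#' @param gmt named list of character vectors; an optional
#'   `"descriptions"` attribute (named character) supplies column 2.
#' @param path file path.
#' @return (read) named list of character vectors with a `"descriptions"`
#'   attribute; (write) the path, invisibly.
#' @export
write_gmt <- function(gmt, path) {
  desc <- attr(gmt, "descriptions")
  lines <- vapply(names(gmt), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else "na"
    paste(c(nm, d, gmt[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
  sets <- lapply(parts, function(x) {
    g <- x[-(1:2)]
    if (anyDuplicated(g)) {
      warning("duplicate gene(s) in set '", x[1], "'; deduplicated")
      g <- unique(g)
    }
    g
  })
  names(sets) <- vapply(parts, `[[`, "", 1)
  attr(sets, "descriptions") <- stats::setNames(vapply(parts, `[[`, "", 2),
                                                names(sets))
  sets
}

#' Write / read protein sequences in FASTA
#'
#' Thin wrappers over seqinr keeping sequences as plain upper-case strings.
#'
#' @param sequences named character vector of sequences.
#' @param path file path.
#' @return (read) named character vector; (write) the path, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  seqinr::write.fasta(as.list(sequences), names = names(sequences),
                      file.out = path, nbchar = 60)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  stats::setNames(toupper(vapply(seqs, `[[`, "", 1)), names(seqs))
}

#' Write / read a genotype table
#'
#' TSV with first column `subject` and one column per SNP; values 0/1/2 or
#' NA. Any other value is a hard error reporting the offending line.
#'
#' @param gt a `genotype_table`.
#' @param path file path.
#' @return (read) a `genotype_table`; (write) the path, invisibly.
#' @export
write_genotypes <- function(gt, path) {
  stopifnot(inherits(gt, "genotype_table"))
  write_tsv_strict(as.data.frame(gt$counts, check.names = FALSE), path,
                   row_names_col = "subject")
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  df <- read_tsv_strict(path, colClasses = "character")
  if (names(df)[1] != "subject") stop("first genotype column must be 'subject'")
  m <- as.matrix(df[, -1, drop = FALSE])
  ok <- m %in% c("0", "1", "2", "NA", NA)
  if (!all(ok)) {
    bad_rows <- sort(unique(((which(!ok) - 1) %% nrow(m)) + 1))
    stop("invalid genotype value(s) at data line(s): ",
         paste(bad_rows + 1, collapse = ", "))   # +1 for the header line
  }
  suppressWarnings(storage.mode(m) <- "integer")
  rownames(m) <- df$subject
  genotype_table(m)
}

#' Write / read a phenotype table
#'
#' TSV with columns `subject`, `phenotype` and optional covariate columns.
#'
#' @param pheno named numeric vector, or data frame with a `subject` column.
#' @param path file path.
#' @return (read) data frame; (write) the path, invisibly.
#' @export
write_phenotype <- function(pheno, path) {
  if (!is.data.frame(pheno))
    pheno <- data.frame(subject = names(pheno), phenotype = as.numeric(pheno),
                        stringsAsFactors = FALSE)
  write_tsv_strict(pheno, path)
}

#' @rdname write_phenotype
#' @export
read_phenotype <- function(path) {
  df <- read_tsv_strict(path)
  if (!all(c("subject", "phenotype") %in% names(df)))
    stop("phenotype TSV must have columns 'subject' and 'phenotype'")
  df
}

#' Write / read a GGM network edge list
#'
#' Edge TSV `gene_a, gene_b, pcor, local_fdr` plus a node TSV.
#'
#' @param net a `ggm_network`.
#' @param path edge TSV path.
#' @param node_path node TSV path.
#' @return (write) the path, invisibly; (read) list with `edges`, `nodes`.
#' @export
write_ggm_network <- function(net, path, node_path) {
  stopifnot(inherits(net, "ggm_network"))
  write_tsv_strict(net$edges, path)
  write_tsv_strict(data.frame(gene = net$nodes, stringsAsFactors = FALSE),
                   node_path)
}

#' @rdname write_ggm_network
#' @export
read_ggm_network <- function(path, node_path) {
  list(edges = read_tsv_strict(path), nodes = read_tsv_strict(node_path)$gene)
}

#' Write / read a power graph as JSON
#'
#' Power nodes as sorted member lists, power edges with their abstracted
#' base-edge lists; lossless round trip.
#'
#' @param pg a `power_graph`.
#' @param path file path.
#' @return (read) a `power_graph`; (write) the path, invisibly.
#' @export
write_power_graph <- function(pg, path) {
  stopifnot(inherits(pg, "power_graph"))
  obj <- list(base_nodes = pg$base_nodes,
              base_degrees = as.list(pg$base_degrees),
              power_nodes = lapply(pg$power_nodes, sort),
              power_edges = lapply(pg$power_edges, function(pe)
                list(u = pe$u, v = pe$v,
                     abstracts = apply(pe$abstracts, 1, as.list))),
              n_base_edges = pg$n_base_edges)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_power_graph
#' @export
read_power_graph <- function(path) {
  obj <- jsonlite::read_json(path)
  pe <- lapply(obj$power_edges, function(e)
    list(u = unlist(e$u), v = unlist(e$v),
         abstracts = do.call(rbind, lapply(e$abstracts, unlist))))
  structure(list(base_nodes = unlist(obj$base_nodes),
                 base_degrees = unlist(obj$base_degrees),
                 power_nodes = lapply(obj$power_nodes, unlist),
                 power_edges = pe,
                 n_base_edges = obj$n_base_edges),
            class = "power_graph")
}

#' Read a plain gene list (one id per line, '#' comments allowed)
#'
#' @param path file path.
#' @return character vector.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x <- trimws(x[nzchar(x) & !startsWith(x, "#")])
  unique(x)
}
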