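#' Typed ceRNA network
#'
#' Nodes carry a gene class and a dysregulation direction; edges are typed
#' as `direct` (miRNA binding: miRNA-lncRNA or miRNA-mRNA) or
#' `coexpression` (positively co-expressed lncRNA-mRNA pair). Direct edges
#' are always incident to exactly one miRNA; co-expression edges never
#' touch a miRNA. No self-loops or duplicate edges.
#'
#' @param nodes data.frame with columns `id`, `gene_class`, `direction`.
#' @param edges data.frame with columns `source`, `target`, `edge_type`.
#' @return object of class `cerna_network`.
#' @export
cerna_network <- function(nodes, edges) {
  nodes <- as.data.frame(nodes)[, c("id", "gene_class", "direction")]
  edges <- as.data.frame(edges)[, c("source", "target", "edge_type")]
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  bad <- setdiff(unique(edges$edge_type), c("direct", "coexpression"))
  if (length(bad)) stop("unknown edge_type: ", paste(bad, collapse = ", "))
  unknown <- setdiff(unique(c(edges$source, edges$target)), nodes$id)
  if (length(unknown)) {
    stop("edges reference unknown nodes: ", paste(unknown, collapse = ", "))
  }
  if (any(edges$source == edges$target)) stop("self-loops are not allowed")
  cls <- stats::setNames(nodes$gene_class, nodes$id)
  n_mirna <- (cls[edges$source] == "miRNA") + (cls[edges$target] == "miRNA")
  if (any(edges$edge_type == "direct" & n_mirna != 1L)) {
    stop("direct edges must be incident to exactly one miRNA")
  }
  if (any(edges$edge_type == "coexpression" & n_mirna != 0L)) {
    stop("coexpression edges must connect lncRNA and mRNA")
  }
  # undirected de-duplication: (a,b) == (b,a)
  key <- paste(pmin(edges$source, edges$target),
               pmax(edges$source, edges$target), edges$edge_type)
  edges <- edges[!duplicated(key), , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  cat(sprintf("<cerna_network> %d nodes, %d edges (%d direct, %d coexpression)\n",
              nrow(x$nodes), nrow(x$edges),
              sum(x$edges$edge_type == "direct"),
              sum(x$edges$edge_type == "coexpression")))
  invisible(x)
}

#' Assemble the resistance ceRNA network from retained triplets
#'
#' Nodes are the union of triplet molecules, annotated with gene class and
#' dysregulation direction from the dysregulated set. Each triplet
#' contributes two direct edges (miRNA-lncRNA, miRNA-mRNA) and one
#' co-expression edge (lncRNA-mRNA); duplicates across triplets collapse,
#' so the edge count equals the number of distinct pairs of each kind.
#'
#' @param triplets data.frame from [filter_coexpressed()] (columns
#'   `lncrna_id`, `mirna_id`, `mrna_id`).
#' @param dys dysregulated set from [intersect_consistent()] supplying
#'   direction attributes; every triplet molecule must be present.
#' @return [cerna_network()]
#' @export
build_network <- function(triplets, dys) {
  ids <- unique(c(triplets$lncrna_id, triplets$mirna_id, triplets$mrna_id))
  m <- match(ids, dys$molecule_id)
  if (anyNA(m)) {
    stop("triplet molecules absent from dysregulated set: ",
         paste(ids[is.na(m)], collapse = ", "))
  }
  nodes <- data.frame(id = ids, gene_class = dys$gene_class[m],
                      direction = dys$direction[m])
  edges <- rbind(
    data.frame(source = triplets$mirna_id, target = triplets$lncrna_id,
               edge_type = "direct"),
    data.frame(source = triplets$mirna_id, target = triplets$mrna_id,
               edge_type = "direct"),
    data.frame(source = triplets$lncrna_id, target = triplets$mrna_id,
               edge_type = "coexpression"))
  cerna_network(nodes, edges)
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    net$edges, directed = FALSE,
    vertices = net$nodes[, c("id", "gene_class", "direction")])
}

#' Write a ceRNA network to GraphML, SIF, or edge-list TSV
#'
#' GraphML preserves all node and edge attributes and is loadable by
#' Cytoscape and igraph; SIF encodes edge type as the relation column;
#' the edge TSV carries both node attributes and edge type in plain
#' columns.
#'
#' @param net [cerna_network()]
#' @param path output file path.
#' @param format `"graphml"`, `"sif"`, or `"edge_tsv"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("graphml", "sif", "edge_tsv")) {
  format <- match.arg(format)
  if (!nrow(net$edges)) warning("writing network with zero edges")
  if (format == "graphml") {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  } else if (format == "sif") {
    lines <- sprintf("%s\t%s\t%s", net$edges$source, net$edges$edge_type,
                     net$edges$target)
    writeLines(lines, path)
  } else {
    cls <- stats::setNames(net$nodes$gene_class, net$nodes$id)
    dir <- stats::setNames(net$nodes$direction, net$nodes$id)
    df <- data.frame(
      source = net$edges$source, target = net$edges$target,
      edge_type = net$edges$edge_type,
      source_class = unname(cls[net$edges$source]),
      source_direction = unname(dir[net$edges$source]),
      target_class = unname(cls[net$edges$target]),
      target_direction = unname(dir[net$edges$target]))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a ceRNA network written by [write_network()]
#'
#' SIF carries no node attributes, so only GraphML and edge TSV
#' round-trip the full network; SIF reading recovers topology and edge
#' types with node attributes set to `NA`.
#'
#' @param path file path.
#' @param format `"graphml"`, `"sif"`, or `"edge_tsv"`.
#' @return [cerna_network()] (node attributes `NA` for SIF).
#' @export
read_network <- function(path, format = c("graphml", "sif", "edge_tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- data.frame(id = igraph::vertex_attr(g, "name"),
                        gene_class = igraph::vertex_attr(g, "gene_class"),
                        direction = igraph::vertex_attr(g, "direction"))
    ed <- igraph::as_data_frame(g, what = "edges")
    edges <- data.frame(source = ed$from, target = ed$to,
                        edge_type = ed$edge_type)
    if (!nrow(ed)) edges <- data.frame(source = character(0),
                                       target = character(0),
                                       edge_type = character(0))
    return(cerna_network(nodes, edges))
  }
  if (format == "sif") {
    raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                             colClasses = "character")
    edges <- data.frame(source = raw[[1L]], target = raw[[3L]],
                        edge_type = raw[[2L]])
    ids <- unique(c(edges$source, edges$target))
    nodes <- data.frame(id = ids, gene_class = NA_character_,
                        direction = NA_character_)
    out <- list(nodes = nodes, edges = edges)
    class(out) <- "cerna_network"
    return(out)
  }
  df <- utils::read.delim(path, sep = "\t", colClasses = "character")
  ids <- unique(c(df$source, df$target))
  first <- function(id, col_s, col_t) {
    v <- c(stats::setNames(df[[col_s]], df$source),
           stats::setNames(df[[col_t]], df$target))
    unname(v[ids])
  }
  nodes <- data.frame(id = ids,
                      gene_class = first(ids, "source_class", "target_class"),
                      direction = first(ids, "source_direction",
                                        "target_direction"))
  cerna_network(nodes, df[, c("source", "target", "edge_type")])
}

#' Read gene-set signatures from a GMT file
#'
#' @param path GMT path (set name, description, then member genes,
#'   tab-separated).
#' @return named list of character vectors (set name -> gene ids).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("no records in ", path)
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(x) {
    if (length(x) < 3L) stop("GMT line with fewer than 3 fields")
    unique(x[-(1:2)])
  })
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 1L)
  sets
}

#' Write gene-set signatures to a GMT file
#' @param sets named list of character vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric (Fisher's-exact-style) gene-set enrichment
#'
#' For each annotation term, the one-sided enrichment p-value is the
#' hypergeometric upper tail P(X >= overlap) of drawing the query from the
#' universe. Terms are intersected with the universe first; results are
#' sorted by p-value and report gene count (overlap) and gene ratio
#' (overlap / query size).
#'
#' @param query_genes character vector of query gene ids (must be within
#'   `universe`).
#' @param annotation named list of gene sets (e.g. from [read_gmt()]).
#' @param universe character vector of background gene ids; defaults to
#'   the union of all annotation genes.
#' @param adjust_method optional [stats::p.adjust()] method for an extra
#'   `p_adjust` column (default `"none"`, column equals raw p).
#' @return data.frame with `term`, `count`, `term_size`, `gene_ratio`,
#'   `p_value`, `p_adjust`, `genes` (`;`-joined overlap), sorted by p.
#' @export
enrich_fisher <- function(query_genes, annotation, universe = NULL,
                          adjust_method = "none") {
  if (!length(query_genes)) stop("empty query gene set")
  if (is.null(universe)) universe <- unique(unlist(annotation))
  universe <- unique(universe)
  query_genes <- unique(query_genes)
  outside <- setdiff(query_genes, universe)
  if (length(outside)) {
    stop("query genes outside universe: ", paste(outside, collapse = ", "))
  }
  N <- length(universe)
  n <- length(query_genes)
  rows <- lapply(names(annotation), function(term) {
    set <- intersect(annotation[[term]], universe)
    K <- length(set)
    hit <- intersect(query_genes, set)
    k <- length(hit)
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, count = k, term_size = K,
               gene_ratio = k / n, p_value = p,
               genes = paste(sort(hit), collapse = ";"))
  })
  out <- do.call(rbind, rows)
  out$p_adjust <- stats::p.adjust(out$p_value, method = adjust_method)
  out <- out[order(out$p_value), c("term", "count", "term_size",
                                   "gene_ratio", "p_value", "p_adjust",
                                   "genes")]
  rownames(out) <- NULL
  out
}
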