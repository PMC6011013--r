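#' Categorize signature genes by biomedical-evidence tier
#'
#' `"high"` when the gene appears in the association table with
#' `assoc_p < 0.05`, `"low"` with `assoc_p > 0.05`, `"no_coverage"` when
#' absent. A p-value of exactly 0.05 falls in `"high"`, consistent with
#' the inclusive screening cutoff.
#'
#' @param genes Character vector of signature genes.
#' @param table Association tibble (columns `gene`, `assoc_p`).
#' @return Tibble with `gene`, `assoc_p` (`NA` when uncovered) and
#'   `category`.
#' @export
categorize_genes <- function(genes, table) {
  table <- association_table(table)
  p <- table$assoc_p[match(genes, table$gene)]
  tibble::tibble(
    gene = genes,
    assoc_p = p,
    category = dplyr::case_when(
      is.na(p) ~ "no_coverage",
      p <= 0.05 ~ "high",
      TRUE ~ "low"))
}

#' Pathway co-membership network over a gene set
#'
#' Connects two genes whenever they share at least one annotated pathway;
#' each edge carries the full list of shared pathway ids (one edge per
#' pair, not parallel edges). Isolated genes -- genes sharing no pathway
#' with any other listed gene -- are excluded, so every node has at least
#' one neighbour.
#'
#' @param genes Character vector (typically a fitted signature).
#' @param annot Pathway membership tibble (columns `gene`, `pathway`).
#' @param categories Optional output of [categorize_genes()] attached as
#'   node attributes.
#' @param lit_counts Optional tibble (`gene`, `lit_count`); genes present
#'   get a `known_marker` flag.
#' @return A `pathway_graph` list with `nodes` and `edges` tibbles.
#' @export
comembership_graph <- function(genes, annot, categories = NULL,
                               lit_counts = NULL) {
  a <- annot[annot$gene %in% genes, , drop = FALSE]
  edges <- tibble::tibble(from = character(), to = character(),
                          pathways = character())
  if (nrow(a) > 0) {
    pairs <- a |>
      dplyr::inner_join(a, by = "pathway", relationship = "many-to-many",
                        suffix = c("_a", "_b")) |>
      dplyr::filter(.data$gene_a < .data$gene_b) |>
      dplyr::group_by(from = .data$gene_a, to = .data$gene_b) |>
      dplyr::summarise(
        pathways = paste(sort(unique(.data$pathway)), collapse = ";"),
        .groups = "drop")
    edges <- dplyr::arrange(pairs, .data$from, .data$to)
  }
  node_ids <- sort(unique(c(edges$from, edges$to)))
  nodes <- tibble::tibble(gene = node_ids)
  if (!is.null(categories)) {
    nodes <- dplyr::left_join(nodes, categories, by = "gene")
  }
  if (!is.null(lit_counts)) {
    nodes <- dplyr::left_join(nodes, lit_counts, by = "gene")
    nodes$known_marker <- !is.na(nodes$lit_count)
  }
  structure(list(nodes = nodes, edges = edges), class = "pathway_graph")
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("<pathway_graph> %d node(s), %d edge(s)\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Export a pathway graph in SIF format
#'
#' One line per edge: `geneA <shared-pathways> geneB`.
#'
#' @param graph A `pathway_graph`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sif <- function(graph, path) {
  lines <- sprintf("%s\t%s\t%s", graph$edges$from, graph$edges$pathways,
                   graph$edges$to)
  writeLines(lines, path)
  invisible(path)
}

#' Export a pathway graph in GraphML format
#'
#' @inheritParams write_sif
#' @export
write_graphml <- function(graph, path) {
  g <- igraph::graph_from_data_frame(
    graph$edges, directed = FALSE,
    vertices = as.data.frame(graph$nodes))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
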