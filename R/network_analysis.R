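# Key-target intersection, compound-target (bipartite) network, PPI
# network, degree / betweenness centrality and hub extraction. Graphs are
# igraph objects with a `kind` vertex attribute ("compound" or "target");
# PPI combined scores are kept as an edge attribute but path computations
# are unweighted.

#' Intersect predicted targets with disease-associated targets
#'
#' @param predicted,disease Character vectors of gene symbols (case-
#'   normalized internally).
#' @return Sorted intersection: the key targets.
#' @export
intersect_targets <- function(predicted, disease) {
  sort(intersect(normalize_symbols(predicted), normalize_symbols(disease)))
}

#' Build the compound-target bipartite network
#'
#' One edge per prediction whose target gene is a key target; isolated
#' nodes never arise (every node comes from a retained edge). The graph is
#' simple: duplicate compound-target pairs collapse to one edge.
#'
#' @param predictions Prediction data.frame with columns `compound_id` and
#'   `gene_symbol` (as from [predict_targets_all()]).
#' @param key_targets Character vector of key-target gene symbols.
#' @return An undirected igraph with vertex attribute `kind`.
#' @export
build_ct_network <- function(predictions, key_targets) {
  key_targets <- normalize_symbols(key_targets)
  hits <- predictions[toupper(predictions$gene_symbol) %in% key_targets, ,
                      drop = FALSE]
  if (nrow(hits) == 0) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(igraph::set_vertex_attr(g, "kind", value = character(0)))
  }
  el <- unique(data.frame(from = hits$compound_id,
                          to = toupper(hits$gene_symbol),
                          stringsAsFactors = FALSE))
  g <- igraph::graph_from_data_frame(el, directed = FALSE)
  igraph::V(g)$kind <- ifelse(igraph::V(g)$name %in% el$from,
                              "compound", "target")
  g
}

#' Betweenness centrality (unweighted shortest paths)
#'
#' Shortest-path betweenness with endpoints excluded, each unordered pair
#' counted once (the undirected convention); unnormalized by default.
#'
#' @param graph An igraph.
#' @param normalized Divide by (n-1)(n-2)/2.
#' @return Named numeric vector over vertices.
#' @export
betweenness_centrality <- function(graph, normalized = FALSE) {
  igraph::betweenness(graph, directed = FALSE, weights = NA,
                      normalized = normalized)
}

#' Node centrality table for an annotated graph
#'
#' @param graph An igraph with a `kind` vertex attribute.
#' @return data.frame: id, kind, degree, betweenness, betweenness_norm,
#'   sorted by degree descending (ties by betweenness, then id).
#' @export
centrality_table <- function(graph) {
  n <- igraph::vcount(graph)
  if (n == 0) {
    return(data.frame(id = character(0), kind = character(0),
                      degree = integer(0), betweenness = numeric(0),
                      betweenness_norm = numeric(0), stringsAsFactors = FALSE))
  }
  kind <- igraph::vertex_attr(graph, "kind")
  if (is.null(kind)) kind <- rep("target", n)
  out <- data.frame(id = igraph::V(graph)$name,
                    kind = kind,
                    degree = unname(igraph::degree(graph)),
                    betweenness = unname(betweenness_centrality(graph)),
                    betweenness_norm = unname(
                      betweenness_centrality(graph, normalized = TRUE)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, -out$betweenness, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a STRING-style interaction table into a PPI network
#'
#' Expects tab-separated columns node1, node2, combined_score (0-1000
#' scale). Keeps edges with combined_score >= `score_min` and, when
#' `allowed_nodes` is given, both endpoints in that set; symmetric
#' duplicate rows and self-loops are removed.
#'
#' @param path TSV path.
#' @param score_min Minimum combined score (default 400, medium confidence).
#' @param allowed_nodes Optional character vector (e.g. the key targets).
#' @return An undirected igraph with edge attribute `combined_score` and
#'   vertex attribute `kind = "target"`.
#' @export
read_ppi_edges <- function(path, score_min = 400, allowed_nodes = NULL) {
  if (!file.exists(path)) np_stop("PPI edge file not found: ", path)
  df <- read_tsv(path)
  need <- c("node1", "node2", "combined_score")
  if (!all(need %in% names(df))) {
    np_stop("PPI table must have columns: ", paste(need, collapse = ", "))
  }
  score <- suppressWarnings(as.numeric(df$combined_score))
  if (any(is.na(score))) {
    np_stop("malformed combined_score at data row ", which(is.na(score))[1],
            " of ", path)
  }
  ppi_network(data.frame(node1 = df$node1, node2 = df$node2,
                         combined_score = score, stringsAsFactors = FALSE),
              score_min, allowed_nodes)
}

#' Build a PPI network from an in-memory edge table
#'
#' @param edges data.frame: node1, node2, combined_score.
#' @inheritParams read_ppi_edges
#' @return An undirected igraph.
#' @export
ppi_network <- function(edges, score_min = 400, allowed_nodes = NULL) {
  edges$node1 <- toupper(trimws(edges$node1))
  edges$node2 <- toupper(trimws(edges$node2))
  keep <- edges$combined_score >= score_min & edges$node1 != edges$node2
  if (!is.null(allowed_nodes)) {
    allowed <- normalize_symbols(allowed_nodes)
    keep <- keep & edges$node1 %in% allowed & edges$node2 %in% allowed
  }
  edges <- edges[keep, , drop = FALSE]
  if (nrow(edges) == 0) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(igraph::set_vertex_attr(g, "kind", value = character(0)))
  }
  a <- pmin(edges$node1, edges$node2)
  b <- pmax(edges$node1, edges$node2)
  first <- !duplicated(paste(a, b, sep = "\r"))
  g <- igraph::graph_from_data_frame(
    data.frame(from = a[first], to = b[first],
               combined_score = edges$combined_score[first],
               stringsAsFactors = FALSE),
    directed = FALSE)
  igraph::V(g)$kind <- "target"
  g
}

#' Rank hub targets of a network
#'
#' Two rankings: (a) all target nodes by degree descending (ties by
#' betweenness, then id) truncated to `top_k`; (b) the target nodes also
#' present in `deg_set` — the expression-derived disease core targets —
#' in the same order. Deterministic under ties.
#'
#' @param graph An igraph with a `kind` vertex attribute.
#' @param deg_set Character vector of expression-derived disease genes.
#' @param top_k Rows to keep in ranking (a) (default all).
#' @return list(by_degree = data.frame, core = character vector).
#' @export
rank_hubs <- function(graph, deg_set = character(0), top_k = Inf) {
  ct <- centrality_table(graph)
  targets <- ct[ct$kind == "target", , drop = FALSE]
  core <- targets$id[targets$id %in% normalize_symbols(deg_set)]
  by_degree <- utils::head(targets, n = if (is.finite(top_k)) top_k
                                        else nrow(targets))
  rownames(by_degree) <- NULL
  list(by_degree = by_degree, core = core)
}

#' Write a graph as a Cytoscape-loadable SIF file
#'
#' @param graph An igraph.
#' @param path Output path.
#' @param interaction Interaction type written in the middle column.
#' @return `path`, invisibly.
#' @export
write_sif <- function(graph, path, interaction = "interacts") {
  el <- igraph::as_edgelist(graph)
  lines <- if (nrow(el)) paste(el[, 1], interaction, el[, 2], sep = "\t")
           else character(0)
  iso <- setdiff(igraph::V(graph)$name,
                 unique(as.vector(el)))
  writeLines(c(lines, iso), path)
  invisible(path)
}

#' Write a graph as GraphML
#'
#' @param graph An igraph.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}
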