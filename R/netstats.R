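#' Load a gene-interaction edge list
#'
#' Reads a TSV with columns `node_a`, `node_b` and an optional `type`
#' (interaction category). Duplicate node pairs are retained as
#' multi-edges (e.g. the same pair supported by co-expression and by
#' physical interaction), matching how network browsers export merged
#' evidence networks. Self-loops are rejected unless explicitly allowed.
#'
#' @param path TSV path; an empty file (or header-only file) yields an
#'   empty graph.
#' @param allow_self_loops keep `a--a` rows instead of erroring.
#' @param isolated_nodes extra node names to add with no edges.
#' @return An undirected `igraph` graph; edge attribute `type` when the
#'   column is present.
#' @export
load_edgelist <- function(path, allow_self_loops = FALSE,
                          isolated_nodes = character()) {
  df <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) NULL
  )
  if (is.null(df) || nrow(df) == 0L) {
    return(igraph::make_empty_graph(directed = FALSE) +
             igraph::vertices(unique(isolated_nodes)))
  }
  if (!all(c("node_a", "node_b") %in% names(df))) {
    stop("edge list needs columns node_a and node_b", call. = FALSE)
  }
  bad <- which(is.na(df$node_a) | is.na(df$node_b) |
                 trimws(df$node_a) == "" | trimws(df$node_b) == "")
  if (length(bad)) {
    stop("malformed edge row at line ", bad[1L] + 1L, " of ", path,
         call. = FALSE)
  }
  loops <- which(df$node_a == df$node_b)
  if (length(loops) && !allow_self_loops) {
    stop("self-loop at line ", loops[1L] + 1L, " of ", path,
         " (set allow_self_loops = TRUE to keep)", call. = FALSE)
  }
  cols <- c("node_a", "node_b", intersect("type", names(df)))
  verts <- unique(c(df$node_a, df$node_b, isolated_nodes))
  igraph::graph_from_data_frame(df[cols], directed = FALSE,
                                vertices = verts)
}

#' Topology summary of an interaction network
#'
#' The node/edge counts and the two degree-based statistics commonly
#' reported for gene networks: the average number of neighbors — the mean
#' over nodes of the count of *distinct* adjacent nodes, so multi-edges
#' collapse — and the network heterogeneity, the coefficient of variation
#' of that neighbor count, `sqrt(population variance) / mean`.
#' Heterogeneity is 0 exactly when every node has the same number of
#' neighbors (e.g. any regular graph). Connected components are counted
#' on the simple graph.
#'
#' @param g an `igraph` graph, as from [load_edgelist()].
#' @param het_variance `"population"` (default, the convention of network
#'   analyzers) or `"sample"` variance in the heterogeneity numerator.
#' @return A one-row data frame: `n_nodes`, `n_edges`, `n_components`,
#'   `n_multi_edge_pairs`, `avg_neighbors`, `heterogeneity`, `empty`
#'   (flag set for the empty graph, whose statistics are reported as 0).
#' @export
topology_summary <- function(g, het_variance = c("population", "sample")) {
  het_variance <- match.arg(het_variance)
  n_nodes <- igraph::vcount(g)
  if (n_nodes == 0L) {
    return(data.frame(n_nodes = 0L, n_edges = 0L, n_components = 0L,
                      n_multi_edge_pairs = 0L, avg_neighbors = 0,
                      heterogeneity = 0, empty = TRUE))
  }
  simple <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  deg <- igraph::degree(simple)
  avg <- mean(deg)
  v <- if (het_variance == "population") {
    mean((deg - avg)^2)
  } else if (length(deg) > 1L) {
    stats::var(deg)
  } else 0
  het <- if (v == 0) 0 else sqrt(v) / avg
  el <- igraph::as_edgelist(igraph::delete_edges(
    g, which(igraph::which_loop(g))))
  pair_key <- if (nrow(el)) paste(pmin(el[, 1], el[, 2]),
                                  pmax(el[, 1], el[, 2]), sep = "\r") else character()
  data.frame(
    n_nodes = n_nodes,
    n_edges = igraph::ecount(g),
    n_components = igraph::components(simple)$no,
    n_multi_edge_pairs = sum(table(pair_key) > 1L),
    avg_neighbors = avg,
    heterogeneity = het,
    empty = FALSE
  )
}
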