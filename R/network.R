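#' Build the interaction network from significant WMIs
#'
#' Nodes are SNPs or genes; one edge per unique significant pair, weighted by
#' the maximum |WMI| over all scopes/traits in which the pair was recovered.
#' At gene level, pairs of SNPs inside the same gene collapse to self-loops;
#' these are retained and flagged (intragenic epistasis is a central signal,
#' not an artifact) and contribute 2 to the gene's degree.
#'
#' @param results output of [scan_cohort()]; gene-level networks need the
#'   `gene_a`/`gene_b` columns populated.
#' @param level `"snp"` or `"gene"`.
#' @param gate `"bonferroni"` (default) or `"nominal"` MI significance.
#' @return object of class `interaction_network`: list with the `igraph`
#'   graph, `edges` and `nodes` tibbles, `level`, `gate`. Empty networks are
#'   returned (not an error) when nothing passes the gate.
#' @export
build_network <- function(results, level = c("snp", "gene"),
                          gate = c("bonferroni", "nominal")) {
  level <- match.arg(level)
  gate <- match.arg(gate)
  flag <- if (gate == "bonferroni") results$significant_bonferroni
          else results$significant_nominal
  sig <- results[which(flag), , drop = FALSE]
  if (level == "gene") {
    assert_that(!anyNA(sig$gene_a) || nrow(sig) == 0L,
                "gene-level network needs gene annotation on the results")
    a <- sig$gene_a; b <- sig$gene_b
  } else {
    a <- sig$snp_a; b <- sig$snp_b
  }
  if (nrow(sig) == 0L) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(structure(list(
      graph = g,
      edges = tibble(from = character(), to = character(), weight = double(),
                     n_occurrences = integer(), self_loop = logical()),
      nodes = tibble(node = character(), degree = integer(),
                     total_weight = double()),
      level = level, gate = gate), class = "interaction_network"))
  }
  # canonical unordered pair ordering, then unique with max-|WMI| weight
  lo <- pmin(a, b); hi <- pmax(a, b)
  edges <- tibble(from = lo, to = hi, wmi_abs = sig$wmi_abs) |>
    group_by(.data$from, .data$to) |>
    summarise(weight = max(.data$wmi_abs), n_occurrences = dplyr::n(),
              .groups = "drop") |>
    mutate(self_loop = .data$from == .data$to) |>
    arrange(.data$from, .data$to)
  node_ids <- sort(unique(c(edges$from, edges$to)))
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges[c("from", "to", "weight")]),
    directed = FALSE,
    vertices = data.frame(name = node_ids))
  deg <- if (length(node_ids)) igraph::degree(g, loops = TRUE) else integer(0)
  strength <- if (length(node_ids)) {
    igraph::strength(g, weights = igraph::E(g)$weight, loops = TRUE)
  } else numeric(0)
  nodes <- tibble(node = node_ids,
                  degree = as.integer(deg[node_ids]),
                  total_weight = as.numeric(strength[node_ids]))
  structure(list(graph = g, edges = edges, nodes = nodes,
                 level = level, gate = gate),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction_network> level=%s gate=%s: %d nodes, %d edges (%d self-loops)\n",
              x$level, x$gate, nrow(x$nodes), nrow(x$edges),
              sum(x$edges$self_loop)))
  invisible(x)
}

#' Top-k hubs of an interaction network
#'
#' Deterministic ranking: degree descending, then total edge weight
#' descending, then node id ascending.
#'
#' @param network an [build_network()] result.
#' @param k how many nodes.
#' @return the top rows of the `nodes` tibble.
#' @export
identify_hubs <- function(network, k = 10L) {
  assert_that(nrow(network$nodes) > 0, "network is empty")
  network$nodes |>
    arrange(dplyr::desc(.data$degree), dplyr::desc(.data$total_weight),
            .data$node) |>
    head(k)
}

#' Write a network as edge-list TSV and GraphML
#'
#' @param network an `interaction_network`.
#' @param edges_path path for the tab-separated edge list (`NULL` to skip).
#' @param graphml_path path for GraphML output (`NULL` to skip).
#' @return the network, invisibly.
#' @export
write_network <- function(network, edges_path = NULL, graphml_path = NULL) {
  if (!is.null(edges_path)) {
    readr::write_tsv(network$edges, edges_path)
  }
  if (!is.null(graphml_path)) {
    igraph::write_graph(network$graph, graphml_path, format = "graphml")
  }
  invisible(network)
}
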