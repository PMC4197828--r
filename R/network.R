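#' Build the merged PPI / TF-target interaction graph
#'
#' Merges undirected protein-protein edges with directed transcription-
#' factor-target edges, restricted to a gene universe (typically the
#' clustered genes). Edges with an endpoint outside the universe and
#' self-loops are dropped; duplicates within and across sources collapse to
#' one neighbour relation that keeps the union of its type tags. Isolated
#' nodes are dropped, so every retained node has degree >= 1. Degree counts
#' distinct neighbours regardless of edge type or direction — each edge is
#' one validated interaction.
#'
#' @param ppi Data frame `a`, `b` (optionally `type`) of undirected edges.
#' @param tf_target Data frame `a` (factor), `b` (target) of directed edges.
#' @param universe Character vector of admissible gene ids.
#' @return Object of class `interaction_graph`: `edges` (a, b in canonical
#'   order, types as "ppi", "tf_target" or "ppi,tf_target"), `graph` (an
#'   undirected simple [igraph::graph_from_data_frame()] used for degree),
#'   `degree` (named), `n_malformed` (skipped input rows).
#' @export
build_network <- function(ppi, tf_target, universe) {
  stopifnot(length(universe) > 0)
  tidy <- function(df, type) {
    if (is.null(df) || nrow(df) == 0)
      return(data.frame(a = character(), b = character(), type = character(),
                        stringsAsFactors = FALSE))
    bad <- !stats::complete.cases(df[c("a", "b")]) |
      df$a == "" | df$b == ""
    data.frame(a = as.character(df$a[!bad]), b = as.character(df$b[!bad]),
               type = type, stringsAsFactors = FALSE)
  }
  raw <- rbind(tidy(ppi, "ppi"), tidy(tf_target, "tf_target"))
  n_malformed <- (NROW(ppi) + NROW(tf_target)) - nrow(raw)
  if (n_malformed > 0)
    message(n_malformed, " malformed edge row(s) skipped")

  keep <- raw$a %in% universe & raw$b %in% universe & raw$a != raw$b
  raw <- raw[keep, , drop = FALSE]
  # canonical unordered pair; a TF->target edge a-b and a PPI b-a are one
  # neighbour relation carrying both tags
  lo <- pmin(raw$a, raw$b); hi <- pmax(raw$a, raw$b)
  key <- paste(lo, hi, sep = "\r")
  types <- vapply(split(raw$type, key),
                  function(t) paste(sort(unique(t)), collapse = ","),
                  character(1))
  pairs <- do.call(rbind, strsplit(names(types), "\r", fixed = TRUE))
  edges <- if (is.null(pairs))
    data.frame(a = character(), b = character(), types = character(),
               stringsAsFactors = FALSE)
  else data.frame(a = pairs[, 1], b = pairs[, 2], types = unname(types),
                  stringsAsFactors = FALSE)
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL

  g <- igraph::graph_from_data_frame(edges[c("a", "b")], directed = FALSE)
  deg <- igraph::degree(g)
  structure(list(edges = edges, graph = g, degree = deg,
                 n_malformed = n_malformed),
            class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat("Interaction graph:", length(x$degree), "genes,", nrow(x$edges),
      "neighbour relations\n")
  invisible(x)
}

#' Degree summary and regulatory-hub calls
#'
#' Hubs are nodes whose degree strictly exceeds `hub_cutoff` (default 19:
#' a node with 20 distinct validated interactions is a hub, one with 19 is
#' not).
#'
#' @param graph An `interaction_graph`.
#' @param hub_cutoff Degree above which a node is a hub (default 19).
#' @return List of class `hub_report`: `nodes` (data frame gene, degree,
#'   hub), `hubs` (gene ids), `summary` (min, median, q3, max degree).
#' @export
hub_report <- function(graph, hub_cutoff = 19) {
  stopifnot(inherits(graph, "interaction_graph"), hub_cutoff >= 1)
  deg <- graph$degree
  if (length(deg) == 0) stop("empty graph")
  nodes <- data.frame(gene = names(deg), degree = as.integer(deg),
                      hub = deg > hub_cutoff, stringsAsFactors = FALSE)
  nodes <- nodes[order(-nodes$degree, nodes$gene), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, hubs = nodes$gene[nodes$hub],
                 hub_cutoff = hub_cutoff,
                 summary = c(min = min(deg),
                             median = stats::median(deg),
                             q3 = stats::quantile(deg, 0.75, names = FALSE),
                             max = max(deg))),
            class = "hub_report")
}

#' @export
print.hub_report <- function(x, ...) {
  s <- x$summary
  cat("Degree: min ", s["min"], ", median ", s["median"], ", Q3 ", s["q3"],
      ", max ", s["max"], "; ", length(x$hubs), " hub(s) at degree > ",
      x$hub_cutoff, "\n", sep = "")
  invisible(x)
}

#' Export an interaction graph
#'
#' SIF rows are `a <type> b` (one row per neighbour relation, combined type
#' tag); GraphML goes through igraph's writer.
#'
#' @param graph An `interaction_graph`.
#' @param sif,graphml Output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
export_network <- function(graph, sif = NULL, graphml = NULL) {
  stopifnot(inherits(graph, "interaction_graph"))
  if (!is.null(sif)) {
    writeLines(paste(graph$edges$a, graph$edges$types, graph$edges$b,
                     sep = "\t"), sif)
  }
  if (!is.null(graphml)) {
    g <- graph$graph
    igraph::E(g)$types <- graph$edges$types
    igraph::write_graph(g, graphml, format = "graphml")
  }
  invisible(c(sif = sif, graphml = graphml))
}
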