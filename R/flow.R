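## Information-flow graphs: directed edges from t-1 predictor nodes
## (inputs and memory-before) to t feature nodes (outputs and memory-after)
## drawn from distinct-informative-set membership, with connectome-based
## disambiguation of redundant predictive sets.

#' Build an information-flow graph from a state recording
#'
#' For every nonzero-entropy node at time t (outputs and memory-after), the
#' distinct informative sets over the t-1 pool (inputs and memory-before)
#' are found at threshold `theta`, and an edge is drawn from every member
#' of every DIS to the target.  An edge is `necessary` (rendered black)
#' when its source appears in every DIS for the target, and `possible`
#' (rendered red) when it appears in some but not all DISs — a redundant
#' predictive set that may be a coincidental prediction.  Each edge is
#' labeled with `I(source; target) / H(target)`, the proportion of the
#' target's entropy the source accounts for on its own (0 for perfectly
#' encrypted pairs).  Zero-entropy nodes are omitted.
#'
#' @param rec a [state_recording] with input, output and memory groups.
#' @param theta threshold proportion (default 1: perfect prediction).
#' @param cap pool-size cap for the power-set search.
#' @return An object of class `flow_graph`: list with `nodes` (data.frame
#'   `id`, `role`, `time`, `entropy`), `edges` (data.frame `from`, `to`,
#'   `label`, `necessity`), `dis` (named list of [find_dis()] collections
#'   per target), `unexplained` (targets with positive entropy but no DIS),
#'   and `theta`.
#' @export
build_flow_graph <- function(rec, theta = 1, cap = .DEFAULT_POOL_CAP) {
  g <- rec$groups
  if (length(g$input) + length(g$memory) == 0L || length(g$output) +
      length(g$memory) == 0L)
    stop("recording must have input/output/memory groups")
  predictors <- c(g$input, g$memory)
  features <- c(g$output, g$memory)
  tab <- pair_states(rec, predictors, features)
  feat_cols <- tab$features            # memory features carry _next suffix

  h_pred <- vapply(predictors, function(p) joint_entropy(tab, p), numeric(1))
  h_feat <- vapply(feat_cols, function(f) joint_entropy(tab, f), numeric(1))
  pool <- predictors[h_pred > .TOL]

  display <- function(col) sub("_next$", "", col)
  nodes <- rbind(
    data.frame(id = predictors, role = ifelse(predictors %in% g$input,
                                              "input", "memory"),
               time = "t-1", entropy = unname(h_pred),
               stringsAsFactors = FALSE),
    data.frame(id = display(feat_cols),
               role = ifelse(display(feat_cols) %in% g$output,
                             "output", "memory"),
               time = "t", entropy = unname(h_feat),
               stringsAsFactors = FALSE))
  nodes <- nodes[nodes$entropy > .TOL, , drop = FALSE]
  rownames(nodes) <- NULL

  dis <- list()
  unexplained <- character(0)
  edges <- data.frame(from = character(0), to = character(0),
                      label = numeric(0), necessity = character(0),
                      stringsAsFactors = FALSE)
  for (fc in feat_cols[h_feat > .TOL]) {
    target <- display(fc)
    d <- find_dis(tab, pool, fc, theta = theta, cap = cap)
    dis[[target]] <- d
    if (length(d$sets) == 0L) {
      unexplained <- c(unexplained, target)
      next
    }
    members <- sort(unique(unlist(d$sets)))
    in_all <- vapply(members, function(m)
      all(vapply(d$sets, function(s) m %in% s, logical(1))), logical(1))
    lab <- vapply(members, function(m)
      mutual_information(tab, m, fc) / d$h_feature, numeric(1))
    edges <- rbind(edges, data.frame(
      from = members, to = target, label = unname(lab),
      necessity = ifelse(unname(in_all), "necessary", "possible"),
      stringsAsFactors = FALSE))
  }
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, dis = dis,
                 unexplained = unexplained, theta = theta),
            class = "flow_graph")
}

#' @export
print.flow_graph <- function(x, ...) {
  cat(sprintf("Information flow graph (theta = %g): %d nodes, %d edges\n",
              x$theta, nrow(x$nodes), nrow(x$edges)))
  nec <- sum(x$edges$necessity == "necessary")
  cat(sprintf("  %d necessary (black), %d possible (red) edges\n",
              nec, nrow(x$edges) - nec))
  if (length(x$unexplained) > 0L)
    warning("targets with positive entropy but no DIS at theta = ", x$theta,
            " (non-deterministic or truncated recording?): ",
            paste(x$unexplained, collapse = ", "), call. = FALSE)
  invisible(x)
}

#' @export
summary.flow_graph <- function(object, ...) {
  list(complexity = flow_complexity(object),
       n_nodes = nrow(object$nodes),
       n_possible = sum(object$edges$necessity == "possible"),
       unexplained = object$unexplained)
}

#' Flow complexity: number of edges in an information-flow graph
#'
#' The total edge count (necessary plus possible) of the graph; a simple
#' proxy for how complex the network's information processing is.
#'
#' @param graph a [flow_graph].
#' @return Integer edge count.
#' @export
flow_complexity <- function(graph) nrow(graph$edges)

#' Prune coincidental predictive sets using the connectome
#'
#' A DIS can predict a target without causing it (a coincidental,
#' mirror-node prediction).  When the physical wiring of the substrate is
#' known, any DIS containing a member with no physical link to the target
#' is removed; edge necessity is then recomputed, so a target left with a
#' single DIS gets all-black (necessary) incoming edges.  Redundancies the
#' connectome cannot resolve remain marked possible.
#'
#' @param graph a [flow_graph].
#' @param conn a [connectome]: data.frame with columns `from` (t-1 node id)
#'   and `to` (t node id), as produced by [connectome_of()].
#' @return The disambiguated [flow_graph].
#' @export
disambiguate <- function(graph, conn) {
  stopifnot(is.data.frame(conn), all(c("from", "to") %in% names(conn)))
  supported <- function(s, target)
    any(conn$from == s & conn$to == target)
  edges <- data.frame(from = character(0), to = character(0),
                      label = numeric(0), necessity = character(0),
                      stringsAsFactors = FALSE)
  for (target in names(graph$dis)) {
    d <- graph$dis[[target]]
    if (length(d$sets) == 0L) next
    keep <- vapply(d$sets, function(s)
      all(vapply(s, supported, logical(1), target = target)), logical(1))
    if (!any(keep)) {
      ## every candidate set contradicts the wiring: flag rather than drop
      graph$unexplained <- union(graph$unexplained, target)
      graph$dis[[target]]$sets <- list()
      graph$dis[[target]]$minimal_size <- -1L
      next
    }
    d$sets <- d$sets[keep]
    d$minimal_size <- min(vapply(d$sets, length, integer(1)))
    graph$dis[[target]] <- d
    members <- sort(unique(unlist(d$sets)))
    in_all <- vapply(members, function(m)
      all(vapply(d$sets, function(s) m %in% s, logical(1))), logical(1))
    old <- graph$edges[graph$edges$to == target, , drop = FALSE]
    lab <- old$label[match(members, old$from)]
    edges <- rbind(edges, data.frame(
      from = members, to = target, label = lab,
      necessity = ifelse(unname(in_all), "necessary", "possible"),
      stringsAsFactors = FALSE))
  }
  rownames(edges) <- NULL
  graph$edges <- edges
  graph
}

#' Convert a flow graph to an igraph object
#'
#' Node attributes: `role`, `time`, `entropy`; edge attributes: `label`
#' (entropy proportion), `necessity`, `color` (black/red).  Memory nodes
#' appear twice (t-1 and t views) under ids suffixed with their time slice
#' only when the same id occurs on both sides.
#'
#' @param graph a [flow_graph].
#' @return An [igraph::graph] object.
#' @export
as_igraph <- function(graph) {
  nodes <- graph$nodes
  ## igraph needs unique vertex names: a node id present at both time
  ## slices (memory) is collapsed into one vertex, as in the figures.
  vert <- nodes[!duplicated(nodes$id), c("id", "role", "entropy"),
                drop = FALSE]
  edges <- graph$edges
  edges$color <- ifelse(edges$necessity == "necessary", "black", "red")
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = vert)
}

#' Export an information-flow graph
#'
#' DOT output is emitted directly (deterministic ordering; necessity as
#' edge color black/red, proportion labels as edge labels, node entropies
#' in node labels).  GraphML goes through igraph and round-trips all node
#' and edge attributes.
#'
#' @param graph a [flow_graph].
#' @param path output file path.
#' @param format `"dot"` or `"graphml"`.
#' @export
export_graph <- function(graph, path, format = c("dot", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph(graph), path, format = "graphml")
    return(invisible(path))
  }
  nodes <- graph$nodes[!duplicated(graph$nodes$id), , drop = FALSE]
  nodes <- nodes[order(match(nodes$role, c("input", "memory", "output")),
                       nodes$id), , drop = FALSE]
  edges <- graph$edges[order(graph$edges$to, graph$edges$from), ,
                       drop = FALSE]
  lines <- c("digraph infoflow {", "  rankdir=TB;")
  shape <- c(input = "box", memory = "ellipse", output = "box")
  for (i in seq_len(nrow(nodes)))
    lines <- c(lines, sprintf(
      "  \"%s\" [label=\"%s\\n%.2f\", shape=%s, role=%s];",
      nodes$id[i], nodes$id[i], nodes$entropy[i], shape[[nodes$role[i]]],
      nodes$role[i]))
  for (i in seq_len(nrow(edges)))
    lines <- c(lines, sprintf(
      "  \"%s\" -> \"%s\" [label=\"%.2f\", color=%s];",
      edges$from[i], edges$to[i], edges$label[i],
      if (edges$necessity[i] == "necessary") "black" else "red"))
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}

#' Read a GraphML flow-graph export back into a flow graph
#'
#' Restores nodes and edges (with necessity and labels) from a file written
#' by [export_graph()] with `format = "graphml"`.  DIS collections are not
#' serialized to GraphML and come back empty.
#'
#' @param path GraphML file path.
#' @return A [flow_graph] (without DIS collections).
#' @export
read_flow_graphml <- function(path) {
  ig <- igraph::read_graph(path, format = "graphml")
  vd <- igraph::as_data_frame(ig, what = "vertices")
  ed <- igraph::as_data_frame(ig, what = "edges")
  nodes <- data.frame(id = vd$name, role = vd$role, time = NA_character_,
                      entropy = vd$entropy, stringsAsFactors = FALSE)
  edges <- data.frame(from = ed$from, to = ed$to, label = ed$label,
                      necessity = ed$necessity, stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, dis = list(),
                 unexplained = character(0), theta = NA_real_),
            class = "flow_graph")
}

#' Plot an information-flow graph
#'
#' @param x a [flow_graph].
#' @param ... passed to [igraph::plot.igraph()].
#' @export
plot.flow_graph <- function(x, ...) {
  ig <- as_igraph(x)
  igraph::plot.igraph(
    ig,
    edge.label = sprintf("%.2f", igraph::E(ig)$label),
    vertex.label = sprintf("%s\n%.2f", igraph::V(ig)$name,
                           igraph::V(ig)$entropy),
    vertex.color = c(input = "palegreen", memory = "white",
                     output = "lightblue")[igraph::V(ig)$role],
    ...)
  invisible(x)
}

#' Dump DIS collections of a flow graph as JSON
#'
#' @param graph a [flow_graph].
#' @param path output path.
#' @export
write_dis_json <- function(graph, path) {
  obj <- lapply(graph$dis, function(d)
    list(feature = d$feature, theta = d$theta, h_feature = d$h_feature,
         sets = d$sets, minimal_size = d$minimal_size,
         trivially_predicted = d$trivially_predicted))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
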