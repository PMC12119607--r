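#' Construct an AOP graph
#'
#' An adverse outcome pathway (AOP) is represented as a directed acyclic
#' graph whose root node carries the (continuous) dose and whose remaining
#' nodes are the measured molecular initiating events (MIEs), key events
#' (KEs), modulating factors and the adverse outcome (AO).
#'
#' @param nodes character vector of unique node identifiers; the first
#'   topological position need not be the root — ordering is recomputed.
#' @param edges two-column character matrix (or list of length-2 vectors)
#'   of directed parent -> child edges.
#' @param roles named character vector mapping each node to one of
#'   `"dose"`, `"MIE"`, `"modulator"`, `"KE"`, `"AO"`. Exactly one node must
#'   have role `"dose"` (the root) and exactly one role `"AO"`.
#' @param labels optional named character vector of free-text labels.
#' @return an object of class `"aop_graph"` with elements `nodes`, `edges`,
#'   `roles`, `labels`, `root` and `order` (a topological ordering).
#' @seealso [default_aop()], [topological_order()]
#' @export
aop_graph <- function(nodes, edges, roles, labels = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop_domain("node identifiers must be unique")
  if (is.list(edges)) edges <- do.call(rbind, edges)
  edges <- matrix(as.character(edges), ncol = 2,
                  dimnames = list(NULL, c("parent", "child")))
  if (!all(edges %in% nodes)) {
    stop_domain("edges reference unknown nodes: ",
                paste(setdiff(unique(c(edges)), nodes), collapse = ", "))
  }
  roles <- roles[nodes]
  ok <- c("dose", "MIE", "modulator", "KE", "AO")
  if (any(is.na(roles)) || !all(roles %in% ok)) {
    stop_domain("every node needs a role in {", paste(ok, collapse = ", "), "}")
  }
  if (sum(roles == "dose") != 1L) stop_domain("exactly one node must have role 'dose'")
  if (sum(roles == "AO") != 1L) stop_domain("exactly one node must have role 'AO'")
  root <- nodes[roles == "dose"]
  if (root %in% edges[, "child"]) stop_domain("root node '", root, "' must have no parents")

  g <- igraph::graph_from_data_frame(
    as.data.frame(edges, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )
  if (!igraph::is_dag(g)) stop_domain("AOP graph must be acyclic")
  reach <- igraph::subcomponent(g, root, mode = "out")$name
  unreachable <- setdiff(nodes, reach)
  if (length(unreachable)) {
    stop_domain("nodes unreachable from the dose root: ",
                paste(unreachable, collapse = ", "))
  }
  ord <- igraph::topo_sort(g, mode = "out")$name
  structure(
    list(nodes = nodes, edges = edges, roles = roles,
         labels = labels %||% setNames(nodes, nodes),
         root = root, order = ord),
    class = "aop_graph"
  )
}

#' Default mucus-hypersecretion AOP
#'
#' Builds the knowledge-driven AOP for whole-cigarette-smoke-induced mucus
#' hypersecretion: dose drives the three upstream assays (ROS generation,
#' GSH depletion, AREG secretion), which jointly drive EGFR activation
#' (KE1); the chain then runs KE1 -> mucin production (KE3) -> goblet-cell
#' metaplasia/hyperplasia (KE4) -> mucus hypersecretion (AO). SP1 activation
#' (KE2) sits between KE1 and KE3 but is excluded by default because its
#' in vitro readout is too fragile to model; set `include_ke2 = TRUE` to
#' restore it. Dose feeds only the three upstream assays; alternative
#' wirings (e.g. dose as a direct parent of every node) can be built with
#' [aop_graph()].
#'
#' @param include_ke2 logical; include the SP1-activation node (KE2)?
#' @return an [aop_graph] with 8 nodes (9 when `include_ke2 = TRUE`).
#' @examples
#' g <- default_aop()
#' topological_order(g)
#' @export
default_aop <- function(include_ke2 = FALSE) {
  nodes <- c("dose", "ROS", "GSH", "AREG", "KE1",
             if (include_ke2) "KE2", "KE3", "KE4", "AO")
  edges <- rbind(
    c("dose", "ROS"), c("dose", "GSH"), c("dose", "AREG"),
    c("ROS", "KE1"), c("GSH", "KE1"), c("AREG", "KE1"),
    if (include_ke2) rbind(c("KE1", "KE2"), c("KE2", "KE3"))
    else c("KE1", "KE3"),
    c("KE3", "KE4"), c("KE4", "AO")
  )
  roles <- c(dose = "dose", ROS = "MIE", GSH = "MIE", AREG = "modulator",
             KE1 = "KE", KE2 = "KE", KE3 = "KE", KE4 = "KE", AO = "AO")
  labels <- c(dose = "WCS dose (nicotine µg/mL)",
              ROS = "ROS generation", GSH = "GSH depletion",
              AREG = "AREG secretion", KE1 = "EGFR activation",
              KE2 = "SP1 activation", KE3 = "Mucin (MUC5AC) production",
              KE4 = "GCM/H", AO = "Mucus hypersecretion")
  aop_graph(nodes, edges, roles[nodes], labels[nodes])
}

#' Topological ordering of an AOP graph
#'
#' @param graph an [aop_graph].
#' @return character vector of node identifiers in which every parent
#'   precedes all of its children.
#' @export
topological_order <- function(graph) {
  stopifnot(inherits(graph, "aop_graph"))
  graph$order
}

#' Parent set of a node
#'
#' @param graph an [aop_graph].
#' @param node node identifier.
#' @return character vector of parents (empty for the root).
#' @export
node_parents <- function(graph, node) {
  stopifnot(inherits(graph, "aop_graph"))
  if (!node %in% graph$nodes) stop_domain("unknown node '", node, "'")
  unname(graph$edges[graph$edges[, "child"] == node, "parent"])
}

#' @export
print.aop_graph <- function(x, ...) {
  cat("AOP graph:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  cat("  root (dose):", x$root, "  AO:", x$nodes[x$roles == "AO"], "\n")
  cat("  topological order:", paste(x$order, collapse = " -> "), "\n")
  invisible(x)
}

#' Serialize / deserialize an AOP graph as JSON
#'
#' @param graph an [aop_graph].
#' @param path file path; for `read_aop_json` the file to read.
#' @return `write_aop_json` returns `path` invisibly; `read_aop_json`
#'   returns an [aop_graph].
#' @export
write_aop_json <- function(graph, path) {
  stopifnot(inherits(graph, "aop_graph"))
  obj <- list(
    nodes = graph$nodes,
    edges = apply(graph$edges, 1, as.list),
    roles = as.list(graph$roles),
    labels = as.list(graph$labels)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_aop_json
#' @export
read_aop_json <- function(path) {
  obj <- jsonlite::read_json(path)
  edges <- do.call(rbind, lapply(obj$edges, unlist))
  aop_graph(unlist(obj$nodes), edges, unlist(obj$roles), unlist(obj$labels))
}
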