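#' Convert a PialNetwork to an igraph graph
#'
#' Node ids become vertex names; edge ids are kept as the `id` edge
#' attribute, edge kinds as `kind`.
#'
#' @param net a [PialNetwork].
#' @return an undirected [igraph::igraph] object (multi-edges preserved).
#' @export
asIgraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net@edges[, c("node_a", "node_b", "id", "kind")],
    directed = FALSE,
    vertices = net@nodes[, c("id", "x_mm", "y_mm", "kind")])
  g
}

finding <- function(severity, element, rule, message) {
  data.frame(severity = severity, element = element, rule = rule,
             message = message, stringsAsFactors = FALSE)
}

emptyFindings <- function() {
  data.frame(severity = character(), element = character(),
             rule = character(), message = character(),
             stringsAsFactors = FALSE)
}

#' Validate a pial network against its invariants
#'
#' Checks the structural invariants of a [PialNetwork] (and, when a
#' [RegionMap] is supplied, its geometric invariants): non-empty node set,
#' connectivity, kind/degree consistency (`bifurcation` requires degree
#' >= 3, `endpoint` degree 1), polyline endpoints matching node
#' coordinates, and every node lying inside or on the slab polygon.
#' Violations are reported as findings, not exceptions.
#'
#' @param net a [PialNetwork].
#' @param rm optional [RegionMap] for the geometric checks.
#' @return a data.frame of findings with columns `severity`, `element`,
#'   `rule`, `message`; zero rows when every invariant holds.
#' @examples
#' nd <- data.frame(id = c("a", "b"), x_mm = c(0, 1), y_mm = c(0, 0),
#'                  kind = c("root", "endpoint"))
#' ed <- data.frame(id = "e1", node_a = "a", node_b = "b", kind = "vessel")
#' validateNetwork(pialNetwork(nd, ed))
#' @export
validateNetwork <- function(net, rm = NULL) {
  stopifnot(is(net, "PialNetwork"))
  out <- emptyFindings()
  nd <- net@nodes; ed <- net@edges
  if (!nrow(nd)) {
    return(finding("error", NA_character_, "nonempty",
                   "network has no nodes"))
  }
  deg <- setNames(rep(0L, nrow(nd)), nd$id)
  if (nrow(ed)) {
    t1 <- table(ed$node_a); t2 <- table(ed$node_b)
    deg[names(t1)] <- deg[names(t1)] + as.integer(t1)
    deg[names(t2)] <- deg[names(t2)] + as.integer(t2)
  }
  if (nrow(nd) > 1) {
    g <- asIgraph(net)
    if (igraph::components(g)$no > 1)
      out <- rbind(out, finding("error", NA_character_, "connected",
                                "graph is not connected"))
  }
  bad <- nd$kind == "bifurcation" & deg[nd$id] < 3
  for (id in nd$id[bad])
    out <- rbind(out, finding("error", id, "bifurcation-degree",
      sprintf("node %s: kind=bifurcation requires degree >= 3 (degree %d)",
              id, deg[[id]])))
  bad <- nd$kind == "endpoint" & deg[nd$id] != 1
  for (id in nd$id[bad])
    out <- rbind(out, finding("error", id, "endpoint-degree",
      sprintf("node %s: kind=endpoint requires degree 1 (degree %d)",
              id, deg[[id]])))
  bad <- nd$kind == "pa" & deg[nd$id] < 1
  for (id in nd$id[bad])
    out <- rbind(out, finding("error", id, "pa-degree",
      sprintf("node %s: kind=pa requires degree >= 1", id)))
  if (nrow(ed) && !all(ed$territory_a %in% TERRITORIES &
                       ed$territory_b %in% TERRITORIES)) {
    bad <- which(!(ed$territory_a %in% TERRITORIES &
                   ed$territory_b %in% TERRITORIES))
    for (i in bad)
      out <- rbind(out, finding("error", ed$id[i], "territory-label",
        sprintf("edge %s: invalid territory label", ed$id[i])))
  }
  # polyline endpoints must match node coordinates
  if (nrow(ed)) {
    xy <- rbind(nd$x_mm, nd$y_mm)
    colnames(xy) <- nd$id
    for (i in which(!is.na(ed$polyline))) {
      pl <- tryCatch(polylineParse(ed$polyline[i]), error = function(e) NULL)
      if (is.null(pl)) {
        out <- rbind(out, finding("error", ed$id[i], "polyline-parse",
          sprintf("edge %s: malformed polyline", ed$id[i])))
        next
      }
      a <- xy[, ed$node_a[i]]; b <- xy[, ed$node_b[i]]
      if (max(abs(pl[1, ] - a)) > 1e-6 ||
          max(abs(pl[nrow(pl), ] - b)) > 1e-6)
        out <- rbind(out, finding("error", ed$id[i], "polyline-endpoints",
          sprintf("edge %s: polyline does not start at node_a and end at node_b",
                  ed$id[i])))
    }
  }
  if (!is.null(rm)) {
    inside <- cppPointsInPolygon(cbind(nd$x_mm, nd$y_mm), ccwRing(rm@slab),
                                 1e-7)
    for (id in nd$id[!inside])
      out <- rbind(out, finding("error", id, "node-in-slab",
        sprintf("node %s lies outside the slab polygon", id)))
  }
  out
}
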