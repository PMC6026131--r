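#' @title Structural quantification of pial networks
#' @name pialnet-topology
#' @description Backbone/offshoot decomposition, independent-loop counting,
#'   LMA edge identification (by curated labels or by the
#'   bifurcation-angle criterion) and the watershed polyline.
NULL

# tangent direction of edge `ei` (row index) at node `v`, unit vector;
# uses the polyline when present, else the straight chord
edgeDirAt <- function(net, ei, v, pos) {
  ed <- net@edges[ei, ]
  pl <- if (!is.na(ed$polyline)) polylineParse(ed$polyline) else NULL
  p0 <- pos[, v]
  if (!is.null(pl) && nrow(pl) >= 2) {
    if (ed$node_a == v) d <- pl[2, ] - pl[1, ]
    else d <- pl[nrow(pl) - 1, ] - pl[nrow(pl), ]
  } else {
    other <- if (ed$node_a == v) ed$node_b else ed$node_a
    d <- pos[, other] - p0
  }
  normalize(d)
}

# acute-branching-angle bisector at node v, excluding edge `ei`;
# NULL when undefined (no other edges, or an exactly opposed pair)
acuteBisectorAt <- function(net, v, ei, pos, incident) {
  others <- setdiff(incident[[v]], ei)
  if (!length(others)) return(NULL)
  dirs <- lapply(others, function(e) edgeDirAt(net, e, v, pos))
  if (length(dirs) == 1) return(dirs[[1]])
  # pair with the smallest separating angle
  best <- NULL; bestAng <- Inf
  for (i in seq_len(length(dirs) - 1)) for (j in seq(i + 1, length(dirs))) {
    ang <- acos(pmin(1, pmax(-1, sum(dirs[[i]] * dirs[[j]]))))
    if (ang < bestAng) { bestAng <- ang; best <- c(i, j) }
  }
  s <- dirs[[best[1]]] + dirs[[best[2]]]
  if (sqrt(sum(s^2)) < 1e-9) return(NULL)
  normalize(s)
}

bridgeEdgeIds <- function(net) {
  g <- asIgraph(net)
  br <- igraph::bridges(g)
  igraph::edge_attr(g, "id", br)
}

#' Count independent loops of a network
#'
#' The cyclomatic number `E - V + components`: the size of any independent
#' cycle basis, which on pial networks equals the number of anastomotic
#' loops.
#'
#' @param net a [PialNetwork].
#' @return integer loop count.
#' @export
loopCount <- function(net) {
  stopifnot(is(net, "PialNetwork"))
  g <- asIgraph(net)
  as.integer(nrow(net@edges) - nrow(net@nodes) +
               igraph::components(g)$no)
}

#' Backbone/offshoot decomposition
#'
#' Splits the network into its backbone -- the bridgeless core, i.e. the
#' union of all edges lying on at least one cycle -- and offshoots, the
#' maximal bridge-connected subtrees hanging off backbone nodes.  Vertices
#' per offshoot counts bifurcation and penetrating-arteriole nodes among
#' the offshoot members; the attachment node is excluded unless it is
#' itself a PA.  A PA lying on the backbone with no hanging subtree is
#' reported as a zero-length offshoot with one vertex.  In the degenerate
#' case of a bridge subtree touching the backbone at more than one node,
#' members are split by graph distance to the nearest attachment
#' (lexicographic tie-break).
#'
#' @param net a connected [PialNetwork] with at least one cycle.
#' @return an object of class `OffshootDecomposition`: a list with
#'   `backbone_edge_ids`, `offshoots` (each with `attachment_node`,
#'   `member_node_ids`, `member_edge_ids`) and `vertices_per_offshoot`.
#' @export
decomposeNetwork <- function(net) {
  stopifnot(is(net, "PialNetwork"))
  g <- asIgraph(net)
  if (igraph::components(g)$no > 1)
    stop("network is not connected")
  if (loopCount(net) == 0)
    stop("acyclic network has no backbone (no cycles present)")
  bridges <- bridgeEdgeIds(net)
  backbone <- setdiff(net@edges$id, bridges)
  be <- net@edges[net@edges$id %in% backbone, ]
  backboneNodes <- unique(c(be$node_a, be$node_b))

  offshoots <- list()
  if (length(bridges)) {
    bg <- igraph::subgraph_from_edges(
      g, igraph::E(g)[igraph::E(g)$id %in% bridges],
      delete.vertices = FALSE)
    comp <- igraph::components(bg)
    memb <- comp$membership
    vnames <- igraph::V(bg)$name
    for (ci in seq_len(comp$no)) {
      vs <- vnames[memb == ci]
      eIn <- net@edges$id[net@edges$id %in% bridges &
                          net@edges$node_a %in% vs &
                          net@edges$node_b %in% vs]
      if (!length(eIn)) next
      att <- sort(intersect(vs, backboneNodes))
      if (length(att) <= 1) {
        attach <- if (length(att)) att else NA_character_
        offshoots[[length(offshoots) + 1]] <- list(
          attachment_node = attach,
          member_node_ids = setdiff(vs, att),
          member_edge_ids = eIn)
      } else {
        # degenerate: split members by distance to nearest attachment
        sub <- igraph::induced_subgraph(g, vs)
        sub <- igraph::subgraph_from_edges(
          sub, igraph::E(sub)[igraph::E(sub)$id %in% eIn],
          delete.vertices = FALSE)
        D <- igraph::distances(sub, v = att, to = vs)
        nearest <- att[apply(D, 2, which.min)]
        names(nearest) <- vs
        eTab <- net@edges[net@edges$id %in% eIn, ]
        dmin <- apply(D, 2, min); names(dmin) <- vs
        for (a in att) {
          mem <- setdiff(vs[nearest == a], att)
          eid <- eTab$id[
            ifelse(dmin[eTab$node_a] >= dmin[eTab$node_b],
                   nearest[eTab$node_a], nearest[eTab$node_b]) == a]
          if (!length(mem) && !length(eid)) next
          offshoots[[length(offshoots) + 1]] <- list(
            attachment_node = a, member_node_ids = mem,
            member_edge_ids = eid)
        }
      }
    }
  }
  # zero-length offshoots: backbone PAs with no hanging subtree
  hangingAt <- vapply(offshoots, function(o) o$attachment_node, character(1))
  paOnBackbone <- net@nodes$id[net@nodes$kind == "pa" &
                               net@nodes$id %in% backboneNodes]
  for (v in setdiff(paOnBackbone, hangingAt))
    offshoots[[length(offshoots) + 1]] <- list(
      attachment_node = v, member_node_ids = character(0),
      member_edge_ids = character(0))

  kind <- setNames(net@nodes$kind, net@nodes$id)
  vpo <- vapply(offshoots, function(o) {
    n <- sum(kind[o$member_node_ids] %in% c("bifurcation", "pa"))
    if (!is.na(o$attachment_node) &&
        kind[[o$attachment_node]] == "pa") n <- n + 1L
    as.integer(n)
  }, integer(1))
  structure(list(backbone_edge_ids = backbone, offshoots = offshoots,
                 vertices_per_offshoot = vpo),
            class = "OffshootDecomposition")
}

#' @export
print.OffshootDecomposition <- function(x, ...) {
  cat(sprintf(
    "OffshootDecomposition: %d backbone edges, %d offshoots, %.2f vertices/offshoot\n",
    length(x$backbone_edge_ids), length(x$offshoots),
    if (length(x$vertices_per_offshoot)) mean(x$vertices_per_offshoot)
    else NaN))
  invisible(x)
}

#' Identify LMA edges
#'
#' `mode = "labels"` returns the curated `kind = "lma"` edges.  `mode =
#' "geometric"` applies the morphological criterion: an LMA is a non-bridge
#' edge whose two endpoint bifurcations have their acute branching angles
#' directed toward each other -- at each endpoint, the bisector of the
#' most acute pair of the other incident edge directions (polyline
#' tangents when present) lies within 90 degrees of the edge's own
#' direction.
#'
#' @param net a [PialNetwork].
#' @param mode `"labels"` or `"geometric"`.
#' @return character vector of edge ids.
#' @export
identifyLmaEdges <- function(net, mode = c("labels", "geometric")) {
  mode <- match.arg(mode)
  stopifnot(is(net, "PialNetwork"))
  if (mode == "labels") return(net@edges$id[net@edges$kind == "lma"])
  deg <- table(c(net@edges$node_a, net@edges$node_b))
  if (!any(deg >= 3)) {
    warning("no bifurcation-degree nodes; geometric identification ",
            "returns no edges")
    return(character(0))
  }
  bridges <- bridgeEdgeIds(net)
  cand <- which(!(net@edges$id %in% bridges))
  if (!length(cand)) return(character(0))
  pos <- rbind(net@nodes$x_mm, net@nodes$y_mm)
  colnames(pos) <- net@nodes$id
  incident <- split(rep(seq_len(nrow(net@edges)), 2),
                    c(net@edges$node_a, net@edges$node_b))
  ok <- vapply(cand, function(ei) {
    ed <- net@edges[ei, ]
    for (v in c(ed$node_a, ed$node_b)) {
      bis <- acuteBisectorAt(net, v, ei, pos, incident)
      if (is.null(bis)) return(FALSE)
      d <- edgeDirAt(net, ei, v, pos)
      if (sum(bis * d) <= 0) return(FALSE)  # angle >= 90 degrees
    }
    TRUE
  }, logical(1))
  net@edges$id[cand[ok]]
}

#' Vertex-per-offshoot ratio by region
#'
#' For each region, the total vertex count over the offshoots assigned to
#' it divided by the number of such offshoots.  Regions with no offshoots
#' are flagged undefined.
#'
#' @param dec an `OffshootDecomposition` from [decomposeNetwork()].
#' @param regionOf character vector (length = number of offshoots) giving
#'   each offshoot's region, `NA` for unassigned; see
#'   [assignOffshootRegions()].
#' @return data.frame with columns `region`, `n_offshoots`,
#'   `total_vertices`, `ratio`, `defined`.
#' @export
vertexOffshootRatio <- function(dec, regionOf) {
  stopifnot(inherits(dec, "OffshootDecomposition"),
            length(regionOf) == length(dec$offshoots))
  regs <- sort(unique(regionOf[!is.na(regionOf)]))
  out <- do.call(rbind, lapply(regs, function(r) {
    i <- which(!is.na(regionOf) & regionOf == r)
    data.frame(region = r, n_offshoots = length(i),
               total_vertices = sum(dec$vertices_per_offshoot[i]),
               ratio = sum(dec$vertices_per_offshoot[i]) / length(i),
               defined = TRUE, stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(region = character(), n_offshoots = integer(),
                      total_vertices = integer(), ratio = numeric(),
                      defined = logical(), stringsAsFactors = FALSE)
  out
}

#' Assign offshoots to cortical regions
#'
#' An offshoot belongs to the region containing its attachment node
#' (`NA` when the attachment lies in no region).
#'
#' @param dec an `OffshootDecomposition`.
#' @param net the [PialNetwork] the decomposition came from.
#' @param rm the matching [RegionMap].
#' @return character vector aligned with `dec$offshoots`.
#' @export
assignOffshootRegions <- function(dec, net, rm) {
  pos <- rbind(net@nodes$x_mm, net@nodes$y_mm)
  colnames(pos) <- net@nodes$id
  vapply(dec$offshoots, function(o) {
    if (is.na(o$attachment_node)) return(NA_character_)
    p <- rbind(pos[, o$attachment_node])
    for (r in names(rm@regions))
      if (cppPointsInPolygon(p, ccwRing(rm@regions[[r]]), 1e-9)[1])
        return(r)
    NA_character_
  }, character(1))
}

#' Watershed polyline from inter-territory LMAs
#'
#' Collects every LMA edge joining two different arterial territories
#' (MCA vs ACA/PCA), takes each edge's midpoint (polyline arc-length
#' midpoint when a polyline exists, else the segment midpoint) and orders
#' the midpoints by angular position about the slab centroid.
#'
#' @param net a [PialNetwork] with territory labels.
#' @param rm optional [RegionMap]; when supplied the slab centroid is used
#'   as the angular origin, otherwise the node centroid.
#' @return ordered two-column matrix of midpoints (zero rows, with a
#'   warning, when no inter-territory LMAs exist).
#' @export
watershedPolyline <- function(net, rm = NULL) {
  stopifnot(is(net, "PialNetwork"))
  ed <- net@edges
  sel <- ed$kind == "lma" & ed$territory_a != ed$territory_b
  if (!any(sel)) {
    warning("no inter-territory LMA edges; empty watershed polyline")
    return(matrix(numeric(0), 0, 2))
  }
  pos <- rbind(net@nodes$x_mm, net@nodes$y_mm)
  colnames(pos) <- net@nodes$id
  mids <- t(vapply(which(sel), function(i) {
    if (!is.na(ed$polyline[i])) polylineMidpoint(polylineParse(ed$polyline[i]))
    else (pos[, ed$node_a[i]] + pos[, ed$node_b[i]]) / 2
  }, numeric(2)))
  ctr <- if (!is.null(rm)) colMeans(ccwRing(rm@slab)) else
    c(mean(net@nodes$x_mm), mean(net@nodes$y_mm))
  ang <- atan2(mids[, 2] - ctr[2], mids[, 1] - ctr[1])
  mids[order(ang), , drop = FALSE]
}
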