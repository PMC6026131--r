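# Small fixtures and independent oracles shared across the suite.

# square slab [0, side]^2 as a region-map-compatible matrix
squareRing <- function(side = 10, origin = c(0, 0)) {
  cbind(origin[1] + c(0, side, side, 0), origin[2] + c(0, 0, side, side))
}

# a 4-node square cycle (unit side, around (1,1)) with optional pendant
# PA leaves hanging off the first `pendants` corners
squareCycleNetwork <- function(pendants = 0, stubBifurcation = FALSE,
                               corners = "bifurcation") {
  nodes <- data.frame(
    id = c("c1", "c2", "c3", "c4"),
    x_mm = c(1, 2, 2, 1), y_mm = c(1, 1, 2, 2),
    kind = corners, stringsAsFactors = FALSE)
  edges <- data.frame(
    id = c("q1", "q2", "q3", "q4"),
    node_a = c("c1", "c2", "c3", "c4"),
    node_b = c("c2", "c3", "c4", "c1"),
    kind = "vessel", stringsAsFactors = FALSE)
  if (pendants > 0) {
    for (i in seq_len(pendants)) {
      pid <- sprintf("p%d", i)
      nodes <- rbind(nodes, data.frame(
        id = pid, x_mm = 0.5, y_mm = 0.4 + 0.2 * i, kind = "pa",
        stringsAsFactors = FALSE))
      edges <- rbind(edges, data.frame(
        id = sprintf("s%d", i), node_a = sprintf("c%d", i), node_b = pid,
        kind = "vessel", stringsAsFactors = FALSE))
    }
  }
  if (stubBifurcation) {
    nodes <- rbind(nodes, data.frame(
      id = c("b1", "pa1", "pa2"),
      x_mm = c(0.5, 0.2, 0.4), y_mm = c(0.5, 0.2, 0.1),
      kind = c("bifurcation", "pa", "pa"), stringsAsFactors = FALSE))
    edges <- rbind(edges, data.frame(
      id = c("t1", "t2", "t3"),
      node_a = c("c3", "b1", "b1"), node_b = c("b1", "pa1", "pa2"),
      kind = "vessel", stringsAsFactors = FALSE))
  }
  pialNetwork(nodes, edges, slabId = "slab")
}

# pure-R BFS connectivity oracle on an edge table (ignoring removed ids)
bfsComponents <- function(nodeIds, edges, dropEdgeId = NULL) {
  if (!is.null(dropEdgeId)) edges <- edges[edges$id != dropEdgeId, ]
  adj <- lapply(setNames(vector("list", length(nodeIds)), nodeIds),
                function(x) character(0))
  for (i in seq_len(nrow(edges))) {
    a <- edges$node_a[i]; b <- edges$node_b[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- setNames(rep(FALSE, length(nodeIds)), nodeIds)
  ncomp <- 0
  for (v in nodeIds) {
    if (seen[[v]]) next
    ncomp <- ncomp + 1
    queue <- v
    seen[[v]] <- TRUE
    while (length(queue)) {
      w <- queue[1]; queue <- queue[-1]
      nb <- adj[[w]][!seen[adj[[w]]]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  ncomp
}

# brute-force bridge oracle: an edge is a bridge iff its removal increases
# the number of connected components
bridgeOracle <- function(net) {
  nd <- networkNodes(net); ed <- networkEdges(net)
  base <- bfsComponents(nd$id, ed)
  ed$id[vapply(ed$id, function(e)
    bfsComponents(nd$id, ed, e) > base, logical(1))]
}

# random connected multigraph with <= maxEdges edges and random coordinates
randomTestNetwork <- function(seed, nV = 12, extra = 4) {
  set.seed(seed)
  ids <- sprintf("v%d", seq_len(nV))
  nodes <- data.frame(id = ids, x_mm = runif(nV, 0, 5),
                      y_mm = runif(nV, 0, 5), kind = "bifurcation",
                      stringsAsFactors = FALSE)
  edges <- data.frame(id = character(0), node_a = character(0),
                      node_b = character(0), kind = character(0),
                      stringsAsFactors = FALSE)
  for (i in 2:nV)
    edges <- rbind(edges, data.frame(
      id = sprintf("e%d", i - 1), node_a = ids[sample(i - 1, 1)],
      node_b = ids[i], kind = "vessel", stringsAsFactors = FALSE))
  k <- nV - 1
  for (j in seq_len(extra)) {
    ab <- sample(nV, 2)
    k <- k + 1
    edges <- rbind(edges, data.frame(
      id = sprintf("e%d", k), node_a = ids[ab[1]], node_b = ids[ab[2]],
      kind = "vessel", stringsAsFactors = FALSE))
  }
  pialNetwork(nodes, edges)
}

# stratified-jittered-grid Monte-Carlo areas of nearest-seed cells,
# restricted to the slab; `n` ~ total points
mcVoronoiAreas <- function(seeds, slab, n = 1e6, seed = 1) {
  set.seed(seed)
  lo <- apply(slab, 2, min); hi <- apply(slab, 2, max)
  nx <- ceiling(sqrt(n * (hi[1] - lo[1]) / (hi[2] - lo[2])))
  ny <- ceiling(n / nx)
  gx <- (rep(seq_len(nx), ny) - runif(nx * ny)) / nx * (hi[1] - lo[1]) + lo[1]
  gy <- (rep(seq_len(ny), each = nx) - runif(nx * ny)) / ny *
    (hi[2] - lo[2]) + lo[2]
  pts <- cbind(gx, gy)
  keep <- pointInPolygon(pts, slab, 0)
  pts <- pts[keep, , drop = FALSE]
  cellArea <- prod((hi - lo) / c(nx, ny))
  best <- rep.int(1L, nrow(pts))
  bestD <- (pts[, 1] - seeds[1, 1])^2 + (pts[, 2] - seeds[1, 2])^2
  if (nrow(seeds) > 1) for (s in 2:nrow(seeds)) {
    d <- (pts[, 1] - seeds[s, 1])^2 + (pts[, 2] - seeds[s, 2])^2
    upd <- d < bestD
    best[upd] <- s
    bestD[upd] <- d[upd]
  }
  counts <- tabulate(best, nbins = nrow(seeds))
  counts * cellArea
}

# quick default-calibration cohort params with a reproducible seed
testParams <- function(...) generatorParams(...)
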