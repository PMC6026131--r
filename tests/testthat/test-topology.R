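# Backbone/offshoot decomposition, loop counting, LMA identification,
# watershed polyline.

test_that("square cycle with pendant PAs decomposes as expected", {
  net <- squareCycleNetwork(pendants = 2)
  dec <- decomposeNetwork(net)
  expect_setequal(dec$backbone_edge_ids, c("q1", "q2", "q3", "q4"))
  expect_length(dec$offshoots, 2)
  expect_identical(sort(dec$vertices_per_offshoot), c(1L, 1L))
})

test_that("a bifurcating stub counts one bifurcation plus two PA leaves", {
  net <- squareCycleNetwork(stubBifurcation = TRUE)
  dec <- decomposeNetwork(net)
  expect_length(dec$offshoots, 1)
  expect_identical(dec$vertices_per_offshoot, 3L)
  # brute-force bridge enumeration agrees on this 7-edge graph
  expect_setequal(setdiff(networkEdges(net)$id, dec$backbone_edge_ids),
                  bridgeOracle(net))
})

test_that("an acyclic network has no backbone", {
  nd <- data.frame(id = c("a", "b", "c"), x_mm = 0:2, y_mm = c(0, 0, 0),
                   kind = c("endpoint", "bifurcation", "endpoint"))
  nd$kind[2] <- "pa"
  ed <- data.frame(id = c("e1", "e2"), node_a = c("a", "b"),
                   node_b = c("b", "c"), kind = "vessel")
  expect_error(decomposeNetwork(pialNetwork(nd, ed)), "backbone|cycle")
})

test_that("loop count equals the spanning-tree cycle-basis size", {
  expect_identical(loopCount(squareCycleNetwork()), 1L)
  nd <- data.frame(id = c("a", "b"), x_mm = 0:1, y_mm = c(0, 0),
                   kind = c("root", "endpoint"))
  ed <- data.frame(id = "e1", node_a = "a", node_b = "b", kind = "vessel")
  expect_identical(loopCount(pialNetwork(nd, ed)), 0L)
  for (s in 1:20) {
    net <- randomTestNetwork(s, nV = sample(5:15, 1), extra = sample(0:8, 1))
    ed <- networkEdges(net)
    # independent cycle basis size: edges minus BFS spanning forest edges
    nComp <- bfsComponents(networkNodes(net)$id, ed)
    basis <- nrow(ed) - (nrow(networkNodes(net)) - nComp)
    expect_identical(loopCount(net), as.integer(basis))
  }
})

test_that("decomposition agrees with brute-force bridge enumeration", {
  for (s in 101:130) {
    net <- randomTestNetwork(s, nV = sample(6:16, 1), extra = sample(1:9, 1))
    bridges <- bridgeOracle(net)
    if (length(bridges) == nrow(networkEdges(net))) {
      expect_error(decomposeNetwork(net), "backbone|cycle")
      next
    }
    dec <- decomposeNetwork(net)
    expect_setequal(dec$backbone_edge_ids,
                    setdiff(networkEdges(net)$id, bridges))
    # partition: backbone and offshoot edges disjoint and exhaustive
    offEdges <- unlist(lapply(dec$offshoots, `[[`, "member_edge_ids"))
    expect_identical(anyDuplicated(c(dec$backbone_edge_ids, offEdges)), 0L)
    expect_setequal(c(dec$backbone_edge_ids, offEdges),
                    networkEdges(net)$id)
  }
})

test_that("label-mode LMA identification is a ground-truth passthrough", {
  p <- generatorParams(seed = 51)
  rm <- generateGeometry(p, seed = 51)
  an <- generateAnimalNetwork(rm, p, seed = 52)
  expect_setequal(identifyLmaEdges(animalNetwork(an), "labels"),
                  groundTruth(an)$lma_edge_ids)
})

test_that("bridges are never identified as LMAs", {
  net <- squareCycleNetwork(pendants = 2)  # pendant stubs are bridges
  expect_false(any(c("s1", "s2") %in% identifyLmaEdges(net, "labels")))
  expect_false(any(c("s1", "s2") %in%
                     identifyLmaEdges(net, "geometric")))
})

test_that("geometric identification recovers the constructed LMA angles", {
  p <- generatorParams(seed = 53)
  tp <- fp <- truth <- 0
  for (k in 1:15) {
    rm <- generateGeometry(p, seed = 5300 + k)
    an <- generateAnimalNetwork(rm, p, seed = 5400 + k)
    got <- identifyLmaEdges(animalNetwork(an), "geometric")
    tr <- groundTruth(an)$lma_edge_ids
    tp <- tp + length(intersect(got, tr))
    fp <- fp + length(setdiff(got, tr))
    truth <- truth + length(tr)
  }
  expect_gte(tp / truth, 0.95)
  expect_lte(fp / truth, 0.05)
})

test_that("vertex/offshoot ratios follow the counting rule", {
  net <- squareCycleNetwork(pendants = 2)
  dec <- decomposeNetwork(net)
  r <- vertexOffshootRatio(dec, rep("barrels", 2))
  expect_equal(r$ratio[r$region == "barrels"], 1.0)
  net2 <- squareCycleNetwork(pendants = 1, stubBifurcation = FALSE)
  # offshoots with vertex counts 1 and 3 average to 2
  net3 <- squareCycleNetwork(pendants = 1, stubBifurcation = TRUE)
  dec3 <- decomposeNetwork(net3)
  expect_setequal(dec3$vertices_per_offshoot, c(1L, 3L))
  r3 <- vertexOffshootRatio(dec3, rep("visual", length(dec3$offshoots)))
  expect_equal(r3$ratio[r3$region == "visual"], 2.0)
})

test_that("ratios match an independent recount from ground truth", {
  p <- generatorParams(seed = 57)
  rm <- generateGeometry(p, seed = 57)
  an <- generateAnimalNetwork(rm, p, seed = 58)
  net <- animalNetwork(an)
  dec <- decomposeNetwork(net)
  reg <- assignOffshootRegions(dec, net, animalRegions(an))
  got <- vertexOffshootRatio(dec, reg)
  # recount: group truth memberships by attachment region, count pa/bif
  tr <- groundTruth(an)
  kind <- stats::setNames(networkNodes(net)$kind, networkNodes(net)$id)
  pos <- networkNodes(net)
  attRegion <- vapply(tr$offshoot_attachments, function(a) {
    p <- c(pos$x_mm[pos$id == a], pos$y_mm[pos$id == a])
    hit <- NA_character_
    for (r in names(regionPolygons(animalRegions(an))))
      if (pointInPolygon(rbind(p), regionPolygons(animalRegions(an))[[r]])[1]) {
        hit <- r; break
      }
    hit
  }, character(1))
  memb <- tr$offshoot_memberships
  for (r in got$region) {
    idx <- which(!is.na(attRegion) & attRegion == r)
    vsum <- sum(vapply(idx, function(i) {
      mem <- names(memb)[memb == i]
      sum(kind[mem] %in% c("bifurcation", "pa"))
    }, numeric(1)))
    expect_identical(got$total_vertices[got$region == r], as.integer(vsum))
    expect_identical(got$n_offshoots[got$region == r], length(idx))
  }
})

test_that("adding a PA leaf to an offshoot adds exactly one vertex", {
  net <- squareCycleNetwork(pendants = 1)
  dec <- decomposeNetwork(net)
  nd <- networkNodes(net); ed <- networkEdges(net)
  nd <- rbind(nd, data.frame(id = "extra", x_mm = 0.1, y_mm = 0.1,
                             kind = "pa"))
  ed <- rbind(ed, data.frame(id = "se", node_a = "p1", node_b = "extra",
                             kind = "vessel", territory_a = "unknown",
                             territory_b = "unknown",
                             polyline = NA_character_))
  dec2 <- decomposeNetwork(pialNetwork(nd, ed))
  expect_identical(length(dec2$offshoots), length(dec$offshoots))
  expect_identical(sum(dec2$vertices_per_offshoot),
                   sum(dec$vertices_per_offshoot) + 1L)
})

test_that("watershed midpoints are angle-ordered about the centroid", {
  nd <- data.frame(id = c("a", "b", "c"), x_mm = c(0, 0, 1),
                   y_mm = c(0, 2, 1),
                   kind = c("bifurcation", "bifurcation", "bifurcation"))
  ed <- data.frame(id = c("w1", "e2", "e3"),
                   node_a = c("a", "a", "b"), node_b = c("b", "c", "c"),
                   kind = c("lma", "vessel", "vessel"),
                   territory_a = c("MCA", "MCA", "MCA"),
                   territory_b = c("ACA", "MCA", "MCA"))
  net <- pialNetwork(nd, ed)
  ws <- watershedPolyline(net)
  expect_equal(nrow(ws), 1)
  expect_equal(ws[1, ], c(0, 1))

  # no inter-territory LMA: empty with warning
  ed$territory_b <- "MCA"
  expect_warning(ws0 <- watershedPolyline(pialNetwork(nd, ed)),
                 "no inter-territory")
  expect_identical(nrow(ws0), 0L)

  # several inter-territory LMAs sort like a brute-force angle oracle
  p <- generatorParams(seed = 61)
  rm <- generateGeometry(p, seed = 61)
  an <- generateAnimalNetwork(rm, p, seed = 62)
  net <- animalNetwork(an)
  edg <- networkEdges(net)
  sel <- edg$kind == "lma" & edg$territory_a != edg$territory_b
  if (sum(sel) >= 2) {
    ws <- watershedPolyline(net, animalRegions(an))
    ctr <- colMeans(slabPolygon(animalRegions(an)))
    ang <- atan2(ws[, 2] - ctr[2], ws[, 1] - ctr[1])
    expect_true(all(diff(ang) >= 0))
  }
})
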