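# Voronoi tiling, majority-area assignment, LMA localisation, count table.

test_that("trivial tilings: whole slab and mirror symmetry", {
  slab <- squareRing(1)
  t1 <- voronoiTiling(matrix(c(0.3, 0.6), 1), slab)
  expect_equal(unname(t1$cell_areas_mm2), 1.0, tolerance = 1e-9)
  t2 <- voronoiTiling(rbind(c(0.25, 0.5), c(0.75, 0.5)), slab)
  expect_equal(unname(t2$cell_areas_mm2[1]), unname(t2$cell_areas_mm2[2]),
               tolerance = 1e-9)
  expect_equal(sum(t2$cell_areas_mm2), 1.0, tolerance = 1e-9)
})

test_that("coincident duplicate seeds are rejected with their ids", {
  pts <- rbind(c(0.2, 0.2), c(0.2, 0.2), c(0.8, 0.8))
  rownames(pts) <- c("pa1", "pa2", "pa3")
  expect_error(voronoiTiling(pts, squareRing(1)), "pa1/pa2")
})

test_that("cell areas match a dense nearest-seed Monte-Carlo estimate", {
  set.seed(77)
  slab <- squareRing(5)
  seeds <- cbind(runif(25, 0.2, 4.8), runif(25, 0.2, 4.8))
  tl <- voronoiTiling(seeds, slab)
  expect_lt(abs(sum(tl$cell_areas_mm2) - 25) / 25, 1e-6)
  mc <- mcVoronoiAreas(seeds, slab, n = 1e6, seed = 78)
  expect_lt(max(abs(mc - unname(tl$cell_areas_mm2)) /
                  unname(tl$cell_areas_mm2)), 0.005)
})

test_that("majority-area rule assigns PAs, with lexicographic ties", {
  slab <- squareRing(4)
  rmap <- regionMap(slab, list(
    barrels = squareRing(1, c(0.5, 0.5)),
    visual = cbind(c(1.5, 3.5, 3.5, 1.5), c(0.5, 0.5, 1.5, 1.5))))
  # a cell lying fully inside barrels is assigned to it
  cellIn <- cbind(c(0.6, 1.2, 1.2, 0.6), c(0.6, 0.6, 1.2, 1.2))
  tin <- structure(list(seed_ids = "z", seeds = rbind(c(0.9, 0.9)),
                        cells = list(cellIn),
                        cell_areas_mm2 = c(z = polygonArea(cellIn))),
                   class = "TerritoryTiling")
  expect_identical(unname(assignPaRegions(tin, rmap)), "barrels")

  # 60/40 overlap: rectangle cell overlapping visual on 60% of its area
  cell <- cbind(c(1.9, 2.9, 2.9, 1.9), c(0.9, 0.9, 1.9, 1.9))
  ov <- polygonArea(clipToConvex(regionPolygons(rmap)$visual, cell))
  expect_equal(ov / polygonArea(cell), 0.6, tolerance = 1e-9)
  tiling <- list(seed_ids = "x", seeds = rbind(c(2.4, 1.2)),
                 cells = list(cell),
                 cell_areas_mm2 = c(x = polygonArea(cell)))
  class(tiling) <- "TerritoryTiling"
  expect_identical(unname(assignPaRegions(tiling, rmap)), "visual")
  # Monte-Carlo cross-check of the clipped share
  set.seed(79)
  pts <- cbind(runif(2e5, 1.9, 2.9), runif(2e5, 0.9, 1.9))
  share <- mean(pointInPolygon(pts, regionPolygons(rmap)$visual, 0))
  expect_lt(abs(share - 0.6), 0.005)

  # exact 50/50 split between auditory and barrels -> lexicographic
  rmap2 <- regionMap(slab, list(
    barrels = squareRing(1, c(1, 1)),
    auditory = squareRing(1, c(2, 1))))
  cell2 <- cbind(c(1.5, 2.5, 2.5, 1.5), c(1.2, 1.2, 1.8, 1.8))
  tiling2 <- list(seed_ids = "y", seeds = rbind(c(2, 1.5)),
                  cells = list(cell2),
                  cell_areas_mm2 = c(y = polygonArea(cell2)))
  class(tiling2) <- "TerritoryTiling"
  expect_warning(a2 <- assignPaRegions(tiling2, rmap2), "tie")
  expect_identical(unname(a2), "auditory")
})

test_that("LMA midpoint rule honours containment and the near cutoff", {
  slab <- squareRing(6)
  rmap <- regionMap(slab, list(
    hindlimb = squareRing(1, c(1, 1)),
    visual = squareRing(1, c(4, 4))))
  nd <- data.frame(id = c("a", "b", "c", "d", "e", "f"),
                   x_mm = c(1.2, 1.8, 4.4, 5.8, 3.0, 3.4),
                   y_mm = c(1.5, 1.5, 3.9, 3.9, 0.5, 0.5),
                   kind = "bifurcation")
  nd$kind <- c("bifurcation", "bifurcation", "bifurcation", "bifurcation",
               "root", "endpoint")
  ed <- data.frame(id = c("l1", "l2", "v1", "v2", "v3"),
                   node_a = c("a", "c", "a", "c", "e"),
                   node_b = c("b", "d", "e", "f", "f"),
                   kind = c("lma", "lma", "vessel", "vessel", "vessel"))
  net <- pialNetwork(nd, ed)
  asg <- assignLmaRegions(net, rmap, nearCutoffMm = 0.3)
  # l1 midpoint (1.5, 1.5) inside hindlimb
  expect_identical(unname(asg["l1"]), "hindlimb")
  # l2 midpoint (5.1, 3.9): 0.1 mm right of visual's right edge at x = 4.5
  expect_identical(unname(asg["l2"]), "visual")
  asg0 <- assignLmaRegions(net, rmap, nearCutoffMm = 0.05)
  expect_true(is.na(asg0["l2"]))
})

test_that("LMA assignment agrees with a brute-force geometry oracle", {
  p <- generatorParams(seed = 81)
  rm <- generateGeometry(p, seed = 81)
  an <- generateAnimalNetwork(rm, p, seed = 82)
  net <- animalNetwork(an)
  asg <- assignLmaRegions(net, rm, nearCutoffMm = 0.3)
  ed <- networkEdges(net)
  nd <- networkNodes(net)
  for (e in names(asg)) {
    i <- which(ed$id == e)
    pl <- ed$polyline[i]
    mid <- if (!is.na(pl)) {
      m <- do.call(rbind, lapply(strsplit(strsplit(pl, ";")[[1]], ","),
                                 as.numeric))
      # arc-length midpoint by fine resampling
      seg <- sqrt(rowSums((m[-1, , drop = FALSE] -
                           m[-nrow(m), , drop = FALSE])^2))
      cum <- c(0, cumsum(seg)); half <- sum(seg) / 2
      j <- max(which(cum <= half)); j <- min(j, nrow(m) - 1)
      t <- if (seg[j] > 0) (half - cum[j]) / seg[j] else 0
      m[j, ] + t * (m[j + 1, ] - m[j, ])
    } else {
      a <- which(nd$id == ed$node_a[i]); b <- which(nd$id == ed$node_b[i])
      c(mean(c(nd$x_mm[a], nd$x_mm[b])), mean(c(nd$y_mm[a], nd$y_mm[b])))
    }
    inReg <- NA_character_
    for (r in sort(names(regionPolygons(rm))))
      if (pointInPolygon(rbind(mid), regionPolygons(rm)[[r]])[1]) {
        inReg <- r; break
      }
    if (is.na(inReg)) {
      dd <- vapply(sort(names(regionPolygons(rm))), function(r)
        distanceToBoundary(rbind(mid), regionPolygons(rm)[[r]])[1],
        numeric(1))
      if (min(dd) <= 0.3) inReg <- names(dd)[which.min(dd)]
    }
    expect_identical(unname(asg[e]), unname(inReg))
  }
})

test_that("count tables have the right schema and conserve counts", {
  p <- generatorParams(nSham = 2, nPlucked = 2, seed = 83)
  co <- generateCohort(p)
  tab <- buildCountTable(co, "pa")
  expect_lte(nrow(tab), 4 * 5)
  expect_true(all(tab$count >= 0))
  for (an in co) {
    sub <- tab[tab$animal_id == an@animalId, ]
    expect_lte(sum(sub$count), length(groundTruth(an)$pa_node_ids))
  }
  # omitted regions disappear as rows
  tab2 <- buildCountTable(co, "pa",
                          omit = data.frame(animal_id = co[[1]]@animalId,
                                            region = "visual"))
  expect_identical(nrow(tab2), nrow(tab) - 1L)
  expect_false(any(tab2$animal_id == co[[1]]@animalId &
                     tab2$region == "visual"))
})

test_that("a hand-placed PA fixture reproduces the manual tally", {
  slab <- squareRing(6)
  rmap <- regionMap(slab, list(
    barrels = squareRing(3, c(0, 0)),        # [0,3] x [0,3]
    visual = squareRing(2.5, c(3.5, 3.5))))  # [3.5,6] x [3.5,6]
  # 12 PAs: 5 in barrels, 4 in visual (cells stay inside their regions),
  # 3 between the regions whose cell majorities fall outside both
  pts <- rbind(c(0.8, 0.8), c(2.0, 0.8), c(0.8, 2.0), c(2.0, 2.0),
               c(1.4, 1.4),
               c(4.4, 4.4), c(5.4, 4.4), c(4.4, 5.4), c(5.4, 5.4),
               c(4.6, 1.2), c(1.2, 4.6), c(3.6, 3.6))
  nd <- data.frame(id = sprintf("pa%02d", 1:12), x_mm = pts[, 1],
                   y_mm = pts[, 2], kind = "pa")
  hub <- data.frame(id = "root", x_mm = 3.1, y_mm = 3.1, kind = "root")
  ed <- data.frame(id = sprintf("e%02d", 1:12), node_a = "root",
                   node_b = nd$id, kind = "vessel")
  an <- new("AnimalSample", animalId = "fix1", group = "sham", sex = "M",
            ageDays = 50, network = pialNetwork(rbind(hub, nd), ed),
            regions = rmap, truth = list())
  tab <- buildCountTable(an, "pa")
  expect_identical(tab$count[tab$region == "barrels"], 5L)
  expect_identical(tab$count[tab$region == "visual"], 4L)
  # independent nearest-seed Monte-Carlo majority check, seed by seed
  mcCells <- mcVoronoiAreas(pts, slab, n = 4e5, seed = 86)
  set.seed(87)
  grid <- cbind(runif(4e5, 0, 6), runif(4e5, 0, 6))
  nearest <- rep.int(1L, nrow(grid))
  bd <- (grid[, 1] - pts[1, 1])^2 + (grid[, 2] - pts[1, 2])^2
  for (s in 2:12) {
    d <- (grid[, 1] - pts[s, 1])^2 + (grid[, 2] - pts[s, 2])^2
    upd <- d < bd; nearest[upd] <- s; bd[upd] <- d[upd]
  }
  expected <- c(rep("barrels", 5), rep("visual", 4), rep(NA_character_, 3))
  for (s in 1:12) {
    cellPts <- grid[nearest == s, , drop = FALSE]
    shares <- vapply(regionPolygons(rmap), function(rp)
      mean(pointInPolygon(cellPts, rp, 0)), numeric(1))
    mcAssign <- if (max(shares) > 0.5) names(which.max(shares)) else
      NA_character_
    expect_identical(unname(mcAssign), expected[s])
  }
})

test_that("assignments are invariant to a rigid translation", {
  set.seed(85)
  slab <- squareRing(5)
  seeds <- cbind(runif(18, 0.3, 4.7), runif(18, 0.3, 4.7))
  rmap <- regionMap(slab, list(
    barrels = squareRing(1.5, c(0.7, 0.7)),
    visual = squareRing(1.5, c(2.8, 2.8))))
  a1 <- assignPaRegions(voronoiTiling(seeds, slab), rmap)
  sh <- c(3.7, -2.1)
  shift <- function(m) sweep(m, 2, sh, "+")
  rmap2 <- regionMap(shift(slab),
                     lapply(regionPolygons(rmap), shift))
  a2 <- assignPaRegions(voronoiTiling(shift(seeds), shift(slab)), rmap2)
  expect_identical(unname(a1), unname(a2))
})
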