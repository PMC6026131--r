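#' @title Synthetic cohort generation
#' @name pialnet-synthgen
#' @description Seeded generation of synthetic pial arterial cohorts with
#'   the statistical and geometric structure the analysis assumes, plus
#'   ground-truth labels for every structure the pipeline must recover.
NULL

# unit vector at `deg` degrees in the local frame (t = 0 deg, n = 90 deg)
dirLocal <- function(t, n, deg) {
  a <- deg * pi / 180
  cos(a) * t + sin(a) * n
}

normalize <- function(v) {
  L <- sqrt(sum(v^2))
  if (L < 1e-12) c(1, 0) else v / L
}

clampInside <- function(p, slab, centroid, margin = 0.99) {
  k <- 0
  while (!cppPointsInPolygon(rbind(p), slab, 0)[1] && k < 200) {
    p <- centroid + margin * (p - centroid)
    k <- k + 1
  }
  p
}

#' Generate per-animal slab and region geometry
#'
#' Builds a convex slab polygon of the requested area and five disjoint
#' convex region polygons at the requested areas (both within 1%), with
#' jittered placement so that every animal's geometry differs while areas
#' are preserved.
#'
#' @param params a [GeneratorParams].
#' @param seed RNG seed (defaults to the params seed).
#' @param slabId identifier for the map.
#' @return a validated [RegionMap].
#' @export
generateGeometry <- function(params = generatorParams(), seed = NULL,
                             slabId = "slab") {
  stopifnot(is(params, "GeneratorParams"))
  validObject(params)
  if (!is.null(seed)) set.seed(seed)
  A <- params@slabAreaMm2
  areas <- params@regionAreasMm2
  if (sum(areas) >= A)
    stop("requested region areas (", sum(areas),
         " mm^2) cannot be placed in a slab of ", A, " mm^2")
  R <- sqrt(A / pi)
  for (attempt in seq_len(60)) {
    rot <- runif(1, 0, 2 * pi)
    slab <- regularPolygon(A, n = 24, rotation = rot)
    # anchor the five regions on a jittered ring, barrels centre-most
    base <- runif(1, 0, 2 * pi)
    ang <- base + 2 * pi * (seq_along(areas) - 1) / length(areas) +
      rnorm(length(areas), 0, 0.02)
    rad <- 0.55 * R
    regions <- list()
    ok <- TRUE
    for (i in seq_along(areas)) {
      a <- areas[i]
      asp <- runif(1, 0.85, 1.18)
      w <- sqrt(a * asp); h <- a / w
      cx <- rad * cos(ang[i]) + rnorm(1, 0, 0.04)
      cy <- rad * sin(ang[i]) + rnorm(1, 0, 0.04)
      poly <- cbind(cx + c(-w, w, w, -w) / 2, cy + c(-h, -h, h, h) / 2)
      if (!all(cppPointsInPolygon(poly, slab, 0))) { ok <- FALSE; break }
      for (p in regions)
        if (cppPolygonArea(cppClipToConvex(poly, p)) > 1e-9) {
          ok <- FALSE; break
        }
      if (!ok) break
      regions[[names(areas)[i]]] <- poly
    }
    if (ok) {
      rm <- regionMap(slab, regions, slabId = slabId)
      got <- regionAreas(rm)
      if (abs(slabArea(rm) - A) / A < 0.01 &&
          all(abs(got[names(areas)] - areas) / areas < 0.01))
        return(rm)
    }
  }
  stop("could not place the requested region areas inside the slab")
}

# greedy nearest-neighbour ordering of LMA sites, from the leftmost site
tourOrder <- function(sites) {
  L <- nrow(sites)
  if (L <= 1) return(seq_len(L))
  left <- which.min(sites[, 1])
  ord <- integer(L); used <- logical(L)
  ord[1] <- left; used[left] <- TRUE
  for (k in 2:L) {
    last <- sites[ord[k - 1], ]
    d <- (sites[, 1] - last[1])^2 + (sites[, 2] - last[2])^2
    d[used] <- Inf
    ord[k] <- which.min(d)
    used[ord[k]] <- TRUE
  }
  ord
}

# nearest point on a polyline; returns list(d2, arclength s)
nearestOnPolyline <- function(q, pl) {
  nseg <- nrow(pl) - 1
  best <- list(d2 = Inf)
  s0 <- 0
  for (i in seq_len(nseg)) {
    a <- pl[i, ]; b <- pl[i + 1, ]
    ab <- b - a
    L2 <- sum(ab^2)
    t <- if (L2 > 0) sum((q - a) * ab) / L2 else 0
    t <- min(max(t, 0), 1)
    p <- a + t * ab
    d2 <- sum((q - p)^2)
    if (d2 < best$d2) best <- list(d2 = d2, s = s0 + t * sqrt(L2))
    s0 <- s0 + sqrt(L2)
  }
  best
}

polylineLength <- function(pl)
  sum(sqrt(rowSums((pl[-1, , drop = FALSE] -
                    pl[-nrow(pl), , drop = FALSE])^2)))

polylinePointAt <- function(pl, s) {
  seg <- sqrt(rowSums((pl[-1, , drop = FALSE] -
                       pl[-nrow(pl), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  s <- min(max(s, 0), cum[length(cum)])
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- min(max(i, 1), nrow(pl) - 1)
  t <- if (seg[i] > 0) (s - cum[i]) / seg[i] else 0
  pl[i, ] + t * (pl[i + 1, ] - pl[i, ])
}

#' Generate one synthetic animal network
#'
#' Realises the count process the analysis assumes: an animal-level
#' log-normal random intercept shared across regions, spatial-Poisson
#' penetrating-arteriole placement (per-region intensities plus uniform
#' background in the slab outside the regions), per-region Poisson LMA
#' placement, a connected backbone tree spanning the attachment sites with
#' each LMA added as a chordal edge (one independent cycle each, endpoint
#' bifurcations with acute angles pointing toward each other), and PA
#' offshoot stubs that with probability `offshootBifurcationProb` carry one
#' extra bifurcation and a second PA leaf.  All ground-truth labels are
#' recorded.
#'
#' @param regions a [RegionMap] from [generateGeometry()].
#' @param params a [GeneratorParams].
#' @param group `"sham"` or `"plucked"`.
#' @param seed optional RNG seed.
#' @param animalId,sex,ageDays animal metadata.
#' @return an [AnimalSample].
#' @export
generateAnimalNetwork <- function(regions, params = generatorParams(),
                                  group = c("sham", "plucked"), seed = NULL,
                                  animalId = "a1", sex = "M",
                                  ageDays = 55) {
  stopifnot(is(regions, "RegionMap"), is(params, "GeneratorParams"))
  group <- match.arg(group)
  if (!is.null(seed)) set.seed(seed)
  slab <- ccwRing(regions@slab)
  centroid <- colMeans(slab)
  uA <- rnorm(1, 0, params@sigmaU)
  rpolys <- regions@regions
  rids <- names(rpolys)
  rareas <- regionAreas(regions)

  mult <- function(r) {
    if (group == "plucked" && r == "barrels") params@deprivationMultiplier
    else 1
  }
  # PA placement: regions + uniform background
  paPts <- matrix(numeric(0), 0, 2)
  expPa <- setNames(numeric(length(rids)), rids)
  for (r in rids) {
    lam <- params@lambdaPaPerMm2 * rareas[[r]] * exp(uA) * mult(r)
    expPa[r] <- lam
    n <- rpois(1, lam)
    if (n > 0) paPts <- rbind(paPts, samplePointsInPolygon(n, rpolys[[r]]))
  }
  bgArea <- slabArea(regions) - sum(rareas)
  nBg <- rpois(1, params@lambdaPaPerMm2 * bgArea * exp(uA))
  got <- 0
  while (got < nBg) {
    cand <- samplePointsInPolygon(nBg - got, slab)
    inReg <- rep(FALSE, nrow(cand))
    for (r in rids)
      inReg <- inReg | cppPointsInPolygon(cand, rpolys[[r]], 0)
    keep <- cand[!inReg, , drop = FALSE]
    if (nrow(keep)) { paPts <- rbind(paPts, keep); got <- got + nrow(keep) }
  }
  # LMA sites per region
  lmaPts <- matrix(numeric(0), 0, 2)
  expLma <- setNames(numeric(length(rids)), rids)
  for (r in rids) {
    rate <- params@lmaRatePerMm2[[r]]
    lam <- rate * rareas[[r]] * exp(uA) * mult(r)
    expLma[r] <- lam
    n <- rpois(1, lam)
    if (n > 0) lmaPts <- rbind(lmaPts, samplePointsInPolygon(n, rpolys[[r]]))
  }
  nPa <- nrow(paPts); nLma <- nrow(lmaPts)
  if (nPa == 0 && nLma == 0)
    stop("degenerate network: zero PAs and zero LMAs generated")

  # ---- node/edge accumulators -------------------------------------------
  nodes <- list(); edges <- list()
  nodeCount <- 0; edgeCount <- 0
  addNode <- function(xy, kind) {
    nodeCount <<- nodeCount + 1
    id <- sprintf("n%d", nodeCount)
    nodes[[nodeCount]] <<- data.frame(id = id, x_mm = xy[1], y_mm = xy[2],
                                      kind = kind, stringsAsFactors = FALSE)
    id
  }
  nodePos <- function(id) {
    i <- as.integer(sub("^n", "", id))
    c(nodes[[i]]$x_mm, nodes[[i]]$y_mm)
  }
  addEdge <- function(a, b, kind = "vessel", ta = "MCA", tb = "MCA",
                      polyline = NULL) {
    edgeCount <<- edgeCount + 1
    id <- sprintf("e%d", edgeCount)
    pl <- if (is.null(polyline)) NA_character_ else
      polylineFormat(rbind(nodePos(a), polyline, nodePos(b)))
    edges[[edgeCount]] <<- data.frame(
      id = id, node_a = a, node_b = b, kind = kind, territory_a = ta,
      territory_b = tb, polyline = pl, stringsAsFactors = FALSE)
    id
  }
  jit <- function() rnorm(1, 0, 2.5)  # degrees

  backboneIds <- character(0)
  lmaIds <- character(0)
  # offshoots accumulated as list(attachment = <query point>, nodes, edges)
  twigs <- list()

  # ---- backbone chain of LMA loops --------------------------------------
  basePl <- list()   # per base edge: polyline matrix (junction..junction)
  baseEnds <- list() # per base edge: c(junction_a_id, junction_b_id)
  rootAttach <- NULL
  if (nLma > 0) {
    ord <- tourOrder(lmaPts)
    s <- lmaPts[ord, , drop = FALSE]
    L <- nLma
    J <- matrix(0, L + 1, 2)
    t1 <- if (L > 1) normalize(s[2, ] - s[1, ]) else c(1, 0)
    tL <- if (L > 1) normalize(s[L, ] - s[L - 1, ]) else c(1, 0)
    J[1, ] <- clampInside(s[1, ] - 0.5 * t1, slab, centroid)
    if (L > 1)
      for (i in 2:L) J[i, ] <- (s[i - 1, ] + s[i, ]) / 2
    J[L + 1, ] <- clampInside(s[L, ] + 0.5 * tL, slab, centroid)
    jid <- vapply(seq_len(L + 1), function(i)
      addNode(J[i, ], "bifurcation"), character(1))
    # root offshoot before the first junction
    rootPos <- clampInside(J[1, ] - 0.3 * t1, slab, centroid)
    rootId <- addNode(rootPos, "root")
    addEdge(rootId, jid[1])
    # tail endpoint after the last junction
    tailPos <- clampInside(J[L + 1, ] + 0.3 * tL, slab, centroid)
    tailId <- addNode(tailPos, "endpoint")
    addEdge(jid[L + 1], tailId)
    twigs <- c(twigs, list(list(nodes = rootId, attach = jid[1]),
                           list(nodes = tailId, attach = jid[L + 1])))

    relDist <- sqrt(rowSums((s - matrix(centroid, L, 2, byrow = TRUE))^2))
    maxR <- max(sqrt(rowSums((slab -
      matrix(centroid, nrow(slab), 2, byrow = TRUE))^2)))
    # per-loop tangent frames, blended at shared junctions so that the
    # four prescribed branch angles at a junction share one frame
    loopT <- lapply(seq_len(L), function(i)
      normalize(J[i + 1, ] - J[i, ]))
    juncT <- vector("list", L + 1)
    juncT[[1]] <- loopT[[1]]
    if (L > 1)
      for (i in 2:L) {
        b <- loopT[[i - 1]] + loopT[[i]]
        juncT[[i]] <- if (sqrt(sum(b^2)) > 1e-6) normalize(b)
                      else loopT[[i - 1]]
      }
    juncT[[L + 1]] <- loopT[[L]]
    for (i in seq_len(L)) {
      tv <- loopT[[i]]
      nv <- c(-tv[2], tv[1])
      jtA <- juncT[[i]]; jnA <- c(-jtA[2], jtA[1])
      jtB <- juncT[[i + 1]]; jnB <- c(-jtB[2], jtB[1])
      ui <- clampInside(s[i, ] - 0.2 * tv, slab, centroid)
      vi <- clampInside(s[i, ] + 0.2 * tv, slab, centroid)
      uid <- addNode(ui, "bifurcation")
      vid <- addNode(vi, "bifurcation")
      # chordal LMA edge; outer-band sites join another arterial territory
      terr <- "MCA"
      if (relDist[i] > 0.6 * maxR)
        terr <- if (s[i, 2] > centroid[2]) "ACA" else "PCA"
      lmaIds <- c(lmaIds, addEdge(uid, vid, kind = "lma",
                                  ta = "MCA", tb = terr))
      # arc j_i -> u_i, tangent 30 deg at j (junction frame), 233 at u
      eA <- addEdge(jid[i], uid, polyline = rbind(
        clampInside(J[i, ] + 0.15 * dirLocal(jtA, jnA, 30 + jit()),
                    slab, centroid),
        clampInside(ui + 0.15 * dirLocal(tv, nv, 233 + jit()),
                    slab, centroid)))
      # arc v_i -> j_{i+1}, tangent 307 deg at v, 150 at j (junction frame)
      eB <- addEdge(vid, jid[i + 1], polyline = rbind(
        clampInside(vi + 0.15 * dirLocal(tv, nv, 307 + jit()),
                    slab, centroid),
        clampInside(J[i + 1, ] + 0.15 * dirLocal(jtB, jnB, 150 + jit()),
                    slab, centroid)))
      backboneIds <- c(backboneIds, tail(lmaIds, 1), eA, eB)
      # endpoint twigs make u and v degree-3 bifurcations
      eu <- addNode(clampInside(ui + 0.25 * dirLocal(tv, nv, 330 + jit()),
                                slab, centroid), "endpoint")
      ev <- addNode(clampInside(vi + 0.25 * dirLocal(tv, nv, 210 + jit()),
                                slab, centroid), "endpoint")
      addEdge(uid, eu)
      addEdge(vid, ev)
      twigs <- c(twigs, list(list(nodes = eu, attach = uid),
                             list(nodes = ev, attach = vid)))
      # sagging base j_i -> j_{i+1}
      mid <- (J[i, ] + J[i + 1, ]) / 2
      basePl[[i]] <- rbind(
        J[i, ],
        clampInside(J[i, ] + 0.2 * dirLocal(jtA, jnA, 350 + jit()),
                    slab, centroid),
        clampInside(mid - 0.15 * nv, slab, centroid),
        clampInside(J[i + 1, ] + 0.2 * dirLocal(jtB, jnB, 190 + jit()),
                    slab, centroid),
        J[i + 1, ])
      baseEnds[[i]] <- c(jid[i], jid[i + 1])
    }
  } else {
    # acyclic fallback: a root hub carrying every offshoot
    hub <- clampInside(if (nPa) colMeans(rbind(paPts)) else centroid,
                       slab, centroid)
    rootId <- addNode(hub, "root")
    rootAttach <- rootId
  }

  # ---- PA offshoots ------------------------------------------------------
  offshoots <- list()  # list(queryPoint, paNodes, bifNode or NULL)
  if (nPa > 0) {
    paIds <- vapply(seq_len(nPa), function(i)
      addNode(paPts[i, ], "pa"), character(1))
    used <- logical(nPa)
    pairWith <- rep(NA_integer_, nPa)
    if (nPa > 1 && params@offshootBifurcationProb > 0) {
      D <- as.matrix(stats::dist(paPts))
      diag(D) <- Inf
      for (k in seq_len(nPa)) {
        if (used[k]) next
        used[k] <- TRUE
        if (runif(1) < params@offshootBifurcationProb) {
          d <- D[k, ]; d[used] <- Inf
          j <- which.min(d)
          if (is.finite(d[j]) && d[j] < 0.8) {
            pairWith[k] <- j
            used[j] <- TRUE
          }
        }
      }
    }
    done <- logical(nPa)
    for (k in seq_len(nPa)) {
      if (done[k]) next
      done[k] <- TRUE
      if (!is.na(pairWith[k])) {
        j <- pairWith[k]; done[j] <- TRUE
        m <- (paPts[k, ] + paPts[j, ]) / 2
        mid <- addNode(m, "bifurcation")
        addEdge(mid, paIds[k])
        addEdge(mid, paIds[j])
        offshoots[[length(offshoots) + 1]] <-
          list(q = m, pas = c(paIds[k], paIds[j]), bif = mid,
               stubFrom = mid)
      } else {
        offshoots[[length(offshoots) + 1]] <-
          list(q = paPts[k, ], pas = paIds[k], bif = NULL,
               stubFrom = paIds[k])
      }
    }
  }

  offMembers <- list()
  offAttach <- character(0)
  if (length(offshoots)) {
    if (is.null(rootAttach)) {
      # project each offshoot onto the nearest base polyline
      att <- lapply(offshoots, function(o) {
        best <- NULL; bi <- NA
        for (i in seq_along(basePl)) {
          cand <- nearestOnPolyline(o$q, basePl[[i]])
          if (is.null(best) || cand$d2 < best$d2) { best <- cand; bi <- i }
        }
        list(base = bi, s = best$s)
      })
      # split each base edge at the attachment arclengths, spreading
      # attachments at least 0.02 mm apart so stub nodes stay degree 3
      for (i in seq_along(basePl)) {
        sel <- which(vapply(att, function(a) a$base, numeric(1)) == i)
        pl <- basePl[[i]]
        seg <- sqrt(rowSums((pl[-1, , drop = FALSE] -
                             pl[-nrow(pl), , drop = FALSE])^2))
        cum <- c(0, cumsum(seg))
        totL <- cum[length(cum)]
        if (!length(sel)) {
          backboneIds <- c(backboneIds,
                           addEdge(baseEnds[[i]][1], baseEnds[[i]][2],
                                   polyline = pl[-c(1, nrow(pl)), ,
                                                 drop = FALSE]))
          next
        }
        ss <- vapply(att[sel], function(a) a$s, numeric(1))
        o2 <- order(ss)
        sel <- sel[o2]; ss <- ss[o2]
        gap <- 0.02
        ss[1] <- min(max(ss[1], gap), totL - gap)
        if (length(ss) > 1)
          for (q in 2:length(ss))
            ss[q] <- min(max(ss[q], ss[q - 1] + gap), totL - gap)
        # merge any attachments still coincident (crowded base)
        bNode <- character(length(sel))
        lastS <- -Inf; lastB <- ""
        for (q in seq_along(sel)) {
          if (q > 1 && ss[q] - lastS < 1e-9) {
            bNode[q] <- lastB
            ss[q] <- lastS
          } else {
            bNode[q] <- addNode(polylinePointAt(pl, ss[q]), "bifurcation")
            lastS <- ss[q]; lastB <- bNode[q]
          }
        }
        cuts <- !duplicated(bNode)
        cutS <- ss[cuts]; cutB <- bNode[cuts]
        fromId <- baseEnds[[i]][1]; fromS <- 0
        for (q in seq_along(cutB)) {
          inner <- pl[cum > fromS + 1e-9 & cum < cutS[q] - 1e-9, ,
                      drop = FALSE]
          backboneIds <- c(backboneIds,
                           addEdge(fromId, cutB[q], polyline =
                                     if (nrow(inner)) inner else NULL))
          fromId <- cutB[q]; fromS <- cutS[q]
        }
        inner <- pl[cum > fromS + 1e-9 & cum < cum[length(cum)] - 1e-9, ,
                    drop = FALSE]
        backboneIds <- c(backboneIds,
                         addEdge(fromId, baseEnds[[i]][2], polyline =
                                   if (nrow(inner)) inner else NULL))
        for (q in seq_along(sel)) {
          o <- offshoots[[sel[q]]]
          addEdge(bNode[q], o$stubFrom)
          offAttach <- c(offAttach, bNode[q])
          offMembers[[length(offMembers) + 1]] <- c(o$pas, o$bif)
        }
      }
    } else {
      for (o in offshoots) {
        addEdge(rootAttach, o$stubFrom)
        offAttach <- c(offAttach, rootAttach)
        offMembers[[length(offMembers) + 1]] <- c(o$pas, o$bif)
      }
    }
  }
  for (tw in twigs) {
    offAttach <- c(offAttach, tw$attach)
    offMembers[[length(offMembers) + 1]] <- tw$nodes
  }
  # offshoots sharing an attachment node are one bridge subtree
  if (length(offMembers)) {
    grp <- split(seq_along(offMembers), offAttach)
    offMembers <- lapply(grp, function(ix)
      unlist(offMembers[ix], use.names = FALSE))
    offAttach <- names(grp)
  }
  membership <- integer(0)
  for (i in seq_along(offMembers))
    membership <- c(membership,
                    setNames(rep(i, length(offMembers[[i]])),
                             offMembers[[i]]))

  net <- pialNetwork(do.call(rbind, nodes), do.call(rbind, edges),
                     slabId = regions@slabId,
                     metadata = list(animal_id = animalId, group = group,
                                     sex = sex, age_days = ageDays))
  truth <- list(
    lma_edge_ids = lmaIds,
    pa_node_ids = if (nPa) net@nodes$id[net@nodes$kind == "pa"] else
      character(0),
    backbone_edge_ids = backboneIds,
    offshoot_memberships = membership,
    offshoot_attachments = offAttach,
    per_region_expected_counts = list(pa = expPa, lma = expLma),
    u_animal = uA)
  new("AnimalSample", animalId = animalId, group = group, sex = sex,
      ageDays = ageDays, network = net, regions = regions, truth = truth)
}

#' Generate a synthetic cohort
#'
#' Generates `nSham + nPlucked` animals with per-animal jittered geometry,
#' sexes interleaved (9 M / 10 F at the default cohort size), ages uniform
#' in `ageRangeDays`, fully reproducible from the params seed.
#'
#' @param params a [GeneratorParams].
#' @return a list of [AnimalSample] objects.
#' @examples
#' \donttest{
#' cohort <- generateCohort(generatorParams(nSham = 2, nPlucked = 1,
#'                                          slabAreaMm2 = 12,
#'                                          regionAreasMm2 = c(barrels = 1.5,
#'                                            hindlimb = 0.8),
#'                                          lmaRatePerMm2 = c(barrels = 1,
#'                                            hindlimb = 2),
#'                                          seed = 7))
#' length(cohort)
#' }
#' @export
generateCohort <- function(params = generatorParams()) {
  stopifnot(is(params, "GeneratorParams"))
  validObject(params)
  n <- params@nSham + params@nPlucked
  if (n == 0) stop("cohort size is zero")
  set.seed(params@seed)
  groups <- c(rep("sham", params@nSham), rep("plucked", params@nPlucked))
  sexes <- rep(c("F", "M"), length.out = n)
  ages <- runif(n, params@ageRangeDays[1], params@ageRangeDays[2])
  lapply(seq_len(n), function(i) {
    rmSeed <- deriveSeed(params@seed, 2L * i)
    netSeed <- deriveSeed(params@seed, 2L * i + 1L)
    rm <- generateGeometry(params, seed = rmSeed,
                           slabId = sprintf("slab%02d", i))
    generateAnimalNetwork(rm, params, group = groups[i], seed = netSeed,
                          animalId = sprintf("m%02d", i), sex = sexes[i],
                          ageDays = ages[i])
  })
}
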