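#' @title Territory assignment and count tables
#' @name pialnet-territories
#' @description Voronoi tessellation of penetrating-arteriole seeds,
#'   majority-area region assignment, LMA localisation and assembly of the
#'   per-animal-by-region count table the count models consume.
NULL

#' Voronoi tiling of PA seeds inside the slab
#'
#' Each cell is the set of slab points nearer (Euclidean) to its seed than
#' to any other, realised by clipping the slab by perpendicular-bisector
#' half-planes.  Cells partition the slab: their areas sum to the slab
#' area.
#'
#' @param paPoints two-column coordinate matrix of PA seeds (rownames used
#'   as seed ids when present) or a data.frame with `id`, `x_mm`, `y_mm`.
#' @param slab slab polygon (matrix) or a [RegionMap].
#' @return an object of class `TerritoryTiling`: list with `seed_ids`,
#'   `seeds` (matrix), `cells` (list of polygons) and `cell_areas_mm2`.
#' @export
voronoiTiling <- function(paPoints, slab) {
  if (is(slab, "RegionMap")) slab <- slab@slab
  slab <- ccwRing(slab)
  if (is.data.frame(paPoints)) {
    ids <- as.character(paPoints$id)
    pts <- cbind(paPoints$x_mm, paPoints$y_mm)
  } else {
    pts <- rbind(paPoints)
    ids <- rownames(pts)
    if (is.null(ids)) ids <- sprintf("s%d", seq_len(nrow(pts)))
  }
  if (nrow(pts) < 1) stop("at least one PA seed is required")
  inside <- cppPointsInPolygon(pts, slab, 1e-9)
  if (!any(inside)) stop("no PA seed lies inside the slab")
  d <- as.matrix(stats::dist(pts))
  diag(d) <- Inf
  dup <- which(d < 1e-9, arr.ind = TRUE)
  if (nrow(dup))
    stop("coincident duplicate seeds: ",
         paste(unique(apply(dup, 1, function(ij)
           paste(sort(ids[ij]), collapse = "/"))), collapse = ", "))
  cells <- cppVoronoiCells(pts, slab)
  areas <- vapply(cells, cppPolygonArea, numeric(1))
  structure(list(seed_ids = ids, seeds = pts, cells = cells,
                 cell_areas_mm2 = setNames(areas, ids)),
            class = "TerritoryTiling")
}

#' @export
print.TerritoryTiling <- function(x, ...) {
  cat(sprintf("TerritoryTiling: %d cells, total area %.4f mm^2\n",
              length(x$cells), sum(x$cell_areas_mm2)))
  invisible(x)
}

#' Majority-area assignment of PAs to regions
#'
#' A PA belongs to a region only if more than half of its Voronoi cell's
#' area lies inside that region; otherwise it belongs to no region.  An
#' exact 0.5 tie is resolved to the lexicographically smallest tied region
#' id, with a warning.
#'
#' @param tiling a `TerritoryTiling` from [voronoiTiling()].
#' @param rm the matching [RegionMap].
#' @return named character vector, seed id -> region id or `NA`.
#' @export
assignPaRegions <- function(tiling, rm) {
  stopifnot(inherits(tiling, "TerritoryTiling"), is(rm, "RegionMap"))
  regs <- lapply(rm@regions, ccwRing)
  rids <- names(regs)
  out <- setNames(rep(NA_character_, length(tiling$seed_ids)),
                  tiling$seed_ids)
  for (i in seq_along(tiling$cells)) {
    cell <- tiling$cells[[i]]
    ca <- tiling$cell_areas_mm2[i]
    if (!is.finite(ca) || ca <= 0) next
    share <- vapply(regs, function(rp) {
      # quick bounding-box rejection before clipping
      if (max(rp[, 1]) < min(cell[, 1]) || min(rp[, 1]) > max(cell[, 1]) ||
          max(rp[, 2]) < min(cell[, 2]) || min(rp[, 2]) > max(cell[, 2]))
        return(0)
      cppPolygonArea(cppClipToConvex(rp, cell)) / ca
    }, numeric(1))
    if (!length(share)) next
    top <- max(share)
    if (top > 0.5 + 1e-12) {
      out[i] <- rids[which.max(share)]
    } else if (abs(top - 0.5) <= 1e-12) {
      tied <- sort(rids[abs(share - top) <= 1e-12])
      warning(sprintf(
        "seed %s: exact 0.5 majority tie (%s); assigning '%s'",
        tiling$seed_ids[i], paste(tied, collapse = ", "), tied[1]))
      out[i] <- tied[1]
    }
  }
  out
}

#' Assign LMA edges to regions by their midpoints
#'
#' An LMA belongs to the region containing its midpoint (polyline
#' arc-length midpoint when a polyline exists).  A midpoint in no region
#' is assigned to the nearest region boundary within `nearCutoffMm`, else
#' to none.
#'
#' @param net a [PialNetwork].
#' @param rm the matching [RegionMap].
#' @param nearCutoffMm near-region cutoff distance (mm), default 0.3.
#' @return named character vector, LMA edge id -> region id or `NA`.
#' @export
assignLmaRegions <- function(net, rm, nearCutoffMm = 0.3) {
  stopifnot(is(net, "PialNetwork"), is(rm, "RegionMap"))
  ed <- net@edges
  sel <- which(ed$kind == "lma")
  out <- setNames(rep(NA_character_, length(sel)), ed$id[sel])
  if (!length(sel)) return(out)
  pos <- rbind(net@nodes$x_mm, net@nodes$y_mm)
  colnames(pos) <- net@nodes$id
  mids <- t(vapply(sel, function(i) {
    if (!is.na(ed$polyline[i])) polylineMidpoint(polylineParse(ed$polyline[i]))
    else (pos[, ed$node_a[i]] + pos[, ed$node_b[i]]) / 2
  }, numeric(2)))
  regs <- lapply(rm@regions, ccwRing)
  rids <- sort(names(regs))
  for (k in seq_len(nrow(mids))) {
    p <- rbind(mids[k, ])
    hit <- NA_character_
    for (r in rids)
      if (cppPointsInPolygon(p, regs[[r]], 1e-9)[1]) { hit <- r; break }
    if (is.na(hit)) {
      dd <- vapply(rids, function(r) cppDistToBoundary(p, regs[[r]])[1],
                   numeric(1))
      if (min(dd) <= nearCutoffMm) hit <- rids[which.min(dd)]
    }
    out[k] <- hit
  }
  out
}

#' Build the per-animal-by-region count table
#'
#' One row per animal and region, holding the response count `count`
#' (whose meaning depends on `flavor`), the region area `area_mm2` and the
#' animal covariates.  Flavors: `pa` counts PAs by the Voronoi
#' majority-area rule; `lma` counts LMAs by the midpoint rule;
#' `offshoot_vertices` and `offshoot_count` summarise the backbone
#' decomposition per attachment region.  Regions listed in `omit` are
#' dropped as rows (omitted, not zero).
#'
#' @param cohort a list of [AnimalSample] objects (or a single one).
#' @param flavor one of `"pa"`, `"lma"`, `"offshoot_vertices"`,
#'   `"offshoot_count"`.
#' @param omit optional data.frame with columns `animal_id`, `region`:
#'   animal-region pairs to omit (e.g. damaged regions).
#' @param nearCutoffMm cutoff for the LMA midpoint rule.
#' @return data.frame with columns `animal_id`, `group`, `sex`,
#'   `age_days`, `region`, `area_mm2`, `count`, `flavor`.
#' @export
buildCountTable <- function(cohort,
                            flavor = c("pa", "lma", "offshoot_vertices",
                                       "offshoot_count"),
                            omit = NULL, nearCutoffMm = 0.3) {
  flavor <- match.arg(flavor)
  if (is(cohort, "AnimalSample")) cohort <- list(cohort)
  rows <- lapply(cohort, function(an) {
    net <- an@network; rm <- an@regions
    rids <- names(rm@regions)
    areas <- regionAreas(rm)
    counts <- setNames(rep(0L, length(rids)), rids)
    if (flavor == "pa") {
      nd <- net@nodes[net@nodes$kind == "pa", ]
      if (nrow(nd)) {
        tl <- voronoiTiling(nd[, c("id", "x_mm", "y_mm")], rm)
        asg <- assignPaRegions(tl, rm)
        tb <- table(asg[!is.na(asg)])
        counts[names(tb)] <- as.integer(tb)
      }
    } else if (flavor == "lma") {
      asg <- assignLmaRegions(net, rm, nearCutoffMm)
      tb <- table(asg[!is.na(asg)])
      counts[names(tb)] <- as.integer(tb)
    } else {
      dec <- decomposeNetwork(net)
      reg <- assignOffshootRegions(dec, net, rm)
      keep <- !is.na(reg)
      if (flavor == "offshoot_count") {
        tb <- table(reg[keep])
        counts[names(tb)] <- as.integer(tb)
      } else {
        agg <- tapply(dec$vertices_per_offshoot[keep], reg[keep], sum)
        counts[names(agg)] <- as.integer(agg)
      }
    }
    data.frame(animal_id = an@animalId, group = an@group, sex = an@sex,
               age_days = an@ageDays, region = rids,
               area_mm2 = as.numeric(areas[rids]),
               count = as.integer(counts[rids]), flavor = flavor,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(omit) && nrow(omit)) {
    drop <- paste(out$animal_id, out$region) %in%
      paste(omit$animal_id, omit$region)
    out <- out[!drop, , drop = FALSE]
  }
  out
}
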