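#' Construct a PialNetwork
#'
#' @param nodes data.frame with columns `id`, `x_mm`, `y_mm`, `kind`.
#' @param edges data.frame with columns `id`, `node_a`, `node_b`, `kind`;
#'   `territory_a`, `territory_b` default to `"unknown"`, `polyline` to `NA`.
#' @param slabId identifier of the matching [RegionMap].
#' @param metadata free-form list.
#' @return a validated [PialNetwork].
#' @examples
#' nd <- data.frame(id = c("a", "b"), x_mm = c(0, 1), y_mm = c(0, 0),
#'                  kind = c("root", "endpoint"))
#' ed <- data.frame(id = "e1", node_a = "a", node_b = "b", kind = "vessel")
#' pialNetwork(nd, ed)
#' @export
pialNetwork <- function(nodes, edges, slabId = NA_character_,
                        metadata = list()) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges)) {
    if (is.null(edges$territory_a)) edges$territory_a <- "unknown"
    if (is.null(edges$territory_b)) edges$territory_b <- "unknown"
    if (is.null(edges$polyline)) edges$polyline <- NA_character_
  } else {
    edges <- data.frame(id = character(), node_a = character(),
                        node_b = character(), kind = character(),
                        territory_a = character(), territory_b = character(),
                        polyline = character(), stringsAsFactors = FALSE)
  }
  for (cl in c("id", "node_a", "node_b", "kind", "territory_a",
               "territory_b", "polyline"))
    edges[[cl]] <- as.character(edges[[cl]])
  nodes$id <- as.character(nodes$id)
  nodes$kind <- as.character(nodes$kind)
  rownames(nodes) <- NULL; rownames(edges) <- NULL
  new("PialNetwork", nodes = nodes, edges = edges, slabId = slabId,
      metadata = metadata)
}

#' Construct a RegionMap
#'
#' @param slab two-column coordinate matrix (mm), open ring.
#' @param regions named list of two-column coordinate matrices; names from
#'   `barrels`, `forelimb`, `hindlimb`, `visual`, `auditory`.
#' @param slabId identifier.
#' @return a validated [RegionMap].
#' @examples
#' sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' regionMap(sq, list(barrels = sq * 0.5))
#' @export
regionMap <- function(slab, regions = list(), slabId = NA_character_) {
  slab <- ccwRing(as.matrix(slab))
  regions <- lapply(regions, function(p) ccwRing(as.matrix(p)))
  new("RegionMap", slab = slab, regions = regions, slabId = slabId)
}

#' Generator settings for synthetic cohorts
#'
#' Returns a [GeneratorParams] object.  The defaults are the study
#' conditions the analysis assumes; see the class documentation.
#'
#' @param slabAreaMm2 target slab area (mm^2).
#' @param regionAreasMm2 named per-region target areas (mm^2).
#' @param lambdaPaPerMm2 global penetrating-arteriole intensity (per mm^2).
#' @param lmaRatePerMm2 named per-region LMA intensities (per mm^2).
#' @param sigmaU sd of the animal-level log-intensity random intercept.
#' @param deprivationMultiplier multiplier on deprived animals'
#'   barrels-region intensities (1 = null effect).
#' @param offshootBifurcationProb probability an offshoot carries one extra
#'   bifurcation and a second PA leaf.
#' @param nSham,nPlucked group sizes.
#' @param ageRangeDays uniform age draw bounds in days.
#' @param seed RNG seed.
#' @return a validated [GeneratorParams].
#' @examples
#' generatorParams(seed = 1)
#' @export
generatorParams <- function(slabAreaMm2 = 35,
                            regionAreasMm2 = c(barrels = 4.0, forelimb = 1.5,
                                               hindlimb = 1.0, visual = 3.0,
                                               auditory = 1.5),
                            lambdaPaPerMm2 = 17.4,
                            lmaRatePerMm2 = c(barrels = 1.0, forelimb = 1.0,
                                              hindlimb = 2.0, visual = 1.0,
                                              auditory = 1.0),
                            sigmaU = 0.25,
                            deprivationMultiplier = 1.0,
                            offshootBifurcationProb = 0.25,
                            nSham = 10, nPlucked = 9,
                            ageRangeDays = c(45, 65),
                            seed = 1L) {
  new("GeneratorParams", slabAreaMm2 = slabAreaMm2,
      regionAreasMm2 = regionAreasMm2, lambdaPaPerMm2 = lambdaPaPerMm2,
      lmaRatePerMm2 = lmaRatePerMm2, sigmaU = sigmaU,
      deprivationMultiplier = deprivationMultiplier,
      offshootBifurcationProb = offshootBifurcationProb,
      nSham = nSham, nPlucked = nPlucked, ageRangeDays = ageRangeDays,
      seed = seed)
}
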