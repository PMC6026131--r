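#' @title Core S4 classes
#' @name pialnet-classes
#' @description S4 containers for traced pial arterial networks, cortical
#'   region geometry, generator settings, simulated animals and fitted
#'   count models.
NULL

NODE_KINDS <- c("bifurcation", "pa", "endpoint", "root")
EDGE_KINDS <- c("vessel", "lma")
TERRITORIES <- c("MCA", "ACA", "PCA", "unknown")
REGION_IDS <- c("auditory", "barrels", "forelimb", "hindlimb", "visual")

#' PialNetwork: a traced pial arterial network
#'
#' A planar undirected multigraph.  Nodes carry millimetre coordinates and a
#' kind (`bifurcation`, `pa`, `endpoint`, `root`); edges carry a kind
#' (`vessel` or `lma`), territory labels for the two incident arterial trees
#' (`MCA`, `ACA`, `PCA`, `unknown`) and an optional polyline tracing the
#' vessel path.  Self-loops are forbidden; multi-edges are allowed (two
#' anastomoses may join the same node pair).
#'
#' @slot nodes data.frame with columns `id`, `x_mm`, `y_mm`, `kind`.
#' @slot edges data.frame with columns `id`, `node_a`, `node_b`, `kind`,
#'   `territory_a`, `territory_b`, `polyline` (semicolon-separated
#'   `"x,y"` pairs or `NA`).
#' @slot slabId identifier linking the network to a [RegionMap].
#' @slot metadata free-form list (animal id, group, unrecognised GraphML
#'   attributes, ...).
#' @exportClass PialNetwork
setClass("PialNetwork",
  representation(nodes = "data.frame", edges = "data.frame",
                 slabId = "character", metadata = "list"),
  prototype(slabId = NA_character_, metadata = list()))

setValidity("PialNetwork", function(object) {
  nd <- object@nodes; ed <- object@edges
  need_n <- c("id", "x_mm", "y_mm", "kind")
  need_e <- c("id", "node_a", "node_b", "kind", "territory_a",
              "territory_b", "polyline")
  if (!all(need_n %in% names(nd)))
    return(sprintf("nodes must have columns %s", paste(need_n, collapse = ", ")))
  if (!all(need_e %in% names(ed)))
    return(sprintf("edges must have columns %s", paste(need_e, collapse = ", ")))
  if (anyDuplicated(nd$id)) return("duplicated node ids")
  if (nrow(ed)) {
    if (anyDuplicated(ed$id)) return("duplicated edge ids")
    bad <- !(ed$node_a %in% nd$id) | !(ed$node_b %in% nd$id)
    if (any(bad))
      return(sprintf("edge %s references a missing node", ed$id[bad][1]))
    if (any(ed$node_a == ed$node_b))
      return(sprintf("edge %s is a self-loop", ed$id[ed$node_a == ed$node_b][1]))
    if (!all(ed$kind %in% EDGE_KINDS)) return("invalid edge kind")
  }
  if (nrow(nd) && !all(nd$kind %in% NODE_KINDS)) return("invalid node kind")
  TRUE
})

#' RegionMap: slab and primary-sensory-region geometry
#'
#' A slab outline and up to five named, pairwise non-overlapping primary
#' sensory region polygons (`barrels`, `forelimb`, `hindlimb`, `visual`,
#' `auditory`) contained in the slab.  Polygons are open rings (the last
#' vertex is not repeated) in planar millimetres, counter-clockwise.
#'
#' @slot slab two-column coordinate matrix (outer ring, mm).
#' @slot regions named list of two-column coordinate matrices.
#' @slot slabId identifier.
#' @exportClass RegionMap
setClass("RegionMap",
  representation(slab = "matrix", regions = "list", slabId = "character"),
  prototype(slabId = NA_character_))

setValidity("RegionMap", function(object) {
  if (ncol(object@slab) != 2 || nrow(object@slab) < 3)
    return("slab must be an n x 2 matrix with n >= 3")
  rid <- names(object@regions)
  if (length(object@regions)) {
    if (is.null(rid) || anyDuplicated(rid)) return("regions must be uniquely named")
    if (!all(rid %in% REGION_IDS))
      return(sprintf("unknown region id(s): %s",
                     paste(setdiff(rid, REGION_IDS), collapse = ", ")))
    for (r in rid) {
      p <- object@regions[[r]]
      if (!is.matrix(p) || ncol(p) != 2 || nrow(p) < 3)
        return(sprintf("region %s is not an n x 2 matrix with n >= 3", r))
    }
    # pairwise overlap beyond tolerance
    if (length(rid) > 1) {
      for (i in seq_len(length(rid) - 1)) for (j in seq(i + 1, length(rid))) {
        ov <- cppPolygonArea(cppClipToConvex(object@regions[[rid[i]]],
                                             object@regions[[rid[j]]]))
        if (ov > 1e-9)
          return(sprintf("regions %s and %s overlap by %.3g mm^2",
                         rid[i], rid[j], ov))
      }
    }
    for (r in rid) {
      inside <- cppPointsInPolygon(object@regions[[r]], object@slab, 1e-9)
      if (!all(inside))
        return(sprintf("region %s is not contained in the slab", r))
    }
  }
  TRUE
})

#' GeneratorParams: settings for the synthetic cohort generator
#'
#' Defaults encode the study conditions the analysis assumes: a 35 mm^2 slab
#' holding five primary sensory regions, a global penetrating-arteriole
#' intensity of 17.4 per mm^2, hindlimb-enriched LMA intensities, a
#' log-normal animal-level random intercept (sd 0.25) and a cohort of
#' 10 sham plus 9 whisker-plucked animals aged P45--P65.
#'
#' @slot slabAreaMm2 target slab area (mm^2).
#' @slot regionAreasMm2 named per-region target areas (mm^2).
#' @slot lambdaPaPerMm2 global PA intensity (per mm^2).
#' @slot lmaRatePerMm2 named per-region LMA intensities (per mm^2).
#' @slot sigmaU sd of the animal-level log-intensity random intercept.
#' @slot deprivationMultiplier multiplicative factor on deprived animals'
#'   barrels-region intensities (1 = null).
#' @slot offshootBifurcationProb probability an offshoot carries one extra
#'   bifurcation and a second PA leaf.
#' @slot nSham,nPlucked group sizes.
#' @slot ageRangeDays uniform age draw bounds (days).
#' @slot seed RNG seed.
#' @exportClass GeneratorParams
setClass("GeneratorParams",
  representation(slabAreaMm2 = "numeric", regionAreasMm2 = "numeric",
                 lambdaPaPerMm2 = "numeric", lmaRatePerMm2 = "numeric",
                 sigmaU = "numeric", deprivationMultiplier = "numeric",
                 offshootBifurcationProb = "numeric", nSham = "numeric",
                 nPlucked = "numeric", ageRangeDays = "numeric",
                 seed = "numeric"))

setValidity("GeneratorParams", function(object) {
  if (object@lambdaPaPerMm2 < 0 || any(object@lmaRatePerMm2 < 0))
    return("intensities must be >= 0")
  if (sum(object@regionAreasMm2) >= object@slabAreaMm2)
    return("region areas must sum to less than the slab area")
  if (object@offshootBifurcationProb < 0 || object@offshootBifurcationProb > 1)
    return("offshootBifurcationProb must be in [0, 1]")
  if (object@sigmaU < 0) return("sigmaU must be >= 0")
  if (object@deprivationMultiplier < 0)
    return("deprivationMultiplier must be >= 0")
  if (object@nSham < 0 || object@nPlucked < 0)
    return("group sizes must be >= 0")
  if (length(object@ageRangeDays) != 2 ||
      diff(object@ageRangeDays) < 0)
    return("ageRangeDays must be increasing bounds")
  TRUE
})

#' AnimalSample: one simulated animal
#'
#' @slot animalId identifier.
#' @slot group `"sham"` or `"plucked"`.
#' @slot sex `"M"` or `"F"`.
#' @slot ageDays age in days.
#' @slot network the [PialNetwork].
#' @slot regions the [RegionMap].
#' @slot truth ground-truth labels: `lma_edge_ids`, `pa_node_ids`,
#'   `backbone_edge_ids`, `offshoot_memberships` (named integer, node ->
#'   offshoot index), `per_region_expected_counts`, `u_animal`.
#' @exportClass AnimalSample
setClass("AnimalSample",
  representation(animalId = "character", group = "character",
                 sex = "character", ageDays = "numeric",
                 network = "PialNetwork", regions = "RegionMap",
                 truth = "list"))

setValidity("AnimalSample", function(object) {
  if (!object@group %in% c("sham", "plucked")) return("invalid group")
  if (!object@sex %in% c("M", "F")) return("invalid sex")
  TRUE
})

#' PialFit: a fitted Poisson mixed count model
#'
#' Result of [fitPoissonGlmm()]: fixed-effect estimates with standard
#' errors, the random-intercept sd, the maximised marginal log-likelihood,
#' the fixed-effect covariance, fitted values (conditional on the empirical
#' Bayes animal intercepts) and Pearson residuals.
#'
#' @slot coef named fixed-effect estimates.
#' @slot se named standard errors.
#' @slot vcov fixed-effect covariance matrix.
#' @slot sigmaU estimated random-intercept sd (0 when fixed at zero).
#' @slot logLik maximised marginal log-likelihood.
#' @slot fitted per-row expected counts.
#' @slot pearson per-row Pearson residuals.
#' @slot converged logical.
#' @slot nObs,nFixed row and fixed-parameter counts.
#' @slot terms character vector of fitted model terms.
#' @slot factorInfo per-factor level bookkeeping used by [tukeyPosthoc()].
#' @slot table the count table the model was fitted to.
#' @exportClass PialFit
setClass("PialFit",
  representation(coef = "numeric", se = "numeric", vcov = "matrix",
                 sigmaU = "numeric", logLik = "numeric", fitted = "numeric",
                 pearson = "numeric", converged = "logical",
                 nObs = "integer", nFixed = "integer", terms = "character",
                 factorInfo = "list", table = "data.frame"))
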