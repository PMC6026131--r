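#' @title Accessors and show methods
#' @name pialnet-accessors
#' @description Accessor generics for the core classes.  Slots should not
#'   be reached into directly.
NULL

#' @describeIn pialnet-accessors node table of a network
#' @param x object.
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @describeIn pialnet-accessors edge table of a network
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @describeIn pialnet-accessors slab polygon (matrix, mm)
#' @export
setGeneric("slabPolygon", function(x) standardGeneric("slabPolygon"))

#' @describeIn pialnet-accessors named list of region polygons
#' @export
setGeneric("regionPolygons", function(x) standardGeneric("regionPolygons"))

#' @describeIn pialnet-accessors named numeric of region areas (mm^2)
#' @export
setGeneric("regionAreas", function(x) standardGeneric("regionAreas"))

#' @describeIn pialnet-accessors slab area (mm^2)
#' @export
setGeneric("slabArea", function(x) standardGeneric("slabArea"))

#' @describeIn pialnet-accessors ground-truth labels of a simulated animal
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

setMethod("networkNodes", "PialNetwork", function(x) x@nodes)
setMethod("networkEdges", "PialNetwork", function(x) x@edges)
setMethod("networkNodes", "AnimalSample", function(x) x@network@nodes)
setMethod("networkEdges", "AnimalSample", function(x) x@network@edges)
setMethod("slabPolygon", "RegionMap", function(x) x@slab)
setMethod("regionPolygons", "RegionMap", function(x) x@regions)
setMethod("regionAreas", "RegionMap", function(x)
  vapply(x@regions, cppPolygonArea, numeric(1)))
setMethod("slabArea", "RegionMap", function(x) cppPolygonArea(x@slab))
setMethod("groundTruth", "AnimalSample", function(x) x@truth)

#' @describeIn pialnet-accessors network of a simulated animal
#' @export
setGeneric("animalNetwork", function(x) standardGeneric("animalNetwork"))
setMethod("animalNetwork", "AnimalSample", function(x) x@network)

#' @describeIn pialnet-accessors region map of a simulated animal
#' @export
setGeneric("animalRegions", function(x) standardGeneric("animalRegions"))
setMethod("animalRegions", "AnimalSample", function(x) x@regions)

#' @param object object to display.
#' @rdname pialnet-accessors
#' @export
setMethod("show", "PialNetwork", function(object) {
  cat(sprintf("PialNetwork: %d nodes, %d edges (%d lma), slab '%s'\n",
              nrow(object@nodes), nrow(object@edges),
              sum(object@edges$kind == "lma"), object@slabId))
})

#' @rdname pialnet-accessors
#' @export
setMethod("show", "RegionMap", function(object) {
  a <- regionAreas(object)
  cat(sprintf("RegionMap '%s': slab %.2f mm^2; %d regions (%s)\n",
              object@slabId, slabArea(object), length(object@regions),
              paste(sprintf("%s %.2f", names(a), a), collapse = ", ")))
})

#' @rdname pialnet-accessors
#' @export
setMethod("show", "AnimalSample", function(object) {
  cat(sprintf("AnimalSample %s: %s %s, age %.0f d; ", object@animalId,
              object@group, object@sex, object@ageDays))
  show(object@network)
})

#' @rdname pialnet-accessors
#' @export
setMethod("show", "PialFit", function(object) {
  cat(sprintf(
    "PialFit: %d obs, %d fixed params, sigma_u = %.4f, logLik = %.3f%s\n",
    object@nObs, object@nFixed, object@sigmaU, object@logLik,
    if (object@converged) "" else " (NOT CONVERGED)"))
  print(round(cbind(estimate = object@coef, se = object@se), 4))
})

#' @rdname pialnet-accessors
#' @export
setMethod("show", "GeneratorParams", function(object) {
  cat(sprintf(paste0(
    "GeneratorParams: slab %.1f mm^2, lambda_PA %.1f /mm^2, sigma_u %.2f,\n",
    "  deprivation x%.2f, cohort %d sham + %d plucked, seed %d\n"),
    object@slabAreaMm2, object@lambdaPaPerMm2, object@sigmaU,
    object@deprivationMultiplier, object@nSham, object@nPlucked,
    as.integer(object@seed)))
})
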