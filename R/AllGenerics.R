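#' Accessors for pipeline objects
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @return the slot contents named by the accessor.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("subjectTable", function(x) standardGeneric("subjectTable"))
#' @rdname accessors
#' @export
setGeneric("gmvMatrix", function(x) standardGeneric("gmvMatrix"))
#' @rdname accessors
#' @export
setGeneric("atlasTable", function(x) standardGeneric("atlasTable"))
#' @rdname accessors
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))
#' @rdname accessors
#' @export
setGeneric("corMatrix", function(x) standardGeneric("corMatrix"))
#' @rdname accessors
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))
#' @rdname accessors
#' @export
setGeneric("zMatrix", function(x) standardGeneric("zMatrix"))
#' @rdname accessors
#' @export
setGeneric("pMatrix", function(x) standardGeneric("pMatrix"))
#' @rdname accessors
#' @export
setGeneric("sigMask", function(x) standardGeneric("sigMask"))
#' @rdname accessors
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))
#' @rdname accessors
#' @export
setGeneric("prevalenceCounts", function(x) standardGeneric("prevalenceCounts"))
#' @rdname accessors
#' @export
setGeneric("featureEdges", function(x) standardGeneric("featureEdges"))
#' @rdname accessors
#' @export
setGeneric("featureZ", function(x) standardGeneric("featureZ"))
#' @rdname accessors
#' @export
setGeneric("chosenK", function(x) standardGeneric("chosenK"))
#' @rdname accessors
#' @export
setGeneric("subtypeLabels", function(x) standardGeneric("subtypeLabels"))
#' @rdname accessors
#' @export
setGeneric("silhouetteByK", function(x) standardGeneric("silhouetteByK"))

#' @rdname accessors
#' @export
setMethod("subjectTable", "CohortBundle", function(x) x@subjects)
#' @rdname accessors
#' @export
setMethod("gmvMatrix", "CohortBundle", function(x) x@gmv)
#' @rdname accessors
#' @export
setMethod("atlasTable", "CohortBundle", function(x) x@atlas)
#' @rdname accessors
#' @export
setMethod("nRegions", "CohortBundle", function(x) ncol(x@gmv))
#' @rdname accessors
#' @export
setMethod("corMatrix", "CovarianceNetwork", function(x) x@correlation)
#' @rdname accessors
#' @export
setMethod("nSubjects", "CovarianceNetwork", function(x) x@nSubjects)
#' @rdname accessors
#' @export
setMethod("zMatrix", "IDSCN", function(x) x@z)
#' @rdname accessors
#' @export
setMethod("pMatrix", "IDSCN", function(x) x@p)
#' @rdname accessors
#' @export
setMethod("sigMask", "IDSCN", function(x) x@mask)
#' @rdname accessors
#' @export
setMethod("patientId", "IDSCN", function(x) x@patientId)
#' @rdname accessors
#' @export
setMethod("prevalenceCounts", "EdgePrevalence", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("featureEdges", "FeatureMatrix", function(x) x@edges)
#' @rdname accessors
#' @export
setMethod("featureZ", "FeatureMatrix", function(x) x@z)
#' @rdname accessors
#' @export
setMethod("chosenK", "ClusteringResult", function(x) x@k)
#' @rdname accessors
#' @export
setMethod("subtypeLabels", "ClusteringResult", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("silhouetteByK", "ClusteringResult", function(x) x@silhouettes)

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig ('%s'): %d patients / %d controls, %d regions, %d sites\n",
              object@scenario, object@nPatients, object@nControls,
              object@nRegions, object@nSites))
  cat(sprintf("  subtypes: %s; planted edges: %d; GMV-effect regions: %d; gamma = %g; seed = %d\n",
              paste(object@subtypeSizes, collapse = "/"),
              length(object@plantedEdges), length(object@gmvEffectRegions),
              object@anxietyCoupling, object@rngSeed))
})

setMethod("show", "CohortBundle", function(object) {
  s <- object@subjects
  cat(sprintf("CohortBundle: %d subjects (%d patients, %d controls) x %d regions, %d site(s)\n",
              nrow(s), sum(s$group == "patient"), sum(s$group == "control"),
              ncol(object@gmv), length(unique(s$site))))
})

setMethod("show", "CovarianceNetwork", function(object) {
  off <- object@correlation[upper.tri(object@correlation)]
  cat(sprintf("CovarianceNetwork: %d regions, n = %d subjects, mean |r| = %.3f\n",
              nrow(object@correlation), object@nSubjects, mean(abs(off))))
})

setMethod("show", "IDSCN", function(object) {
  cat(sprintf("IDSCN for patient '%s': %d regions, %d significant edge(s) (Bonferroni %g over %d edges)\n",
              object@patientId, nrow(object@z),
              sum(object@mask[upper.tri(object@mask)]), object@alpha,
              object@familySize))
})

setMethod("show", "EdgePrevalence", function(object) {
  cnt <- object@counts[upper.tri(object@counts)]
  cat(sprintf("EdgePrevalence over %d patients: %d edge(s) hit at least once, max prevalence %d\n",
              object@nPatients, sum(cnt > 0), if (length(cnt)) max(cnt) else 0L))
})

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d patients x %d edges (prevalence %s)\n",
              nrow(object@z), ncol(object@z),
              paste(range(object@edges$count), collapse = "-")))
})

setMethod("show", "ClusteringResult", function(object) {
  sz <- tabulate(object@labels, nbins = object@k)
  cat(sprintf("ClusteringResult: k = %d (mean silhouette %.3f), sizes %s\n",
              object@k, object@silhouettes[as.character(object@k)],
              paste(sz, collapse = "/")))
})
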