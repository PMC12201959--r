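#' @import methods
#' @importFrom stats cor pnorm pt qnorm rnorm runif rbinom sd kmeans
#'   chisq.test t.test cor.test dist complete.cases
#' @importFrom utils head
NULL

#' Simulation configuration for synthetic morphometric cohorts
#'
#' Parameter bundle consumed by [generateCohort()]. The defaults of the
#' `"paper_like"` scenario (see [defaultConfig()]) emulate a two-subtype
#' patient cohort of 164 patients and 164 controls over a 166-region
#' grey-matter-volume atlas, with inter-regional covariance induced by a
#' latent-factor model, additive site/age/sex/education effects, planted
#' per-patient edge co-deviations, regional volume deficits in one subtype,
#' and anxiety scores coupled to the planted deviations.
#'
#' @slot nPatients,nControls,nRegions,nSites,nLatentFactors integer scalars.
#' @slot baselineNoiseSd independent per-region noise SD of the unit-scale
#'   latent model (the model is built at unit total variance and then scaled
#'   per region).
#' @slot covariateEffectScale SD at which per-region age/sex/education/site
#'   coefficients are drawn (age and education per 10 years).
#' @slot plantedEdges list of plant specifications as produced by
#'   [plantSpec()]: each has `edge` (region pair, i < j), `carriers` (count
#'   per subtype), `delta` (co-deviation magnitude in residual SDs) and
#'   `sign` (+1 same-direction, -1 opposite).
#' @slot subtypeSizes integer vector of ground-truth subtype sizes summing to
#'   `nPatients`.
#' @slot anxietyCoupling coupling gamma between a patient's mean planted-edge
#'   deviation signal and the HAMA-14 anxiety total.
#' @slot gmvEffectRegions region indices receiving a subtype-1 volume deficit.
#' @slot gmvEffectSize deficit magnitude in units of region residual SD.
#' @slot rngSeed integer seed; the whole cohort is deterministic given the
#'   config.
#' @slot scenario the scenario name the config was built from ("custom" for
#'   hand-built configs).
#'
#' @seealso [defaultConfig()], [generateCohort()]
#' @export
setClass("SimulationConfig", representation(
  nPatients = "integer",
  nControls = "integer",
  nRegions = "integer",
  nSites = "integer",
  nLatentFactors = "integer",
  baselineNoiseSd = "numeric",
  covariateEffectScale = "numeric",
  plantedEdges = "list",
  subtypeSizes = "integer",
  anxietyCoupling = "numeric",
  gmvEffectRegions = "integer",
  gmvEffectSize = "numeric",
  rngSeed = "integer",
  scenario = "character"
))

setValidity("SimulationConfig", function(object) {
  msgs <- character()
  if (object@nRegions < 3L)
    msgs <- c(msgs, "nRegions must be >= 3")
  if (any(object@subtypeSizes <= 0L))
    msgs <- c(msgs, "subtypeSizes must be strictly positive")
  if (sum(object@subtypeSizes) != object@nPatients)
    msgs <- c(msgs, sprintf("sum(subtypeSizes) (%d) must equal nPatients (%d)",
                            sum(object@subtypeSizes), object@nPatients))
  if (object@baselineNoiseSd <= 0)
    msgs <- c(msgs, "baselineNoiseSd must be positive")
  nsub <- length(object@subtypeSizes)
  for (pe in object@plantedEdges) {
    e <- pe$edge
    if (e[1L] >= e[2L])
      msgs <- c(msgs, sprintf("planted edge (%d, %d): first index must be < second", e[1L], e[2L]))
    if (e[2L] > object@nRegions)
      msgs <- c(msgs, sprintf("planted edge (%d, %d) exceeds nRegions = %d", e[1L], e[2L], object@nRegions))
    if (length(pe$carriers) != nsub)
      msgs <- c(msgs, "plant carriers must give one count per subtype")
    else if (any(pe$carriers > object@subtypeSizes))
      msgs <- c(msgs, sprintf("planted edge (%d, %d): carriers exceed a subtype size", e[1L], e[2L]))
    if (any(pe$delta <= 0) || !length(pe$delta) %in% 1:2)
      msgs <- c(msgs, "plant delta must be a positive scalar or range")
    if (!pe$sign %in% c(-1, 1))
      msgs <- c(msgs, "plant sign must be +1 or -1")
  }
  plantRegions <- unlist(lapply(object@plantedEdges, `[[`, "edge"))
  if (anyDuplicated(plantRegions))
    msgs <- c(msgs, sprintf("region(s) %s appear in more than one plant",
                            paste(unique(plantRegions[duplicated(plantRegions)]),
                                  collapse = ", ")))
  if (any(object@gmvEffectRegions > object@nRegions))
    msgs <- c(msgs, "gmvEffectRegions exceed nRegions")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Cohort container: subject table, GMV matrix and region atlas
#'
#' The unit every pipeline stage consumes. Rows of the GMV matrix align 1:1
#' with the subject table; columns align with the atlas.
#'
#' @slot subjects data.frame with columns `subject_id`, `group`
#'   ("patient"/"control"), `site`, `age`, `sex` (0/1), `education`,
#'   `hamd17`, `hama14` (clinical scores may be NA for controls).
#' @slot gmv numeric matrix, subjects x regions, strictly positive, row names
#'   = subject ids.
#' @slot atlas data.frame with columns `region_index` (1-based) and
#'   `region_name`.
#'
#' @seealso [cohortBundle()], [readCohort()], [generateCohort()]
#' @export
setClass("CohortBundle", representation(
  subjects = "data.frame",
  gmv = "matrix",
  atlas = "data.frame"
))

setValidity("CohortBundle", function(object) {
  s <- object@subjects; g <- object@gmv; a <- object@atlas
  msgs <- character()
  need <- c("subject_id", "group", "site", "age", "sex", "education")
  miss <- setdiff(need, names(s))
  if (length(miss))
    return(sprintf("subject table lacks column(s): %s", paste(miss, collapse = ", ")))
  if (nrow(g) != nrow(s))
    msgs <- c(msgs, sprintf("GMV rows (%d) do not match subject rows (%d)", nrow(g), nrow(s)))
  if (!is.null(rownames(g)) && !identical(rownames(g), as.character(s$subject_id)))
    msgs <- c(msgs, "GMV row names do not align with subject ids")
  if (ncol(g) != nrow(a))
    msgs <- c(msgs, sprintf("GMV has %d regions but atlas has %d", ncol(g), nrow(a)))
  if (!all(s$group %in% c("patient", "control")))
    msgs <- c(msgs, "group must be 'patient' or 'control'")
  for (v in c("site", "age", "sex", "education"))
    if (anyNA(s[[v]]))
      msgs <- c(msgs, sprintf("missing values in covariate '%s'", v))
  if (anyNA(g) || !all(is.finite(g)))
    msgs <- c(msgs, "GMV matrix contains missing or non-finite values")
  else if (any(g <= 0))
    msgs <- c(msgs, "GMV values must be strictly positive")
  ctrl <- s$group == "control"
  if (sum(ctrl) >= 2L) {
    v <- apply(g[ctrl, , drop = FALSE], 2L, stats::var)
    if (any(v <= 0))
      msgs <- c(msgs, sprintf("region(s) with zero variance among controls: %s",
                              paste(which(v <= 0), collapse = ", ")))
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Covariate-adjusted structural covariance network
#'
#' Symmetric region x region matrix of Pearson correlations between
#' covariate-residualized regional volumes, with the sample size it was
#' computed from.
#'
#' @slot correlation symmetric numeric matrix, unit diagonal.
#' @slot nSubjects number of subjects the correlations were computed from.
#'
#' @seealso [covarianceNetwork()], [perturbedNetwork()]
#' @export
setClass("CovarianceNetwork", representation(
  correlation = "matrix",
  nSubjects = "integer"
))

setValidity("CovarianceNetwork", function(object) {
  m <- object@correlation
  msgs <- character()
  if (nrow(m) != ncol(m)) msgs <- c(msgs, "correlation matrix must be square")
  else {
    if (max(abs(m - t(m))) > 1e-8) msgs <- c(msgs, "correlation matrix must be symmetric")
    if (any(abs(diag(m) - 1) > 1e-12)) msgs <- c(msgs, "diagonal must be exactly 1")
    off <- m[upper.tri(m)]
    if (length(off) && (min(off) < -1 - 1e-12 || max(off) > 1 + 1e-12))
      msgs <- c(msgs, "off-diagonal entries must lie in [-1, 1]")
  }
  if (object@nSubjects < 3L) msgs <- c(msgs, "nSubjects must be >= 3")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' One patient's individualized differential SCN
#'
#' Z-scored deviation of the perturbed network (controls + this patient) from
#' the reference control network, with two-tailed p-values and the
#' Bonferroni-significant edge mask.
#'
#' @slot patientId subject id.
#' @slot z symmetric Z matrix, zero diagonal.
#' @slot p two-tailed p-value matrix (diagonal 1).
#' @slot mask logical matrix: edge significant after Bonferroni correction.
#' @slot familySize number of unique edges used for the correction.
#' @slot alpha corrected significance level.
#'
#' @seealso [buildAllIDSCN()], [idscnZ()], [edgeSignificance()]
#' @export
setClass("IDSCN", representation(
  patientId = "character",
  z = "matrix",
  p = "matrix",
  mask = "matrix",
  familySize = "integer",
  alpha = "numeric"
))

setValidity("IDSCN", function(object) {
  msgs <- character()
  z <- object@z
  if (max(abs(z - t(z))) > 1e-8) msgs <- c(msgs, "Z matrix must be symmetric")
  if (any(diag(z) != 0)) msgs <- c(msgs, "Z diagonal must be zero")
  if (!identical(dim(z), dim(object@p)) || !identical(dim(z), dim(object@mask)))
    msgs <- c(msgs, "z, p and mask must share dimensions")
  if (object@alpha <= 0 || object@alpha >= 1) msgs <- c(msgs, "alpha must be in (0,1)")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Per-edge patient prevalence of significant deviation
#'
#' Counts, for every region pair, the number of patients whose IDSCN marks
#' that edge significant.
#'
#' @slot counts symmetric integer matrix of per-edge patient counts.
#' @slot nPatients number of patients counted over.
#'
#' @seealso [edgePrevalence()], [selectFeatureEdges()]
#' @export
setClass("EdgePrevalence", representation(
  counts = "matrix",
  nPatients = "integer"
))

setValidity("EdgePrevalence", function(object) {
  cnt <- object@counts[upper.tri(object@counts)]
  if (length(cnt) && (min(cnt) < 0 || max(cnt) > object@nPatients))
    "counts must lie in [0, nPatients]" else TRUE
})

#' Patients x selected-edges feature matrix of IDSCN Z-scores
#'
#' @slot z numeric matrix, patients x edges; row names are patient ids,
#'   column names "i-j" (1-based region indices).
#' @slot edges data.frame with columns `i`, `j`, `count` in feature-column
#'   order (descending prevalence, ties by canonical edge order).
#'
#' @seealso [featureMatrix()], [clusterSubtypes()]
#' @export
setClass("FeatureMatrix", representation(
  z = "matrix",
  edges = "data.frame"
))

setValidity("FeatureMatrix", function(object) {
  msgs <- character()
  if (ncol(object@z) != nrow(object@edges))
    msgs <- c(msgs, "feature columns must match edge table rows")
  if (anyNA(object@z)) msgs <- c(msgs, "feature matrix must have no missing entries")
  if (nrow(object@edges) >= 2L) {
    cnt <- object@edges$count
    if (is.unsorted(rev(cnt))) msgs <- c(msgs, "edges must be in descending prevalence order")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' K-means subtyping result with silhouette model selection
#'
#' @slot k chosen number of clusters (argmax of best-restart mean silhouette).
#' @slot labels integer subtype per patient, named by patient id; subtype 1
#'   is the largest cluster.
#' @slot silhouettes named numeric: best-restart mean silhouette per k on the
#'   grid.
#' @slot seed RNG seed used.
#'
#' @seealso [clusterSubtypes()]
#' @export
setClass("ClusteringResult", representation(
  k = "integer",
  labels = "integer",
  silhouettes = "numeric",
  seed = "integer"
))

setValidity("ClusteringResult", function(object) {
  msgs <- character()
  if (any(object@labels < 1L) || any(object@labels > object@k))
    msgs <- c(msgs, "labels must lie in 1..k")
  best <- object@silhouettes[as.character(object@k)]
  if (is.na(best) || any(object@silhouettes > best + 1e-12))
    msgs <- c(msgs, "chosen k must maximize mean silhouette over the grid")
  if (any(object@silhouettes < -1 - 1e-12 | object@silhouettes > 1 + 1e-12))
    msgs <- c(msgs, "silhouette values must lie in [-1, 1]")
  sz <- tabulate(object@labels, nbins = object@k)
  if (is.unsorted(rev(sz)))
    msgs <- c(msgs, "cluster sizes must be non-increasing in label order")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})
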