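#' Write a cohort to the standard file layout
#'
#' Writes `subjects.tsv`, `gmv.tsv` (subject_id + one column per region,
#' named by atlas region), `atlas.tsv` and, when ground truth is supplied,
#' `truth.json`. All tables are UTF-8 TSV with a header row; region indices
#' in files are 1-based.
#'
#' @param cohort a [CohortBundle-class].
#' @param dir output directory (created if needed).
#' @param truth optional ground-truth list from [generateCohort()].
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- subjectTable(cohort); a <- atlasTable(cohort)
  data.table::fwrite(s, file.path(dir, "subjects.tsv"), sep = "\t")
  g <- data.table::as.data.table(gmvMatrix(cohort))
  data.table::setnames(g, a$region_name)
  g <- cbind(data.table::data.table(subject_id = s$subject_id), g)
  data.table::fwrite(g, file.path(dir, "gmv.tsv"), sep = "\t")
  data.table::fwrite(a, file.path(dir, "atlas.tsv"), sep = "\t")
  if (!is.null(truth))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort from the standard file layout
#'
#' Validates presence of the three files, subject/GMV alignment, numeric
#' volumes and covariate completeness, and returns a validated bundle.
#'
#' @param dir directory containing `subjects.tsv`, `gmv.tsv`, `atlas.tsv`.
#' @return a [CohortBundle-class].
#' @export
readCohort <- function(dir) {
  for (f in c("subjects.tsv", "gmv.tsv", "atlas.tsv"))
    if (!file.exists(file.path(dir, f)))
      stop("missing cohort file: ", f)
  s <- as.data.frame(data.table::fread(file.path(dir, "subjects.tsv"),
                                       sep = "\t"))
  g <- as.data.frame(data.table::fread(file.path(dir, "gmv.tsv"), sep = "\t"))
  a <- as.data.frame(data.table::fread(file.path(dir, "atlas.tsv"), sep = "\t"))
  if (!"subject_id" %in% names(g))
    stop("gmv.tsv lacks a subject_id column")
  if (!identical(as.character(g$subject_id), as.character(s$subject_id)))
    stop("subject ids in gmv.tsv do not align with subjects.tsv")
  gm <- as.matrix(g[, setdiff(names(g), "subject_id"), drop = FALSE])
  if (!is.numeric(gm)) stop("non-numeric GMV values in gmv.tsv")
  colnames(gm) <- NULL
  for (v in c("age", "sex", "education")) s[[v]] <- as.numeric(s[[v]])
  for (v in c("hamd17", "hama14"))
    if (v %in% names(s)) s[[v]] <- as.integer(s[[v]])
  cohortBundle(s, gm, a)
}

#' Pipeline parameter registry
#'
#' @param alphaEdge corrected per-edge significance level for the IDSCN masks
#'   (default 0.001).
#' @param bonferroniFamily edge family size; NULL derives `choose(R, 2)` from
#'   the atlas.
#' @param prevalenceFraction minimum fraction of patients for feature edges
#'   (default 0.05).
#' @param kMin,kMax,nRestarts clustering grid and restarts (defaults 2, 10,
#'   100).
#' @param subtypeAlpha corrected level for the subtype comparisons (default
#'   0.05).
#' @param rngSeed seed for the clustering restarts.
#' @return a validated list of class `idscnPipelineConfig`.
#' @export
pipelineConfig <- function(alphaEdge = 0.001, bonferroniFamily = NULL,
                           prevalenceFraction = 0.05, kMin = 2L, kMax = 10L,
                           nRestarts = 100L, subtypeAlpha = 0.05,
                           rngSeed = 1L) {
  stopifnot(alphaEdge > 0, alphaEdge < 1, subtypeAlpha > 0, subtypeAlpha < 1,
            prevalenceFraction > 0, prevalenceFraction < 1, kMin >= 2L,
            kMax >= kMin, nRestarts >= 1L)
  structure(list(alphaEdge = alphaEdge, bonferroniFamily = bonferroniFamily,
                 prevalenceFraction = prevalenceFraction,
                 kMin = as.integer(kMin), kMax = as.integer(kMax),
                 nRestarts = as.integer(nRestarts),
                 subtypeAlpha = subtypeAlpha, rngSeed = as.integer(rngSeed)),
            class = "idscnPipelineConfig")
}

stageLog <- function(verbose, stage, t0) {
  if (verbose)
    message(sprintf("[idscn] %-12s %6.1f s", stage,
                    as.numeric(proc.time()[3L]) - t0))
}

#' Run the full subtyping pipeline
#'
#' simulate/read -> IDSCN construction -> prevalent-edge selection ->
#' k-means subtyping -> subtype characterization. With `outDir` set, writes
#' `features.tsv`, `labels.tsv`, `clustering.json`, `idscn_edges.tsv`
#' (significant edges per patient; `allEdges = TRUE` writes every edge),
#' `edge_comparison.tsv`, `gmv_comparison.tsv`, `clinical_correlations.tsv`,
#' `demographics.tsv`, a consolidated `report.json`, a `manifest.json`
#' (config, seeds, file digests, timestamp) and the Z-matrix store
#' `zstore.rds`. `report.json` is deterministic given cohort and config;
#' volatile fields (timestamps, wall times) live only in the manifest.
#'
#' @param cohort a [CohortBundle-class] or a directory for [readCohort()].
#' @param config a [pipelineConfig()] list.
#' @param outDir optional output directory.
#' @param allEdges write all edges (not only significant ones) to
#'   `idscn_edges.tsv`.
#' @param verbose log stage timings.
#' @return invisibly, a list: `report`, `idscns`, `features`, `clustering`,
#'   `edgeComparison`, `gmvComparison`, `clinicalCorrelations`,
#'   `demographics`.
#' @export
runPipeline <- function(cohort, config = pipelineConfig(), outDir = NULL,
                        allEdges = FALSE, verbose = TRUE) {
  t0 <- as.numeric(proc.time()[3L])
  if (is.character(cohort)) cohort <- readCohort(cohort)
  validObject(cohort)
  s <- subjectTable(cohort)
  pat <- s$group == "patient"
  R <- nRegions(cohort)
  family <- if (is.null(config$bonferroniFamily)) choose(R, 2)
            else config$bonferroniFamily
  stageLog(verbose, "load", t0)

  idscns <- withCallingHandlers(
    buildAllIDSCN(cohort, alpha = config$alphaEdge, familySize = family),
    error = function(e) stop("stage 'build' failed: ", conditionMessage(e),
                             call. = FALSE))
  stageLog(verbose, "build", t0)

  thr <- prevalenceThreshold(sum(pat), config$prevalenceFraction)
  prev <- edgePrevalence(idscns)
  edges <- tryCatch(selectFeatureEdges(prev, thr),
                    error = function(e) stop("stage 'subtype' failed: ",
                                             conditionMessage(e), call. = FALSE))
  feats <- featureMatrix(idscns, edges)
  clus <- clusterSubtypes(feats, kMin = config$kMin, kMax = config$kMax,
                          nRestarts = config$nRestarts, seed = config$rngSeed)
  labels <- subtypeLabels(clus)
  stageLog(verbose, "subtype", t0)

  patSub <- s[pat, , drop = FALSE]
  covs <- patSub[, c("age", "sex", "education", "site")]
  edgeCmp <- compareEdges(feats, labels, covs, alpha = config$subtypeAlpha)
  gmvCmp <- compareGMV(gmvMatrix(cohort)[pat, , drop = FALSE], labels, covs,
                       atlasTable(cohort), alpha = config$subtypeAlpha)
  corrs <- edgeClinicalCorrelation(feats, patSub[, c("hamd17", "hama14")])
  demo <- demographics(patSub, labels)
  stageLog(verbose, "characterize", t0)

  report <- list(
    notes = paste("GMV comparison is a region-level covariate-adjusted test",
                  "with Bonferroni correction, not a voxel-wise cluster",
                  "inference."),
    n_regions = R,
    edge_family_size = family,
    n_patients = sum(pat), n_controls = sum(!pat),
    prevalence_threshold = thr,
    n_selected_edges = nrow(edges),
    selected_edges = edges,
    chosen_k = chosenK(clus),
    silhouette_by_k = as.list(silhouetteByK(clus)),
    subtype_sizes = as.list(table(labels)),
    n_significant_edge_differences = sum(edgeCmp$significant),
    significant_gmv_regions = gmvCmp$region_index[gmvCmp$significant],
    edge_comparison = edgeCmp,
    clinical_correlations = corrs,
    demographics = demo)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    fz <- data.table::data.table(subject_id = rownames(featureZ(feats)),
                                 featureZ(feats))
    data.table::fwrite(fz, file.path(outDir, "features.tsv"), sep = "\t")
    data.table::fwrite(
      data.table::data.table(subject_id = names(labels), subtype = labels),
      file.path(outDir, "labels.tsv"), sep = "\t")
    jsonlite::write_json(
      list(chosen_k = chosenK(clus),
           silhouette_by_k = as.list(silhouetteByK(clus)),
           seed = config$rngSeed),
      file.path(outDir, "clustering.json"), auto_unbox = TRUE, digits = NA)
    et <- data.table::rbindlist(lapply(idscns, function(x) {
      m <- if (allEdges) upper.tri(sigMask(x)) else
        sigMask(x) & upper.tri(sigMask(x))
      idx <- which(m, arr.ind = TRUE)
      data.table::data.table(
        patient_id = patientId(x), region_i = idx[, 1L], region_j = idx[, 2L],
        z = zMatrix(x)[idx], p_raw = pMatrix(x)[idx],
        p_bonferroni = pmin(1, pMatrix(x)[idx] * x@familySize),
        significant = sigMask(x)[idx])
    }))
    data.table::fwrite(et, file.path(outDir, "idscn_edges.tsv"), sep = "\t")
    saveRDS(lapply(idscns, zMatrix), file.path(outDir, "zstore.rds"))
    data.table::fwrite(edgeCmp, file.path(outDir, "edge_comparison.tsv"),
                       sep = "\t")
    data.table::fwrite(gmvCmp, file.path(outDir, "gmv_comparison.tsv"),
                       sep = "\t")
    data.table::fwrite(corrs, file.path(outDir, "clinical_correlations.tsv"),
                       sep = "\t")
    data.table::fwrite(demo, file.path(outDir, "demographics.tsv"),
                       sep = "\t")
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    manifest <- list(
      package_version = as.character(utils::packageVersion("idscn")),
      config = unclass(config), timestamp = format(Sys.time(), tz = "UTC"),
      wall_seconds = as.numeric(proc.time()[3L]) - t0)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  stageLog(verbose, "write", t0)

  invisible(list(report = report, idscns = idscns, features = feats,
                 clustering = clus, edgeComparison = edgeCmp,
                 gmvComparison = gmvCmp, clinicalCorrelations = corrs,
                 demographics = demo))
}
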