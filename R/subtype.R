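#' Patient-count threshold for edge prevalence
#'
#' Rounds `fraction * nPatients` half away from zero, with a floor of 1
#' patient. 5 percent of 164 patients gives 8.
#'
#' @param nPatients number of patients.
#' @param fraction prevalence fraction in (0, 1).
#' @return integer patient count.
#' @examples
#' prevalenceThreshold(164, 0.05)  # 8
#' @export
prevalenceThreshold <- function(nPatients, fraction = 0.05) {
  stopifnot(fraction > 0, fraction < 1, nPatients >= 1)
  max(1L, as.integer(floor(nPatients * fraction + 0.5)))
}

#' Count, per edge, the patients with a significant deviation
#'
#' @param idscns list of [IDSCN-class] (equal shapes).
#' @return an [EdgePrevalence-class].
#' @export
edgePrevalence <- function(idscns) {
  stopifnot(length(idscns) >= 1L)
  d <- dim(sigMask(idscns[[1L]]))
  for (x in idscns)
    if (!identical(dim(sigMask(x)), d))
      stop("IDSCN masks differ in shape")
  counts <- Reduce(`+`, lapply(idscns, function(x) sigMask(x) * 1L))
  storage.mode(counts) <- "integer"
  new("EdgePrevalence", counts = counts, nPatients = length(idscns))
}

#' Select prevalent edges as clustering features
#'
#' Edges significant in at least `threshold` patients, sorted by descending
#' prevalence with ties broken by canonical edge order (ascending `i`, then
#' `j`).
#'
#' @param prev an [EdgePrevalence-class].
#' @param threshold minimum patient count (see [prevalenceThreshold()]).
#' @return data.frame with columns `i`, `j` (1-based region indices, i < j)
#'   and `count`.
#' @export
selectFeatureEdges <- function(prev, threshold) {
  stopifnot(threshold >= 1)
  cnt <- prevalenceCounts(prev)
  ut <- which(upper.tri(cnt), arr.ind = TRUE)
  keep <- cnt[ut] >= threshold
  if (!any(keep))
    stop("no edge reaches the prevalence threshold (", threshold,
         " patients); review the threshold or the significance level")
  df <- data.frame(i = ut[keep, 1L], j = ut[keep, 2L],
                   count = cnt[ut][keep])
  df <- df[order(-df$count, df$i, df$j), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Assemble the patients x selected-edges Z feature matrix
#'
#' Entries are the raw IDSCN Z-scores (no per-column re-standardization: the
#' Z transform already places all edges on a common scale). Rows follow the
#' order of `idscns`.
#'
#' @param idscns list of [IDSCN-class].
#' @param edges edge table from [selectFeatureEdges()].
#' @return a [FeatureMatrix-class].
#' @export
featureMatrix <- function(idscns, edges) {
  stopifnot(nrow(edges) >= 1L)
  z <- vapply(idscns, function(x) zMatrix(x)[cbind(edges$i, edges$j)],
              numeric(nrow(edges)))
  z <- if (nrow(edges) == 1L) matrix(z, ncol = 1L) else t(z)
  rownames(z) <- vapply(idscns, patientId, character(1L))
  colnames(z) <- sprintf("%d-%d", edges$i, edges$j)
  new("FeatureMatrix", z = z, edges = as.data.frame(edges))
}

#' Mean silhouette width of a partition
#'
#' Euclidean (or any supplied) distances; singleton clusters score 0, as do
#' points with zero separation and cohesion.
#'
#' @param dmat symmetric distance matrix.
#' @param labels integer cluster labels.
#' @return mean silhouette over points, in \[-1, 1\].
#' @export
meanSilhouette <- function(dmat, labels) {
  dmat <- as.matrix(dmat)
  n <- length(labels)
  stopifnot(nrow(dmat) == n)
  labs <- sort(unique(labels))
  if (length(labs) < 2L) stop("silhouette needs at least two clusters")
  sizes <- vapply(labs, function(l) sum(labels == l), integer(1L))
  S <- vapply(labs, function(l) rowSums(dmat[, labels == l, drop = FALSE]),
              numeric(n))
  own <- match(labels, labs)
  a <- S[cbind(seq_len(n), own)] / pmax(sizes[own] - 1L, 1L)
  B <- sweep(S, 2L, sizes, "/")
  B[cbind(seq_len(n), own)] <- Inf
  b <- apply(B, 1L, min)
  s <- ifelse(sizes[own] == 1L, 0, (b - a) / pmax(a, b))
  s[!is.finite(s)] <- 0
  mean(s)
}

#' K-means subtyping with restart-and-silhouette model selection
#'
#' For every k on the grid, runs `nRestarts` k-means clusterings (Euclidean,
#' initial centers drawn uniformly from the data points, run to convergence)
#' and keeps the restart with the largest mean silhouette (ties by smaller
#' within-cluster sum of squares). The chosen k maximizes that best-restart
#' mean silhouette over the grid (ties to the smaller k). Labels are
#' renumbered so cluster sizes are non-increasing: subtype 1 is the largest
#' cluster.
#'
#' @param x a [FeatureMatrix-class] or plain numeric matrix (rows =
#'   patients).
#' @param kMin,kMax cluster-number grid (defaults 2 and 10).
#' @param nRestarts random restarts per k (default 100).
#' @param seed RNG seed; results are deterministic given `(x, seed)`.
#' @return a [ClusteringResult-class].
#' @export
clusterSubtypes <- function(x, kMin = 2L, kMax = 10L, nRestarts = 100L,
                            seed = 1L) {
  X <- if (is(x, "FeatureMatrix")) featureZ(x) else as.matrix(x)
  n <- nrow(X)
  stopifnot(kMin >= 2L, kMax >= kMin, kMax < n, nRestarts >= 1L)
  if (nrow(unique(X)) == 1L)
    stop("all feature rows are identical; silhouette is undefined")
  dmat <- as.matrix(dist(X))
  set.seed(as.integer(seed))
  grid <- seq.int(kMin, kMax)
  silByK <- rep(NA_real_, length(grid))
  labsByK <- vector("list", length(grid))
  for (gi in seq_along(grid)) {
    k <- grid[gi]
    bestSil <- -Inf; bestWss <- Inf; bestLab <- NULL
    for (r in seq_len(nRestarts)) {
      km <- NULL
      for (attempt in seq_len(50L)) {
        ctr <- X[sample.int(n, k), , drop = FALSE]
        if (anyDuplicated(ctr)) next
        km <- tryCatch(
          suppressWarnings(stats::kmeans(X, centers = ctr, iter.max = 200L)),
          error = function(e) NULL)
        if (!is.null(km) && all(km$size > 0L)) break
        km <- NULL
      }
      if (is.null(km))
        stop("k-means failed to produce ", k,
             " non-empty clusters after repeated redraws")
      sil <- meanSilhouette(dmat, km$cluster)
      if (sil > bestSil + 1e-12 ||
          (abs(sil - bestSil) <= 1e-12 && km$tot.withinss < bestWss)) {
        bestSil <- sil; bestWss <- km$tot.withinss; bestLab <- km$cluster
      }
    }
    silByK[gi] <- bestSil
    labsByK[[gi]] <- bestLab
  }
  best <- which(silByK >= max(silByK) - 1e-12)[1L]
  k <- grid[best]
  lab <- labsByK[[best]]
  sizes <- tabulate(lab, nbins = k)
  map <- integer(k)
  map[order(-sizes, seq_len(k))] <- seq_len(k)
  lab <- map[lab]
  names(lab) <- rownames(X)
  names(silByK) <- as.character(grid)
  new("ClusteringResult", k = as.integer(k), labels = as.integer(lab) |>
        stats::setNames(rownames(X)),
      silhouettes = silByK, seed = as.integer(seed))
}
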