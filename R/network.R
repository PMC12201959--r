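#' Build the covariate design matrix
#'
#' Intercept + age + sex + education + one-hot site with the first site level
#' as the reference. A single-site cohort yields no site columns. Constant
#' age, sex or education is rejected by name, as is any other rank
#' deficiency.
#'
#' @param subjects data.frame with `age`, `sex`, `education`, `site` columns
#'   (extra columns ignored).
#' @return numeric design matrix with one row per subject.
#' @examples
#' s <- data.frame(age = c(20, 30, 40, 50, 25, 35),
#'                 sex = c(0, 1, 0, 1, 0, 1),
#'                 education = c(9, 12, 16, 10, 13, 15),
#'                 site = rep(c("a", "b"), 3))
#' colnames(buildDesign(s))
#' @export
buildDesign <- function(subjects) {
  need <- c("age", "sex", "education", "site")
  miss <- setdiff(need, names(subjects))
  if (length(miss))
    stop("subject table lacks covariate column(s): ", paste(miss, collapse = ", "))
  for (v in need)
    if (anyNA(subjects[[v]]))
      stop("missing values in covariate '", v, "'")
  for (v in c("age", "sex", "education"))
    if (length(unique(subjects[[v]])) < 2L)
      stop("covariate '", v, "' is constant; design would be rank deficient")
  X <- cbind("(Intercept)" = 1,
             age = as.numeric(subjects$age),
             sex = as.numeric(subjects$sex),
             education = as.numeric(subjects$education))
  site <- factor(subjects$site)
  if (nlevels(site) > 1L) {
    D <- stats::model.matrix(~site)[, -1L, drop = FALSE]
    colnames(D) <- paste0("site", levels(site)[-1L])
    X <- cbind(X, D)
  }
  if (nrow(X) < ncol(X) + 2L)
    stop(sprintf("need at least %d subjects for a %d-column design",
                 ncol(X) + 2L, ncol(X)))
  if (qr(X)$rank < ncol(X))
    stop("covariate design is rank deficient")
  X
}

#' Covariate-adjusted structural covariance network
#'
#' Residualizes every region against the design by least squares, then takes
#' Pearson correlations of the residuals for every region pair.
#'
#' @param gmv subjects x regions numeric matrix.
#' @param design design matrix from [buildDesign()] (rows aligned with
#'   `gmv`).
#' @return a [CovarianceNetwork-class] with `nSubjects = nrow(gmv)`.
#' @export
covarianceNetwork <- function(gmv, design) {
  gmv <- as.matrix(gmv)
  if (nrow(gmv) != nrow(design))
    stop("GMV rows and design rows do not align")
  res <- qr.resid(qr(design), gmv)
  v <- colSums(res^2)
  bad <- which(v <= 1e-12 * nrow(res))
  if (length(bad))
    stop("zero residual variance in region(s): ", paste(bad, collapse = ", "))
  C <- stats::cor(res)
  C <- (C + t(C)) / 2
  diag(C) <- 1
  dimnames(C) <- NULL
  new("CovarianceNetwork", correlation = C, nSubjects = nrow(gmv))
}

#' Leave-one-in perturbed network
#'
#' Appends one patient to the control sample, rebuilds the covariate design
#' on the combined n+1 subjects, and recomputes the covariate-adjusted
#' correlation network.
#'
#' @param controlsGmv controls x regions matrix.
#' @param controlsSubjects control subject table.
#' @param patientGmv the patient's region vector.
#' @param patientSubject one-row subject table for the patient.
#' @return a [CovarianceNetwork-class] with `nSubjects = n controls + 1`.
#' @export
perturbedNetwork <- function(controlsGmv, controlsSubjects, patientGmv,
                             patientSubject) {
  if (!patientSubject$site[1L] %in% unique(controlsSubjects$site))
    stop("patient site '", patientSubject$site[1L],
         "' absent among controls; its site effect cannot be estimated")
  cols <- c("age", "sex", "education", "site")
  comb <- rbind(controlsSubjects[, cols, drop = FALSE],
                patientSubject[, cols, drop = FALSE])
  gmv <- rbind(as.matrix(controlsGmv), matrix(as.numeric(patientGmv), 1L))
  covarianceNetwork(gmv, buildDesign(comb))
}

#' Z-score the difference between perturbed and reference networks
#'
#' For each edge, `Z = (pSCN - rSCN) / ((1 - rSCN^2) / (n - 1))` where `n` is
#' the reference sample size. The diagonal is forced to zero.
#'
#' @param rscn reference [CovarianceNetwork-class] (controls only, n
#'   subjects).
#' @param pscn perturbed [CovarianceNetwork-class] (n + 1 subjects).
#' @return symmetric numeric Z matrix.
#' @examples
#' # hand check: r 0.5 -> 0.6 at n = 164 gives 0.1 / (0.75/163) = 21.73
#' @export
idscnZ <- function(rscn, pscn) {
  R0 <- corMatrix(rscn); R1 <- corMatrix(pscn)
  if (!identical(dim(R0), dim(R1)))
    stop("reference and perturbed networks differ in shape")
  n <- nSubjects(rscn)
  if (nSubjects(pscn) != n + 1L)
    stop("perturbed network must have exactly one more subject than the reference")
  off <- abs(R0) >= 1 - 1e-15
  diag(off) <- FALSE
  if (any(off)) {
    idx <- which(off, arr.ind = TRUE)
    idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
    stop(sprintf("reference correlation is +/-1 at edge(s): %s",
                 paste(sprintf("(%d,%d)", idx[, 1L], idx[, 2L]), collapse = ", ")))
  }
  Z <- (R1 - R0) / ((1 - R0^2) / (n - 1))
  diag(Z) <- 0
  Z
}

#' Two-tailed edge significance with Bonferroni correction
#'
#' @param z symmetric Z matrix.
#' @param familySize number of unique edges in the correction family
#'   (13,695 for a 166-region atlas).
#' @param alpha corrected significance level; an edge is significant iff
#'   `p * familySize < alpha`.
#' @return list with `p` (two-tailed standard-normal p matrix, diagonal 1)
#'   and `mask` (logical significance matrix, diagonal FALSE).
#' @export
edgeSignificance <- function(z, familySize, alpha = 0.001) {
  stopifnot(familySize >= 1L, alpha > 0, alpha < 1)
  p <- 2 * pnorm(-abs(z))
  diag(p) <- 1
  mask <- p * familySize < alpha
  diag(mask) <- FALSE
  list(p = p, mask = mask)
}

#' Build every patient's IDSCN against the control reference network
#'
#' The reference network is computed once from the controls; each patient is
#' then added in turn (leave-one-in), the network recomputed with the design
#' refit on the combined sample, and the deviation Z-scored and thresholded.
#'
#' @param cohort a [CohortBundle-class].
#' @param alpha corrected per-edge significance level (default 0.001).
#' @param familySize edge family for the Bonferroni correction; defaults to
#'   `choose(nRegions, 2)`.
#' @return named list of [IDSCN-class], in subject-table patient order.
#' @export
buildAllIDSCN <- function(cohort, alpha = 0.001, familySize = NULL) {
  s <- subjectTable(cohort); g <- gmvMatrix(cohort)
  pat <- which(s$group == "patient"); ctl <- which(s$group == "control")
  if (length(pat) < 1L) stop("cohort has no patients")
  R <- ncol(g)
  if (is.null(familySize)) familySize <- choose(R, 2)
  familySize <- as.integer(familySize)
  ctlSub <- s[ctl, , drop = FALSE]
  ctlGmv <- g[ctl, , drop = FALSE]
  design <- buildDesign(ctlSub)
  if (length(ctl) < ncol(design) + 3L)
    stop("too few controls for the covariate design")
  rscn <- covarianceNetwork(ctlGmv, design)
  out <- vector("list", length(pat))
  for (m in seq_along(pat)) {
    i <- pat[m]
    pscn <- perturbedNetwork(ctlGmv, ctlSub, g[i, ], s[i, , drop = FALSE])
    z <- idscnZ(rscn, pscn)
    sig <- edgeSignificance(z, familySize, alpha)
    out[[m]] <- new("IDSCN", patientId = as.character(s$subject_id[i]),
                    z = z, p = sig$p, mask = sig$mask,
                    familySize = familySize, alpha = alpha)
  }
  names(out) <- as.character(s$subject_id[pat])
  out
}
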