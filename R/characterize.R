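bonferroni <- function(p, family) pmin(1, p * family)

covariateColumns <- function(covariates) {
  if (is.null(covariates)) return(NULL)
  if (is.matrix(covariates)) return(covariates)
  if (is.data.frame(covariates)) {
    if (all(c("age", "sex", "education", "site") %in% names(covariates)))
      return(buildDesign(covariates)[, -1L, drop = FALSE])
    return(as.matrix(covariates))
  }
  stop("covariates must be NULL, a matrix, or a data.frame")
}

#' Covariate-adjusted two-group t-test
#'
#' Least-squares fit of the values on intercept + group indicator +
#' covariates; the reported t is the group coefficient over its standard
#' error, with a two-tailed p from the t distribution on the residual degrees
#' of freedom. With no covariates this reduces exactly to the classical
#' pooled-variance two-sample t statistic. The indicator codes the
#' first-sorted group label, so `t > 0` means that group is larger.
#'
#' @param values numeric outcome per subject.
#' @param labels group label per subject (exactly 2 groups, each >= 3
#'   members).
#' @param covariates NULL, a covariate matrix, or a subjects-style data.frame
#'   with `age`, `sex`, `education`, `site` (run through [buildDesign()]).
#' @return list with `t`, `p`, `df`, `estimate` (adjusted group-1 minus
#'   group-2 mean) and `direction` (label of the larger group).
#' @export
adjustedGroupT <- function(values, labels, covariates = NULL) {
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  if (length(groups) != 2L)
    stop("exactly two groups are required, got ", length(groups))
  if (any(table(labels) < 3L))
    stop("each group needs at least 3 members")
  g <- as.numeric(labels == groups[1L])
  X <- cbind("(Intercept)" = 1, group = g, covariateColumns(covariates))
  if (qr(X)$rank < ncol(X))
    stop("design including covariates is rank deficient")
  n <- length(values)
  fit <- stats::lm.fit(X, values)
  df <- n - ncol(X)
  if (df < 1L) stop("no residual degrees of freedom")
  sigma2 <- sum(fit$residuals^2) / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * XtXinv[2L, 2L])
  tval <- fit$coefficients["group"] / se
  p <- 2 * stats::pt(-abs(tval), df)
  list(t = unname(tval), p = unname(p), df = df,
       estimate = unname(fit$coefficients["group"]),
       direction = if (tval >= 0) groups[1L] else groups[2L])
}

#' Compare selected edges between subtypes
#'
#' Covariate-adjusted group t-test per selected edge, Bonferroni-corrected
#' over the selected-edge family.
#'
#' @param features a [FeatureMatrix-class] (rows = patients).
#' @param labels subtype label per patient (aligned with feature rows).
#' @param covariates as in [adjustedGroupT()].
#' @param alpha corrected significance level (default 0.05).
#' @return data.frame with one row per edge: `edge`, `i`, `j`, `t`, `p_raw`,
#'   `p_bonferroni`, `direction`, `significant`.
#' @export
compareEdges <- function(features, labels, covariates = NULL, alpha = 0.05) {
  Z <- featureZ(features); ed <- featureEdges(features)
  fam <- ncol(Z)
  res <- lapply(seq_len(fam), function(e) adjustedGroupT(Z[, e], labels, covariates))
  out <- data.frame(
    edge = colnames(Z),
    i = ed$i, j = ed$j,
    t = vapply(res, `[[`, numeric(1L), "t"),
    p_raw = vapply(res, `[[`, numeric(1L), "p"),
    direction = vapply(res, `[[`, character(1L), "direction"))
  out$p_bonferroni <- bonferroni(out$p_raw, fam)
  out$significant <- out$p_bonferroni < alpha
  out
}

#' Compare regional grey-matter volume between subtypes
#'
#' Region-level covariate-adjusted group t-tests with Bonferroni correction
#' over all atlas regions. This is a region-level test, not a voxel-wise
#' cluster inference.
#'
#' @param gmv patients x regions matrix (patient rows only).
#' @param labels subtype per patient.
#' @param covariates as in [adjustedGroupT()].
#' @param atlas region table (`region_index`, `region_name`).
#' @param alpha corrected significance level (default 0.05).
#' @return data.frame with one row per region: `region_index`,
#'   `region_name`, `t`, `p_raw`, `p_bonferroni`, `direction`,
#'   `significant`.
#' @export
compareGMV <- function(gmv, labels, covariates = NULL,
                       atlas = makeAtlas(ncol(gmv)), alpha = 0.05) {
  gmv <- as.matrix(gmv)
  fam <- ncol(gmv)
  res <- lapply(seq_len(fam), function(r) adjustedGroupT(gmv[, r], labels, covariates))
  out <- data.frame(
    region_index = atlas$region_index,
    region_name = atlas$region_name,
    t = vapply(res, `[[`, numeric(1L), "t"),
    p_raw = vapply(res, `[[`, numeric(1L), "p"),
    direction = vapply(res, `[[`, character(1L), "direction"))
  out$p_bonferroni <- bonferroni(out$p_raw, fam)
  out$significant <- out$p_bonferroni < alpha
  out
}

#' Pearson correlation between edge Z-scores and clinical scores
#'
#' @param features a [FeatureMatrix-class].
#' @param scores data.frame of numeric clinical scores (e.g. `hamd17`,
#'   `hama14`), rows aligned with feature rows; NAs dropped pairwise.
#' @return data.frame with one row per (edge, score) pair: `edge`, `score`,
#'   `r`, `p`, `n`.
#' @export
edgeClinicalCorrelation <- function(features, scores) {
  Z <- featureZ(features)
  scores <- as.data.frame(scores)
  stopifnot(nrow(scores) == nrow(Z))
  rows <- list()
  for (e in colnames(Z)) for (sc in names(scores)) {
    ok <- stats::complete.cases(Z[, e], scores[[sc]])
    if (sum(ok) < 3L)
      stop("fewer than 3 complete pairs for edge ", e, " and score ", sc)
    x <- Z[ok, e]; y <- scores[[sc]][ok]
    if (sd(x) == 0 || sd(y) == 0)
      stop("zero variance in edge ", e, " or score ", sc)
    ct <- stats::cor.test(x, y, method = "pearson")
    rows[[length(rows) + 1L]] <- data.frame(
      edge = e, score = sc, r = unname(ct$estimate), p = ct$p.value,
      n = sum(ok))
  }
  do.call(rbind, rows)
}

#' Demographic and clinical comparison of two groups
#'
#' Chi-square test (2x2, continuity correction off by default) for sex;
#' classical two-sample t-tests for age, education and the clinical totals.
#'
#' @param subjects subject table rows for the compared patients.
#' @param labels group label per row.
#' @param correct logical, apply Yates continuity correction to the
#'   chi-square test.
#' @return data.frame with one row per variable: `variable`, `test`,
#'   `statistic`, `p`, `group1`, `group2` (mean (SD) or level counts).
#' @export
demographics <- function(subjects, labels, correct = FALSE) {
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  if (length(groups) != 2L) stop("exactly two groups are required")
  if (any(table(labels) == 0L)) stop("empty group")
  rows <- list()

  sexLevels <- if (all(subjects$sex %in% c(0, 1))) c(0, 1)
               else sort(unique(subjects$sex))
  tab <- table(factor(subjects$sex, levels = sexLevels),
               factor(labels, levels = groups))
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
    zm <- c(rownames(tab)[rowSums(tab) == 0L],
            colnames(tab)[colSums(tab) == 0L])
    stop("degenerate 2x2 margin for sex: ", paste(zm, collapse = ", "))
  }
  cs <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  fmtCounts <- function(col) paste(sprintf("%s:%d", rownames(tab), tab[, col]),
                                   collapse = " ")
  rows[["sex"]] <- data.frame(
    variable = "sex", test = "chi-square",
    statistic = unname(cs$statistic), p = cs$p.value,
    group1 = fmtCounts(1L), group2 = fmtCounts(2L))

  for (v in intersect(c("age", "education", "hamd17", "hama14"),
                      names(subjects))) {
    x1 <- subjects[[v]][labels == groups[1L]]
    x2 <- subjects[[v]][labels == groups[2L]]
    if (all(is.na(x1)) || all(is.na(x2))) next
    tt <- stats::t.test(x1, x2, var.equal = TRUE)
    fmt <- function(x) sprintf("%.2f (%.2f)", mean(x, na.rm = TRUE),
                               sd(x, na.rm = TRUE))
    rows[[v]] <- data.frame(
      variable = v, test = "two-sample t",
      statistic = unname(tt$statistic), p = tt$p.value,
      group1 = fmt(x1), group2 = fmt(x2))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
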