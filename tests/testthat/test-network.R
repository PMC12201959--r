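test_that("the covariate design has the documented columns", {
  s <- makeSubjects(165L, nSites = 6L)
  X <- buildDesign(s)
  expect_identical(ncol(X), 9L)  # intercept + age + sex + education + 5 sites
  expect_identical(colnames(X)[1:4], c("(Intercept)", "age", "sex", "education"))

  single <- makeSubjects(20L, nSites = 1L)
  expect_identical(ncol(buildDesign(single)), 4L)

  bad <- makeSubjects(20L)
  bad$education <- 12
  expect_error(buildDesign(bad), "education")
  bad2 <- makeSubjects(20L)
  bad2$age[3] <- NA
  expect_error(buildDesign(bad2), "age")
})

test_that("covariance network equals plain correlation under intercept-only design", {
  set.seed(4)
  g <- matrix(rnorm(60), 20L, 3L)
  net <- covarianceNetwork(g, matrix(1, 20L, 1L))
  expect_equal(corMatrix(net), unname(cor(g)), tolerance = 1e-12)
  expect_identical(nSubjects(net), 20L)

  # exact affine copy gives r = 1
  g2 <- cbind(g[, 1L], 3 + 2 * g[, 1L])
  net2 <- covarianceNetwork(g2, matrix(1, 20L, 1L))
  expect_equal(corMatrix(net2)[1L, 2L], 1, tolerance = 1e-12)
})

test_that("residualized correlation matches the brute-force oracle", {
  set.seed(5)
  s <- makeSubjects(30L, nSites = 2L)
  X <- buildDesign(s)
  g <- matrix(rnorm(30L * 5L), 30L, 5L) + outer(s$age / 10, runif(5L))
  expect_equal(corMatrix(covarianceNetwork(g, X)), oracleResidCor(g, X),
               tolerance = 1e-10)

  # 5-subject, 3-region toy with one covariate
  gt <- matrix(c(1, 2, 3, 5, 4,
                 2, 1, 4, 3, 6,
                 9, 7, 5, 3, 2), 5L, 3L)
  Xt <- cbind(1, c(1, 2, 3, 4, 5))
  expect_equal(corMatrix(covarianceNetwork(gt, Xt)), oracleResidCor(gt, Xt),
               tolerance = 1e-12)

  gz <- cbind(g[, 1:2], 0.5 * s$age)  # region fully explained by covariates
  expect_error(covarianceNetwork(gz, X), "zero residual variance.*3")
})

test_that("perturbed network equals brute-force recomputation on the stacked sample", {
  set.seed(6)
  s <- makeSubjects(25L, nSites = 2L)
  g <- matrix(rnorm(25L * 4L), 25L, 4L)
  pat <- makeSubjects(1L, nSites = 1L, seed = 99L)
  pg <- rnorm(4L)
  net <- perturbedNetwork(g, s, pg, pat)
  expect_identical(nSubjects(net), 26L)
  comb <- rbind(s[, c("age", "sex", "education", "site")],
                pat[, c("age", "sex", "education", "site")])
  expect_equal(corMatrix(net),
               oracleResidCor(rbind(g, pg), buildDesign(comb)),
               tolerance = 1e-10)

  pat2 <- pat; pat2$site <- "siteXX"
  expect_error(perturbedNetwork(g, s, pg, pat2), "siteXX")
})

test_that("a patient identical to a control barely perturbs the network", {
  res <- generateCohort(defaultConfig("null", rngSeed = 8L))
  s <- subjectTable(res$cohort); g <- gmvMatrix(res$cohort)
  ctl <- which(s$group == "control")
  rscn <- covarianceNetwork(g[ctl, ], buildDesign(s[ctl, ]))
  pscn <- perturbedNetwork(g[ctl, ], s[ctl, ], g[ctl[1L], ],
                           s[ctl[1L], , drop = FALSE])
  # duplicating one control reweights each correlation by O(1/n)
  expect_lt(max(abs(corMatrix(pscn) - corMatrix(rscn))), 0.05)
})

test_that("the Z statistic follows the perturbation formula", {
  mkNet <- function(r, n) {
    m <- matrix(c(1, r, r, 1), 2L)
    new("CovarianceNetwork", correlation = m, nSubjects = as.integer(n))
  }
  # identity case
  expect_equal(idscnZ(mkNet(0.4, 164L), mkNet(0.4, 165L)),
               matrix(0, 2L, 2L))
  # hand evaluation: 0.1 / ((1 - 0.25)/163)
  z <- idscnZ(mkNet(0.5, 164L), mkNet(0.6, 165L))
  expect_equal(z[1L, 2L], 0.1 / ((1 - 0.25) / 163), tolerance = 1e-12)
  expect_equal(z[1L, 2L], 21.7333, tolerance = 1e-4)
  # odd symmetry under joint negation
  zNeg <- idscnZ(mkNet(-0.5, 164L), mkNet(-0.6, 165L))
  expect_equal(zNeg, -z, tolerance = 1e-12)
  # degenerate reference correlation is rejected naming the edge
  expect_error(idscnZ(mkNet(1, 164L), mkNet(0.9, 165L)), "\\(1,2\\)")
  # sample-size contract
  expect_error(idscnZ(mkNet(0.5, 164L), mkNet(0.6, 164L)), "one more subject")
})

test_that("edge significance applies the Bonferroni family", {
  z <- matrix(0, 3L, 3L)
  sig <- edgeSignificance(z, familySize = 13695L, alpha = 0.001)
  expect_equal(sig$p[1L, 2L], 1)
  expect_false(any(sig$mask))

  cutoff <- qnorm(1 - 0.001 / 13695 / 2)
  expect_equal(cutoff, 5.3836, tolerance = 1e-4)
  z[1L, 2L] <- z[2L, 1L] <- cutoff + 0.01
  z[1L, 3L] <- z[3L, 1L] <- cutoff - 0.01
  sig <- edgeSignificance(z, 13695L, 0.001)
  expect_true(sig$mask[1L, 2L])
  expect_false(sig$mask[1L, 3L])
})

test_that("batch IDSCN construction composes the stepwise operations", {
  res <- generateCohort(defaultConfig("toy", rngSeed = 10L))
  co <- res$cohort
  ids <- buildAllIDSCN(co, alpha = 0.001)
  s <- subjectTable(co); g <- gmvMatrix(co)
  expect_length(ids, 12L)
  expect_identical(names(ids), s$subject_id[s$group == "patient"])

  ctl <- which(s$group == "control")
  rscn <- covarianceNetwork(g[ctl, ], buildDesign(s[ctl, ]))
  k <- which(s$group == "patient")[3L]
  pscn <- perturbedNetwork(g[ctl, ], s[ctl, ], g[k, ], s[k, , drop = FALSE])
  zk <- idscnZ(rscn, pscn)
  expect_equal(zMatrix(ids[[3L]]), zk, tolerance = 1e-12)
  expect_equal(sigMask(ids[[3L]]),
               edgeSignificance(zk, choose(8, 2), 0.001)$mask)

  # symmetry and zero diagonal of every Z
  for (x in ids) {
    expect_equal(zMatrix(x), t(zMatrix(x)))
    expect_true(all(diag(zMatrix(x)) == 0))
  }

  # invariance to control row re-ordering
  perm <- c(which(s$group == "patient"), rev(ctl))
  co2 <- cohortBundle(s[perm, ], g[perm, ], atlasTable(co))
  ids2 <- buildAllIDSCN(co2, alpha = 0.001)
  expect_equal(zMatrix(ids2[[3L]]), zMatrix(ids[[3L]]), tolerance = 1e-10)
})
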