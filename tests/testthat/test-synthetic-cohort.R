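test_that("scenario configs carry the documented geometry", {
  cfg <- defaultConfig("paper_like")
  expect_identical(cfg@nPatients, 164L)
  expect_identical(cfg@nControls, 164L)
  expect_identical(cfg@nRegions, 166L)
  expect_identical(cfg@subtypeSizes, c(117L, 47L))
  expect_length(cfg@plantedEdges, 10L)
  expect_true(all(vapply(cfg@plantedEdges,
                         function(p) sum(p$carriers) >= 8L, logical(1))))
  # nine plants exclusive to subtype 1, one carried by both subtypes
  excl <- vapply(cfg@plantedEdges, function(p) p$carriers[2L] == 0L, logical(1))
  expect_identical(sum(excl), 9L)

  nullCfg <- defaultConfig("null")
  expect_length(nullCfg@plantedEdges, 0L)
  expect_length(nullCfg@gmvEffectRegions, 0L)
  expect_identical(nullCfg@anxietyCoupling, 0)

  toy <- defaultConfig("toy")
  expect_identical(choose(toy@nRegions, 2), 28)

  expect_error(defaultConfig("bogus"), "paper_like")
})

test_that("invalid configurations are rejected with descriptive errors", {
  expect_error(simulationConfig(subtypeSizes = c(100L, 47L)),
               "subtypeSizes")
  expect_error(simulationConfig(nRegions = 2L), "nRegions")
  expect_error(simulationConfig(
    plantedEdges = list(plantSpec(1, 2, carriers = c(200L, 0L)))),
    "exceed a subtype size")
  expect_error(simulationConfig(
    plantedEdges = list(plantSpec(160, 170, carriers = c(8L, 0L)))),
    "exceeds nRegions")
  expect_error(plantSpec(5, 2, carriers = c(8L, 0L)))
  expect_error(simulationConfig(
    plantedEdges = list(plantSpec(1, 2, carriers = c(8L, 0L)),
                        plantSpec(2, 3, carriers = c(8L, 0L)))),
    "more than one plant")
})

test_that("cohort generation is deterministic given the config seed", {
  cfg <- defaultConfig("null", rngSeed = 11L)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(gmvMatrix(a$cohort), gmvMatrix(b$cohort))
  expect_identical(subjectTable(a$cohort), subjectTable(b$cohort))
  expect_identical(a$truth, b$truth)
  c2 <- generateCohort(defaultConfig("null", rngSeed = 12L))
  expect_false(identical(gmvMatrix(a$cohort), gmvMatrix(c2$cohort)))
})

test_that("generated cohorts have the documented shape and positivity", {
  res <- generateCohort(defaultConfig("paper_like", rngSeed = 3L))
  expect_identical(dim(gmvMatrix(res$cohort)), c(328L, 166L))
  expect_true(all(gmvMatrix(res$cohort) > 0))
  s <- subjectTable(res$cohort)
  expect_identical(sum(s$group == "patient"), 164L)
  expect_identical(table(res$truth$subtype), table(c(rep(1, 117), rep(2, 47))))

  toy <- generateCohort(defaultConfig("toy", rngSeed = 3L))
  expect_identical(dim(gmvMatrix(toy$cohort)), c(32L, 8L))
  expect_true(all(gmvMatrix(toy$cohort) > 0))
})

test_that("clinical scores are bounded integers with the planted coupling", {
  res <- generateCohort(defaultConfig("paper_like", rngSeed = 5L))
  s <- subjectTable(res$cohort)
  pat <- s[s$group == "patient", ]
  expect_true(all(pat$hamd17 %in% 0:52))
  expect_true(all(pat$hama14 %in% 0:56))
  expect_true(all(is.na(s$hamd17[s$group == "control"])))

  # gamma > 0 at upscaled n: anxiety signal and HAMA positively correlated
  up <- simulationConfig(nPatients = 2000L, nControls = 50L,
                         subtypeSizes = c(1400L, 600L),
                         plantedEdges = paperLikePlants(c(1400L, 600L)),
                         rngSeed = 9L)
  resUp <- generateCohort(up)
  pats <- subjectTable(resUp$cohort)
  pats <- pats[pats$group == "patient", ]
  r <- cor(resUp$truth$anxietySignal, pats$hama14)
  expect_gt(r, 0.3)

  # gamma = 0: no expected HAMA difference between subtypes
  up0 <- simulationConfig(nPatients = 2000L, nControls = 50L,
                          subtypeSizes = c(1000L, 1000L),
                          anxietyCoupling = 0, rngSeed = 9L)
  res0 <- generateCohort(up0)
  p0 <- subjectTable(res0$cohort)
  p0 <- p0[p0$group == "patient", ]
  tt <- t.test(p0$hama14 ~ res0$truth$subtype)
  expect_gt(tt$p.value, 0.001)
})

test_that("null-scenario control correlations match the loading model", {
  cfg <- simulationConfig(nPatients = 10L, nControls = 2000L,
                          subtypeSizes = c(5L, 5L), rngSeed = 21L)
  res <- generateCohort(cfg)
  s <- subjectTable(res$cohort)
  ctl <- s$group == "control"
  net <- covarianceNetwork(gmvMatrix(res$cohort)[ctl, ],
                           buildDesign(s[ctl, ]))
  lam <- res$truth$loadings
  Sigma <- lam %*% t(lam) + diag(res$truth$noiseSd^2)
  analytic <- stats::cov2cor(Sigma)
  emp <- corMatrix(net)
  ut <- upper.tri(emp)
  expect_lt(abs(mean(emp[ut]) - mean(analytic[ut])), 0.05)
  # element-wise agreement is also tight at n = 2000
  expect_lt(max(abs(emp[ut] - analytic[ut])), 0.12)
})

test_that("planted carriers attain Bonferroni-significant edge deviations", {
  # plant-effectiveness at the conventional 5-SD co-deviation: the carried
  # edge must exceed the corrected cutoff in at least 90% of carriers
  cfg <- simulationConfig(
    nPatients = 40L, nControls = 164L, nRegions = 40L, nSites = 2L,
    subtypeSizes = c(20L, 20L),
    plantedEdges = list(plantSpec(3L, 7L, carriers = c(20L, 20L), delta = 5,
                                  baselineR = -0.9)),
    rngSeed = 31L)
  hits <- 0L; tot <- 0L
  for (seed in 31:35) {
    cfg@rngSeed <- seed
    res <- generateCohort(cfg)
    ids <- buildAllIDSCN(res$cohort, familySize = choose(166, 2))
    hits <- hits + sum(vapply(ids, function(x) sigMask(x)[3L, 7L], logical(1)))
    tot <- tot + length(ids)
  }
  expect_gte(hits / tot, 0.9)
})
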