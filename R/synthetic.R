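#' Specify a planted edge co-deviation
#'
#' A plant makes selected patients violate the covariance of one region pair.
#' The generator simulates each planted pair as its own two-region factor
#' block whose baseline correlation is `baselineR` (strongly negative by
#' default) and which is uncorrelated with every other region. For a carrier
#' with random sign `u` in {+1, -1}, the carrier's latent-plus-noise residual
#' is *replaced* by `u * delta` residual SDs at region `i` and by
#' `u * sign * delta` at region `j`. With `sign = +1` against a negative
#' baseline correlation this same-sign co-deviation contradicts the reference
#' covariance, and the leave-one-in Z responds with approximately
#' `delta^2 * (1 - baselineR) / (1 - baselineR^2)` -- about `10 * delta^2`
#' at the default `baselineR = -0.9`. The per-region deviation itself stays
#' around one residual SD, so the perturbation is confined to the planted
#' edge: edges incident to the pair (which would need a 5-SD marginal
#' outlier) and pairs across plant blocks (baseline correlation zero,
#' products about `delta^2`) stay far below the per-edge Bonferroni cutoff.
#'
#' @param i,j 1-based region indices, `i < j`.
#' @param carriers integer vector, number of carriers drawn from each ground
#'   truth subtype (one entry per subtype).
#' @param delta co-deviation magnitude in units of region residual SD: a
#'   scalar (same for every carrier) or a length-2 range from which each
#'   carrier's magnitude is drawn uniformly.
#' @param sign +1 (same-direction co-deviation) or -1 (opposite).
#' @param baselineR baseline correlation of the planted pair, in (-1, 1).
#' @return a list usable in the `plantedEdges` slot of a
#'   [SimulationConfig-class].
#' @export
plantSpec <- function(i, j, carriers, delta = c(0.85, 1.15), sign = 1,
                      baselineR = -0.9) {
  stopifnot(length(i) == 1L, length(j) == 1L, i < j,
            length(delta) %in% 1:2, all(delta > 0), !is.unsorted(delta),
            sign %in% c(-1, 1), all(carriers >= 0),
            abs(baselineR) < 1)
  list(edge = c(as.integer(i), as.integer(j)),
       carriers = as.integer(carriers),
       delta = as.numeric(delta), sign = as.numeric(sign),
       baselineR = as.numeric(baselineR))
}

#' Construct a simulation configuration
#'
#' Low-level constructor; most users want [defaultConfig()]. Defaults follow
#' the `"paper_like"` scenario: 164 patients in two subtypes of 117 and 47,
#' 164 controls, 166 regions over 6 sites.
#'
#' @param nPatients,nControls,nRegions,nSites,nLatentFactors cohort geometry.
#' @param baselineNoiseSd independent noise SD of the unit-variance latent
#'   model; with the default 12-factor loadings (one global factor at
#'   variance share 0.30, eleven idiosyncratic at 0.35 jointly) the default
#'   `sqrt(0.35)` puts total variance near 1 and mean off-diagonal
#'   correlation near 0.3.
#' @param covariateEffectScale SD of per-region covariate coefficients.
#' @param plantedEdges list of [plantSpec()] entries.
#' @param subtypeSizes ground-truth subtype sizes (sum = `nPatients`).
#' @param anxietyCoupling gamma linking planted-edge deviation to HAMA-14.
#' @param gmvEffectRegions,gmvEffectSize regions with a subtype-1 volume
#'   deficit and its magnitude in residual SDs.
#' @param rngSeed integer seed.
#' @param scenario label recorded on the object.
#' @return a validated [SimulationConfig-class].
#' @export
simulationConfig <- function(nPatients = 164L, nControls = 164L,
                             nRegions = 166L, nSites = 6L,
                             nLatentFactors = 12L,
                             baselineNoiseSd = sqrt(0.35),
                             covariateEffectScale = 0.3,
                             plantedEdges = list(),
                             subtypeSizes = c(117L, 47L),
                             anxietyCoupling = 5,
                             gmvEffectRegions = integer(0),
                             gmvEffectSize = 1.2,
                             rngSeed = 1L,
                             scenario = "custom") {
  new("SimulationConfig",
      nPatients = as.integer(nPatients), nControls = as.integer(nControls),
      nRegions = as.integer(nRegions), nSites = as.integer(nSites),
      nLatentFactors = as.integer(nLatentFactors),
      baselineNoiseSd = as.numeric(baselineNoiseSd),
      covariateEffectScale = as.numeric(covariateEffectScale),
      plantedEdges = plantedEdges,
      subtypeSizes = as.integer(subtypeSizes),
      anxietyCoupling = as.numeric(anxietyCoupling),
      gmvEffectRegions = as.integer(gmvEffectRegions),
      gmvEffectSize = as.numeric(gmvEffectSize),
      rngSeed = as.integer(rngSeed), scenario = scenario)
}

# Planted-edge set of the paper_like scenario: nine disjoint edges in a block
# of neighbouring regions carried exclusively by subtype 1, plus one distant
# edge carried by every patient of both subtypes (equal 100% proportion), so
# that by construction 9 of the 10 prevalent edges separate the subtypes and
# 1 does not. The upper part of the per-carrier magnitude range crosses the
# per-edge Bonferroni cutoff (|Z| ~ 5.4), putting planted prevalences far
# above the 8-patient threshold, while the continuum keeps subtype 1 a
# single smooth cloud for the clustering.
paperLikePlants <- function(subtypeSizes = c(117L, 47L)) {
  ex <- list(c(121L, 122L), c(123L, 124L), c(125L, 126L), c(127L, 128L),
             c(129L, 130L), c(131L, 132L), c(133L, 134L), c(135L, 136L),
             c(137L, 138L))
  plants <- lapply(ex, function(e)
    plantSpec(e[1L], e[2L], carriers = c(subtypeSizes[1L], 0L)))
  c(plants, list(plantSpec(40L, 90L, carriers = subtypeSizes)))
}

#' Default configurations for the three built-in scenarios
#'
#' * `"paper_like"`: 164 patients (subtypes 117/47) and 164 controls over 166
#'   regions; 10 planted edges each carried by at least 8 patients, 9 of them
#'   exclusive to subtype 1 and 1 carried by everyone; 3 regions with lower
#'   volume in subtype 1; anxiety coupled to planted deviation.
#' * `"null"`: same geometry, nothing planted, no volume effect, zero anxiety
#'   coupling.
#' * `"toy"`: 8 regions (28 edges), 12 patients (8/4), 20 controls, 2 sites
#'   -- small enough for brute-force oracles and smoke tests.
#'
#' @param scenario one of `"paper_like"`, `"null"`, `"toy"`.
#' @param rngSeed integer seed stored in the config.
#' @return a [SimulationConfig-class].
#' @examples
#' cfg <- defaultConfig("toy")
#' choose(166, 2)  # edge family size of the paper_like atlas: 13695
#' @export
defaultConfig <- function(scenario = c("paper_like", "null", "toy"),
                          rngSeed = 1L) {
  scenario <- tryCatch(match.arg(scenario),
                       error = function(e)
                         stop("unknown scenario; valid scenarios are ",
                              "'paper_like', 'null', 'toy'", call. = FALSE))
  switch(scenario,
    paper_like = simulationConfig(
      plantedEdges = paperLikePlants(),
      gmvEffectRegions = c(3L, 60L, 150L),
      rngSeed = rngSeed, scenario = scenario),
    null = simulationConfig(
      plantedEdges = list(), gmvEffectRegions = integer(0),
      anxietyCoupling = 0, rngSeed = rngSeed, scenario = scenario),
    toy = simulationConfig(
      nPatients = 12L, nControls = 20L, nRegions = 8L, nSites = 2L,
      nLatentFactors = 3L, subtypeSizes = c(8L, 4L),
      plantedEdges = list(plantSpec(1L, 2L, carriers = c(8L, 0L), delta = 5)),
      gmvEffectRegions = integer(0),
      rngSeed = rngSeed, scenario = scenario))
}

#' Generate a synthetic region atlas
#'
#' @param nRegions number of regions.
#' @return data.frame with `region_index` (1-based) and synthetic
#'   `region_name` labels.
#' @export
makeAtlas <- function(nRegions) {
  data.frame(region_index = seq_len(nRegions),
             region_name = sprintf("R%03d", seq_len(nRegions)))
}

#' Construct a cohort bundle
#'
#' @param subjects subject table (see [CohortBundle-class]).
#' @param gmv subjects x regions matrix of positive volumes.
#' @param atlas region label table; defaults to a synthetic atlas sized to
#'   `gmv`.
#' @return a validated [CohortBundle-class].
#' @export
cohortBundle <- function(subjects, gmv, atlas = makeAtlas(ncol(gmv))) {
  gmv <- as.matrix(gmv)
  rownames(gmv) <- as.character(subjects$subject_id)
  new("CohortBundle", subjects = as.data.frame(subjects), gmv = gmv,
      atlas = as.data.frame(atlas))
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Attach clinical scores to a generated cohort
#'
#' HAMD-17 totals are drawn from one common distribution for all patients (no
#' planted subtype difference). HAMA-14 totals are
#' `baseline + gamma * signal + noise`, where `signal` is the patient's mean
#' planted-edge deviation (delta averaged over all planted edges, zero for
#' non-carried edges), so when `gamma > 0` the subtype carrying more planted
#' edges has higher expected anxiety and planted-edge Z-scores correlate
#' positively with HAMA. Scores are clipped to the scale ranges (HAMD 0-52,
#' HAMA 0-56) and rounded to integers.
#'
#' Draws from the current RNG state; [generateCohort()] calls this within its
#' seeded stream.
#'
#' @param truth ground-truth list from [generateCohort()] (needs
#'   `$anxietySignal`).
#' @param config the [SimulationConfig-class] used.
#' @return data.frame with `subject_id`, `hamd17`, `hama14` for patients.
#' @export
generateClinicalScores <- function(truth, config) {
  sig <- truth$anxietySignal
  n <- length(sig)
  hamd <- round(clip(rnorm(n, mean = 22, sd = 5), 0, 52))
  hama <- round(clip(18 + config@anxietyCoupling * sig + rnorm(n, 0, 4), 0, 56))
  if (anyNA(hamd) || anyNA(hama) || !all(is.finite(c(hamd, hama))))
    stop("non-finite clinical scores generated")
  data.frame(subject_id = names(sig), hamd17 = as.integer(hamd),
             hama14 = as.integer(hama))
}

#' Generate a synthetic cohort with ground truth
#'
#' Regional volumes for each subject are built as region means + per-region
#' covariate effects (age, sex, education, site) + a latent-factor term
#' (loadings x standard-normal factor scores) + independent noise, all on a
#' unit-variance scale that is then stretched by a per-region scale factor.
#' Planted co-deviations are then implanted into patient carriers by residual
#' replacement (see [plantSpec()]; regions named in plants are simulated
#' factor-free), subtype-1 volume deficits applied to `gmvEffectRegions`,
#' and the whole matrix floor-shifted if needed so every value is strictly
#' positive. Clinical scores are attached via
#' [generateClinicalScores()]. The result is deterministic given the config
#' (including its `rngSeed`).
#'
#' @param config a [SimulationConfig-class].
#' @return list with `cohort` (a [CohortBundle-class], patients first) and
#'   `truth` (list: `subtype`, `carriedEdges`, `gmvRegions`,
#'   `anxietySignal`, `loadings`, `noiseSd`).
#' @examples
#' res <- generateCohort(defaultConfig("toy", rngSeed = 7))
#' dim(gmvMatrix(res$cohort))
#' @export
generateCohort <- function(config) {
  validObject(config)
  set.seed(config@rngSeed)
  nP <- config@nPatients; nC <- config@nControls
  nS <- nP + nC; R <- config@nRegions; L <- config@nLatentFactors

  ids <- c(sprintf("P%04d", seq_len(nP)), sprintf("C%04d", seq_len(nC)))
  subjects <- data.frame(
    subject_id = ids,
    group = rep(c("patient", "control"), c(nP, nC)),
    site = rep_len(sprintf("site%02d", seq_len(config@nSites)), nS),
    age = round(runif(nS, 18, 60)),
    sex = rbinom(nS, 1L, 0.5),
    education = round(runif(nS, 6, 19)))

  # latent loadings: one global factor plus idiosyncratic factors; each
  # planted pair becomes its own two-region factor block at unit variance
  # with baseline correlation baselineR, uncorrelated with everything else
  nPl <- length(config@plantedEdges)
  lambda <- cbind(sqrt(0.30) * runif(R, 0.9, 1.1),
                  if (L > 1L) matrix(rnorm(R * (L - 1L), 0,
                                           sqrt(0.35 / (L - 1L))), R, L - 1L))
  noiseSd <- rep(config@baselineNoiseSd, R)
  if (nPl) {
    lambda <- cbind(lambda, matrix(0, R, nPl))
    for (ei in seq_len(nPl)) {
      pe <- config@plantedEdges[[ei]]
      a <- pe$edge[1L]; b <- pe$edge[2L]; rho <- pe$baselineR
      lambda[c(a, b), ] <- 0
      lambda[a, L + ei] <- sqrt(abs(rho))
      lambda[b, L + ei] <- sign(rho) * sqrt(abs(rho))
      noiseSd[c(a, b)] <- sqrt(1 - abs(rho))
    }
  }
  sdModel <- sqrt(rowSums(lambda^2) + noiseSd^2)
  scores <- matrix(rnorm(nS * ncol(lambda)), nS, ncol(lambda))
  resid <- scores %*% t(lambda) +
    matrix(rnorm(nS * R), nS, R) * rep(noiseSd, each = nS)

  # covariate effects, coefficients per region (age/education per decade)
  sc <- config@covariateEffectScale
  betaAge <- rnorm(R, 0, sc); betaSex <- rnorm(R, 0, sc)
  betaEdu <- rnorm(R, 0, sc)
  siteEff <- matrix(rnorm(config@nSites * R, 0, sc), config@nSites, R)
  siteIdx <- match(subjects$site, sprintf("site%02d", seq_len(config@nSites)))
  covEff <- outer((subjects$age - mean(subjects$age)) / 10, betaAge) +
    outer(subjects$sex - mean(subjects$sex), betaSex) +
    outer((subjects$education - mean(subjects$education)) / 10, betaEdu) +
    siteEff[siteIdx, , drop = FALSE]

  subtype <- rep(seq_along(config@subtypeSizes), config@subtypeSizes)
  names(subtype) <- ids[seq_len(nP)]

  # planted co-deviations (patient rows only): the carrier's residual at the
  # two regions is replaced by +/- delta residual SDs with a shared sign
  carried <- rep(list(character(0)), nP)
  names(carried) <- ids[seq_len(nP)]
  carriedDelta <- matrix(0, nP, max(1L, length(config@plantedEdges)))
  for (ei in seq_along(config@plantedEdges)) {
    pe <- config@plantedEdges[[ei]]
    rows <- unlist(lapply(seq_along(pe$carriers), function(t) {
      pool <- which(subtype == t)
      if (pe$carriers[t] == length(pool)) pool
      else sort(sample(pool, pe$carriers[t]))
    }))
    u <- sample(c(-1, 1), length(rows), replace = TRUE)
    delta <- if (length(pe$delta) == 2L)
      runif(length(rows), pe$delta[1L], pe$delta[2L])
    else rep(pe$delta, length(rows))
    a <- pe$edge[1L]; b <- pe$edge[2L]
    resid[rows, a] <- u * delta * sdModel[a]
    resid[rows, b] <- u * pe$sign * delta * sdModel[b]
    for (kk in seq_along(rows))
      carried[[rows[kk]]] <- c(carried[[rows[kk]]], sprintf("%d-%d", a, b))
    carriedDelta[rows, ei] <- delta
  }

  # subtype-1 regional volume deficit: a homogeneous shift with tightened
  # residual spread, so the group-level mean effect is reliably detectable
  # without turning each subtype-1 patient into a marginal outlier whose
  # region z-score would bleed into individual edge significances
  if (length(config@gmvEffectRegions)) {
    rows <- which(subtype == 1L)
    regs <- config@gmvEffectRegions
    resid[rows, regs] <-
      sweep(0.3 * resid[rows, regs, drop = FALSE], 2L,
            config@gmvEffectSize * sdModel[regs], "-")
  }

  mu <- runif(R, 5, 9)
  scale <- runif(R, 0.5, 0.9)
  gmv <- sweep(sweep(resid + covEff, 2L, scale, "*"), 2L, mu, "+")
  lo <- min(gmv)
  if (lo <= 0.05) gmv <- gmv + (0.05 - lo)
  rownames(gmv) <- ids
  colnames(gmv) <- NULL

  anxietySignal <- if (length(config@plantedEdges))
    rowMeans(carriedDelta[, seq_along(config@plantedEdges), drop = FALSE])
  else rep(0, nP)
  names(anxietySignal) <- ids[seq_len(nP)]

  truth <- list(subtype = subtype, carriedEdges = carried,
                gmvRegions = config@gmvEffectRegions,
                anxietySignal = anxietySignal,
                loadings = lambda, noiseSd = noiseSd)

  scoresTab <- generateClinicalScores(truth, config)
  subjects$hamd17 <- NA_integer_
  subjects$hama14 <- NA_integer_
  m <- match(scoresTab$subject_id, subjects$subject_id)
  subjects$hamd17[m] <- scoresTab$hamd17
  subjects$hama14[m] <- scoresTab$hama14

  list(cohort = cohortBundle(subjects, gmv, makeAtlas(R)), truth = truth)
}
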