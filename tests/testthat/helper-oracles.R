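# Brute-force reference implementations, kept deliberately naive and
# independent of the package internals.

# residualize each column by explicit normal equations, then textbook Pearson
oracleResidCor <- function(gmv, design) {
  X <- as.matrix(design)
  beta <- solve(t(X) %*% X) %*% t(X) %*% gmv
  res <- gmv - X %*% beta
  R <- ncol(gmv)
  out <- diag(1, R)
  for (a in seq_len(R - 1L)) for (b in (a + 1L):R) {
    x <- res[, a]; y <- res[, b]
    r <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    out[a, b] <- out[b, a] <- r
  }
  out
}

oracleZ <- function(r0, r1, n) (r1 - r0) / ((1 - r0^2) / (n - 1))

# regression t for the group dummy via explicit normal equations
oracleAdjustedT <- function(values, labels, covariates = NULL) {
  groups <- sort(unique(as.character(labels)))
  g <- as.numeric(as.character(labels) == groups[1L])
  X <- cbind(1, g)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  XtXi <- solve(t(X) %*% X)
  beta <- XtXi %*% t(X) %*% values
  res <- values - X %*% beta
  df <- length(values) - ncol(X)
  s2 <- sum(res^2) / df
  tval <- beta[2L] / sqrt(s2 * XtXi[2L, 2L])
  list(t = tval, p = 2 * pt(-abs(tval), df))
}

# subject tables with non-degenerate covariates for design tests
makeSubjects <- function(n, nSites = 2L, seed = 1L) {
  set.seed(seed)
  data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = "control",
    site = rep_len(sprintf("site%02d", seq_len(nSites)), n),
    age = round(runif(n, 18, 60)),
    sex = sample(rep_len(c(0, 1), n)),
    education = round(runif(n, 6, 19)))
}
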