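# Independent brute-force oracles and small fixture builders used across the
# test files.

# Exact two-sided signed-rank p by full enumeration of the 2^n sign
# assignments (midranks under ties), independent of the package's dynamic
# programming path.
oracleWilcoxonP <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Wall <- as.vector(signs %*% r)
  lo <- mean(Wall <= V + 1e-9)
  hi <- mean(Wall >= V - 1e-9)
  min(1, 2 * min(lo, hi))
}

# Exact Friedman p by full enumeration of all (k!)^n within-block orderings.
oracleFriedmanP <- function(values) {
  values <- as.matrix(values)
  nb <- nrow(values)
  k <- ncol(values)
  rr <- t(apply(values, 1, rank))
  statOf <- function(rmat) {
    A <- sum(rmat^2)
    C <- nb * k * (k + 1)^2 / 4
    if (abs(A - C) < 1e-12) return(0)
    (k - 1) * sum((colSums(rmat) - nb * (k + 1) / 2)^2) / (A - C)
  }
  obs <- statOf(rr)
  perms <- gtoolsPerm(k)
  combos <- as.matrix(expand.grid(rep(list(seq_len(nrow(perms))), nb)))
  stats <- apply(combos, 1, function(idx) {
    pm <- t(vapply(seq_len(nb), function(b) rr[b, perms[idx[b], ]],
                   numeric(k)))
    statOf(pm)
  })
  mean(stats >= obs - 1e-9)
}

# permutations of 1..k (tiny local implementation, no extra dependency)
gtoolsPerm <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- gtoolsPerm(k - 1)
  out <- NULL
  for (i in seq_len(k)) {
    rest <- setdiff(seq_len(k), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), k - 1)))
  }
  unname(out)
}

# A smooth non-trivial cumulative test curve on a 0.1 Gy grid.
logisticTestCurve <- function(d50 = 20, g = 0.4, maxDose = 60, ...) {
  edges <- seq(0, maxDose, by = 0.1)
  v <- plogis(-g * (edges - d50))
  v[v < 1e-7] <- 0
  v[1] <- 1
  dvhCurve(edges, v, kind = "cumulative", ...)
}

# Small deterministic cohort configs used by several files.
smallConfig <- function(seed = 7, nPatients = 3, ...) {
  cohortConfig(nPatients = nPatients, seed = seed, ...)
}

nullProfiles <- function() {
  pr <- defaultModalityProfiles()$proton
  out <- list(photon = pr, proton = pr, helium = pr)
  out$photon@modality <- "photon"
  out$helium@modality <- "helium"
  out
}
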