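#' Wilcoxon signed-rank test for paired samples
#'
#' Paired two-sided signed-rank test. Zero differences are dropped before
#' ranking (classic Wilcoxon convention); absolute differences are ranked
#' with midranks under ties. For \code{n <= exactLimit} non-zero pairs the
#' p-value is permutation-exact, computed by dynamic programming over the
#' 2^n equiprobable sign assignments of the (possibly tied) ranks; the
#' two-sided p doubles the smaller tail probability (capped at 1). Above the
#' limit a normal approximation with tie and continuity correction is used.
#' If every difference is zero the test is degenerate: statistic NA, p = 1.
#'
#' @param x numeric vector (first condition, or differences if \code{y} is
#'   NULL).
#' @param y optional numeric vector paired with \code{x}.
#' @param exactLimit maximum n for the exact permutation distribution
#'   (default 25).
#' @return List with elements \code{statistic} (V, the sum of ranks of
#'   positive differences), \code{p.value}, \code{n} (non-zero pairs),
#'   \code{exact} (logical), \code{degenerate} (logical).
#' @examples
#' wilcoxonSignedRank(c(1, 2, 3, 4, 5))  # V = 15, p = 1/16
#' @export
wilcoxonSignedRank <- function(x, y = NULL, exactLimit = 25) {
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  if (anyNA(d)) .errBadArgument("missing values in differences")
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(statistic = NA_real_, p.value = 1, n = 0L,
                exact = TRUE, degenerate = TRUE))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= exactLimit) {
    # permutation-exact via the generating polynomial of doubled ranks
    ir <- as.integer(round(2 * r))
    tot <- sum(ir)
    counts <- numeric(tot + 1L)  # counts[w + 1] = #assignments with 2V = w
    counts[1L] <- 1
    for (k in ir) {
      shifted <- c(numeric(k), counts[seq_len(tot + 1L - k)])
      counts <- counts + shifted
    }
    counts <- counts / 2^n
    w2 <- as.integer(round(2 * V))
    lo <- sum(counts[seq_len(w2 + 1L)])
    hi <- sum(counts[(w2 + 1L):(tot + 1L)])
    p <- min(1, 2 * min(lo, hi))
    return(list(statistic = V, p.value = p, n = n, exact = TRUE,
                degenerate = FALSE))
  }
  mu <- n * (n + 1) / 4
  tie <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie^3 - tie) / 48
  cc <- sign(V - mu) * 0.5
  z <- (V - mu - cc) / sqrt(sigma2)
  list(statistic = V, p.value = min(1, 2 * stats::pnorm(-abs(z))), n = n,
       exact = FALSE, degenerate = FALSE)
}

# all permutations of seq_len(k), rows = k! orderings
.permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(k - 1L)
  out <- NULL
  for (i in seq_len(k)) {
    rest <- setdiff(seq_len(k), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), k - 1L)))
  }
  unname(out)
}

# tie-corrected Friedman chi-square from a matrix of within-block ranks
.friedmanStat <- function(R, rr) {
  nb <- nrow(rr)
  k <- ncol(rr)
  A <- sum(rr^2)
  C <- nb * k * (k + 1)^2 / 4
  if (abs(A - C) < 1e-12) return(0)
  (k - 1) * sum((R - nb * (k + 1) / 2)^2) / (A - C)
}

#' Friedman rank test for paired samples across k treatments
#'
#' Nonparametric repeated-measures test: within each block (patient) the k
#' treatment values are ranked (midranks under ties) and the tie-corrected
#' Friedman chi-square is computed from the column rank sums. For
#' \code{n <= exactLimit} blocks the p-value is permutation-exact: the null
#' distribution enumerates all (k!)^n equiprobable within-block orderings by
#' dynamic programming over the joint column-sum states. Above the limit the
#' chi-square approximation with k - 1 degrees of freedom is used. A matrix
#' whose blocks are all completely tied is degenerate: statistic 0, p = 1.
#'
#' @param values numeric matrix, blocks (patients) in rows, treatments
#'   (modalities) in columns; at least 2 complete rows.
#' @param exactLimit maximum number of blocks for the exact distribution
#'   (default 8).
#' @return List with \code{statistic}, \code{p.value}, \code{meanRanks},
#'   \code{n}, \code{k}, \code{exact}.
#' @examples
#' m <- rbind(c(1, 2, 3), c(1.5, 2.5, 3.5), c(1, 2.2, 3.1))
#' friedmanTest(m)  # perfect ordering: statistic 2n = 6
#' @export
friedmanTest <- function(values, exactLimit = 8) {
  values <- as.matrix(values)
  if (anyNA(values)) .errBadArgument("missing values in Friedman input")
  nb <- nrow(values)
  k <- ncol(values)
  if (nb < 2L || k < 2L)
    .errBadArgument("need >= 2 complete blocks and >= 2 treatments")
  rr <- t(apply(values, 1L, rank))
  R <- colSums(rr)
  stat <- .friedmanStat(R, rr)
  meanRanks <- R / nb
  if (stat == 0 && all(abs(rr - (k + 1) / 2) < 1e-12))
    return(list(statistic = 0, p.value = 1, meanRanks = meanRanks,
                n = nb, k = k, exact = TRUE))
  if (nb <= exactLimit && k <= 4L) {
    perms <- .permutations(k)
    cur <- list(list(S = numeric(k), p = 1))
    for (b in seq_len(nb)) {
      nxt <- new.env(hash = TRUE, parent = emptyenv())
      contribs <- matrix(rr[b, perms], nrow(perms), k)
      for (st in cur) {
        for (j in seq_len(nrow(contribs))) {
          S <- st$S + contribs[j, ]
          key <- paste(round(2 * S), collapse = ",")
          prev <- if (exists(key, envir = nxt, inherits = FALSE))
            get(key, envir = nxt, inherits = FALSE) else NULL
          if (is.null(prev)) {
            assign(key, list(S = S, p = st$p / nrow(contribs)), envir = nxt)
          } else {
            prev$p <- prev$p + st$p / nrow(contribs)
            assign(key, prev, envir = nxt)
          }
        }
      }
      cur <- mget(ls(nxt), envir = nxt)
    }
    pv <- 0
    for (st in cur) {
      s <- .friedmanStat(st$S, rr)
      if (s >= stat - 1e-9) pv <- pv + st$p
    }
    return(list(statistic = stat, p.value = min(1, pv),
                meanRanks = meanRanks, n = nb, k = k, exact = TRUE))
  }
  list(statistic = stat,
       p.value = stats::pchisq(stat, df = k - 1, lower.tail = FALSE),
       meanRanks = meanRanks, n = nb, k = k, exact = FALSE)
}
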