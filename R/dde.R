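# digital differential expression: Audic-Claverie exact test, R statistic,
# library/contig filters, and correlation-based profile clustering

# log p(y | x) for the Audic-Claverie model:
# p(y|x) = (n2/n1)^y (x+y)! / (x! y! (1 + n2/n1)^(x+y+1))
.acLogProb <- function(yy, x, n1, n2) {
  r <- n2 / n1
  yy * log(r) + lgamma(x + yy + 1) - lgamma(x + 1) - lgamma(yy + 1) -
    (x + yy + 1) * log1p(r)
}

#' Audic-Claverie two-sided p-value for a pair of EST counts
#'
#' Exact conditional test for digital expression data: given \code{x}
#' tags for a transcript in a library of \code{n1} total ESTs, the
#' probability of seeing \code{y} tags in a library of \code{n2} is
#' \deqn{p(y|x) = (n2/n1)^y \frac{(x+y)!}{x!\,y!\,(1+n2/n1)^{x+y+1}}}
#' evaluated in log space.  The two-sided p-value doubles the smaller
#' tail, capped at 1.  The test is symmetric under swapping
#' \code{(x, n1)} and \code{(y, n2)}.
#'
#' @param x,y Tag counts of the transcript in the two libraries.
#' @param n1,n2 Total EST counts of the two libraries.
#' @return Two-sided p-value in [0, 1].
#' @examples
#' acPvalue(0, 10, 1000, 1000)  # ~ 2 * 2^-10
#' @export
acPvalue <- function(x, y, n1, n2) {
  if (n1 < 1 || n2 < 1) stop("library totals must be >= 1")
  if (x > n1 || y > n2) stop("counts cannot exceed library totals")
  if (x < 0 || y < 0) stop("counts must be nonnegative")
  # equal counts at equal depth: the lower tail is exactly 1/2 (odd
  # binomial symmetry), so the doubled p-value is exactly 1
  if (x == y && n1 == n2) return(1)
  # lower tail: sum over y' = 0..y
  lower <- sum(exp(.acLogProb(0:y, x, n1, n2)))
  # upper tail: sum from y upward until terms vanish
  upper <- 0
  yy <- y
  repeat {
    block <- sum(exp(.acLogProb(yy:(yy + 63L), x, n1, n2)))
    upper <- upper + block
    yy <- yy + 64L
    if (block < 1e-16 * upper || block == 0) break
  }
  min(1, 2 * min(lower, upper))
}

#' R statistic for multi-library EST counts
#'
#' Log-likelihood-ratio measure of count heterogeneity across libraries:
#' \deqn{R = \sum_j x_j \ln\frac{x_j}{N_j \sum x / \sum N}}
#' with \eqn{0 \ln 0 = 0}.  The p-value uses the asymptotic null
#' \eqn{2R \sim \chi^2_{m-1}} (standard likelihood-ratio theory), where
#' m is the number of libraries.
#'
#' @param counts Per-library tag counts of one contig.
#' @param totals Per-library total EST counts.
#' @return List with \code{R} and \code{p}.
#' @examples
#' rStatistic(c(0, 20), c(1000, 1000))$R  # 20 * log(2)
#' @export
rStatistic <- function(counts, totals) {
  if (length(counts) < 2L) stop("at least two libraries required")
  if (length(counts) != length(totals)) stop("counts/totals length mismatch")
  if (sum(totals) <= 0) stop("library totals must be positive")
  f <- sum(counts) / sum(totals)
  terms <- ifelse(counts > 0, counts * log(counts / (totals * f)), 0)
  R <- sum(terms)
  list(R = R, p = stats::pchisq(2 * R, df = length(counts) - 1L,
                                lower.tail = FALSE))
}

#' Differential expression configuration
#'
#' @param alpha Significance level (default 0.05).
#' @param minLibraryEsts Libraries with fewer total ESTs are discarded
#'   (default 300).
#' @param minContigEsts Contigs with fewer total ESTs are not tested
#'   (default 3, i.e. more than two ESTs).
#' @param mergeMap Optional named character vector mapping library id to
#'   merged group id (libraries from the same tissue are often pooled).
#' @param bonferroni Apply Bonferroni correction to the R test threshold.
#' @return List of class \code{"DeConfig"}.
#' @export
deConfig <- function(alpha = 0.05, minLibraryEsts = 300, minContigEsts = 3,
                     mergeMap = NULL, bonferroni = TRUE) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (minContigEsts < 3) stop("minContigEsts must be >= 3")
  structure(list(alpha = alpha, min_library_ests = minLibraryEsts,
                 min_contig_ests = minContigEsts, merge_map = mergeMap,
                 bonferroni = bonferroni), class = "DeConfig")
}

#' Select differentially expressed contigs from a count matrix
#'
#' Pipeline of the classic digital-expression screen: (1) libraries are
#' merged per \code{mergeMap}; (2) libraries with fewer than
#' \code{minLibraryEsts} total ESTs are discarded; (3) contigs with fewer
#' than \code{minContigEsts} ESTs are dropped; (4) the R test is applied
#' with a Bonferroni-adjusted threshold \code{alpha / n tested contigs};
#' (5) the AC test is applied to all library pairs, and a contig is
#' AC-significant when at least one library scores below \code{alpha}
#' against every other library; (6) the reported set is the union of the
#' two, tagged by which test selected each contig.
#'
#' @param counts Integer matrix, rows = contigs, columns = libraries
#'   (from \code{\link{buildCountMatrix}}).
#' @param config A \code{\link{deConfig}}.
#' @return Data frame: \code{contig_id}, \code{r_value}, \code{r_pvalue},
#'   \code{ac_best} (the minimax AC p-value of step 5),
#'   \code{significant_by} (\code{"R"}, \code{"AC"} or \code{"R+AC"}).
#'   The normalized per-library profiles of the selected contigs are
#'   attached as attribute \code{"profiles"}, the tested (filtered,
#'   merged) matrix as attribute \code{"tested"}.
#' @export
selectDeContigs <- function(counts, config = deConfig()) {
  if (nrow(counts) == 0L) stop("count matrix is empty")
  m <- counts
  if (!is.null(config$merge_map)) {
    grp <- config$merge_map[colnames(m)]
    grp[is.na(grp)] <- colnames(m)[is.na(grp)]
    m <- t(rowsum(t(m), group = grp))
  }
  totals <- colSums(m)
  m <- m[, totals >= config$min_library_ests, drop = FALSE]
  if (ncol(m) < 2L) stop("fewer than two libraries pass the size filter")
  m <- m[rowSums(m) >= config$min_contig_ests, , drop = FALSE]
  if (nrow(m) == 0L) stop("no contigs pass the EST count filter")
  totals <- colSums(m)
  nTested <- nrow(m)
  rCut <- if (config$bonferroni) config$alpha / nTested else config$alpha

  rRes <- apply(m, 1L, rStatistic, totals = totals)
  rVal <- vapply(rRes, `[[`, numeric(1), "R")
  rP <- vapply(rRes, `[[`, numeric(1), "p")

  nLib <- ncol(m)
  acP <- matrix(NA_real_, nLib, nLib)
  acBest <- numeric(nTested)
  for (i in seq_len(nTested)) {
    x <- m[i, ]
    for (a in seq_len(nLib))
      for (b in seq_len(nLib))
        if (a < b) {
          p <- acPvalue(x[a], x[b], totals[a], totals[b])
          acP[a, b] <- p; acP[b, a] <- p
        }
    # minimax: best library's worst pairwise p
    acBest[i] <- min(apply(acP, 1L, max, na.rm = TRUE))
  }

  sigR <- rP < rCut
  sigAC <- acBest < config$alpha
  keep <- sigR | sigAC
  res <- data.frame(
    contig_id = rownames(m)[keep],
    r_value = rVal[keep],
    r_pvalue = rP[keep],
    ac_best = acBest[keep],
    significant_by = ifelse(sigR[keep] & sigAC[keep], "R+AC",
                            ifelse(sigR[keep], "R", "AC")),
    stringsAsFactors = FALSE)
  prof <- m[keep, , drop = FALSE] / pmax(rowSums(m[keep, , drop = FALSE]), 1)
  attr(res, "profiles") <- prof
  attr(res, "tested") <- m
  res
}

#' Hierarchically cluster normalized expression profiles
#'
#' Each contig's per-library counts are divided by the contig total; the
#' distance between two contigs is 1 minus the product-moment correlation
#' of their normalized profiles (a zero-variance profile is uncorrelated
#' with everything by convention, distance 1), and the rows are joined by
#' agglomerative clustering.
#'
#' @param profiles Numeric matrix of profiles (rows = contigs), e.g. the
#'   \code{"profiles"} attribute of \code{\link{selectDeContigs}}, or raw
#'   counts (rows are renormalized to sum to 1).
#' @param linkage Agglomeration method (default \code{"average"}).
#' @return List: \code{hclust} (the tree), \code{order} (leaf order),
#'   \code{matrix} (the reordered normalized matrix, rendered dark-high
#'   in the pipeline heatmap).
#' @export
profileCluster <- function(profiles, linkage = "average") {
  if (nrow(profiles) < 2L) stop("at least two profiles required")
  prof <- profiles / pmax(rowSums(profiles), .Machine$double.xmin)
  v <- apply(prof, 1L, stats::var)
  d <- matrix(1, nrow(prof), nrow(prof),
              dimnames = list(rownames(prof), rownames(prof)))
  ok <- which(v > 0)
  if (length(ok) >= 2L) {
    cc <- stats::cor(t(prof[ok, , drop = FALSE]))
    d[ok, ok] <- 1 - cc
  }
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  list(hclust = hc, order = hc$order,
       matrix = prof[hc$order, , drop = FALSE])
}
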