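# term enrichment and orthologous-family prevalence screening

#' Hypergeometric over/under-representation of one term
#'
#' With X ~ Hypergeometric(N, K, n) (a focal set of \code{n} annotated
#' clusters drawn from a union of \code{N} whose term carries \code{K}
#' members), returns \code{p_over = P[X >= k]} and
#' \code{p_under = P[X <= k]}.
#'
#' @param k Term count in the focal set.
#' @param n Focal set size.
#' @param K Term count in the union.
#' @param N Union size.
#' @return List with \code{p_over} and \code{p_under}.
#' @examples
#' hypergeomTermTest(5, 5, 5, 10)$p_over  # 1 / choose(10, 5)
#' @export
hypergeomTermTest <- function(k, n, K, N) {
  if (K > N || n > N || k > min(n, K) || k < max(0, n + K - N))
    stop("inconsistent hypergeometric margins")
  list(p_over = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
       p_under = stats::phyper(k, K, N - K, n))
}

#' Compare annotation-term percentages between two datasets
#'
#' Each term's cluster count is divided by the dataset's total annotated
#' clusters (clusters with several terms count once per term), yielding
#' comparable percentages; the table is sorted by absolute percentage
#' difference.
#'
#' @param countsA,countsB Named numeric vectors: term -> cluster count.
#' @param totalA,totalB Total annotated clusters per dataset (defaults:
#'   sum of the counts).
#' @return Data frame: \code{term}, \code{count_a}, \code{pct_a},
#'   \code{count_b}, \code{pct_b}, \code{difference} (pct_a - pct_b),
#'   \code{ratio}.
#' @export
domainPrevalence <- function(countsA, countsB, totalA = sum(countsA),
                             totalB = sum(countsB)) {
  if (totalA <= 0 || totalB <= 0) stop("totals must be positive")
  terms <- sort(union(names(countsA), names(countsB)))
  ca <- ifelse(terms %in% names(countsA), countsA[terms], 0)
  cb <- ifelse(terms %in% names(countsB), countsB[terms], 0)
  pa <- 100 * ca / totalA
  pb <- 100 * cb / totalB
  out <- data.frame(term = terms, count_a = unname(ca), pct_a = unname(pa),
                    count_b = unname(cb), pct_b = unname(pb),
                    difference = unname(pa - pb),
                    ratio = unname(ifelse(pb > 0, pa / pb, NA_real_)),
                    stringsAsFactors = FALSE)
  out[order(-abs(out$difference)), , drop = FALSE]
}

#' Hypergeometric enrichment of every term of one dataset against a union
#'
#' Tests each term of the focal dataset for over- and
#' under-representation relative to the pooled union of both datasets,
#' adding Benjamini-Hochberg adjusted p-values alongside the raw ones.
#'
#' @param countsA,countsB Named numeric term count vectors of the focal
#'   and companion datasets.
#' @param totalA,totalB Total annotated clusters per dataset.
#' @return Data frame: \code{term}, \code{k}, \code{K}, \code{p_over},
#'   \code{p_under}, \code{fdr_over}, \code{fdr_under}.
#' @export
termEnrichment <- function(countsA, countsB, totalA = sum(countsA),
                           totalB = sum(countsB)) {
  terms <- sort(union(names(countsA), names(countsB)))
  ca <- ifelse(terms %in% names(countsA), countsA[terms], 0)
  cb <- ifelse(terms %in% names(countsB), countsB[terms], 0)
  N <- totalA + totalB
  res <- lapply(seq_along(terms), function(i)
    hypergeomTermTest(ca[i], totalA, ca[i] + cb[i], N))
  pOver <- vapply(res, `[[`, numeric(1), "p_over")
  pUnder <- vapply(res, `[[`, numeric(1), "p_under")
  data.frame(term = terms, k = unname(ca), K = unname(ca + cb),
             p_over = pOver, p_under = pUnder,
             fdr_over = stats::p.adjust(pOver, "BH"),
             fdr_under = stats::p.adjust(pUnder, "BH"),
             stringsAsFactors = FALSE)
}

#' Screen a family-by-species matrix for focal-specific and prominent
#' families
#'
#' A family is \code{specific} when the focal species together hold at
#' least \code{minFocal} members and every other species none;
#' \code{prominent} when the focal sum reaches \code{minFocal}, no other
#' species exceeds \code{maxOther} members, and the focal sum is at least
#' \code{prominentRatio} times the largest non-focal count; otherwise
#' \code{background}.
#'
#' @param matrix Integer matrix, rows = families, columns = species (see
#'   \code{\link{readFamilyMatrix}}).
#' @param focal Character vector of focal species (matrix columns).
#' @param minFocal Minimum summed focal members (default 3).
#' @param maxOther Maximum members tolerated in any single non-focal
#'   species for prominence (default 1).
#' @param prominentRatio Minimum focal-sum : max-non-focal ratio
#'   (default 3).
#' @return Data frame: \code{family}, \code{focal_count},
#'   \code{max_other}, \code{label}.
#' @export
familyPrevalenceScreen <- function(matrix, focal, minFocal = 3,
                                   maxOther = 1, prominentRatio = 3.0) {
  if (!all(focal %in% colnames(matrix)))
    stop("unknown focal species: ",
         paste(setdiff(focal, colnames(matrix)), collapse = ", "))
  other <- setdiff(colnames(matrix), focal)
  focalSum <- rowSums(matrix[, focal, drop = FALSE])
  maxOth <- if (length(other))
    apply(matrix[, other, drop = FALSE], 1L, max) else rep(0L, nrow(matrix))
  label <- rep("background", nrow(matrix))
  prominent <- focalSum >= minFocal & maxOth <= maxOther &
    focalSum >= prominentRatio * maxOth
  specific <- focalSum >= minFocal & maxOth == 0L
  label[prominent] <- "prominent"
  label[specific] <- "specific"
  data.frame(family = rownames(matrix), focal_count = unname(focalSum),
             max_other = unname(maxOth), label = label,
             stringsAsFactors = FALSE)
}
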