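# EST trimming and bacterial-contaminant screening

# first occurrence of adapter within the leading searchLimit bases allowing
# up to maxMismatch substitutions (no indels); returns 0-based end or -1
.findAdapter <- function(chars, adapter, maxMismatch = 2L,
                         searchLimit = 50L) {
  la <- nchar(adapter)
  if (la == 0L || length(chars) < la) return(-1L)
  ad <- seqToChars(adapter)
  lastStart <- min(searchLimit, length(chars) - la + 1L)
  for (p in seq_len(lastStart)) {
    if (sum(chars[p:(p + la - 1L)] != ad) <= maxMismatch)
      return(p + la - 1L)  # 1-based inclusive end of the adapter copy
  }
  -1L
}

.runLength <- function(chars, base, fromEnd = FALSE) {
  n <- length(chars)
  if (n == 0L) return(0L)
  idx <- if (fromEnd) n:1 else 1:n
  r <- 0L
  for (i in idx) {
    if (chars[i] == base) r <- r + 1L else break
  }
  r
}

.trimOnce <- function(chars, quals, adapter, polyaMinRun, qualityFloor,
                      window, maxAdapterMismatch, adapterSearchLimit) {
  # 1. leading adapter / vector remnant
  if (!is.null(adapter) && nzchar(adapter)) {
    e <- .findAdapter(chars, adapter, maxAdapterMismatch, adapterSearchLimit)
    if (e > 0L) {
      chars <- chars[-seq_len(e)]
      if (!is.null(quals)) quals <- quals[-seq_len(e)]
    }
  }
  # 2. 3' clip at first sliding window of mean quality < floor
  if (!is.null(quals) && length(quals) >= window) {
    means <- stats::filter(quals, rep(1 / window, window), sides = 1)
    bad <- which(!is.na(means) & means < qualityFloor)
    if (length(bad)) {
      cut <- bad[1L] - window  # keep bases before the offending window
      chars <- chars[seq_len(max(cut, 0L))]
      quals <- quals[seq_len(max(cut, 0L))]
    }
  }
  # 3. terminal mononucleotide runs: 5' polyT, 3' polyA
  rT <- .runLength(chars, "T", fromEnd = FALSE)
  if (rT >= polyaMinRun) {
    chars <- chars[-seq_len(rT)]
    if (!is.null(quals)) quals <- quals[-seq_len(rT)]
  }
  rA <- .runLength(chars, "A", fromEnd = TRUE)
  if (rA >= polyaMinRun && length(chars) > 0L) {
    keep <- seq_len(length(chars) - rA)
    chars <- chars[keep]
    if (!is.null(quals)) quals <- quals[keep]
  }
  list(chars = chars, quals = quals)
}

#' Trim one EST read
#'
#' Applies the classic EST cleanup rules: removal of a leading
#' vector/adapter remnant (allowing up to \code{maxAdapterMismatch}
#' substitutions within the first \code{adapterSearchLimit} bases), 3'
#' clipping at the first sliding window whose mean quality drops below
#' \code{qualityFloor} (skipped when no qualities are given), and removal
#' of terminal mononucleotide runs (3' polyA / 5' polyT of at least
#' \code{polyaMinRun} bases).  Rules are iterated to a fixed point, so
#' trimming is idempotent.  Reads shorter than \code{minLength} after
#' trimming are rejected with a reason code.
#'
#' @param sequence Read sequence (character over A/C/G/T/N).
#' @param qualities Optional integer vector of per-base quality scores.
#' @param adapter Adapter/vector sequence to strip from the 5' end
#'   (\code{NULL} or \code{""} to skip).
#' @param minLength Minimum retained length (default 100 nt).
#' @param polyaMinRun Minimum terminal run length treated as a tail.
#' @param qualityFloor Mean window quality below which the 3' end is
#'   clipped.
#' @param window Sliding window width for quality clipping.
#' @param maxAdapterMismatch Substitutions tolerated in the adapter copy.
#' @param adapterSearchLimit Adapter search restricted to this many
#'   leading bases.
#' @return List with \code{sequence}, \code{qualities}, \code{rejected}
#'   (logical) and \code{reason} (\code{NA}, \code{"short"} or
#'   \code{"empty"}).
#' @examples
#' trimRead(paste0(strrep("ACGT", 40), strrep("A", 20)))$sequence
#' @export
trimRead <- function(sequence, qualities = NULL, adapter = NULL,
                     minLength = 100, polyaMinRun = 8, qualityFloor = 15,
                     window = 10, maxAdapterMismatch = 2,
                     adapterSearchLimit = 50) {
  if (minLength < 1) stop("minLength must be >= 1")
  if (grepl("[^ACGTN]", sequence))
    stop("sequence contains characters outside {A,C,G,T,N}")
  chars <- seqToChars(sequence)
  quals <- qualities
  repeat {
    before <- length(chars)
    out <- .trimOnce(chars, quals, adapter, polyaMinRun, qualityFloor,
                     window, maxAdapterMismatch, adapterSearchLimit)
    chars <- out$chars
    quals <- out$quals
    if (length(chars) == before || length(chars) == 0L) break
  }
  s <- charsToSeq(chars)
  if (length(chars) == 0L)
    return(list(sequence = "", qualities = NULL, rejected = TRUE,
                reason = "empty"))
  if (length(chars) < minLength)
    return(list(sequence = s, qualities = quals, rejected = TRUE,
                reason = "short"))
  list(sequence = s, qualities = quals, rejected = FALSE, reason = NA_character_)
}

#' Trim every read of an EstSet
#'
#' Vectorized driver for \code{\link{trimRead}}.
#'
#' @param ests An \code{\linkS4class{EstSet}}.
#' @param ... Passed to \code{\link{trimRead}}.
#' @return List with \code{ests} (trimmed \code{EstSet}, rejected reads
#'   dropped) and \code{rejected} (data.frame: \code{read_id},
#'   \code{reason}).
#' @export
trimReads <- function(ests, ...) {
  seqs <- as.character(estSequences(ests))
  quals <- estQualities(ests)
  hasQ <- length(quals) > 0L
  out <- lapply(seq_along(seqs), function(i)
    trimRead(seqs[[i]], qualities = if (hasQ) quals[[i]] else NULL, ...))
  rej <- vapply(out, `[[`, logical(1), "rejected")
  rejected <- data.frame(
    read_id = names(seqs)[rej],
    reason = vapply(out[rej], `[[`, character(1), "reason"))
  keep <- which(!rej)
  trimmedSeqs <- vapply(out[keep], `[[`, character(1), "sequence")
  names(trimmedSeqs) <- names(seqs)[keep]
  newQuals <- if (hasQ) lapply(out[keep], `[[`, "qualities") else list()
  trimmed <- EstSet(DNAStringSet(trimmedSeqs),
                    libraries = ests@libraries[keep],
                    qualities = newQuals,
                    conditions = ests@conditions)
  list(ests = trimmed, rejected = rejected)
}

#' Screen clusters for bacterial contamination from a similarity hit table
#'
#' A cluster is flagged as contaminant when it has at least one hit that
#' is both highly significant and highly identical: e-value at or below
#' \code{evalueCut} and percent identity strictly above \code{identityCut}.
#' The published rule prints the e-value inequality the other way around;
#' weaker hits indicating contamination is incoherent, so the significant
#' direction is the default and \code{flagWeakerHits} restores the printed
#' one.
#'
#' @param clusterIds Character vector of all cluster ids to partition.
#' @param hits Data frame with columns \code{query_id}, \code{evalue},
#'   \code{pct_identity} (e.g. from \code{\link{readBlastTab}}).
#' @param evalueCut E-value threshold (default \code{1e-40}).
#' @param identityCut Percent identity threshold (default 80).
#' @param flagWeakerHits If \code{TRUE}, flag hits with evalue
#'   \emph{greater} than the cut instead.
#' @return List with \code{clean} and \code{contaminant} character
#'   vectors; disjoint and together covering \code{clusterIds}.  Clusters
#'   without hits are clean.
#' @examples
#' hits <- data.frame(query_id = "c1", evalue = 1e-50, pct_identity = 85)
#' screenContaminants(c("c1", "c2"), hits)
#' @export
screenContaminants <- function(clusterIds, hits, evalueCut = 1e-40,
                               identityCut = 80, flagWeakerHits = FALSE) {
  if (nrow(hits) > 0 && !all(hits$query_id %in% clusterIds))
    stop("hits reference unknown cluster ids")
  eOk <- if (flagWeakerHits) hits$evalue > evalueCut else hits$evalue <= evalueCut
  bad <- unique(hits$query_id[eOk & hits$pct_identity > identityCut])
  list(clean = setdiff(clusterIds, bad),
       contaminant = intersect(clusterIds, bad))
}
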