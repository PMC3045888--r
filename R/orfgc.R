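# CDS/UTR annotation on consensus sequences; GC and GC3 profiling

# all ORFs in one frame of one strand-oriented sequence; returns a
# data.frame of 0-based half-open [start, end) spans (stop codon included
# when present)
.frameOrfs <- function(chars, frame) {
  n <- length(chars)
  starts <- seq.int(frame + 1L, n - 2L, by = 3L)
  if (length(starts) == 0L) return(NULL)
  codons <- paste0(chars[starts], chars[starts + 1L], chars[starts + 2L])
  isStop <- codons %in% STOPS
  isAtg <- codons == "ATG"
  orfs <- NULL
  i <- 1L
  while (i <= length(codons)) {
    if (isAtg[i]) {
      j <- i
      while (j <= length(codons) && !isStop[j]) j <- j + 1L
      hasStop <- j <= length(codons)
      endCodon <- if (hasStop) j else length(codons)
      orfs <- rbind(orfs, data.frame(
        start = starts[i] - 1L,
        end = starts[endCodon] + 2L,
        has_stop = hasStop))
      i <- if (hasStop) j + 1L else length(codons) + 1L
    } else i <- i + 1L
  }
  orfs
}

# longest stop-free stretch of codons in a frame (fallback when no ATG)
.stopFreeSpan <- function(chars, frame) {
  n <- length(chars)
  starts <- seq.int(frame + 1L, n - 2L, by = 3L)
  if (length(starts) == 0L) return(c(0L, 0L))
  codons <- paste0(chars[starts], chars[starts + 1L], chars[starts + 2L])
  isStop <- codons %in% STOPS
  best <- c(0L, 0L); run <- 0L; runStart <- 1L
  for (i in seq_along(codons)) {
    if (isStop[i]) { run <- 0L; runStart <- i + 1L }
    else {
      run <- run + 1L
      if (run * 3L > best[2] - best[1])
        best <- c(starts[runStart] - 1L, starts[i] + 2L)
    }
  }
  best
}

#' Predict the CDS/UTR structure of a consensus sequence
#'
#' Without a guide, scans all six frames for open reading frames that
#' start at an ATG and end at a stop codon (or at the sequence end) and
#' keeps the longest.  With a guide (e.g. a similarity-derived frame and
#' strand), the ORF is anchored in that frame: the 5' end is expanded to
#' the nearest upstream in-frame ATG and the 3' end to the next in-frame
#' stop.  When no frame contains an ATG the longest stop-free frame is
#' annotated with \code{full_length = FALSE} and reason \code{"no_atg"}.
#'
#' Coordinates are 0-based half-open on the consensus as given; for
#' \code{strand == "-"} they refer to the reverse complement (use
#' \code{\link{extractCds}} to obtain the coding sequence).
#'
#' @param consensus Consensus nucleotide sequence (length >= 3).
#' @param guide Optional list \code{list(frame =, strand =)} fixing the
#'   reading frame.
#' @return One-row data.frame: \code{frame} (0/1/2), \code{strand},
#'   \code{cds_start}, \code{cds_end}, \code{utr5_len}, \code{utr3_len},
#'   \code{full_length}, \code{reason}.
#' @examples
#' predictCds("AAATGGCGTAGAA")  # cds [2,11), UTRs 2 and 2
#' @export
predictCds <- function(consensus, guide = NULL) {
  if (nchar(consensus) < 3L) stop("consensus must be >= 3 nt")
  strands <- if (is.null(guide)) c("+", "-") else guide$strand
  frames <- if (is.null(guide)) 0:2 else guide$frame
  best <- NULL
  for (st in strands) {
    s <- if (st == "+") consensus else revComp(consensus)
    chars <- seqToChars(s)
    for (fr in frames) {
      orfs <- .frameOrfs(chars, fr)
      if (is.null(orfs)) next
      for (i in seq_len(nrow(orfs))) {
        len <- orfs$end[i] - orfs$start[i]
        if (is.null(best) || len > best$len) {
          best <- list(len = len, frame = fr, strand = st,
                       start = orfs$start[i], end = orfs$end[i],
                       has_stop = orfs$has_stop[i], seqlen = length(chars))
        }
      }
    }
  }
  if (is.null(best)) {
    # no ATG anywhere: report the longest stop-free frame
    bestSpan <- NULL
    for (st in strands) {
      s <- if (st == "+") consensus else revComp(consensus)
      chars <- seqToChars(s)
      for (fr in frames) {
        sp <- .stopFreeSpan(chars, fr)
        if (is.null(bestSpan) || (sp[2] - sp[1]) > (bestSpan$end - bestSpan$start))
          bestSpan <- list(frame = fr, strand = st, start = sp[1],
                           end = sp[2], seqlen = length(chars))
      }
    }
    return(data.frame(frame = bestSpan$frame, strand = bestSpan$strand,
                      cds_start = bestSpan$start, cds_end = bestSpan$end,
                      utr5_len = bestSpan$start,
                      utr3_len = bestSpan$seqlen - bestSpan$end,
                      full_length = FALSE, reason = "no_atg",
                      stringsAsFactors = FALSE))
  }
  data.frame(frame = best$frame, strand = best$strand,
             cds_start = best$start, cds_end = best$end,
             utr5_len = best$start, utr3_len = best$seqlen - best$end,
             full_length = best$has_stop, reason = NA_character_,
             stringsAsFactors = FALSE)
}

#' Extract the coding sequence described by a CDS annotation
#'
#' @param consensus The consensus the annotation was computed on.
#' @param annotation One-row data.frame from \code{\link{predictCds}}.
#' @return The CDS as a character string (reverse-complemented for minus
#'   strand annotations).
#' @export
extractCds <- function(consensus, annotation) {
  s <- if (annotation$strand == "+") consensus else revComp(consensus)
  substr(s, annotation$cds_start + 1L, annotation$cds_end)
}

#' GC and GC3 composition of a coding sequence
#'
#' \code{gc} is the overall G+C fraction of the sequence; \code{gc3} is
#' the fraction of codons whose third position is G or C.  The terminal
#' stop codon, whose third position is constrained, is excluded from GC3
#' unless \code{includeStop = TRUE}.
#'
#' @param cds Coding sequence; length must be divisible by 3.
#' @param includeStop Keep a terminal stop codon in the GC3 denominator.
#' @return List with \code{gc} and \code{gc3}, both in [0, 1].
#' @examples
#' gcMetrics("ATGGCG")  # gc = 4/6, gc3 = 1
#' @export
gcMetrics <- function(cds, includeStop = FALSE) {
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length must be divisible by 3")
  ch <- seqToChars(cds)
  gc <- mean(ch %in% c("G", "C"))
  third <- ch[seq.int(3L, n, by = 3L)]
  lastCodon <- substr(cds, n - 2L, n)
  if (!includeStop && lastCodon %in% STOPS && length(third) > 1L)
    third <- third[-length(third)]
  list(gc = gc, gc3 = mean(third %in% c("G", "C")))
}

#' Smoothed class histogram of composition values
#'
#' Bins values in [0, 1] into \code{nClasses} equal classes and smooths
#' the class heights with a three-class moving average; the edge classes
#' average the two available neighbors.
#'
#' @param values Numeric vector of fractions in [0, 1].
#' @param nClasses Number of classes (default 100).
#' @return List with \code{mids} (class centers), \code{raw} (counts) and
#'   \code{smoothed} heights.
#' @export
smoothedHistogram <- function(values, nClasses = 100) {
  if (length(values) == 0L) stop("values must be nonempty")
  if (any(values < 0 | values > 1)) stop("values must lie in [0, 1]")
  breaks <- seq(0, 1, length.out = nClasses + 1L)
  cls <- pmin(pmax(findInterval(values, breaks, rightmost.closed = TRUE), 1L),
              nClasses)
  raw <- tabulate(cls, nbins = nClasses)
  sm <- numeric(nClasses)
  for (i in seq_len(nClasses)) {
    lo <- max(1L, i - 1L); hi <- min(nClasses, i + 1L)
    sm[i] <- mean(raw[lo:hi])
  }
  list(mids = (breaks[-1L] + breaks[-length(breaks)]) / 2,
       raw = raw, smoothed = sm)
}

#' Annotate every contig consensus and profile GC composition
#'
#' @param contigs A \code{\linkS4class{ContigSet}} (singlets included).
#' @param includeSinglets Annotate singlets as well (default TRUE).
#' @return List with \code{annotations} (data.frame, one row per
#'   sequence: id + \code{\link{predictCds}} columns + \code{gc_cds},
#'   \code{gc3}, \code{gc_consensus}) and \code{gc3_histogram} from
#'   \code{\link{smoothedHistogram}} over full-length CDS annotations.
#' @export
annotateCds <- function(contigs, includeSinglets = TRUE) {
  seqs <- as.character(contigConsensus(contigs))
  if (includeSinglets)
    seqs <- c(seqs, as.character(contigSinglets(contigs)))
  rows <- lapply(names(seqs), function(id) {
    ann <- predictCds(seqs[[id]])
    cds <- extractCds(seqs[[id]], ann)
    g <- if (nchar(cds) >= 3L && nchar(cds) %% 3L == 0L)
      gcMetrics(cds) else list(gc = NA_real_, gc3 = NA_real_)
    chAll <- seqToChars(seqs[[id]])
    cbind(data.frame(id = id, stringsAsFactors = FALSE), ann,
          data.frame(gc_cds = g$gc, gc3 = g$gc3,
                     gc_consensus = mean(chAll %in% c("G", "C"))))
  })
  annotations <- do.call(rbind, rows)
  fl <- annotations[annotations$full_length & !is.na(annotations$gc3), ]
  hist <- if (nrow(fl) > 0L) smoothedHistogram(fl$gc3) else NULL
  list(annotations = annotations, gc3_histogram = hist)
}
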