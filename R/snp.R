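# haplotype-filtered SNP detection, classification, synonymy and KA/KS

#' Build the read-by-position alignment matrix of a contig
#'
#' @param contigs A \code{\linkS4class{ContigSet}}.
#' @param contigId Contig id.
#' @param ests The \code{\linkS4class{EstSet}} holding the member reads.
#' @return List with \code{aln} (character matrix, rows = member reads,
#'   columns = consensus positions, \code{"-"} where a read does not
#'   cover) and \code{qualities} (matching integer matrix or \code{NULL}).
#' @export
contigAlignment <- function(contigs, contigId, ests) {
  m <- contigMembers(contigs)[[match(contigId, names(contigConsensus(contigs)))]]
  width <- nchar(as.character(contigConsensus(contigs)[[contigId]]))
  aln <- matrix("-", nrow = nrow(m), ncol = width,
                dimnames = list(m$read_id, NULL))
  quals <- estQualities(ests)
  hasQ <- length(quals) > 0L
  qm <- if (hasQ) matrix(NA_integer_, nrow = nrow(m), ncol = width,
                         dimnames = list(m$read_id, NULL)) else NULL
  seqs <- as.character(estSequences(ests))
  for (i in seq_len(nrow(m))) {
    rid <- m$read_id[i]
    s <- seqs[[rid]]
    q <- if (hasQ) quals[[rid]] else NULL
    if (m$strand[i] == "-") {
      s <- revComp(s)
      if (!is.null(q)) q <- rev(q)
    }
    ch <- seqToChars(s)
    idx <- m$offset[i] + seq_along(ch)
    keep <- idx >= 1L & idx <= width
    aln[i, idx[keep]] <- ch[keep]
    if (!is.null(q)) qm[i, idx[keep]] <- q[keep]
  }
  list(aln = aln, qualities = qm)
}

.alleleCounts <- function(col, qcol, qualityFloor) {
  ok <- col %in% BASES
  if (!is.null(qcol)) ok <- ok & !is.na(qcol) & qcol >= qualityFloor
  if (!any(ok)) return(integer(0))
  sort(table(col[ok]), decreasing = TRUE)
}

#' Detect reliable SNPs in a contig alignment
#'
#' Implements a haplotype-based three-filter strategy.  Filter 1 screens
#' alignment columns with at least two observed alleles, discarding bases
#' below \code{qualityFloor} when qualities exist.  Filter 2 partitions
#' the reads into haplotypes by their allele vectors over the candidate
#' columns; haplotypes consisting of a single sequence are removed, so
#' isolated single-read alleles that are not linked to other
#' polymorphisms are never called.  Filter 3 scores each remaining column
#' by redundancy and allele balance, \code{confidence = (1 - 1/d) * (2 *
#' minor / d)} with \code{d} the column depth, and drops calls below
#' \code{confidenceFloor}.  Contigs whose two largest haplotype groups
#' show more than \code{paralogDivergenceCut} fixed differences per 100
#' aligned bases are flagged as collapsed paralogs.
#'
#' @param aln Character alignment matrix from
#'   \code{\link{contigAlignment}} (rows = reads, \code{"-"} = no
#'   coverage), or the list that function returns.
#' @param qualities Optional integer matrix matching \code{aln}.
#' @param minReads Minimum reads in the contig (default 4: two expected
#'   copies per allele).
#' @param minAlleleSupport Minimum reads supporting an allele (default 2).
#' @param confidenceFloor Minimum confidence score (default 0.2).
#' @param paralogDivergenceCut Fixed differences per 100 bp above which
#'   the contig is flagged (default 3).
#' @param qualityFloor Base quality below which a base supports no allele.
#' @return List: \code{calls} (data.frame: \code{position} 0-based,
#'   \code{alleles} \code{"C:2,T:2"}-style support string,
#'   \code{allelic_class}, \code{mutation_class}, \code{confidence},
#'   \code{synonymy} = \code{NA} until labelled), \code{haplotypes} (list
#'   of read-id vectors of the surviving haplotypes),
#'   \code{paralog_flag}, and \code{reason} (\code{"below_min_reads"}
#'   when the contig was not screened).
#' @export
detectSnps <- function(aln, qualities = NULL, minReads = 4,
                       minAlleleSupport = 2, confidenceFloor = 0.2,
                       paralogDivergenceCut = 3, qualityFloor = 20) {
  if (is.list(aln) && !is.matrix(aln)) {
    qualities <- aln$qualities
    aln <- aln$aln
  }
  empty <- data.frame(position = integer(0), alleles = character(0),
                      allelic_class = character(0),
                      mutation_class = character(0),
                      confidence = numeric(0), synonymy = character(0))
  if (nrow(aln) < minReads)
    return(list(calls = empty, haplotypes = list(), paralog_flag = FALSE,
                reason = "below_min_reads"))

  # Filter 1: candidate columns with >= 2 quality-passing alleles
  candidate <- integer(0)
  for (j in seq_len(ncol(aln))) {
    cnt <- .alleleCounts(aln[, j], if (is.null(qualities)) NULL
                         else qualities[, j], qualityFloor)
    if (length(cnt) >= 2L) candidate <- c(candidate, j)
  }
  if (length(candidate) == 0L)
    return(list(calls = empty, haplotypes = list(), paralog_flag = FALSE,
                reason = NA_character_))

  # Filter 2: haplotype partition; singleton haplotypes removed
  vecs <- apply(aln[, candidate, drop = FALSE], 1L, function(r) {
    r[!r %in% BASES] <- "."
    paste(r, collapse = "")
  })
  groups <- split(rownames(aln), vecs)
  surviving <- groups[vapply(groups, length, integer(1)) >= 2L]
  survivors <- unlist(surviving, use.names = FALSE)

  calls <- empty
  if (length(survivors) >= 2L) {
    sub <- aln[survivors, , drop = FALSE]
    subQ <- if (!is.null(qualities)) qualities[survivors, , drop = FALSE]
      else NULL
    makeCall <- function(j, cnt, kept) {
      d <- sum(cnt)
      minor <- as.integer(kept[2L])
      conf <- (1 - 1 / d) * (2 * minor / d)   # Filter 3
      if (conf < confidenceFloor) return(NULL)
      nAll <- length(kept)
      mclass <- if (nAll > 2L) "multi"
        else if (isTransition(names(kept)[1], names(kept)[2]))
          "transition" else "transversion"
      data.frame(
        position = j - 1L,
        alleles = paste(sprintf("%s:%d", names(kept), as.integer(kept)),
                        collapse = ","),
        allelic_class = c("bi", "tri", "tetra")[min(nAll, 4L) - 1L],
        mutation_class = mclass,
        confidence = conf, synonymy = NA_character_,
        stringsAsFactors = FALSE)
    }
    pending <- list()   # columns whose minor allele has support 1
    for (j in candidate) {
      cnt <- .alleleCounts(sub[, j], if (is.null(subQ)) NULL else subQ[, j],
                           qualityFloor)
      strong <- cnt[cnt >= minAlleleSupport]
      if (length(strong) >= 2L) {
        cl <- makeCall(j, cnt, strong)
        if (!is.null(cl)) calls <- rbind(calls, cl)
      } else if (length(strong) == 1L && any(cnt == 1L)) {
        pending[[length(pending) + 1L]] <- list(j = j, cnt = cnt)
      }
    }
    # linked-singleton clause: a support-1 minor allele carried by a read
    # of a surviving haplotype is kept when the contig has other called
    # SNPs defining that haplotype
    if (length(pending) && nrow(calls) > 0L) {
      for (p in pending) {
        singles <- names(p$cnt)[p$cnt == 1L]
        carried <- vapply(singles, function(a)
          any(sub[, p$j] == a), logical(1))
        kept <- p$cnt[p$cnt >= minAlleleSupport | (p$cnt == 1L & carried)]
        if (length(kept) >= 2L) {
          cl <- makeCall(p$j, p$cnt, sort(kept, decreasing = TRUE))
          if (!is.null(cl)) calls <- rbind(calls, cl)
        }
      }
      calls <- calls[order(calls$position), , drop = FALSE]
    }
  }

  # paralog screen: fixed differences between the two largest haplotypes
  paralog <- FALSE
  if (length(surviving) >= 2L) {
    sizes <- vapply(surviving, length, integer(1))
    top <- names(sort(sizes, decreasing = TRUE))[1:2]
    g1 <- aln[surviving[[top[1]]], , drop = FALSE]
    g2 <- aln[surviving[[top[2]]], , drop = FALSE]
    fixedDiff <- 0L
    for (j in seq_len(ncol(aln))) {
      a <- unique(g1[, j]); a <- a[a %in% BASES]
      b <- unique(g2[, j]); b <- b[b %in% BASES]
      if (length(a) == 1L && length(b) == 1L && a != b)
        fixedDiff <- fixedDiff + 1L
    }
    paralog <- fixedDiff * 100 / ncol(aln) > paralogDivergenceCut
  }

  list(calls = calls, haplotypes = unname(surviving),
       paralog_flag = paralog, reason = NA_character_)
}

#' Summarize SNP calls over a screened dataset
#'
#' @param calls Data frame of calls carrying a \code{contig_id} column
#'   (rbind of per-contig \code{\link{detectSnps}} results).
#' @param screenedBases Named numeric: aligned consensus length of every
#'   SNP-screened contig (zero-call contigs included).
#' @return List: \code{n_snps}, \code{transitions}, \code{transversions},
#'   \code{ts_tv_ratio}, \code{allelic_class_pct} (percentages),
#'   \code{density_per_100bp} (SNPs x 100 / screened bases) and
#'   \code{frac_contigs_with_snp}.
#' @export
summarizeSnps <- function(calls, screenedBases) {
  ts <- sum(calls$mutation_class == "transition")
  tv <- sum(calls$mutation_class == "transversion")
  cls <- table(factor(calls$allelic_class, levels = c("bi", "tri", "tetra")))
  clsPct <- stats::setNames(100 * as.numeric(cls) / max(nrow(calls), 1L),
                            names(cls))
  list(
    n_snps = nrow(calls),
    transitions = ts,
    transversions = tv,
    ts_tv_ratio = if (tv > 0) ts / tv else NA_real_,
    allelic_class_pct = clsPct,
    density_per_100bp = nrow(calls) * 100 / sum(screenedBases),
    frac_contigs_with_snp =
      mean(names(screenedBases) %in% calls$contig_id)
  )
}

#' Label SNP calls as synonymous, nonsynonymous or noncoding
#'
#' Positions outside the annotated CDS are \code{noncoding}.  Inside it,
#' each alternate allele is substituted into its codon and translated:
#' when every alternate preserves the amino acid the call is
#' \code{synonymous}, when every alternate changes it the call is
#' \code{nonsynonymous}, and a tri-/tetra-allelic call with mixed effects
#' is \code{ambiguous}.
#'
#' @param calls \code{calls} data.frame from \code{\link{detectSnps}}.
#' @param annotation One-row data.frame from \code{\link{predictCds}} for
#'   the same contig.
#' @param consensus The contig consensus sequence.
#' @return \code{calls} with the \code{synonymy} column filled.
#' @export
labelSynonymy <- function(calls, annotation, consensus) {
  if (nrow(calls) == 0L) return(calls)
  n <- nchar(consensus)
  if (any(calls$position >= n)) stop("SNP position beyond consensus length")
  s <- if (annotation$strand == "+") consensus else revComp(consensus)
  tab <- codonTable()
  for (i in seq_len(nrow(calls))) {
    p <- calls$position[i]                       # 0-based on consensus
    pc <- if (annotation$strand == "+") p else n - 1L - p  # coding orient.
    if (pc < annotation$cds_start || pc >= annotation$cds_end) {
      calls$synonymy[i] <- "noncoding"
      next
    }
    off <- pc - annotation$cds_start
    codonStart <- annotation$cds_start + 3L * (off %/% 3L)
    codon <- substr(s, codonStart + 1L, codonStart + 3L)
    within <- off %% 3L + 1L
    alleles <- sub(":.*", "", strsplit(calls$alleles[i], ",")[[1]])
    if (annotation$strand == "-")
      alleles <- c(A = "T", C = "G", G = "C", T = "A")[alleles]
    refBase <- substr(codon, within, within)
    alts <- setdiff(alleles, refBase)
    if (length(alts) == 0L) {
      calls$synonymy[i] <- "synonymous"
      next
    }
    refAA <- tab[codon]
    effects <- vapply(alts, function(a) {
      mut <- codon
      substr(mut, within, within) <- a
      identical(unname(tab[mut]), unname(refAA))
    }, logical(1))
    calls$synonymy[i] <- if (all(effects)) "synonymous"
      else if (all(!effects)) "nonsynonymous" else "ambiguous"
  }
  calls
}

#' Synonymous and nonsynonymous site counts of a CDS
#'
#' Per-codon fractional site counting: each codon position contributes
#' the fraction of its three possible substitutions that preserve the
#' encoded amino acid to S, and the remainder to N, so that
#' \code{S + N = 3 * codons}.
#'
#' @param cds Coding sequence, length divisible by 3.
#' @return Named numeric \code{c(S =, N =)}.
#' @export
synonymousSites <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L || n == 0L) stop("CDS length must be a positive multiple of 3")
  tab <- codonTable()
  S <- 0
  starts <- seq.int(1L, n, by = 3L)
  for (cs in starts) {
    codon <- substr(cds, cs, cs + 2L)
    aa <- tab[codon]
    for (pos in 1:3) {
      ref <- substr(codon, pos, pos)
      for (b in setdiff(BASES, ref)) {
        mut <- codon
        substr(mut, pos, pos) <- b
        if (identical(unname(tab[mut]), unname(aa))) S <- S + 1 / 3
      }
    }
  }
  c(S = S, N = 3 * length(starts) - S)
}

#' KA/KS from labelled SNP calls of one contig
#'
#' KA is the nonsynonymous SNP count divided by the nonsynonymous site
#' count of the consensus CDS, KS the synonymous analogue; the ratio is
#' undefined (NA) when KS is zero.  Proportions are uncorrected:
#' within-contig allelic divergence is small enough that multiple-hit
#' correction is unnecessary.
#'
#' @param calls Labelled calls from \code{\link{labelSynonymy}}.
#' @param annotation One-row data.frame from \code{\link{predictCds}}.
#' @param consensus The contig consensus.
#' @return List: \code{ka}, \code{ks}, \code{ratio} (NA when undefined),
#'   \code{S}, \code{N}.
#' @export
computeKaKs <- function(calls, annotation, consensus) {
  cds <- extractCds(consensus, annotation)
  if (nchar(cds) < 3L) stop("no CDS available for KA/KS")
  sites <- synonymousSites(cds)
  nSyn <- sum(calls$synonymy == "synonymous", na.rm = TRUE)
  nNon <- sum(calls$synonymy == "nonsynonymous", na.rm = TRUE)
  ka <- nNon / sites[["N"]]
  ks <- nSyn / sites[["S"]]
  list(ka = ka, ks = ks,
       ratio = if (ks > 0) ka / ks else NA_real_,
       S = sites[["S"]], N = sites[["N"]])
}
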