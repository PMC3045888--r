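# greedy seed-and-extend EST clustering at published overlap parameters

.kmerSet <- function(s, k, step = 1L) {
  n <- nchar(s)
  if (n < k) return(character(0))
  starts <- seq.int(1L, n - k + 1L, by = step)
  unique(substring(s, starts, starts + k - 1L))
}

# majority-rule consensus; ties broken alphabetically (A<C<G<T); columns
# with no A/C/G/T coverage become N
.consensusFromMembers <- function(members, readChars) {
  width <- 0L
  for (i in seq_len(nrow(members)))
    width <- max(width, members$offset[i] +
                   length(readChars[[members$read_id[i]]]))
  counts <- matrix(0L, nrow = 4L, ncol = width, dimnames = list(BASES, NULL))
  for (i in seq_len(nrow(members))) {
    ch <- readChars[[members$read_id[i]]]
    idx <- members$offset[i] + seq_along(ch)
    keep <- ch %in% BASES
    if (any(keep)) {
      ii <- cbind(match(ch[keep], BASES), idx[keep])
      agg <- rowsum(rep(1L, nrow(ii)), group = (ii[, 2] - 1L) * 4L + ii[, 1])
      pos <- as.integer(rownames(agg))
      counts[pos] <- counts[pos] + agg[, 1]
    }
  }
  cons <- BASES[max.col(t(counts), ties.method = "first")]
  cons[colSums(counts) == 0L] <- "N"
  charsToSeq(cons)
}

.overlapAlign <- function(readSeq, consensus) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(readSeq, consensus, type = "overlap",
                                      substitutionMatrix = mat,
                                      gapOpening = 5, gapExtension = 1)
  alnLen <- nchar(as.character(Biostrings::pattern(pa)))
  if (alnLen == 0L)
    return(list(len = 0L, identity = 0, offset = 0L))
  id <- Biostrings::nmatch(pa) / alnLen
  pStart <- Biostrings::pattern(pa)@range@start
  sStart <- Biostrings::subject(pa)@range@start
  list(len = alnLen, identity = id, offset = sStart - pStart)
}

#' Cluster trimmed ESTs into contigs and singlets
#'
#' Greedy agglomeration in the spirit of classic EST assembly: reads are
#' taken longest-first; each read joins the first existing cluster (in
#' creation order) with which its best overlap alignment spans at least
#' \code{minOverlap} bases at identity at least \code{minIdentity}
#' (defaults: the published 40 bases / 90\%); otherwise it founds a new
#' cluster.  Overlaps are found by shared k-mer seeding followed by
#' ends-free pairwise alignment (affine gaps, open 5 / extend 1); identity
#' is matches over alignment length.  Consensus is the column-wise
#' majority with ties broken alphabetically.  Reverse-complement joining
#' is attempted when the forward orientation fails.
#'
#' @param ests An \code{\linkS4class{EstSet}} of trimmed reads.
#' @param minIdentity Minimum overlap identity (fraction, default 0.90).
#' @param minOverlap Minimum overlap length in bases (default 40).
#' @param checkRevComp Also try the reverse complement of each read.
#' @param k Seed k-mer length (default 12).
#' @return A \code{\linkS4class{ContigSet}}; every input read appears in
#'   exactly one contig or as one singlet.
#' @examples
#' es <- EstSet(c(a = strrep("ACGGT", 40), b = strrep("ACGGT", 40)), "L1")
#' clusterEsts(es)
#' @export
clusterEsts <- function(ests, minIdentity = 0.90, minOverlap = 40,
                        checkRevComp = TRUE, k = 12) {
  if (length(ests) == 0L) stop("reads must be nonempty")
  seqs <- as.character(estSequences(ests))
  ord <- order(-nchar(seqs), seq_along(seqs))
  seqs <- seqs[ord]
  readChars <- lapply(seqs, seqToChars)
  rcCache <- new.env(parent = emptyenv())

  clusters <- list()        # each: list(members = df, consensus = chr)
  index <- new.env(parent = emptyenv(), size = 4096L)

  addToIndex <- function(ci, consensus) {
    for (km in .kmerSet(consensus, k, step = 4L)) {
      cur <- index[[km]]
      if (is.null(cur)) index[[km]] <- ci
      else if (!ci %in% cur) index[[km]] <- c(cur, ci)
    }
  }

  for (ri in seq_along(seqs)) {
    rid <- names(seqs)[ri]
    s <- seqs[[ri]]
    rc <- if (checkRevComp) revComp(s) else NULL
    kms <- .kmerSet(s, k)
    if (!is.null(rc)) kms <- unique(c(kms, .kmerSet(rc, k)))
    cand <- integer(0)
    for (km in kms) {
      hit <- index[[km]]
      if (!is.null(hit)) cand <- c(cand, hit)
    }
    cand <- sort(unique(cand))
    placed <- FALSE
    for (ci in cand) {
      cons <- clusters[[ci]]$consensus
      aln <- .overlapAlign(s, cons)
      strand <- "+"
      useSeq <- s
      if ((aln$len < minOverlap || aln$identity < minIdentity) &&
          !is.null(rc)) {
        aln2 <- .overlapAlign(rc, cons)
        if (aln2$len >= minOverlap && aln2$identity >= minIdentity) {
          aln <- aln2; strand <- "-"; useSeq <- rc
        }
      }
      if (aln$len >= minOverlap && aln$identity >= minIdentity) {
        if (strand == "-") readChars[[rid]] <- seqToChars(useSeq)
        m <- clusters[[ci]]$members
        m <- rbind(m, data.frame(read_id = rid, offset = aln$offset,
                                 strand = strand, stringsAsFactors = FALSE))
        shift <- min(m$offset)
        if (shift < 0L) m$offset <- m$offset - shift
        clusters[[ci]]$members <- m
        clusters[[ci]]$consensus <- .consensusFromMembers(m, readChars)
        addToIndex(ci, clusters[[ci]]$consensus)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      ci <- length(clusters) + 1L
      clusters[[ci]] <- list(
        members = data.frame(read_id = rid, offset = 0L, strand = "+",
                             stringsAsFactors = FALSE),
        consensus = s)
      addToIndex(ci, s)
    }
  }

  sizes <- vapply(clusters, function(cl) nrow(cl$members), integer(1))
  contigIdx <- which(sizes >= 2L)
  singletIdx <- which(sizes == 1L)
  consensus <- DNAStringSet(vapply(clusters[contigIdx], `[[`, character(1),
                                   "consensus"))
  names(consensus) <- sprintf("Contig%d", seq_along(contigIdx))
  members <- lapply(clusters[contigIdx], `[[`, "members")
  singletIds <- vapply(clusters[singletIdx],
                       function(cl) cl$members$read_id[1], character(1))
  singlets <- DNAStringSet(seqs[singletIds])
  new("ContigSet", consensus = consensus, members = members,
      singlets = singlets)
}

#' Build the contig-by-library EST count matrix
#'
#' Entry (c, L) is the number of member reads of cluster c sequenced from
#' library L; the frequency of a contig over a library is its digital
#' transcript abundance.  Singlets are included as single-count rows, and
#' libraries without any read keep an all-zero column.
#'
#' @param contigs A \code{\linkS4class{ContigSet}}.
#' @param libraries Named character vector mapping read id to library id
#'   (e.g. \code{estLibraries(ests)}).
#' @param libLevels Optional character vector fixing the column set (and
#'   order); defaults to the libraries observed.
#' @return Integer matrix, rows = cluster ids (contigs then singlets),
#'   columns = libraries.  Row sums equal cluster member counts.
#' @export
buildCountMatrix <- function(contigs, libraries, libLevels = NULL) {
  if (is.null(libLevels)) libLevels <- sort(unique(unname(libraries)))
  memb <- contigMembers(contigs)
  ids <- c(names(contigConsensus(contigs)), names(contigSinglets(contigs)))
  m <- matrix(0L, nrow = length(ids), ncol = length(libLevels),
              dimnames = list(ids, libLevels))
  lookup <- function(reads) {
    lib <- libraries[reads]
    if (anyNA(lib)) stop("read with unknown library assignment: ",
                         paste(reads[is.na(lib)][1], collapse = ", "))
    lib
  }
  for (i in seq_along(memb)) {
    tab <- table(lookup(memb[[i]]$read_id))
    if (!all(names(tab) %in% libLevels))
      stop("library outside libLevels: ",
           setdiff(names(tab), libLevels)[1])
    m[i, names(tab)] <- as.integer(tab)
  }
  sIds <- names(contigSinglets(contigs))
  if (length(sIds)) {
    lib <- lookup(sIds)
    for (j in seq_along(sIds))
      m[length(memb) + j, lib[j]] <- 1L
  }
  m
}

#' Summarize an assembly
#'
#' @param contigs A \code{\linkS4class{ContigSet}}.
#' @param libraries Optional named read id -> library id map, enabling
#'   the contigs-per-library distribution.
#' @return List: \code{n_contigs}, \code{n_singlets}, \code{n_clusters},
#'   \code{consensus_length} (mean/min/max over all clusters),
#'   \code{size_histogram} (table of contig member counts),
#'   \code{frac_le20} and \code{frac_lt50} (fraction of contigs with <=
#'   20 and < 50 ESTs), and, when \code{libraries} is given,
#'   \code{libraries_per_contig} (table).
#' @export
assemblySummary <- function(contigs, libraries = NULL) {
  sizes <- vapply(contigMembers(contigs), nrow, integer(1))
  lens <- c(Biostrings::width(contigConsensus(contigs)),
            Biostrings::width(contigSinglets(contigs)))
  out <- list(
    n_contigs = length(contigs),
    n_singlets = length(contigSinglets(contigs)),
    n_clusters = length(contigs) + length(contigSinglets(contigs)),
    consensus_length = c(mean = mean(lens), min = min(lens), max = max(lens)),
    size_histogram = table(sizes),
    frac_le20 = if (length(sizes)) mean(sizes <= 20) else NA_real_,
    frac_lt50 = if (length(sizes)) mean(sizes < 50) else NA_real_
  )
  if (!is.null(libraries)) {
    nlib <- vapply(contigMembers(contigs), function(m)
      length(unique(libraries[m$read_id])), integer(1))
    out$libraries_per_contig <- table(nlib)
  }
  out
}
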