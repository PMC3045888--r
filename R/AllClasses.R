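#' @import methods
#' @importFrom Biostrings DNAStringSet reverseComplement readDNAStringSet
#'   writeXStringSet subseq GENETIC_CODE pairwiseAlignment nmatch nmismatch
#'   pattern subject
#' @importFrom S4Vectors metadata metadata<-
NULL

#' EstSet: a collection of EST reads with library assignments
#'
#' Container for single-pass 5' cDNA reads (ESTs).  Each read carries a
#' library assignment and, optionally, per-base integer quality scores.
#'
#' @slot sequences A \link[Biostrings]{DNAStringSet}, named by read id.
#' @slot libraries Character vector parallel to \code{sequences}: the
#'   cDNA library each read was sequenced from.
#' @slot qualities A list of integer vectors (one per read, same length
#'   as the read) or an empty list when no qualities are available.
#' @slot conditions Named character vector mapping library id to a
#'   condition tag (e.g. \code{"development"}, \code{"stress"}); may be
#'   empty.
#'
#' @seealso \code{\link{EstSet}} constructor, \code{\link{trimReads}},
#'   \code{\link{clusterEsts}}
#' @exportClass EstSet
setClass("EstSet",
  representation(
    sequences = "DNAStringSet",
    libraries = "character",
    qualities = "list",
    conditions = "character"
  )
)

setValidity("EstSet", function(object) {
  msg <- NULL
  n <- length(object@sequences)
  if (length(object@libraries) != n)
    msg <- c(msg, "libraries must be parallel to sequences")
  if (is.null(names(object@sequences)) && n > 0L)
    msg <- c(msg, "sequences must be named by read id")
  if (anyDuplicated(names(object@sequences)))
    msg <- c(msg, "read ids must be unique")
  if (length(object@qualities) > 0L) {
    if (length(object@qualities) != n)
      msg <- c(msg, "qualities must be empty or parallel to sequences")
    else {
      ok <- mapply(function(q, w) is.null(q) || length(q) == w,
                   object@qualities, Biostrings::width(object@sequences))
      if (!all(ok))
        msg <- c(msg, "each quality vector must match its read length")
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct an EstSet
#'
#' @param sequences Named character vector or \code{DNAStringSet} of reads.
#' @param libraries Character vector of library ids, one per read (recycled
#'   if length 1).
#' @param qualities Optional list of integer quality vectors, one per read.
#' @param conditions Optional named character vector: library id ->
#'   condition tag.
#' @return An \code{\linkS4class{EstSet}}.
#' @examples
#' es <- EstSet(c(r1 = "ACGTACGT", r2 = "TTTTACGT"), libraries = "L1")
#' length(es)
#' @export
EstSet <- function(sequences, libraries, qualities = list(),
                   conditions = character()) {
  if (!is(sequences, "DNAStringSet"))
    sequences <- DNAStringSet(sequences)
  if (length(libraries) == 1L && length(sequences) > 1L)
    libraries <- rep(libraries, length(sequences))
  new("EstSet", sequences = sequences, libraries = libraries,
      qualities = qualities, conditions = conditions)
}

#' @describeIn EstSet Number of reads.
#' @param x An \code{EstSet}.
#' @export
setMethod("length", "EstSet", function(x) length(x@sequences))

#' Accessors for EstSet and ContigSet
#'
#' \code{estSequences} returns the reads of an \code{EstSet};
#' \code{estLibraries} the per-read library assignment;
#' \code{estQualities} the per-read quality vectors (empty list when
#' absent); \code{libraryConditions} the library -> condition map.
#'
#' @param x An \code{\linkS4class{EstSet}}.
#' @return See the individual descriptions.
#' @name est-accessors
#' @export
estSequences <- function(x) x@sequences

#' @rdname est-accessors
#' @export
estLibraries <- function(x) {
  stats::setNames(x@libraries, names(x@sequences))
}

#' @rdname est-accessors
#' @export
estQualities <- function(x) x@qualities

#' @rdname est-accessors
#' @export
libraryConditions <- function(x) x@conditions

setMethod("show", "EstSet", function(object) {
  cat("EstSet with", length(object), "reads from",
      length(unique(object@libraries)), "libraries\n")
  if (length(object) > 0L)
    cat("  read length range:",
        paste(range(Biostrings::width(object@sequences)), collapse = "-"),
        "nt\n")
  cat("  qualities:", if (length(object@qualities)) "present" else "absent",
      "\n")
})

#' Subset an EstSet by read id or index
#' @param x An \code{EstSet}.
#' @param i Indices or read ids.
#' @param j,drop,... Ignored.
#' @export
setMethod("[", "EstSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, names(x@sequences))
  q <- if (length(x@qualities)) x@qualities[i] else list()
  new("EstSet", sequences = x@sequences[i], libraries = x@libraries[i],
      qualities = q, conditions = x@conditions)
})

#' ContigSet: the result of EST overlap clustering
#'
#' Holds the contigs (multi-read clusters) and singlets produced by
#' \code{\link{clusterEsts}}.  A "cluster" is either a contig or a
#' singlet; together they are the putative transcripts of the dataset.
#'
#' @slot consensus \code{DNAStringSet} of contig consensus sequences,
#'   named by contig id.
#' @slot members List (one element per contig) of data.frames with
#'   columns \code{read_id}, \code{offset} (0-based start of the read on
#'   the consensus) and \code{strand} (\code{"+"}/\code{"-"}).
#' @slot singlets \code{DNAStringSet} of unassembled reads, named by
#'   read id.
#'
#' @seealso \code{\link{clusterEsts}}, \code{\link{buildCountMatrix}},
#'   \code{\link{assemblySummary}}
#' @exportClass ContigSet
setClass("ContigSet",
  representation(
    consensus = "DNAStringSet",
    members = "list",
    singlets = "DNAStringSet"
  )
)

setValidity("ContigSet", function(object) {
  msg <- NULL
  if (length(object@members) != length(object@consensus))
    msg <- c(msg, "one member table per contig required")
  sizes <- vapply(object@members, nrow, integer(1))
  if (length(sizes) && any(sizes < 2L))
    msg <- c(msg, "contigs must have >= 2 members (singlets go in @singlets)")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn ContigSet Number of contigs (excluding singlets).
#' @param x A \code{ContigSet}.
#' @export
setMethod("length", "ContigSet", function(x) length(x@consensus))

#' @rdname est-accessors
#' @export
contigConsensus <- function(x) x@consensus

#' @rdname est-accessors
#' @export
contigMembers <- function(x) x@members

#' @rdname est-accessors
#' @export
contigSinglets <- function(x) x@singlets

setMethod("show", "ContigSet", function(object) {
  sizes <- vapply(object@members, nrow, integer(1))
  cat("ContigSet:", length(object), "contigs,",
      length(object@singlets), "singlets (",
      length(object) + length(object@singlets), "clusters )\n")
  if (length(object) > 0L) {
    cat("  contig sizes:", paste(range(sizes), collapse = "-"),
        "reads; consensus length:",
        paste(range(Biostrings::width(object@consensus)), collapse = "-"),
        "nt\n")
  }
})
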