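# shared helpers: seeds, sequence strings, small parsers

BASES <- c("A", "C", "G", "T")

# derive a reproducible per-stage sub-seed from a global seed; keeps the
# result a positive 32-bit integer so set.seed() accepts it
substreamSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(seed) * 48271 + h * 9973) %% 2147483587) + 1L
}

seqToChars <- function(s) strsplit(as.character(s), "", fixed = TRUE)[[1]]

charsToSeq <- function(ch) paste(ch, collapse = "")

revComp <- function(s) {
  as.character(reverseComplement(DNAStringSet(s)))
}

# codon table keyed by codon string, value = one-letter amino acid ('*' stop)
codonTable <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

translateCodons <- function(codons) {
  tab <- codonTable()
  aa <- tab[codons]
  aa[is.na(aa)] <- "X"
  unname(aa)
}

isTransition <- function(a, b) {
  (a %in% c("A", "G") && b %in% c("A", "G")) ||
    (a %in% c("C", "T") && b %in% c("C", "T"))
}

# draw a substituted base; transitions favoured by tsTvRatio : 1
mutateBase <- function(base, tsTvRatio = 2) {
  transition <- c(A = "G", G = "A", C = "T", T = "C")[base]
  transversions <- setdiff(BASES, c(base, transition))
  if (stats::runif(1) < tsTvRatio / (tsTvRatio + 1)) unname(transition)
  else sample(transversions, 1L)
}

randomDna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

#' Read a 12-column similarity hit table
#'
#' Parses the tab-separated 12-column tabular format produced by standard
#' sequence-similarity search tools (query, subject, percent identity,
#' alignment length, mismatches, gap opens, query/subject coordinates,
#' e-value, bit score).
#'
#' @param path Path to the tab-separated file (no header).
#' @return A data.frame with the 12 standard columns.
#' @seealso \code{\link{screenContaminants}}
#' @export
readBlastTab <- function(path) {
  cols <- c("query_id", "subject_id", "pct_identity", "align_length",
            "mismatches", "gapopens", "qstart", "qend", "sstart", "send",
            "evalue", "bitscore")
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) != 12L)
    stop("expected 12 tab-separated columns, found ", ncol(df))
  names(df) <- cols
  df
}

#' Read a family-by-species count matrix
#'
#' Reads a TSV whose first column holds family ids and whose remaining
#' columns hold per-species member counts (missing entries, '-' or empty,
#' are zeros), e.g. an orthologous-group table.
#'
#' @param path Path to the TSV (with header).
#' @return Integer matrix, rows = families, columns = species.
#' @seealso \code{\link{familyPrevalenceScreen}}
#' @export
readFamilyMatrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          colClasses = "character")
  fam <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  m[m %in% c("-", "", "NA")] <- "0"
  # non-numeric columns (e.g. a trailing annotation) are dropped
  numeric <- apply(m, 2L, function(col)
    !anyNA(suppressWarnings(as.integer(col))))
  m <- m[, numeric, drop = FALSE]
  mode(m) <- "integer"
  rownames(m) <- fam
  m
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
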