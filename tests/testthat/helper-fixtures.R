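# shared fixture builders (everything generated in code, seeded)

randSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# negative-binomial route to the Audic-Claverie two-sided p; independent
# of the package's log-space summation
acOracle <- function(x, y, n1, n2) {
  p <- n1 / (n1 + n2)
  lower <- stats::pnbinom(y, size = x + 1, prob = p)
  upper <- if (y == 0) 1 else 1 - stats::pnbinom(y - 1, size = x + 1, prob = p)
  min(1, 2 * min(lower, upper))
}

# a ContigSet with hand-set membership (consensus content irrelevant)
mkContigSet <- function(sizes, libsPerContig = NULL, width = 60) {
  members <- list()
  rid <- 0L
  for (i in seq_along(sizes)) {
    ids <- sprintf("r%03d", rid + seq_len(sizes[i]))
    rid <- rid + sizes[i]
    members[[i]] <- data.frame(read_id = ids, offset = 0L, strand = "+",
                               stringsAsFactors = FALSE)
  }
  cons <- Biostrings::DNAStringSet(
    vapply(seq_along(sizes), function(i) randSeq(width), character(1)))
  names(cons) <- sprintf("Contig%d", seq_along(sizes))
  new("ContigSet", consensus = cons, members = members,
      singlets = Biostrings::DNAStringSet())
}

# alignment matrix of full-length reads copied from two haplotypes
hapAlignment <- function(hapA, hapB, nA = 2, nB = 2) {
  stopifnot(nchar(hapA) == nchar(hapB))
  rows <- c(replicate(nA, strsplit(hapA, "")[[1]], simplify = FALSE),
            replicate(nB, strsplit(hapB, "")[[1]], simplify = FALSE))
  m <- do.call(rbind, rows)
  rownames(m) <- sprintf("r%d", seq_len(nA + nB))
  m
}

table4Path <- function() {
  system.file("extdata", "coffea_orthomcl_families.tsv", package = "estmine")
}
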