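# synthetic transcriptome + EST library generator with ground truth

AA20 <- setdiff(unique(Biostrings::GENETIC_CODE), "*")
STOPS <- c("TAA", "TAG", "TGA")

# codons per amino acid, split by third-base class (S = G/C, W = A/T)
.codonClasses <- local({
  gc <- Biostrings::GENETIC_CODE
  byAA <- split(names(gc), as.character(gc))
  lapply(byAA, function(cds) {
    third <- substr(cds, 3, 3)
    list(S = cds[third %in% c("G", "C")], W = cds[third %in% c("A", "T")])
  })
})

# random DNA in which every ATG occurrence has been destroyed; emulates
# the scarcity of upstream AUGs in real 5' UTRs and keeps ORF calling
# anchored at the true start codon
.randomUtr <- function(n) {
  s <- seqToChars(randomDna(n))
  if (n >= 3L) {
    for (i in seq_len(n - 2L)) {
      if (s[i] == "A" && s[i + 1L] == "T" && s[i + 2L] == "G")
        s[i + 2L] <- sample(c("C", "T"), 1L)
    }
  }
  charsToSeq(s)
}

# build one CDS of nCodons coding codons (incl. ATG, excl. stop) whose
# third-position G/C fraction is as close to gc3Target as the forced
# codons (Met, Trp) allow
.sampleCds <- function(nCodons, gc3Target) {
  aas <- c("M", sample(AA20, nCodons - 1L, replace = TRUE))
  classes <- .codonClasses[aas]
  forced <- vapply(classes, function(cl) length(cl$W) == 0L, logical(1))
  nS <- round(gc3Target * nCodons)
  free <- which(!forced)
  nSfree <- max(0L, min(length(free), nS - sum(forced)))
  sPos <- if (nSfree > 0L) sample(free, nSfree) else integer(0)
  useS <- forced
  useS[sPos] <- TRUE
  codons <- vapply(seq_len(nCodons), function(i) {
    pool <- if (useS[i]) classes[[i]]$S else classes[[i]]$W
    if (length(pool) == 0L) pool <- unlist(classes[[i]], use.names = FALSE)
    if (length(pool) == 1L) pool else sample(pool, 1L)
  }, character(1))
  paste0(paste(codons, collapse = ""), sample(STOPS, 1L))
}

.truncNorm <- function(n, mean, sd, min) {
  x <- round(stats::rnorm(n, mean, sd))
  pmax(x, min)
}

# mutate k positions of a transcript without touching the start/stop codons
# and without creating an in-frame stop inside the CDS
.divergeTranscript <- function(transcript, cdsStart, cdsEnd, k,
                               tsTvRatio = 2) {
  ch <- seqToChars(transcript)
  n <- length(ch)
  banned <- c(seq(cdsStart + 1L, min(cdsStart + 3L, n)),
              seq(max(1L, cdsEnd - 2L), cdsEnd))
  candidates <- setdiff(seq_len(n), banned)
  chosen <- character(0)
  positions <- sample(candidates)
  taken <- 0L
  for (p in positions) {
    if (taken >= k) break
    old <- ch[p]
    new <- mutateBase(old, tsTvRatio)
    ch[p] <- new
    # reject mutations creating an internal in-frame stop
    if (p > cdsStart && p <= cdsEnd - 3L) {
      ci <- cdsStart + 3L * ((p - cdsStart - 1L) %/% 3L)  # codon start, 0-based
      codon <- paste(ch[(ci + 1L):(ci + 3L)], collapse = "")
      if (codon %in% STOPS) {
        ch[p] <- old
        next
      }
    }
    taken <- taken + 1L
  }
  charsToSeq(ch)
}

#' Generate a synthetic transcriptome with known ground truth
#'
#' Builds \code{nGenes} gene models with 5'UTR/CDS/3'UTR structure.  Each
#' CDS starts with ATG, ends with a stop codon, contains no internal
#' in-frame stop, and has its third-codon-position G+C fraction (GC3)
#' drawn from a mixture of modes, so unimodal or bimodal GC3 profiles can
#' be emulated.  Optionally plants near-identical paralog pairs and
#' bi-allelic variants (two haplotype sequences per chosen gene, fully
#' linked) at a controllable transition:transversion ratio.
#'
#' @param nGenes Number of base gene models (>= 1).
#' @param lengthParams List with elements \code{utr5}, \code{cdsCodons},
#'   \code{utr3}, each \code{c(mean=, sd=, min=)}.  Defaults follow the
#'   median structure of dicot EST contigs (5'UTR ~160 nt, CDS ~280
#'   codons, 3'UTR ~240 nt).
#' @param gc3Modes Two-column matrix (or list of pairs) of GC3 mode
#'   centers and weights; weights must sum to 1.
#' @param gc3Spread Standard deviation of per-gene jitter around the mode
#'   center (default 0.03).
#' @param tsTvRatio Transition:transversion ratio for planted variants.
#' @param nParalogPairs Number of diverged duplicate genes to add.
#' @param paralogDivergence Fraction of positions differing within a
#'   paralog pair (default 0.04).
#' @param nAllelicVariants Number of genes receiving a second haplotype.
#' @param snpsPerVariant Linked SNPs planted per variant gene (default 3).
#' @param seed Integer seed; identical seeds give identical output.
#' @return List with \code{genes} (data.frame: \code{gene_id},
#'   \code{utr5}, \code{cds}, \code{utr3}, \code{gc3_target},
#'   \code{transcript}, \code{transcript_alt}) and \code{truth} (list:
#'   \code{snp_sites}, \code{paralog_pairs}, \code{de_genes},
#'   \code{contaminant_ids}).
#' @examples
#' tx <- generateTranscriptome(5, seed = 1)
#' substr(tx$genes$cds[1], 1, 3)  # "ATG"
#' @export
generateTranscriptome <- function(nGenes,
                                  lengthParams = list(
                                    utr5 = c(mean = 160, sd = 50, min = 10),
                                    cdsCodons = c(mean = 280, sd = 80, min = 50),
                                    utr3 = c(mean = 240, sd = 60, min = 10)),
                                  gc3Modes = cbind(center = 0.45, weight = 1),
                                  gc3Spread = 0.03,
                                  tsTvRatio = 2,
                                  nParalogPairs = 0,
                                  paralogDivergence = 0.04,
                                  nAllelicVariants = 0,
                                  snpsPerVariant = 3,
                                  seed = 1) {
  if (nGenes < 1) stop("nGenes must be >= 1")
  gc3Modes <- do.call(rbind, lapply(asplit(as.matrix(gc3Modes), 1), as.numeric))
  if (abs(sum(gc3Modes[, 2]) - 1) > 1e-9)
    stop("gc3Modes weights must sum to 1")
  if (any(gc3Modes[, 1] < 0 | gc3Modes[, 1] > 1))
    stop("gc3Modes centers must lie in [0,1]")
  if (tsTvRatio <= 0) stop("tsTvRatio must be positive")
  need <- c("utr5", "cdsCodons", "utr3")
  if (!all(need %in% names(lengthParams)) ||
      !all(vapply(lengthParams[need],
                  function(p) all(c("mean", "sd", "min") %in% names(p)),
                  logical(1))))
    stop("invalid lengthParams distribution spec")
  set.seed(substreamSeed(seed, "transcriptome"))

  mode <- sample.int(nrow(gc3Modes), nGenes, replace = TRUE,
                     prob = gc3Modes[, 2])
  gc3Target <- pmin(1, pmax(0, gc3Modes[mode, 1] +
                              stats::rnorm(nGenes, 0, gc3Spread)))
  u5 <- .truncNorm(nGenes, lengthParams$utr5["mean"],
                   lengthParams$utr5["sd"], lengthParams$utr5["min"])
  nc <- .truncNorm(nGenes, lengthParams$cdsCodons["mean"],
                   lengthParams$cdsCodons["sd"], lengthParams$cdsCodons["min"])
  u3 <- .truncNorm(nGenes, lengthParams$utr3["mean"],
                   lengthParams$utr3["sd"], lengthParams$utr3["min"])

  genes <- data.frame(
    gene_id = sprintf("g%04d", seq_len(nGenes)),
    utr5 = vapply(u5, .randomUtr, character(1)),
    cds = mapply(.sampleCds, nc, gc3Target),
    utr3 = vapply(u3, function(n) randomDna(n), character(1)),
    gc3_target = gc3Target,
    stringsAsFactors = FALSE
  )

  # paralog pairs: diverged full-length duplicates appended as new genes
  paralogPairs <- data.frame(gene_a = character(0), gene_b = character(0),
                             divergence = numeric(0))
  if (nParalogPairs > 0) {
    src <- sample(genes$gene_id, nParalogPairs)
    for (g in src) {
      row <- genes[genes$gene_id == g, ]
      tr <- paste0(row$utr5, row$cds, row$utr3)
      cdsStart <- nchar(row$utr5)
      cdsEnd <- cdsStart + nchar(row$cds)
      k <- max(1L, round(paralogDivergence * nchar(tr)))
      mutated <- .divergeTranscript(tr, cdsStart, cdsEnd, k, tsTvRatio)
      newId <- paste0(g, "p")
      genes <- rbind(genes, data.frame(
        gene_id = newId,
        utr5 = substr(mutated, 1, cdsStart),
        cds = substr(mutated, cdsStart + 1, cdsEnd),
        utr3 = substr(mutated, cdsEnd + 1, nchar(mutated)),
        gc3_target = row$gc3_target, stringsAsFactors = FALSE))
      paralogPairs <- rbind(paralogPairs, data.frame(
        gene_a = g, gene_b = newId, divergence = paralogDivergence))
    }
  }

  genes$transcript <- paste0(genes$utr5, genes$cds, genes$utr3)
  genes$transcript_alt <- NA_character_

  # allelic variants: a second haplotype carrying linked bi-allelic SNPs,
  # placed in the 5' region so typical 5'-anchored reads cover them
  snpSites <- data.frame(gene_id = character(0), position = integer(0),
                         ref = character(0), alt = character(0),
                         freq_ref = numeric(0))
  if (nAllelicVariants > 0) {
    pool <- genes$gene_id[seq_len(nGenes)]
    chosen <- sample(pool, min(nAllelicVariants, length(pool)))
    for (g in chosen) {
      i <- which(genes$gene_id == g)
      tr <- genes$transcript[i]
      cdsStart <- nchar(genes$utr5[i])
      window <- min(400L, nchar(tr))
      ok <- setdiff(seq_len(window), (cdsStart + 1L):(cdsStart + 3L))
      pos <- sort(sample(ok, min(snpsPerVariant, length(ok))))
      ch <- seqToChars(tr)
      for (p in pos) {
        ref <- ch[p]
        alt <- mutateBase(ref, tsTvRatio)
        ch[p] <- alt
        snpSites <- rbind(snpSites, data.frame(
          gene_id = g, position = p - 1L, ref = ref, alt = alt,
          freq_ref = 0.5))
      }
      genes$transcript_alt[i] <- charsToSeq(ch)
    }
  }

  list(genes = genes,
       truth = list(snp_sites = snpSites, paralog_pairs = paralogPairs,
                    de_genes = character(0), contaminant_ids = character(0)))
}

#' Define one EST library design
#'
#' @param libraryId Library identifier.
#' @param condition Condition tag, one of \code{"development"} or
#'   \code{"stress"}.
#' @param nReads Number of reads to sequence from this library.
#' @param expression Named numeric vector of per-gene sampling
#'   probabilities (must sum to 1 within 1e-9).
#' @param contaminantFraction Probability that a read is a bacterial
#'   contaminant instead of a transcript read (in [0, 1)).
#' @param errorRate Per-base substitution probability.
#' @return A validated list of class \code{"LibraryDesign"}.
#' @export
libraryDesign <- function(libraryId, condition = c("development", "stress"),
                          nReads, expression, contaminantFraction = 0,
                          errorRate = 0) {
  condition <- match.arg(condition)
  if (abs(sum(expression) - 1) > 1e-9)
    stop("expression probabilities must sum to 1")
  if (contaminantFraction < 0 || contaminantFraction >= 1)
    stop("contaminantFraction must lie in [0, 1)")
  structure(list(library_id = libraryId, condition = condition,
                 n_reads = as.integer(nReads), expression = expression,
                 contaminant_fraction = contaminantFraction,
                 error_rate = errorRate),
            class = "LibraryDesign")
}

#' Build a two-condition library design set with planted DE genes
#'
#' Convenience constructor for a balanced development/stress experiment:
#' all genes share a uniform baseline, and \code{nDe} randomly chosen
#' genes are shifted \code{fold}-fold up in one condition block — half of
#' them in the stress libraries, half in the development libraries — so
#' expression profiles form two anticorrelated condition blocks.
#'
#' @param genes The \code{genes} data.frame from
#'   \code{\link{generateTranscriptome}}.
#' @param nDev,nStress Numbers of development and stress libraries.
#' @param nDe Number of differentially expressed genes to plant.
#' @param fold Expression fold change of planted genes (>= 1).
#' @param nReads Reads per library.
#' @param seed Integer seed for the DE gene draw.
#' @return List with \code{designs} (list of \code{libraryDesign}s),
#'   \code{de_genes} (planted gene ids) and \code{de_direction} (named
#'   \code{"development"}/\code{"stress"}: the condition each gene is up
#'   in).
#' @export
conditionDesigns <- function(genes, nDev = 4, nStress = 4, nDe = 20,
                             fold = 5, nReads = 1500, seed = 1) {
  set.seed(substreamSeed(seed, "designs"))
  ids <- genes$gene_id
  de <- sample(ids, nDe)
  strUp <- de[seq_len(ceiling(nDe / 2))]
  devUp <- setdiff(de, strUp)
  base <- stats::setNames(rep(1, length(ids)), ids)
  devW <- base; devW[devUp] <- fold
  strW <- base; strW[strUp] <- fold
  devExpr <- devW / sum(devW)
  strExpr <- strW / sum(strW)
  designs <- c(
    lapply(seq_len(nDev), function(i)
      libraryDesign(sprintf("DEV%d", i), "development", nReads, devExpr)),
    lapply(seq_len(nStress), function(i)
      libraryDesign(sprintf("STR%d", i), "stress", nReads, strExpr))
  )
  direction <- stats::setNames(
    ifelse(de %in% strUp, "stress", "development"), de)
  list(designs = designs, de_genes = de, de_direction = direction)
}

.decayQualities <- function(n) {
  q <- round(stats::rnorm(n, 40, 3))
  tail <- min(60L, n)
  idx <- (n - tail + 1L):n
  q[idx] <- q[idx] - round(seq(0, 32, length.out = tail))
  pmax(pmin(q, 60L), 2L)
}

#' Simulate 5'-anchored EST libraries from a transcriptome
#'
#' Each read is \code{adapter + 5' transcript fragment (+ substitution
#' errors) + polyA run} where the fragment reaches the transcript 3' end.
#' Contaminant reads are drawn from a separate random-composition pool
#' and recorded in the truth.  Genes with a planted second haplotype are
#' sequenced from either haplotype with probability 1/2.
#'
#' @param genes The \code{genes} data.frame from
#'   \code{\link{generateTranscriptome}}.
#' @param designs List of \code{\link{libraryDesign}} objects.
#' @param readLength \code{c(mean=, sd=, min=)} of the truncated-normal
#'   read length (defaults mean 650, sd 150, floor 100, the scale of
#'   classic 5' EST surveys).
#' @param adapter Vector/adapter remnant prepended to every transcript
#'   read (\code{""} for none).
#' @param polyARange Integer range \code{c(min, max)} of the polyA run
#'   appended when a read runs off the transcript 3' end.
#' @param withQualities Emit per-base qualities with a 3' decay so
#'   quality trimming is exercised.
#' @param seed Integer seed (expanded into per-library substreams).
#' @return List with \code{ests} (an \code{\linkS4class{EstSet}}) and
#'   \code{truth} (list: \code{read_gene} named map, \code{read_haplotype},
#'   \code{contaminant_ids}, \code{de_genes} inferred from the designs as
#'   genes whose sampling probability differs >= 2-fold between condition
#'   means).
#' @examples
#' tx <- generateTranscriptome(3, seed = 1)
#' d <- libraryDesign("L1", "development", 20,
#'   stats::setNames(rep(1 / 3, 3), tx$genes$gene_id))
#' sim <- simulateEstLibraries(tx$genes, list(d), seed = 1)
#' length(sim$ests)
#' @export
simulateEstLibraries <- function(genes, designs,
                                 readLength = c(mean = 650, sd = 150, min = 100),
                                 adapter = "",
                                 polyARange = c(8L, 25L),
                                 withQualities = FALSE,
                                 seed = 1) {
  if (length(designs) == 0L) stop("designs must be nonempty")
  for (d in designs) {
    unknown <- setdiff(names(d$expression), genes$gene_id)
    if (length(unknown))
      stop("design ", d$library_id, " references unknown genes: ",
           paste(utils::head(unknown, 3), collapse = ", "))
  }
  tx <- stats::setNames(genes$transcript, genes$gene_id)
  txAlt <- stats::setNames(genes$transcript_alt, genes$gene_id)

  perLib <- vector("list", length(designs))
  conditions <- character(0)

  for (di in seq_along(designs)) {
    d <- designs[[di]]
    set.seed(substreamSeed(seed, paste0("lib:", d$library_id)))
    conditions[d$library_id] <- d$condition
    n <- d$n_reads
    lens <- .truncNorm(n, readLength["mean"], readLength["sd"],
                       readLength["min"])
    isContam <- stats::runif(n) < d$contaminant_fraction
    geneIds <- rep(NA_character_, n)
    if (any(!isContam))
      geneIds[!isContam] <- sample(names(d$expression), sum(!isContam),
                                   replace = TRUE, prob = d$expression)
    rids <- sprintf("%s_r%05d", d$library_id, seq_len(n))
    sVec <- character(n); hapVec <- integer(n)
    qVec <- if (withQualities) vector("list", n) else NULL
    for (i in seq_len(n)) {
      if (isContam[i]) {
        s <- randomDna(lens[i])
        hapVec[i] <- 0L
      } else {
        g <- geneIds[i]
        hapVec[i] <- 1L
        t <- tx[[g]]
        if (!is.na(txAlt[[g]]) && stats::runif(1) < 0.5) {
          t <- txAlt[[g]]; hapVec[i] <- 2L
        }
        frag <- substr(t, 1L, min(lens[i], nchar(t)))
        if (lens[i] >= nchar(t)) {
          pa <- sample(polyARange[1]:polyARange[2], 1L)
          frag <- paste0(frag, strrep("A", pa))
        }
        s <- paste0(adapter, frag)
        if (d$error_rate > 0) {
          ch <- seqToChars(s)
          hit <- which(stats::runif(length(ch)) < d$error_rate)
          for (p in hit) ch[p] <- sample(setdiff(BASES, ch[p]), 1L)
          s <- charsToSeq(ch)
        }
      }
      sVec[i] <- s
      if (withQualities) qVec[[i]] <- .decayQualities(nchar(s))
    }
    geneIds[isContam] <- "contaminant"
    perLib[[di]] <- list(rids = rids, seqs = sVec, gene = geneIds,
                         hap = hapVec, quals = qVec,
                         contam = rids[isContam],
                         lib = rep(d$library_id, n))
  }
  seqs <- stats::setNames(unlist(lapply(perLib, `[[`, "seqs")),
                          unlist(lapply(perLib, `[[`, "rids")))
  libs <- unlist(lapply(perLib, `[[`, "lib"))
  readGene <- stats::setNames(unlist(lapply(perLib, `[[`, "gene")),
                              names(seqs))
  readHap <- stats::setNames(unlist(lapply(perLib, `[[`, "hap")),
                             names(seqs))
  contamIds <- as.character(unlist(lapply(perLib, `[[`, "contam")))
  quals <- if (withQualities)
    stats::setNames(unlist(lapply(perLib, `[[`, "quals"), recursive = FALSE),
                    names(seqs)) else list()

  # condition-dependent genes implied by the designs (>= 2-fold shift)
  deGenes <- character(0)
  conds <- vapply(designs, `[[`, character(1), "condition")
  if (length(unique(conds)) == 2L) {
    allG <- unique(unlist(lapply(designs, function(d) names(d$expression))))
    prob <- function(d, g) ifelse(g %in% names(d$expression),
                                  d$expression[g], 0)
    pDev <- rowMeans(sapply(designs[conds == "development"], prob, g = allG))
    pStr <- rowMeans(sapply(designs[conds == "stress"], prob, g = allG))
    hi <- pmax(pDev, pStr); lo <- pmin(pDev, pStr)
    deGenes <- allG[hi > 0 & (lo == 0 | hi / pmax(lo, .Machine$double.xmin) >= 2)]
  }

  ests <- EstSet(DNAStringSet(seqs), libraries = libs,
                 qualities = quals, conditions = conditions)
  list(ests = ests,
       truth = list(read_gene = readGene, read_haplotype = readHap,
                    contaminant_ids = contamIds, de_genes = deGenes))
}

#' Write simulated reads and truth to disk
#'
#' Emits reads as FASTA (and FASTQ when qualities are present), the
#' library table as TSV (read_id, library_id, condition), and the ground
#' truth as JSON.
#'
#' @param sim Result of \code{\link{simulateEstLibraries}}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "reads.fasta")
  writeXStringSet(estSequences(sim$ests), fa)
  paths <- fa
  if (length(estQualities(sim$ests))) {
    fq <- file.path(dir, "reads.fastq")
    .writeFastq(sim$ests, fq)
    paths <- c(paths, fq)
  }
  libTab <- data.frame(read_id = names(estSequences(sim$ests)),
                       library_id = sim$ests@libraries,
                       condition = unname(
                         libraryConditions(sim$ests)[sim$ests@libraries]))
  tsv <- file.path(dir, "library_table.tsv")
  writeTsv(libTab, tsv)
  tj <- file.path(dir, "truth.json")
  jsonlite::write_json(sim$truth, tj, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, tsv, tj))
}

.writeFastq <- function(ests, path) {
  seqs <- as.character(estSequences(ests))
  quals <- estQualities(ests)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    q <- quals[[i]]
    writeLines(c(paste0("@", names(seqs)[i]), seqs[[i]], "+",
                 intToUtf8(pmin(q, 93L) + 33L)), con)
  }
  invisible(path)
}
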