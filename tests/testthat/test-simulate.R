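test_that("transcriptome generation is deterministic and respects the gene model invariants", {
  tx1 <- generateTranscriptome(10, seed = 42)
  tx2 <- generateTranscriptome(10, seed = 42)
  expect_identical(tx1, tx2)

  g <- tx1$genes
  expect_true(all(substr(g$cds, 1, 3) == "ATG"))
  expect_true(all(substr(g$cds, nchar(g$cds) - 2, nchar(g$cds)) %in%
                    c("TAA", "TAG", "TGA")))
  expect_true(all(nchar(g$cds) %% 3 == 0))
  # no internal in-frame stop
  internalStops <- vapply(g$cds, function(cds) {
    starts <- seq(1, nchar(cds) - 3, by = 3)
    any(substring(cds, starts, starts + 2) %in% c("TAA", "TAG", "TGA"))
  }, logical(1))
  expect_false(any(internalStops))
})

test_that("codon choice restricted to G/C third positions forces GC3 = 1", {
  tx <- generateTranscriptome(10, gc3Modes = cbind(1.0, 1.0), gc3Spread = 0,
                              seed = 7)
  gc3 <- vapply(tx$genes$cds, function(cds) gcMetrics(cds)$gc3, numeric(1))
  expect_equal(unname(gc3), rep(1, 10))
})

test_that("realized GC3 is bimodal with peaks at the requested mode centers", {
  tx <- generateTranscriptome(600, gc3Modes = cbind(c(0.40, 0.80), c(0.5, 0.5)),
                              seed = 21)
  # independent oracle: direct third-position codon scan, stop excluded
  gc3 <- vapply(tx$genes$cds, function(cds) {
    ch <- strsplit(cds, "")[[1]]
    third <- ch[seq(3, length(ch) - 3, by = 3)]
    mean(third %in% c("G", "C"))
  }, numeric(1))
  h <- hist(gc3, breaks = seq(0, 1, 0.05), plot = FALSE)
  lowPeak <- h$mids[which.max(h$counts * (h$mids < 0.6))]
  highPeak <- h$mids[which.max(h$counts * (h$mids > 0.6))]
  expect_gte(lowPeak, 0.35); expect_lte(lowPeak, 0.45)
  expect_gte(highPeak, 0.75); expect_lte(highPeak, 0.85)
})

test_that("library simulation conserves read counts and honours degenerate profiles", {
  tx <- generateTranscriptome(5, seed = 3)
  ids <- tx$genes$gene_id
  dA <- libraryDesign("LA", "development", 50,
                      stats::setNames(c(1, 0, 0, 0, 0), ids))
  dB <- libraryDesign("LB", "stress", 30,
                      stats::setNames(rep(0.2, 5), ids))
  sim <- simulateEstLibraries(tx$genes, list(dA, dB), seed = 5)
  libs <- estLibraries(sim$ests)
  expect_equal(sum(libs == "LA"), 50)
  expect_equal(sum(libs == "LB"), 30)
  # degenerate profile: every LA read maps to the first gene
  laReads <- names(libs)[libs == "LA"]
  expect_true(all(sim$truth$read_gene[laReads] == ids[1]))
})

test_that("zero-noise reads are prefix-anchored substrings of their transcript", {
  tx <- generateTranscriptome(8, seed = 13)
  d <- libraryDesign("L1", "development", 60,
                     stats::setNames(rep(1 / 8, 8), tx$genes$gene_id))
  sim <- simulateEstLibraries(tx$genes, list(d), adapter = "", seed = 13)
  trx <- stats::setNames(tx$genes$transcript, tx$genes$gene_id)
  seqs <- as.character(estSequences(sim$ests))
  ok <- vapply(names(seqs), function(rid) {
    t <- trx[[sim$truth$read_gene[[rid]]]]
    # a read either stays inside the transcript or runs into the polyA tail
    startsWith(t, seqs[[rid]]) ||
      startsWith(paste0(t, strrep("A", 40)), seqs[[rid]])
  }, logical(1))
  expect_true(all(ok))
})

test_that("contaminant counts follow the design fraction binomially", {
  tx <- generateTranscriptome(5, seed = 2)
  d <- libraryDesign("L1", "development", 1000,
                     stats::setNames(rep(0.2, 5), tx$genes$gene_id),
                     contaminantFraction = 0.1)
  sim <- simulateEstLibraries(tx$genes, list(d), seed = 11)
  nContam <- length(sim$truth$contaminant_ids)
  # binomial(1000, 0.1) quantiles 0.001/0.999
  expect_gte(nContam, 70)
  expect_lte(nContam, 130)
})

test_that("planted SNP allele frequencies converge to the design frequencies", {
  tx <- generateTranscriptome(4, nAllelicVariants = 2, seed = 17)
  variant <- tx$genes$gene_id[!is.na(tx$genes$transcript_alt)]
  expect_length(variant, 2)
  d <- libraryDesign("L1", "development", 400,
                     stats::setNames(rep(0.25, 4), tx$genes$gene_id))
  sim <- simulateEstLibraries(tx$genes, list(d), seed = 17)
  for (g in variant) {
    hap <- sim$truth$read_haplotype[sim$truth$read_gene == g]
    n <- length(hap)
    se <- sqrt(0.25 / n)
    expect_lt(abs(mean(hap == 2) - 0.5), 3 * se)
  }
})

test_that("invalid generator and design parameters are rejected", {
  expect_error(generateTranscriptome(0), "nGenes")
  expect_error(generateTranscriptome(5, gc3Modes = cbind(c(0.3, 0.6), c(0.5, 0.4))),
               "sum to 1")
  expect_error(generateTranscriptome(5, lengthParams = list(utr5 = c(mean = 10))),
               "lengthParams")
  expect_error(libraryDesign("L", "stress", 10, c(g1 = 0.5, g2 = 0.4)),
               "sum to 1")
  expect_error(libraryDesign("L", "stress", 10, c(g1 = 1), contaminantFraction = 1),
               "contaminantFraction")
  tx <- generateTranscriptome(2, seed = 1)
  expect_error(simulateEstLibraries(tx$genes, list()), "nonempty")
  bad <- libraryDesign("L", "stress", 10, c(nosuch = 1))
  expect_error(simulateEstLibraries(tx$genes, list(bad)), "unknown genes")
})
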