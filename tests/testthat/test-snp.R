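test_that("balanced linked SNPs in a 4-read contig are called bi-allelic", {
  set.seed(61)
  hapA <- randSeq(300)
  ch <- strsplit(hapA, "")[[1]]
  pos <- c(50, 180)  # two linked columns
  ch[50] <- switch(ch[50], A = "G", G = "A", C = "T", T = "C")
  ch[180] <- switch(ch[180], A = "G", G = "A", C = "T", T = "C")
  hapB <- paste(ch, collapse = "")
  det <- detectSnps(hapAlignment(hapA, hapB))
  expect_equal(det$calls$position, pos - 1L)
  expect_true(all(det$calls$allelic_class == "bi"))
  expect_true(all(det$calls$mutation_class == "transition"))
  # confidence: depth 4, balanced minor 2 -> (1 - 1/4) * (2*2/4) = 0.75
  expect_equal(det$calls$confidence, c(0.75, 0.75))
  expect_length(det$haplotypes, 2)
  expect_false(det$paralog_flag)
})

test_that("an isolated single-read allele is never called", {
  set.seed(62)
  s <- randSeq(300)
  ch <- strsplit(s, "")[[1]]
  ch[100] <- setdiff(c("A", "C", "G", "T"), ch[100])[1]
  odd <- paste(ch, collapse = "")
  aln <- hapAlignment(s, odd, nA = 3, nB = 1)  # 3x ref, 1x variant
  det <- detectSnps(aln)
  expect_equal(nrow(det$calls), 0L)
})

test_that("contigs below the four-read rule are skipped with a reason", {
  set.seed(63)
  s <- randSeq(200)
  det <- detectSnps(hapAlignment(s, s, nA = 2, nB = 1))
  expect_equal(nrow(det$calls), 0L)
  expect_identical(det$reason, "below_min_reads")
})

test_that("two haplotype groups separated by many fixed differences flag a paralog", {
  set.seed(64)
  hapA <- randSeq(300)
  ch <- strsplit(hapA, "")[[1]]
  pos <- sample(300, 12)  # 12 / 300 bp = 4 per 100 bp > cut of 3
  for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  hapB <- paste(ch, collapse = "")
  det <- detectSnps(hapAlignment(hapA, hapB), paralogDivergenceCut = 3)
  expect_true(det$paralog_flag)
  # the same divergence spread over 600 bp falls below the cut
  det2 <- detectSnps(hapAlignment(paste0(hapA, hapA), paste0(hapB, hapA)),
                     paralogDivergenceCut = 3)
  expect_false(det2$paralog_flag)
})

test_that("generator-planted variants are recovered with no false calls", {
  tx <- generateTranscriptome(6, nAllelicVariants = 3, seed = 65)
  variant <- tx$genes$gene_id[!is.na(tx$genes$transcript_alt)]
  for (g in variant) {
    i <- which(tx$genes$gene_id == g)
    det <- detectSnps(hapAlignment(tx$genes$transcript[i],
                                   tx$genes$transcript_alt[i]))
    truthPos <- tx$truth$snp_sites$position[tx$truth$snp_sites$gene_id == g]
    expect_setequal(det$calls$position, truthPos)  # recall 1, no false calls
  }
})

test_that("transition/transversion and density summaries follow their definitions", {
  calls <- data.frame(
    contig_id = c("c1", "c1", "c2"),
    mutation_class = c("transition", "transversion", "transition"),
    allelic_class = c("bi", "bi", "tri"))
  s <- summarizeSnps(calls, c(c1 = 250, c2 = 150, c3 = 200))
  expect_equal(s$transitions, 2)
  expect_equal(s$transversions, 1)
  expect_equal(s$density_per_100bp, 3 * 100 / 600)
  expect_equal(s$frac_contigs_with_snp, 2 / 3)
  expect_equal(unname(s$allelic_class_pct[["bi"]]), 100 * 2 / 3)
  # 2 SNPs over 400 screened bases -> 0.5 SNP / 100 bp
  s2 <- summarizeSnps(calls[1:2, ], c(c1 = 400))
  expect_equal(s2$density_per_100bp, 0.5)
})

test_that("synonymy labels follow the genetic code and the CDS bounds", {
  consensus <- paste0("ATG", "GGA", "TAA", "GCTGC")  # Met-Gly-stop + 3'UTR
  ann <- predictCds(consensus)
  calls <- data.frame(
    position = c(5L, 3L, 10L),
    alleles = c("A:2,G:2", "G:2,A:2", "G:2,C:2"),
    allelic_class = "bi", mutation_class = "transition",
    confidence = 0.75, synonymy = NA_character_,
    stringsAsFactors = FALSE)
  out <- labelSynonymy(calls, ann, consensus)
  expect_equal(out$synonymy, c("synonymous",     # GGA -> GGG, Gly
                               "nonsynonymous",  # GGA -> AGA, Gly -> Arg
                               "noncoding"))     # 3' UTR
  expect_error(
    labelSynonymy(data.frame(position = 99L, alleles = "A:2,C:2",
                             synonymy = NA), ann, consensus),
    "beyond")
})

test_that("fractional site counting conserves S + N = 3 x codons", {
  set.seed(66)
  for (i in 1:5) {
    nc <- sample(20:80, 1)
    cds <- paste(sample(names(Biostrings::GENETIC_CODE), nc, replace = TRUE),
                 collapse = "")
    sites <- synonymousSites(cds)
    expect_equal(sites[["S"]] + sites[["N"]], 3 * nc)
  }
})

test_that("site counts match a whole-sequence translation oracle", {
  set.seed(67)
  codons <- sample(names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"],
                   30, replace = TRUE)
  cds <- paste(codons, collapse = "")
  # oracle: mutate every position, translate the whole CDS via Biostrings
  protein <- function(s)
    as.character(Biostrings::translate(Biostrings::DNAString(s)))
  ref <- protein(cds)
  S <- 0
  for (p in seq_len(nchar(cds))) {
    for (b in setdiff(c("A", "C", "G", "T"), substr(cds, p, p))) {
      mut <- cds
      substr(mut, p, p) <- b
      if (identical(protein(mut), ref)) S <- S + 1 / 3
    }
  }
  sites <- synonymousSites(cds)
  expect_equal(sites[["S"]], S)
})

test_that("KA/KS equals the hand-computed quotients for planted SNPs", {
  set.seed(68)
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  inner <- sample(setdiff(sense, "ATG"), 98, replace = TRUE)
  inner[c(10, 40)] <- c("GGA", "GCT")  # four-fold codons for syn SNPs
  inner[70] <- "GGA"                   # target for the nonsyn SNP
  cds <- paste0("ATG", paste(inner, collapse = ""), "TAA")  # 100 codons
  ann <- predictCds(cds)
  expect_equal(c(ann$cds_start, ann$cds_end), c(0L, 300L))

  # 2 synonymous third-position SNPs (GGA->GGG, GCT->GCC) and one
  # nonsynonymous first-position SNP (GGA->AGA, Gly->Arg); codon i of the
  # CDS occupies 0-based positions 3i .. 3i+2 (ATG is codon 0)
  calls <- data.frame(
    position = c(10L * 3L + 2L, 40L * 3L + 2L, 70L * 3L),
    alleles = c("A:2,G:2", "T:2,C:2", "G:2,A:2"),
    synonymy = NA_character_, stringsAsFactors = FALSE)
  calls <- labelSynonymy(calls, ann, cds)
  expect_equal(calls$synonymy,
               c("synonymous", "synonymous", "nonsynonymous"))
  res <- computeKaKs(calls, ann, cds)
  expect_equal(res$ka, 1 / res$N)
  expect_equal(res$ks, 2 / res$S)
  expect_equal(res$ratio, (1 / res$N) / (2 / res$S))
  # independent per-codon enumeration of the site totals
  expect_equal(res$S + res$N, 300)
})

test_that("KA/KS degenerate cases: no SNPs and synonymous-only SNPs", {
  cds <- paste0("ATG", "GGAGGCGGT", "TAA")
  ann <- predictCds(cds)
  none <- computeKaKs(data.frame(position = integer(0),
                                 synonymy = character(0)), ann, cds)
  expect_equal(c(none$ka, none$ks), c(0, 0))
  expect_true(is.na(none$ratio))  # undefined, not infinite

  synOnly <- data.frame(position = 5L, alleles = "A:2,G:2",
                        synonymy = NA_character_, stringsAsFactors = FALSE)
  synOnly <- labelSynonymy(synOnly, ann, cds)
  res <- computeKaKs(synOnly, ann, cds)
  expect_equal(res$ka, 0)
  expect_gt(res$ks, 0)
  expect_equal(res$ratio, 0)
})
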