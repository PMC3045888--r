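test_that("polyA tails and short reads are handled by the published rules", {
  set.seed(31)
  s <- randSeq(150)
  # keep the run boundaries crisp: no terminal A / leading T on the insert
  while (grepl("A$", s) || grepl("^T", s)) s <- randSeq(150)
  out <- trimRead(paste0(s, strrep("A", 20)))
  expect_identical(out$sequence, s)
  expect_false(out$rejected)

  short <- trimRead(randSeq(90))
  expect_true(short$rejected)
  expect_identical(short$reason, "short")

  # 5' polyT is the mirror rule for reversed clones
  out2 <- trimRead(paste0(strrep("T", 12), s))
  expect_identical(out2$sequence, s)
})

test_that("a leading adapter with one mismatch is removed, insert intact", {
  set.seed(32)
  adapter <- "GTACGTA"
  # the insert must not itself contain a near-match of the short adapter
  # in its leading window (the example's "insert returned intact" premise)
  nearMatch <- function(s) {
    ad <- strsplit(adapter, "")[[1]]
    any(vapply(1:50, function(p)
      sum(strsplit(substr(s, p, p + 6), "")[[1]] != ad) <= 2, logical(1)))
  }
  insert <- randSeq(200)
  while (nearMatch(insert) || grepl("A$", insert)) insert <- randSeq(200)
  adCopy <- adapter
  substr(adCopy, 4, 4) <- "A"  # one mismatch
  read <- paste0(adCopy, insert)

  # brute-force oracle: first window in the leading 50 bases with <= 2
  # mismatches against the adapter
  oracleEnd <- NA
  for (p in 1:50) {
    win <- substr(read, p, p + nchar(adapter) - 1)
    mm <- sum(strsplit(win, "")[[1]] != strsplit(adapter, "")[[1]])
    if (mm <= 2) { oracleEnd <- p + nchar(adapter) - 1; break }
  }
  expect_equal(oracleEnd, 7)  # the mismatched copy still anchors at base 1

  out <- trimRead(read, adapter = adapter)
  expect_identical(out$sequence, insert)
})

test_that("trimming is idempotent and never leaves a non-substring", {
  set.seed(33)
  for (i in 1:25) {
    n <- sample(120:400, 1)
    s <- randSeq(n)
    if (runif(1) < 0.5) s <- paste0("GTACGTA", s)
    if (runif(1) < 0.5) s <- paste0(s, strrep("A", sample(8:20, 1)))
    q <- pmax(2, round(rnorm(nchar(s), 35, 4)) -
                c(rep(0, nchar(s) - 40), seq(0, 30, length.out = 40)))
    t1 <- trimRead(s, qualities = q, adapter = "GTACGTA")
    if (t1$rejected) next
    t2 <- trimRead(t1$sequence, qualities = t1$qualities, adapter = "GTACGTA")
    expect_identical(t2$sequence, t1$sequence)
    expect_lte(nchar(t1$sequence), nchar(s))
    expect_true(grepl(t1$sequence, s, fixed = TRUE))
  }
})

test_that("quality clipping cuts the 3' end at the first failing window", {
  set.seed(34)
  s <- randSeq(200)
  while (grepl("A$", substr(s, 1, 148))) s <- randSeq(200)
  q <- c(rep(40L, 150), rep(5L, 50))  # clean 150, junk 50
  out <- trimRead(s, qualities = q, qualityFloor = 15, window = 10)
  expect_false(out$rejected)
  # first window with mean < 15 starts at base 149 ((2*40 + 8*5)/10 = 12),
  # so bases 1..148 survive
  expect_identical(out$sequence, substr(s, 1, 148))
})

test_that("non-nucleotide characters raise a format error", {
  expect_error(trimRead("ACGTXACGT"), "outside")
})

test_that("contaminant screening applies both thresholds and is exhaustive", {
  hits <- data.frame(
    query_id = c("c1", "c2", "c3"),
    evalue = c(1e-50, 1e-50, 1e-10),
    pct_identity = c(85, 75, 95))
  res <- screenContaminants(c("c1", "c2", "c3", "c4"), hits)
  expect_identical(res$contaminant, "c1")   # significant AND identical
  expect_setequal(res$clean, c("c2", "c3", "c4"))
  expect_length(intersect(res$clean, res$contaminant), 0)

  # no hits at all -> everything clean
  none <- screenContaminants(c("a", "b"), hits[0, ])
  expect_setequal(none$clean, c("a", "b"))
})

test_that("screening recovers every simulated contaminant from a truth-derived hit table", {
  tx <- generateTranscriptome(5, seed = 8)
  d <- libraryDesign("L1", "development", 200,
                     stats::setNames(rep(0.2, 5), tx$genes$gene_id),
                     contaminantFraction = 0.15)
  sim <- simulateEstLibraries(tx$genes, list(d), seed = 8)
  contam <- sim$truth$contaminant_ids
  hits <- data.frame(query_id = contam, evalue = 1e-60, pct_identity = 92)
  res <- screenContaminants(names(estSequences(sim$ests)), hits)
  expect_setequal(res$contaminant, contam)  # recall 1.0
})
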