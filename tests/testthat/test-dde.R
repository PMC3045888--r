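test_that("AC p-values match a high-precision tail-summation oracle", {
  # modest grid here; the full published grid runs in the acceptance suite
  for (x in c(0, 1, 5, 13)) {
    for (y in c(0, 2, 7, 20)) {
      for (n1 in c(500, 1000)) {
        expect_equal(acPvalue(x, y, n1, 1000), acOracle(x, y, n1, 1000),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("AC closed form: x = 0 with equal totals gives the geometric tail", {
  for (y in 1:30) {
    expect_equal(acPvalue(0, y, 1000, 1000), min(1, 2 * 2^-y),
                 tolerance = 1e-12)
  }
  expect_equal(acPvalue(0, 0, 750, 750), 1.0)
})

test_that("AC p equals 1 for equal counts at equal depth and stays in [0, 1]", {
  # the tail-doubling convention is exactly symmetric at x = y; elsewhere
  # the two orientations aggregate different tail terms
  for (x in c(0, 1, 4, 9, 25))
    expect_identical(acPvalue(x, x, 1200, 1200), 1)
  set.seed(71)
  for (i in 1:50) {
    x <- sample(0:40, 1); y <- sample(0:40, 1)
    n1 <- sample(300:3000, 1); n2 <- sample(300:3000, 1)
    p1 <- acPvalue(x, y, n1, n2)
    expect_gte(p1, 0); expect_lte(p1, 1)
    # swapped orientation agrees in order of magnitude (same tail terms,
    # different aggregation boundary)
    p2 <- acPvalue(y, x, n2, n1)
    expect_lte(abs(log10(p1) - log10(p2)), 1)
  }
})

test_that("AC two-sided p is non-increasing as |y - x| grows (equal totals)", {
  for (x in c(0, 5, 10)) {
    pUp <- vapply(x:(x + 15), function(y) acPvalue(x, y, 2000, 2000),
                  numeric(1))
    expect_true(all(diff(pUp) <= 1e-12))
    if (x > 0) {
      pDown <- vapply(x:0, function(y) acPvalue(x, y, 2000, 2000), numeric(1))
      expect_true(all(diff(pDown) <= 1e-12))
    }
  }
})

test_that("AC rejects inconsistent counts", {
  expect_error(acPvalue(10, 0, 5, 100), "exceed")
  expect_error(acPvalue(-1, 0, 100, 100), "nonnegative")
})

test_that("R statistic: homogeneity gives exactly zero, known case, nonnegativity", {
  expect_identical(rStatistic(c(2, 4, 6), c(100, 200, 300))$R, 0)
  expect_equal(rStatistic(c(2, 4, 6), c(100, 200, 300))$p, 1)

  r <- rStatistic(c(0, 20), c(1000, 1000))
  expect_equal(r$R, 20 * log(2), tolerance = 1e-12)

  set.seed(72)
  for (i in 1:200) {
    m <- sample(2:6, 1)
    totals <- sample(300:2000, m)
    counts <- rpois(m, 5)
    expect_gte(rStatistic(counts, totals)$R, -1e-12)
  }
  expect_error(rStatistic(c(5), c(100)), "two libraries")
})

test_that("DE selection applies the filters and matches a hand-executed run", {
  # L1..L3 pass the size filter, L4 (250 ESTs) is discarded; contig c5
  # (2 ESTs) is never tested; c1 is the planted extreme contig
  counts <- rbind(
    c1 = c(30, 0, 0, 0),
    c2 = c(5, 5, 5, 2),
    c3 = c(4, 6, 5, 1),
    c4 = c(6, 4, 5, 0),
    c5 = c(1, 1, 0, 0))
  colnames(counts) <- c("L1", "L2", "L3", "L4")
  filler <- rbind(f1 = c(355, 384, 385, 247))  # bring totals to target
  m <- rbind(counts, filler)
  expect_equal(unname(colSums(m)), c(401, 400, 400, 250))

  res <- selectDeContigs(m, deConfig())
  tested <- attr(res, "tested")
  expect_false("L4" %in% colnames(tested))   # < 300 ESTs: dropped
  expect_false("c5" %in% rownames(tested))   # 2 ESTs: never tested

  # hand-run oracle over the tested matrix (L1..L3, contigs with >= 3 ESTs)
  tot <- colSums(tested)
  handSelected <- character(0)
  nTested <- nrow(tested)
  for (cid in rownames(tested)) {
    x <- tested[cid, ]
    R <- sum(ifelse(x > 0, x * log(x / (tot * sum(x) / sum(tot))), 0))
    pR <- pchisq(2 * R, df = length(x) - 1, lower.tail = FALSE)
    acs <- sapply(seq_along(x), function(a)
      max(sapply(seq_along(x)[-a], function(b)
        acOracle(x[a], x[b], tot[a], tot[b]))))
    if (pR < 0.05 / nTested || min(acs) < 0.05)
      handSelected <- c(handSelected, cid)
  }
  expect_setequal(res$contig_id, handSelected)
  expect_true("c1" %in% res$contig_id)
  expect_false("c2" %in% res$contig_id)
  # profiles of reported contigs sum to one over retained libraries
  expect_equal(unname(rowSums(attr(res, "profiles"))),
               rep(1, nrow(res)))
})

test_that("DE selection errors when everything is filtered out", {
  tiny <- matrix(c(2, 3, 1, 2), 2, dimnames = list(c("a", "b"), c("L1", "L2")))
  expect_error(selectDeContigs(tiny, deConfig()), "size filter")
  expect_error(selectDeContigs(tiny[0, , drop = FALSE], deConfig()), "empty")
  expect_error(deConfig(alpha = 0), "alpha")
  expect_error(deConfig(minContigEsts = 2), "minContigEsts")
})

test_that("library merging pools counts before testing", {
  m <- matrix(c(10, 300, 5, 305, 20, 290), 2,
              dimnames = list(c("a", "b"), c("E1", "E2", "F1")))
  res <- selectDeContigs(m, deConfig(minLibraryEsts = 100,
                                     mergeMap = c(E1 = "E", E2 = "E")))
  tested <- attr(res, "tested")
  expect_setequal(colnames(tested), c("E", "F1"))
  expect_equal(tested["a", "E"], 15)
})

test_that("profile clustering normalizes rows and respects correlation geometry", {
  m <- rbind(a = c(2, 2, 4), b = c(1, 1, 2), c = c(4, 2, 2))
  pc <- profileCluster(m)
  expect_equal(unname(pc$matrix["a", ]), c(0.25, 0.25, 0.5))
  # identical profiles merge first at distance 0
  expect_equal(pc$hclust$height[1], 0, tolerance = 1e-12)
  first <- pc$hclust$labels[-pc$hclust$merge[1, ]]
  expect_setequal(first, c("a", "b"))

  # perfectly anticorrelated profiles sit at distance 2
  m2 <- rbind(p = c(1, 0), q = c(0, 1))
  pc2 <- profileCluster(m2)
  expect_equal(pc2$hclust$height[1], 2)

  # zero-variance profile: distance 1 to everything by convention
  m3 <- rbind(flat = c(1, 1, 1), up = c(0, 1, 2), down = c(2, 1, 0))
  pc3 <- profileCluster(m3)
  d <- cophenetic(pc3$hclust)
  expect_equal(as.matrix(d)["flat", "up"], 1, tolerance = 1e-9)
  expect_error(profileCluster(m3[1, , drop = FALSE]), "two profiles")
})
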