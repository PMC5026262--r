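test_that("insert-size discordance thresholds follow mean + 3 sd", {
  aln <- rbind(pairRows(1L, "chr1", 10000L, 5500L),
               pairRows(2L, "chr1", 20000L, 600L),
               alnRow(3L, 1L, "S1", "chr1", 30000L, 30099L, "+"),
               alnRow(3L, 2L, "S1", NA, NA, NA, NA, mapq = NA, uniq = FALSE,
                      aligned = FALSE, mateChrom = "chr1",
                      seq = strrep("A", 100)))
  prs <- findDiscordantPairs(aln, testModel)$pairs
  expect_equal(prs[frag == 1L, type], "del")        # 5500 > 650
  expect_equal(prs[frag == 2L, type], "concordant") # 600 < 650
  expect_equal(prs[frag == 3L, type], "anchor")     # unique + unaligned mate
  expect_equal(prs[frag == 3L, mobileSeq], strrep("A", 100))
})

test_that("the insert model needs at least 100 concordant pairs", {
  few <- rbindlist(lapply(1:20, function(i)
    pairRows(i, "chr1", 1000L + 300L * i, 500L)))
  expect_error(findDiscordantPairs(few), "100")
  est <- findDiscordantPairs(backgroundPairs(200L))$model
  expect_lt(abs(est[["mean"]] - 500), 25)
  expect_lt(abs(est[["sd"]] - 50), 25)
})

test_that("detector A recovers a planted cluster and applies its filters", {
  prs <- labelPairs(delCluster(6, 50000L, 55000L))
  calls <- callDeletionsDetectorA(prs)
  expect_equal(nrow(calls), 1L)
  expect_lt(abs(calls$start - 50000L), testModel[["sd"]])
  expect_lt(abs(calls$end - 55000L), testModel[["sd"]])
  expect_equal(calls$support, 6L)

  # four supporting pairs are not enough
  expect_equal(nrow(callDeletionsDetectorA(
    labelPairs(delCluster(4, 50000L, 55000L)))), 0L)
  # median mapping quality below 20 is rejected by A...
  low <- labelPairs(delCluster(6, 50000L, 55000L, mapq = 10L))
  expect_equal(nrow(callDeletionsDetectorA(low)), 0L)
  # ...but not by B, which has no MAPQ filter
  expect_equal(nrow(callDeletionsDetectorB(low, testModel)), 1L)
})

test_that("detector B reports breakpoint-interval midpoints", {
  prs <- labelPairs(delCluster(6, 50000L, 55000L))
  dp <- prs[type == "del"]
  gmax <- as.integer(500 + 3 * 50) - 200L   # per-pair max concordant gap
  lLo <- max(dp$lend) + 1L; lHi <- min(dp$lend + gmax)
  rHi <- min(dp$rstart) - 1L; rLo <- max(dp$rstart - gmax)
  calls <- callDeletionsDetectorB(prs, testModel)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$start, as.integer(round((lLo + lHi) / 2)))
  expect_equal(calls$end, as.integer(round((rLo + rHi) / 2)))

  # support of exactly five is retained
  expect_equal(nrow(callDeletionsDetectorB(
    labelPairs(delCluster(5, 50000L, 55000L)), testModel)), 1L)
  # length out of 1-25 kb is filtered
  expect_equal(nrow(callDeletionsDetectorB(
    labelPairs(delCluster(6, 50000L, 80000L)), testModel)), 0L)
  expect_equal(nrow(callDeletionsDetectorA(
    labelPairs(delCluster(6, 50000L, 50500L)))), 0L)
})

test_that("detector merging uses the 250 bp confidence-interval rule", {
  a <- mkCall(10000, 15000, "A")
  b1 <- mkCall(10100, 15100, "B")
  m <- mergeDetectors(a, b1)
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, 10000L)  # A breakpoints win
  expect_equal(m$end, 15000L)
  expect_equal(m$detector, "both")

  # left windows disjoint (600 > 500): two events survive
  b2 <- mkCall(10600, 15000, "B")
  expect_equal(nrow(mergeDetectors(a, b2)), 2L)
  # single-detector calls are kept
  expect_equal(nrow(mergeDetectors(a, mkCall(1, 1, "B")[0])), 1L)
  expect_equal(nrow(mergeDetectors(a[0], b1)), 1L)
})

test_that("TE insertions require two opposite clusters pointing inward", {
  sim <- tinyStudy()
  pl <- sim$planted
  fd <- findDiscordantPairs(sim$alignments[["Pn1"]])
  ins <- detectTeInsertions(fd$pairs, sim$toy$teLibrary,
                            sim$toy$teSuperfamily, fd$model)
  carried <- pl$truth[type == "insertion"][
    pl$genotypes[variant_id, "Pn1"] > 0L]
  # every call sits within 250 bp of a planted site and is classified
  for (j in seq_len(nrow(ins))) {
    d <- carried[chrom == ins$chrom[j],
                 min(abs(start - (ins$start[j] + ins$end[j]) / 2))]
    expect_lt(d, 250)
  }
  hits <- sapply(seq_len(nrow(carried)), function(i)
    any(ins$chrom == carried$chrom[i] &
          abs((ins$start + ins$end) / 2 - carried$start[i]) <= 250))
  expect_gte(mean(hits), 0.8)
  # classified sites agree with the planted superfamily
  for (j in seq_len(nrow(ins))) {
    k <- which(carried$chrom == ins$chrom[j] &
                 abs((ins$start[j] + ins$end[j]) / 2 - carried$start) <= 250)
    if (length(k) == 1 && ins$teClass[j] != "unclassified" &&
        ins$teClass[j] != "unknown")
      expect_equal(ins$teClass[j],
                   unname(sim$toy$teSuperfamily[carried$teFamily[k]]))
  }

  # a forward cluster alone never yields a call
  onlyFw <- fd$pairs[type != "anchor" | anchorStrand == "+"]
  insFw <- detectTeInsertions(onlyFw, sim$toy$teLibrary,
                              sim$toy$teSuperfamily, fd$model)
  expect_equal(nrow(insFw), 0L)
  expect_error(detectTeInsertions(fd$pairs, Biostrings::DNAStringSet(),
                                  character(), fd$model), "empty")
})

test_that("mobile reads matching nothing give an unclassified site", {
  decoy <- Biostrings::DNAStringSet(c(decoy = strrep("ACGG", 500)))
  sim <- tinyStudy()
  fd <- findDiscordantPairs(sim$alignments[["Pn1"]])
  ins <- detectTeInsertions(fd$pairs, decoy, c(decoy = "LTR Gypsy"),
                            fd$model)
  expect_true(nrow(ins) > 0)
  expect_true(all(ins$teClass == "unclassified"))
})

test_that("genotypes follow the 0.2/0.8 fraction and depth-5 rules", {
  mkGeno <- function(nSupp, nConc) {
    supp <- if (nSupp > 0) delCluster(nSupp, 50000L, 55000L) else NULL
    conc <- if (nConc > 0) rbindlist(lapply(seq_len(nConc), function(i)
      pairRows(2000L + i, "chr1", 50000L - 250L - i * 2L, 500L))) else NULL
    prs <- labelPairs(rbind(supp, conc))
    genotypeVariant(prs, "chr1", 50000L, 55000L, "deletion", testModel)
  }
  expect_equal(mkGeno(10, 10)$call, "het")     # f = 0.5
  expect_equal(mkGeno(17, 3)$call, "hom")      # f = 0.85
  expect_equal(mkGeno(4, 0)$call, "no_call")   # depth 4 < 5
  expect_equal(mkGeno(0, 20)$call, "non_carrier")
  expect_equal(mkGeno(2, 18)$call, "non_carrier")  # f = 0.1 < 0.2
})

test_that("cross-sample merging chains, keeps best support, is order-stable", {
  calls <- rbind(mkCall(10000, 15000, "both", 20L, "S1"),
                 mkCall(10100, 15100, "both", 30L, "S2"),
                 mkCall(10200, 15200, "both", 10L, "S3"),
                 mkCall(40000, 45000, "both", 9L, "S2"))
  m <- mergeAcrossSamples(calls, ci = 500L)
  expect_equal(nrow(m), 2L)
  expect_equal(m$start[1], 10100L)   # highest support wins coordinates
  expect_equal(m$nSamples[1], 3L)
  # deletions 2 kb apart stay distinct
  far <- rbind(mkCall(10000, 15000, "both", 5L, "S1"),
               mkCall(12000, 17000, "both", 5L, "S2"))
  expect_equal(nrow(mergeAcrossSamples(far, ci = 500L)), 2L)
  # catalogue invariant to input order
  m2 <- mergeAcrossSamples(calls[sample(.N, .N)], ci = 500L)
  expect_identical(as.data.frame(m), as.data.frame(m2))
})

test_that("pool frequencies reflect carrier dosage", {
  hom <- delCluster(20, 50000L, 55000L)
  prs <- labelPairs(hom)
  cat1 <- data.table(variant_id = "V1", chrom = "chr1", start = 50000L,
                     end = 55000L, len = 5001L, type = "deletion")
  pf <- estimatePoolFrequency(prs, cat1, testModel)
  expect_equal(pf$frequency, 1)
  expect_true(pf$fixedInPool)
  # absent variant: only reference-concordant pairs crossing the breakpoint
  conc <- rbindlist(lapply(1:20, function(i)
    pairRows(3000L + i, "chr1", 50000L - 250L - 2L * i, 500L)))
  pf0 <- estimatePoolFrequency(labelPairs(conc), cat1, testModel)
  expect_equal(pf0$frequency, 0)
  expect_false(pf0$fixedInPool)
  # no informative fragments: frequency undefined
  pfNA <- estimatePoolFrequency(labelPairs(pairRows(1L, "chr5", 100L, 500L)),
                                cat1, testModel)
  expect_true(is.na(pfNA$frequency))
})
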