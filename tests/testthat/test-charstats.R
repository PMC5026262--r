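test_that("affected genes follow the overlap rules for each variant type", {
  genes <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(c(1000, 5000), c(2000, 6000)))
  genes$gene_id <- c("gA", "gB")
  cat1 <- data.table(
    chrom = "chr1", start = c(1500L, 5100L, 3000L),
    end = c(2500L, 5200L, 3100L),
    type = c("deletion", "insertion", "insertion"))
  expect_setequal(affectedGenes(cat1, genes), c("gA", "gB"))
  # an insertion interval only partially inside a gene does not count
  cat2 <- data.table(chrom = "chr1", start = 900L, end = 1100L,
                     type = "insertion")
  expect_length(affectedGenes(cat2, genes), 0)
  # the same interval as a deletion does count
  cat2$type <- "deletion"
  expect_equal(affectedGenes(cat2, genes), "gA")
})

test_that("variant randomization matches exhaustive placement on a toy", {
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(4001, 6000))
  genes$gene_id <- "gA"
  cat1 <- data.table(chrom = "chr1", start = 1L, end = 1000L,
                     type = "deletion")
  r <- randomizeVariantPlacement(cat1, c(chr1 = 10000), genes, n = 400,
                                 seed = 5)
  # exhaustive: starts 1..9001; overlap iff start in [3002, 6000]
  exact <- length(3002:6000) / 9001
  expect_lt(abs(r$nullMean - exact), 0.08)
  expect_equal(r$observed, 0)

  # no genes: every replicate overlaps zero genes
  r0 <- randomizeVariantPlacement(cat1, c(chr1 = 10000), genes[0], n = 20,
                                  seed = 5)
  expect_true(all(r0$replicates == 0))
  # wall-to-wall genes: every replicate hits at least one gene per variant
  wall <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10000))
  wall$gene_id <- "gAll"
  rw <- randomizeVariantPlacement(cat1, c(chr1 = 10000), wall, n = 20,
                                  seed = 5)
  expect_true(all(rw$replicates >= 1))
  expect_error(randomizeVariantPlacement(
    data.table(chrom = "chr1", start = 1L, end = 20000L, type = "deletion"),
    c(chr1 = 10000), genes), "longer")
})

test_that("Poisson window enrichment matches the cumulative sum", {
  w <- tileWindows(c(chr1 = 1e6), 2.5e5)
  res <- poissonWindowEnrichment(w, c(8L, 0L, 2L, 1L), lambda = 2)
  # p(X >= 8 | lambda = 2) ~ 0.0011, by direct summation
  psum <- 1 - sum(exp(-2) * 2^(0:7) / factorial(0:7))
  expect_equal(res$pvalue[1], psum, tolerance = 1e-12)
  expect_equal(round(res$pvalue[1], 4), 0.0011)
  expect_equal(res$pvalue[2], 1)
  # monotone decreasing in the observed count
  counts <- 0:10
  ps <- poissonWindowEnrichment(tileWindows(c(chr1 = 11 * 2.5e5), 2.5e5),
                                counts, lambda = 2)$pvalue
  expect_true(all(diff(ps) < 0))
  # per-chromosome lambda scope
  w2 <- tileWindows(c(chrA = 5e5, chrB = 5e5), 2.5e5)
  res2 <- poissonWindowEnrichment(w2, c(4L, 0L, 10L, 10L),
                                  scope = "chromosome")
  expect_equal(res2$lambda, c(2, 2, 10, 10))
})

test_that("window repetitiveness reflects genome-wide k-mer copy number", {
  unit <- PanSV:::randomDna(100)
  genome <- Biostrings::DNAStringSet(c(
    chrR = strrep(unit, 10),         # every 20-mer occurs ~10 times
    chrU = PanSV:::randomDna(1000)))
  w <- tileWindows(genome, 1000)
  sc <- windowRepetitiveness(genome, w, k = 20)
  expect_gt(sc[1], 8)
  expect_lt(sc[2], 1.5)
})

test_that("repetitiveness contrast equals a hand-computed rank test", {
  scores <- c(5.1, 4.2, 6.3, 1.0, 1.2, 0.9, 1.1, 1.3)
  counts <- c(3L, 2L, 4L, 0L, 0L, 0L, 0L, 0L)
  res <- windowRepetitivenessContrast(scores, counts, thresholds = 1L)
  hi <- scores[counts >= 1]; lo <- scores[counts == 0]
  # brute-force Mann-Whitney U and exact p
  U <- sum(outer(hi, lo, ">")) + 0.5 * sum(outer(hi, lo, "=="))
  expect_equal(res$W, U)
  expect_equal(res$pvalue,
               min(1, 2 * (1 - stats::pwilcox(U - 1, length(hi),
                                              length(lo)))),
               tolerance = 1e-10)
  # identical score distributions in the two groups: p ~ 1
  resEq <- windowRepetitivenessContrast(rep(c(1, 2), 8),
                                        c(rep(0L, 8), rep(1L, 8)),
                                        thresholds = 1L)
  expect_gt(resEq$pvalue, 0.5)
  # empty carrying group: NA with notice columns filled
  resNA <- windowRepetitivenessContrast(scores, rep(0L, 8), thresholds = 1L)
  expect_true(is.na(resNA$pvalue))
})

test_that("CNV clustering p-values match exhaustive label enumeration", {
  genes <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(seq(1, 10 * 1000, 1000)[1:10], width = 500))
  genes$gene_id <- paste0("g", 1:10)
  windows <- tileWindows(c(chr1 = 10000), 2000)  # 2 genes per window
  # exhaustive null over all C(10,4) subsets
  mids <- GenomicRanges::start(genes) + 249
  winOf <- findInterval(mids, seq(1, 10000, 2000))
  clusteredOf <- function(sel) {
    t <- tabulate(winOf[sel], nbins = 5)
    sum(t[t >= 2])
  }
  combs <- combn(10, 4)
  nullAll <- apply(combs, 2, clusteredOf)
  cnv <- paste0("g", c(1, 2, 3, 4))   # two full windows: observed = 4
  obs <- clusteredOf(1:4)
  exactP <- (sum(nullAll >= obs)) / ncol(combs)
  r <- cnvClusterTest(cnv, genes, windows, sims = 4000, seed = 9)
  expect_equal(r$observed, obs)
  expect_lt(abs(r$p - exactP), 0.05)
  # all CNVs in one window, null (almost) never as extreme
  # all genes CNV: observed equals every replicate, p = 1
  rAll <- cnvClusterTest(genes$gene_id, genes, windows, sims = 200,
                         seed = 9)
  expect_equal(rAll$p, 1)
  rFew <- cnvClusterTest("g1", genes, windows, sims = 100, seed = 9)
  expect_equal(rFew$p, 1)
})

test_that("telomere-distance chi-square equals its definition", {
  # 200 genes uniform over 22 Mb on one chromosome
  pos <- seq(5e4, 21.95e6, length.out = 200)
  genes <- GenomicRanges::GRanges("chrT", IRanges::IRanges(pos, width = 100))
  genes$gene_id <- paste0("g", 1:200)
  chromLen <- c(chrT = 22e6)
  # CNVs exactly proportional to genes: every gene a CNV
  rProp <- telomereDistanceTest(genes$gene_id, genes, chromLen)
  expect_equal(rProp$chisq, 0, tolerance = 1e-12)
  expect_equal(rProp$p, 1)
  # all CNVs within 2 Mb of an end
  nearEnd <- genes$gene_id[pos < 2e6 | pos > 20e6]
  rEnd <- telomereDistanceTest(nearEnd, genes, chromLen)
  expect_lt(rEnd$p, 0.001)
  expect_equal(rEnd$chisq,
               sum((rEnd$table$observed - rEnd$table$expected)^2 /
                     rEnd$table$expected), tolerance = 1e-12)
})

test_that("FPKM computation and the expressed flag follow the definition", {
  counts <- matrix(c(100L, 0L, 0L, 0L, 0L, 0L, 0L, 0L), 2, byrow = TRUE,
                   dimnames = list(c("gA", "gB"),
                                   paste0("t", 1:4)))
  fp <- computeFpkm(counts, transcriptLengths = c(2000, 1000),
                    totals = c(1e6, 1e6, 2e6, 1e6))
  expect_equal(fp$fpkm["gA", "t1"], 50)
  expect_equal(fp$fpkm["gA", "t3"], 0)
  expect_true(fp$expressed["gA"])
  expect_false(fp$expressed["gB"])
  # expressed on a single non-zero tissue
  counts["gB", "t2"] <- 1L
  expect_true(computeFpkm(counts, c(2000, 1000))$expressed["gB"])
  expect_error(computeFpkm(counts, c(2000, 0)), "positive")
})

test_that("randomization mean test matches exhaustive subset enumeration", {
  allv <- c(1, 2, 3, 10, 11, 12)
  aff <- c(1, 2)   # observed mean 1.5, lower than almost all subsets
  r <- randomizationMeanTest(aff, allv, s = 3000, direction = "lower",
                             seed = 3)
  combs <- combn(6, 2)
  exact <- mean(colMeans(matrix(allv[combs], 2)) <= 1.5)
  expect_lt(abs(r$p - exact), 0.03)
  # extreme case: affected mean below every replicate
  rx <- randomizationMeanTest(c(-100, -200), allv, s = 500,
                              direction = "lower", seed = 4)
  expect_equal(rx$p, 1 / 501)
  # affected = all genes: every subset is the full set
  rall <- randomizationMeanTest(allv, allv, s = 100, direction = "lower",
                                seed = 5)
  expect_equal(rall$p, 1)
  # the literal printed bookkeeping flips the tail
  rlit <- randomizationMeanTest(c(-100, -200), allv, s = 500,
                                direction = "lower", literal = TRUE,
                                seed = 4)
  expect_equal(rlit$p, 1)
  expect_error(randomizationMeanTest(numeric(), allv), "empty")
})

test_that("term enrichment equals the hypergeometric tail", {
  bg <- sprintf("g%04d", 1:1000)
  subset <- bg[1:20]
  gt <- data.table(gene_id = c(bg[1:10], bg[21:60]), term = "T1")
  res <- fisherTermEnrichment(subset, bg, gt)
  # subset 10/20 with term, background 50/1000
  expect_equal(res$pvalue,
               stats::phyper(10 - 1, 50, 950, 20, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_true(res$significant)

  # term carried by everything: p = 1
  gtAll <- data.table(gene_id = bg, term = "T2")
  expect_equal(fisherTermEnrichment(subset, bg, gtAll)$pvalue, 1)
  # terms absent from the subset are not reported
  gtOut <- data.table(gene_id = bg[900:950], term = "T3")
  expect_equal(nrow(fisherTermEnrichment(subset, bg, gtOut)), 0L)
  expect_error(fisherTermEnrichment(c("zzz"), bg, gt), "contained")
})
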