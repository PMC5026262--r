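test_that("the seeded ungapped search finds exact and diverged homology", {
  set.seed(61)
  te <- PanSV:::randomDna(2000)
  hits <- ungappedLocalHits(te, te)
  expect_gte(nrow(hits), 1)
  expect_equal(hits$qstart[1], 1L)
  expect_equal(hits$qend[1], 2000L)
  expect_lt(hits$evalue[1], 1e-100)
  # 10% divergence still yields strong local hits covering most of the query
  div <- mutateSequence(te, 0.10)
  h2 <- ungappedLocalHits(te, div, maxE = 1e-10)
  cov <- sum(IRanges::width(IRanges::reduce(
    IRanges::IRanges(h2$qstart, h2$qend)))) / 2000
  expect_gt(cov, 0.8)
  # reverse-complement homology is found on the minus strand
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(te)))
  h3 <- ungappedLocalHits(te, rc)
  expect_true(any(h3$strand == "-"))
  # unrelated sequence: nothing at stringent E
  h4 <- ungappedLocalHits(PanSV:::randomDna(500), PanSV:::randomDna(500),
                          maxE = 1e-20)
  expect_equal(nrow(h4), 0L)
})

# fixture: genome with one annotated Gypsy copy, plus library entries
cascadeFixture <- function() {
  set.seed(62)
  gypsy <- PanSV:::randomDna(3000)
  hat <- PanSV:::randomDna(2000)
  backbone <- PanSV:::randomDna(30000)
  chr <- paste0(substr(backbone, 1, 10000), gypsy,
                substr(backbone, 10001, 30000))
  genome <- Biostrings::DNAStringSet(c(chr1 = chr))
  repeats <- GenomicRanges::GRanges("chr1",
                                    IRanges::IRanges(10001, 13000))
  repeats$family <- "famG"
  repeats$superfamily <- "LTR Gypsy"
  repeats$class <- "I"
  teLibrary <- Biostrings::DNAStringSet(c(famG = gypsy, famH = hat))
  teSuper <- c(famG = "LTR Gypsy", famH = "TIR hAT")
  list(genome = genome, repeats = repeats, teLibrary = teLibrary,
       teSuper = teSuper, gypsy = gypsy, hat = hat)
}

test_that("step 1 labels deletions overlapping annotated repeats", {
  fx <- cascadeFixture()
  cl <- classifyDeletionSequence("chr1", 10001, 13000, fx$genome,
                                 fx$repeats, fx$teLibrary, fx$teSuper)
  expect_equal(cl$superfamily, "LTR Gypsy")
  expect_equal(cl$class, "I")
  expect_equal(cl$evidence, "annotation-overlap")
  # a sequence classifiable at step 1 never reaches the homology steps
  cl2 <- classifyDeletionSequence("chr1", 9500, 12500, fx$genome,
                                  fx$repeats, fx$teLibrary, fx$teSuper)
  expect_equal(cl2$evidence, "annotation-overlap")   # 2500/3001 covered
})

test_that("step 2 labels library-covered sequences away from annotation", {
  fx <- cascadeFixture()
  # deletion at 20001..22000 equals the hAT entry (planted into the genome)
  g2 <- fx$genome
  chr <- as.character(g2[[1]])
  substr(chr, 20001, 22000) <- fx$hat
  g2 <- Biostrings::DNAStringSet(c(chr1 = chr))
  cl <- classifyDeletionSequence("chr1", 20001, 22000, g2, fx$repeats,
                                 fx$teLibrary, fx$teSuper)
  expect_equal(cl$superfamily, "TIR hAT")
  expect_equal(cl$class, "II")
  expect_equal(cl$evidence, "library-scan")
})

test_that("step 3 applies the 80%-length or both-400bp-ends rules", {
  fx <- cascadeFixture()
  extra <- PanSV:::randomDna(1700)
  # deletion of 2000 bp: an extraDb element matches 85% of its length
  delSeq <- paste0(extra, PanSV:::randomDna(300))
  chr <- paste0(as.character(fx$genome[[1]]), delSeq, PanSV:::randomDna(500))
  g2 <- Biostrings::DNAStringSet(c(chr1 = chr))
  st <- 33001L + 1e4  # wherever the deletion starts: compute exactly
  st <- nchar(as.character(fx$genome[[1]])) + 1L
  cl <- classifyDeletionSequence(
    "chr1", st, st + 1999L, g2, fx$repeats, fx$teLibrary, fx$teSuper,
    extraDb = Biostrings::DNAStringSet(c(helX = extra)),
    extraSuperfamily = c(helX = "Helitron"))
  expect_equal(cl$superfamily, "Helitron")
  expect_equal(cl$evidence, "homology-search")

  # both 400 bp extremities covered, middle missing: still classified
  ends <- paste0(substr(extra, 1, 450), PanSV:::randomDna(1100),
                 substr(extra, 451, 900))
  chr3 <- paste0(as.character(fx$genome[[1]]), ends)
  g3 <- Biostrings::DNAStringSet(c(chr1 = chr3))
  cl3 <- classifyDeletionSequence(
    "chr1", st, st + nchar(ends) - 1L, g3, fx$repeats, fx$teLibrary,
    fx$teSuper,
    extraDb = Biostrings::DNAStringSet(c(helX = extra)),
    extraSuperfamily = c(helX = "Helitron"))
  expect_equal(cl3$superfamily, "Helitron")

  # one matching end only: unclassified
  oneEnd <- paste0(substr(extra, 1, 450), PanSV:::randomDna(1550))
  chr4 <- paste0(as.character(fx$genome[[1]]), oneEnd)
  g4 <- Biostrings::DNAStringSet(c(chr1 = chr4))
  cl4 <- classifyDeletionSequence(
    "chr1", st, st + nchar(oneEnd) - 1L, g4, fx$repeats, fx$teLibrary,
    fx$teSuper,
    extraDb = Biostrings::DNAStringSet(c(helX = extra)),
    extraSuperfamily = c(helX = "Helitron"))
  expect_equal(cl4$superfamily, "unclassified")
  expect_equal(cl4$evidence, "none")
})

test_that("planted TE deletions are annotated through the cascade", {
  sim <- tinyStudy()
  toy <- sim$toy
  teDel <- sim$planted$truth[type == "deletion" & teClass != "none"]
  skip_if(nrow(teDel) == 0, "no TE-derived deletion planted")
  ann <- annotateDeletions(teDel, toy$genome, toy$repeats, toy$teLibrary,
                           toy$teSuperfamily)
  planted <- unname(toy$teSuperfamily[teDel$teFamily])
  expect_true(all(ann$superfamily == planted))
  expect_true(all(ann$evidence == "annotation-overlap"))
  expect_true(all(ann$teClass == "II"))  # class I never planted as deletion
})

test_that("LTR dating inverts the planted divergence", {
  expect_equal(ltrInsertionTime(0), 0)
  expect_equal(ltrInsertionTime(0.00944, 4.72e-9), 1e6)
  expect_equal(ltrInsertionTime(0.2), 2 * ltrInsertionTime(0.1))
  expect_error(ltrInsertionTime(-1), "non-negative")
  expect_error(ltrInsertionTime(0.1, 0), "positive")

  set.seed(63)
  for (K in c(0.05, 0.1, 0.2, 0.3)) {
    ltr <- replicate(40, PanSV:::randomDna(1000))
    ltr3 <- vapply(ltr, mutateSequence, "", rate = K)
    dated <- dateLtrElements(ltr, ltr3)
    expect_lt(abs(median(dated$K) - K) / K, 0.15)
    expect_equal(dated$T, dated$K / (2 * 4.72e-9))
  }
})

test_that("age-distribution comparison matches a brute-force ECDF scan", {
  same <- c(1, 2, 3, 4, 5)
  r <- compareAgeDistributions(same, same)
  expect_equal(r$D, 0)
  expect_equal(r$p, 1)
  r2 <- compareAgeDistributions(c(1, 2, 3), c(11, 12, 13))
  expect_equal(r2$D, 1)
  # brute-force maximum ECDF difference on random small inputs
  set.seed(64)
  for (i in 1:5) {
    x <- runif(7); y <- runif(9)
    grid <- sort(c(x, y))
    Dbrute <- max(vapply(grid, function(t)
      abs(mean(x <= t) - mean(y <= t)), 0))
    expect_equal(compareAgeDistributions(x, y)$D, Dbrute, tolerance = 1e-12)
  }
  expect_error(compareAgeDistributions(1, c(1, 2)), "two")
})
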