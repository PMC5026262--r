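test_that("toy genome generation is seed-deterministic", {
  p <- tinyParams()
  a <- buildToyGenome(p, seed = 5)
  b <- buildToyGenome(p, seed = 5)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(as.character(a$teLibrary), as.character(b$teLibrary))
  expect_identical(as.data.frame(a$repeats), as.data.frame(b$repeats))
  expect_identical(as.data.frame(a$genes), as.data.frame(b$genes))
})

test_that("a config without TE families yields an empty repeat annotation", {
  p <- tinyParams(nTeFamilies = 0L, teFraction = 0)
  toy <- buildToyGenome(p, seed = 2)
  expect_length(toy$repeats, 0)
  expect_length(toy$teLibrary, 0)
})

test_that("LTR families carry identical 5' and 3' terminal repeats", {
  toy <- buildToyGenome(tinyParams(), seed = 4)
  ltrFams <- names(toy$teSuperfamily)[
    toy$teSuperfamily %in% c("LTR Gypsy", "LTR Copia", "LTR")]
  skip_if(length(ltrFams) == 0, "no LTR family drawn for this seed")
  for (f in ltrFams) {
    s <- toy$teLibrary[[f]]
    L <- toy$params$ltrLength
    expect_identical(as.character(Biostrings::subseq(s, 1, L)),
                     as.character(Biostrings::subseq(s, length(s) - L + 1,
                                                     length(s))))
  }
})

test_that("genes are non-overlapping and clear of repeats", {
  toy <- tinyStudy()$toy
  ov <- GenomicRanges::findOverlaps(toy$genes, drop.self = TRUE)
  expect_length(ov, 0)
  expect_length(GenomicRanges::findOverlaps(toy$genes, toy$repeats), 0)
})

test_that("planted variants are realized exactly in the haplotypes", {
  sim <- tinyStudy()
  toy <- sim$toy; pl <- sim$planted
  s <- "Pn1"
  haps <- buildHaplotypes(toy, pl, s)
  geno <- pl$genotypes[, s]
  for (hap in 1:2) {
    carried <- pl$truth[
      geno[variant_id] == 2L |
        (geno[variant_id] == 1L & pl$hapOfHet[variant_id, s] == hap)]
    for (chromName in names(toy$genome)) {
      ev <- carried[chrom == chromName][order(start)]
      refLen <- Biostrings::width(toy$genome)[chromName]
      expLen <- refLen -
        sum(ev[type == "deletion", len]) + sum(ev[type == "insertion", len])
      expect_equal(Biostrings::width(haps[[hap]])[chromName],
                   unname(expLen))
      # junction sequence of the first carried deletion is realized
      del1 <- ev[type == "deletion"][1]
      if (!is.na(del1$start)) {
        ref <- as.character(toy$genome[[chromName]])
        junction <- paste0(substr(ref, del1$start - 30L, del1$start - 1L),
                           substr(ref, del1$end + 1L, del1$end + 30L))
        expect_true(grepl(junction, as.character(haps[[hap]][[chromName]]),
                          fixed = TRUE))
      }
    }
  }
})

test_that("zero planted variants leave haplotypes identical to the reference", {
  p <- tinyParams(nDeletions = 0L, nInsertions = 0L, teDelFraction = 0)
  toy <- buildToyGenome(p, seed = 3)
  pl <- plantStructuralVariants(toy, StudyDesign(), seed = 3)
  expect_equal(nrow(pl$truth), 0L)
  haps <- buildHaplotypes(toy, pl, "Pd1")
  expect_identical(as.character(haps[[1]]), as.character(toy$genome))
})

test_that("species patterns constrain carriers and the reference individual", {
  sim <- tinyStudy()
  pl <- sim$planted
  d <- sim$design
  sp <- speciesOf(d)
  hd <- highDepthSamples(d)
  for (i in seq_len(nrow(pl$truth))) {
    pat <- strsplit(pl$truth$pattern[i], "/", fixed = TRUE)[[1]]
    g <- pl$genotypes[i, hd]
    carrierSp <- unique(sp[hd][g > 0])
    expect_setequal(carrierSp, pat)
  }
  # the Pt reference individual is never a homozygous carrier
  expect_true(all(pl$genotypes[, "Pt1"] < 2L))
})

test_that("simulated depth matches the target within 10%", {
  sim <- tinyStudy()
  a <- sim$alignments[["Pn2"]]
  basesAligned <- a[aligned == TRUE, sum(end - start + 1)]
  gsize <- sum(sim$toy$params$chromLengths)
  expect_lt(abs(basesAligned / gsize - 30) / 30, 0.1)
})

test_that("pairs straddling a homozygous deletion show inflated inserts", {
  sim <- tinyStudy()
  pl <- sim$planted
  hom <- pl$truth[type == "deletion"][
    pl$genotypes[variant_id, "Pn1"] == 2L][1]
  skip_if(is.na(hom$variant_id), "no homozygous deletion for Pn1")
  fd <- findDiscordantPairs(sim$alignments[["Pn1"]])
  sup <- fd$pairs[type == "del" & chrom == hom$chrom &
                    lend < hom$start & rstart > hom$end]
  expect_gte(nrow(sup), 5)
  # observed span ~ deletion length + library insert
  expect_lt(abs(median(sup$span) - hom$len - fd$model[["mean"]]),
            4 * fd$model[["sd"]])
})

test_that("reads inside inserted elements become unaligned mobile mates", {
  sim <- tinyStudy()
  pl <- sim$planted
  ins <- pl$truth[type == "insertion"][
    pl$genotypes[variant_id, "Pn1"] > 0L][1]
  skip_if(is.na(ins$variant_id), "no insertion carried by Pn1")
  fd <- findDiscordantPairs(sim$alignments[["Pn1"]])
  anchors <- fd$pairs[type == "anchor" & chrom == ins$chrom &
                        abs(anchorEnd - ins$start) < 600]
  expect_gt(nrow(anchors), 0)
  # mobile sequences are substrings of the inserted element
  tele <- as.character(sim$toy$teLibrary[[ins$teFamily]])
  mob <- anchors[!is.na(mobileSeq), mobileSeq]
  expect_true(any(vapply(mob, grepl, TRUE, x = tele, fixed = TRUE)))
})

test_that("NB gene counts scale with copy number and collapse to Poisson", {
  ids <- sprintf("g%03d", 1:400)
  cn <- matrix(2L, 400, 6, dimnames = list(ids, paste0("s", 1:6)))
  base <- rep(100, 400)
  k2 <- simulateGeneCounts(cn, base, alpha = 0.05, seed = 2)
  expect_lt(abs(mean(k2) - 100) / 100, 0.05)
  cn4 <- cn; cn4[, 1:3] <- 4L
  k4 <- simulateGeneCounts(cn4, base, alpha = 0.05, seed = 2)
  expect_lt(abs(mean(k4[, 1:3]) / mean(k4[, 4:6]) - 2), 0.1)
  # Poisson limit: variance/mean ~ 1
  kp <- simulateGeneCounts(cn, rep(10, 400), alpha = 0, seed = 3)
  vm <- mean(apply(kp, 1, var)) / mean(kp)
  expect_lt(abs(vm - 1), 0.15)
  expect_error(simulateGeneCounts(cn - 3L, base), "non-negative")
})

test_that("pooling downsamples each sample to the target depth", {
  sim <- tinyStudy()
  gsize <- sum(sim$toy$params$chromLengths)
  two <- sim$alignments[c("Pn1", "Pn2")]
  pool <- buildPool(two, gsize, targetDepth = 5, readLength = 100, seed = 4)
  perSample <- pool[, .(nfrag = data.table::uniqueN(frag)), by = sample_id]
  target <- round(5 * gsize / 200)
  expect_equal(perSample$nfrag, rep(target, 2))
  # deterministic under a fixed seed
  pool2 <- buildPool(two, gsize, targetDepth = 5, readLength = 100, seed = 4)
  expect_identical(pool$frag, pool2$frag)
  # a sample already at/below target is used in full, with a warning below
  small <- pool[sample_id == "Pn1"]
  expect_warning(buildPool(list(Pn1 = small), gsize, targetDepth = 10),
                 "below")
})

test_that("ortholog CDS pairs honour their substitution targets", {
  expect_error(simulateOrthologCds(2, nCodons = 49), "150")
  same <- simulateOrthologCds(3, nCodons = 60, dnTarget = 0, dsTarget = 0,
                              seed = 5)
  expect_identical(as.character(same$cds1), as.character(same$cds2))
  syn <- simulateOrthologCds(5, nCodons = 100, dnTarget = 0,
                             dsTarget = 0.1, seed = 6)
  expect_true(all(syn$truth$nonSynSubs == 0))
  expect_true(sum(syn$truth$synSubs) > 0)
  res <- dndsPairs(syn$cds1, syn$cds2)
  expect_true(all(res$dN < 1e-8))
  expect_true(any(res$dS > 0))
})
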