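suppressMessages(library(data.table))

# small study used by unit tests: 0.4 Mb, 7 high-depth samples
.fixtureCache <- new.env(parent = emptyenv())

tinyParams <- function(...) {
  args <- utils::modifyList(
    list(chromLengths = c(chr1 = 2e5, chr2 = 2e5), nGenes = 60L,
         nTeFamilies = 10L, nDeletions = 12L, nInsertions = 12L,
         nCnvGenes = 8L),
    list(...))
  do.call(simParams, args)
}

tinyStudy <- function() {
  if (is.null(.fixtureCache$tiny)) {
    .fixtureCache$tiny <- simulateStudy(tinyParams(), StudyDesign(),
                                        seed = 11L)
  }
  .fixtureCache$tiny
}

# full-scale study under the default conditions (3 Mb, 30x); shared between
# the recovery and pan-genome acceptance checks
defaultStudy <- function() {
  if (is.null(.fixtureCache$full)) {
    sim <- simulateStudy(simParams(), StudyDesign(), seed = 7L)
    cv <- callStructuralVariants(sim$alignments, sim$toy$teLibrary,
                                 sim$toy$teSuperfamily)
    .fixtureCache$full <- list(sim = sim, cv = cv)
  }
  .fixtureCache$full
}

# hand-built alignment rows (1-based closed coordinates)
alnRow <- function(frag, read, sample_id, chrom, start, end, strand,
                   mapq = 60L, mateChrom = chrom, mateStart = NA_integer_,
                   mateStrand = NA_character_, isize = NA_integer_,
                   uniq = TRUE, aligned = TRUE, seq = NA_character_) {
  data.table(frag = as.integer(frag), read = as.integer(read),
             sample_id = sample_id, chrom = chrom,
             start = as.integer(start), end = as.integer(end),
             strand = strand, mapq = as.integer(mapq),
             mateChrom = mateChrom, mateStart = as.integer(mateStart),
             mateStrand = mateStrand, isize = as.integer(isize),
             uniq = uniq, aligned = aligned, seq = seq)
}

# a pair of 100 bp reads with given outer span, as alignment rows
pairRows <- function(frag, chrom, start1, span, sample_id = "S1",
                     mapq = 60L, rl = 100L) {
  s2 <- start1 + span - rl
  rbind(
    alnRow(frag, 1L, sample_id, chrom, start1, start1 + rl - 1L, "+",
           mapq = mapq, mateStart = s2, mateStrand = "-", isize = span),
    alnRow(frag, 2L, sample_id, chrom, s2, s2 + rl - 1L, "-",
           mapq = mapq, mateStart = start1, mateStrand = "+", isize = span))
}

# many concordant pairs so the insert model is estimable
backgroundPairs <- function(n = 150L, chrom = "chr9", sample_id = "S1",
                            seed = 1L) {
  set.seed(seed)
  rbindlist(lapply(seq_len(n), function(i) {
    pairRows(9000L + i, chrom, 1000L + 37L * i,
             span = round(rnorm(1, 500, 50)), sample_id = sample_id)
  }))
}

testModel <- c(mean = 500, sd = 50)
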