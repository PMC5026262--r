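#' Parameters of the synthetic study
#'
#' Bundles every tunable of the toy-genome generator. Defaults emulate the
#' study conditions: a small multi-chromosome reference, a TE library spanning
#' the common plant superfamilies, 2x100 bp paired-end libraries from a
#' 400-600 bp insert-size fraction (mean 500, sd 50), high-depth samples at
#' 30x, a low-depth pool at 5x per member, deletions of 1-25 kb, and
#' TE insertions drawn from the library (class I strictly as insertions,
#' class II as both insertions and deletions).
#'
#' @param chromLengths named integer vector of chromosome lengths.
#' @param nGenes number of non-overlapping gene models to place.
#' @param nTeFamilies number of TE families in the library.
#' @param teFraction approximate fraction of the genome covered by planted
#'   repeat copies.
#' @param ltrLength length (bp) of the identical 5'/3' terminal repeats of
#'   LTR-class families.
#' @param nDeletions,nInsertions planted INDEL counts.
#' @param nCnvGenes number of genes given altered copy number.
#' @param delRange deletion length range (bp).
#' @param teDelFraction fraction of deletions placed exactly over an annotated
#'   class II repeat copy (TE-related deletions).
#' @param exclusion minimum distance (bp) between planted variants.
#' @param insertMean,insertSd,readLength paired-end library model (bp).
#' @param depth,poolDepth target sequencing depth (x) for high-depth samples
#'   and pool members.
#' @param baseMeanLog,baseMeanSd log-normal parameters of per-gene baseline
#'   fragment counts for the depth-of-coverage track.
#' @param dispersion negative-binomial dispersion of simulated gene counts.
#' @param delPatternProbs,insPatternProbs named probabilities over the seven
#'   species-pattern categories (Pn, Pd, Pt, Pn/Pd, Pn/Pt, Pd/Pt, Pn/Pd/Pt).
#' @param pFixedDel,pFixedIns probability that a Pn- or Pd-involving variant
#'   is fixed (homozygous in every carrier-species sample).
#' @param referenceErrorFraction fraction of variants allowed to be
#'   homozygous in the reference individual (assembly-artifact emulation).
#' @param copyDivergence substitution divergence applied to each planted
#'   repeat copy and inserted element relative to its family consensus.
#' @return a named list of parameters.
#' @export
simParams <- function(
    chromLengths = c(chr1 = 1e6, chr2 = 1e6, chr3 = 1e6),
    nGenes = 300L, nTeFamilies = 30L, teFraction = 0.25, ltrLength = 300L,
    nDeletions = 60L, nInsertions = 60L, nCnvGenes = 40L,
    delRange = c(1000L, 25000L), teDelFraction = 0.6, exclusion = 1000L,
    insertMean = 500, insertSd = 50, readLength = 100L,
    depth = 30, poolDepth = 5,
    baseMeanLog = log(150), baseMeanSd = 0.6, dispersion = 0.01,
    delPatternProbs = c(Pn = 0.40, Pd = 0.22, Pt = 0.15, `Pn/Pd` = 0.116,
                        `Pn/Pt` = 0.017, `Pd/Pt` = 0.017, `Pn/Pd/Pt` = 0.038),
    insPatternProbs = c(Pn = 0.45, Pd = 0.25, Pt = 0.13, `Pn/Pd` = 0.139,
                        `Pn/Pt` = 0.003, `Pd/Pt` = 0.003, `Pn/Pd/Pt` = 0.012),
    pFixedDel = 0.78, pFixedIns = 0.62,
    referenceErrorFraction = 0, copyDivergence = 0.02) {
  if (insertMean <= 2 * readLength)
    stop("insert mean must exceed twice the read length")
  p <- as.list(environment())
  p$delPatternProbs <- delPatternProbs / sum(delPatternProbs)
  p$insPatternProbs <- insPatternProbs / sum(insPatternProbs)
  p
}

randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

#' Mutate a sequence at a given substitution density
#'
#' Applies `round(rate * nchar)` substitution events at uniformly random
#' positions (repeat hits allowed, so realized divergence saturates as in a
#' Kimura-type process). Each event is a transition with probability
#' `tsProb`, otherwise one of the two transversions.
#'
#' @param seq character scalar over ACGT.
#' @param rate expected substitution events per site.
#' @param tsProb probability that an event is a transition.
#' @return the mutated sequence (character scalar).
#' @export
mutateSequence <- function(seq, rate, tsProb = 0.5) {
  n <- nchar(seq)
  nev <- rpois(1, rate * n)
  if (nev == 0) return(seq)
  x <- strsplit(seq, "")[[1]]
  pos <- sample.int(n, nev, replace = TRUE)
  for (p in pos) {
    b <- x[p]
    if (runif(1) < tsProb) {
      x[p] <- TRANSITION[[b]]
    } else {
      x[p] <- sample(setdiff(c("A", "C", "G", "T"),
                             c(b, TRANSITION[[b]])), 1)
    }
  }
  paste(x, collapse = "")
}

SUPERFAMILIES <- data.frame(
  superfamily = c("LTR Gypsy", "LTR Copia", "LINE L1", "LTR", "SINE",
                  "TIR hAT", "Helitron", "TIR CACTA", "TIR PIF/Harbinger",
                  "TIR Mutator", "Class II unknown"),
  class = c("I", "I", "I", "I", "I", "II", "II", "II", "II", "II", "II"),
  minLen = c(8500, 4000, 3000, 1500, 200, 1500, 2000, 1500, 800, 1000, 800),
  maxLen = c(9500, 5000, 5000, 3000, 400, 3000, 4000, 3000, 1500, 2500, 2000),
  ltr = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
          FALSE, FALSE),
  weight = c(4, 3, 1, 1, 1, 3, 2, 2, 1, 1, 1),
  stringsAsFactors = FALSE
)

#' Class (I or II) implied by a superfamily label
#' @param superfamily character vector of superfamily labels.
#' @return "I", "II" or "unclassified" per element.
#' @export
classOfSuperfamily <- function(superfamily) {
  m <- setNames(SUPERFAMILIES$class, SUPERFAMILIES$superfamily)
  out <- unname(m[superfamily])
  out[is.na(out)] <- "unclassified"
  out
}

#' Build a toy reference genome with TE library and gene models
#'
#' Generates random chromosomes, a TE library whose families carry plant
#' superfamily labels (LTR families get identical 5'/3' terminal repeats),
#' plants repeat copies until roughly `teFraction` of the genome is
#' TE-derived (recorded as a repeat annotation), and places non-overlapping
#' gene models with CDS/UTR/intron structure in the repeat-free space.
#' Deterministic for a fixed seed.
#'
#' @param params a [simParams()] list.
#' @param seed integer RNG seed.
#' @return a list: `genome` (DNAStringSet), `teLibrary` (DNAStringSet named
#'   by family), `teSuperfamily` (named character, family -> superfamily),
#'   `teClass` (named character, family -> "I"/"II"), `genes` and `features`
#'   (GRanges, as [loadAnnotation()]), `repeats` (GRanges with `family`,
#'   `superfamily`, `class`), `params`.
#' @export
buildToyGenome <- function(params = simParams(), seed = 1L) {
  set.seed(seed)
  nf <- params$nTeFamilies
  fams <- sprintf("fam%02d", seq_len(nf))
  sf_idx <- if (nf > 0)
    sample(nrow(SUPERFAMILIES), nf, replace = TRUE,
           prob = SUPERFAMILIES$weight) else integer()
  teSuper <- setNames(SUPERFAMILIES$superfamily[sf_idx], fams)
  teClass <- setNames(SUPERFAMILIES$class[sf_idx], fams)
  lib <- character(nf)
  for (i in seq_len(nf)) {
    row <- SUPERFAMILIES[sf_idx[i], ]
    len <- round(runif(1, row$minLen, row$maxLen))
    if (row$ltr) {
      ltr <- randomDna(params$ltrLength)
      lib[i] <- paste0(ltr, randomDna(max(0L, len - 2L * params$ltrLength)),
                       ltr)
    } else {
      lib[i] <- randomDna(len)
    }
  }
  teLibrary <- DNAStringSet(setNames(lib, fams))

  chroms <- lapply(params$chromLengths, randomDna)
  # plant repeat copies
  rep_chrom <- character(); rep_start <- integer(); rep_end <- integer()
  rep_fam <- character()
  if (nf > 0 && params$teFraction > 0) {
    target <- params$teFraction * sum(params$chromLengths)
    placed <- 0; tries <- 0
    occ <- lapply(params$chromLengths, function(x) IRanges())
    while (placed < target && tries < 50 * nf) {
      tries <- tries + 1
      fi <- sample(nf, 1)
      L <- nchar(lib[fi])
      ci <- sample(length(chroms), 1)
      clen <- params$chromLengths[ci]
      if (clen < L + 400) next
      st <- sample.int(clen - L - 200L, 1) + 100L
      cand <- IRanges(st, st + L - 1L)
      if (length(findOverlaps(cand + 200L, occ[[ci]])) > 0) next
      occ[[ci]] <- c(occ[[ci]], cand)
      copy <- mutateSequence(lib[fi], params$copyDivergence)
      substr(chroms[[ci]], st, st + L - 1L) <- copy
      rep_chrom <- c(rep_chrom, names(params$chromLengths)[ci])
      rep_start <- c(rep_start, st); rep_end <- c(rep_end, st + L - 1L)
      rep_fam <- c(rep_fam, fams[fi])
      placed <- placed + L; tries <- 0
    }
  }
  repeats <- GRanges(rep_chrom, IRanges(rep_start, rep_end))
  repeats$family <- rep_fam
  repeats$superfamily <- unname(teSuper[rep_fam])
  repeats$class <- unname(teClass[rep_fam])

  # place genes in repeat-free space
  g_chrom <- character(); g_start <- integer(); g_end <- integer()
  occ <- split(ranges(repeats), factor(as.character(seqnames(repeats)),
                                       levels = names(params$chromLengths)))
  occ <- as.list(occ)
  tries <- 0
  while (length(g_start) < params$nGenes) {
    tries <- tries + 1
    if (tries > 200 * params$nGenes)
      stop("cannot place requested genes: capacity exceeded")
    L <- sample(1000:4000, 1)
    ci <- sample(length(chroms), 1)
    cn <- names(params$chromLengths)[ci]
    clen <- params$chromLengths[ci]
    st <- sample.int(as.integer(clen - L - 200L), 1) + 100L
    cand <- IRanges(st, st + L - 1L)
    if (length(findOverlaps(cand + 100L, occ[[cn]])) > 0) next
    occ[[cn]] <- c(occ[[cn]], cand)
    g_chrom <- c(g_chrom, cn); g_start <- c(g_start, st)
    g_end <- c(g_end, st + L - 1L)
  }
  ord <- order(match(g_chrom, names(params$chromLengths)), g_start)
  g_chrom <- g_chrom[ord]; g_start <- g_start[ord]; g_end <- g_end[ord]
  gid <- sprintf("gene%04d", seq_along(g_start))
  genes <- GRanges(g_chrom, IRanges(g_start, g_end),
                   strand = sample(c("+", "-"), length(gid), TRUE))
  genes$gene_id <- gid

  # gene structure: optional introns, UTR ends, CDS in between
  feat <- list()
  tlen <- integer(length(genes))
  for (i in seq_along(genes)) {
    s <- g_start[i]; e <- g_end[i]; L <- e - s + 1L
    nInt <- sample(0:2, 1)
    ints <- IRanges()
    if (nInt > 0 && L > 1200L) {
      pos <- sort(sample(seq(s + 400L, e - 400L), nInt * 2L))
      ints <- IRanges::reduce(IRanges(pos[seq(1, by = 2, length.out = nInt)],
                                      pos[seq(2, by = 2, length.out = nInt)]))
      ints <- ints[IRanges::width(ints) >= 40]
    }
    exons <- IRanges::setdiff(IRanges(s, e), ints)
    u5 <- min(sample(100:300, 1), IRanges::width(exons)[1] - 10L)
    u3 <- min(sample(100:300, 1),
              IRanges::width(exons)[length(exons)] - 10L)
    utr5 <- IRanges(s, s + u5 - 1L)
    utr3 <- IRanges(e - u3 + 1L, e)
    cds <- IRanges::setdiff(exons, c(utr5, utr3))
    tlen[i] <- sum(IRanges::width(exons))
    add <- function(r, tp) {
      if (length(r) == 0L) return(NULL)
      g <- GRanges(g_chrom[i], r, strand = strand(genes)[i])
      g$gene_id <- gid[i]; g$type <- tp
      g
    }
    feat[[i]] <- suppressWarnings(do.call(c, Filter(Negate(is.null), list(
      add(cds, "CDS"), add(ints, "intron"), add(utr5, "five_prime_UTR"),
      add(utr3, "three_prime_UTR")))))
  }
  genes$transcript_length <- tlen
  features <- suppressWarnings(do.call(c, feat))
  genome <- DNAStringSet(setNames(unlist(chroms),
                                  names(params$chromLengths)))
  list(genome = genome, teLibrary = teLibrary, teSuperfamily = teSuper,
       teClass = teClass, genes = genes, features = features,
       repeats = repeats, params = params)
}

PATTERN_LEVELS <- c("Pn", "Pd", "Pt", "Pn/Pd", "Pn/Pt", "Pd/Pt", "Pn/Pd/Pt")

samplePatternGeno <- function(pattern, design, fixed, refSample) {
  sp <- speciesOf(design)
  inPat <- strsplit(pattern, "/", fixed = TRUE)[[1]]
  g <- setNames(integer(length(sp)), names(sp))
  for (s in names(sp)) {
    if (!sp[s] %in% inPat) next
    if (fixed) {
      g[s] <- 2L
    } else {
      g[s] <- sample(c(0L, 1L, 2L), 1, prob = c(0.15, 0.45, 0.40))
    }
  }
  # reference individual: heterozygous only
  if (nzchar(refSample) && g[refSample] == 2L) g[refSample] <- 1L
  # every pattern species needs >= 1 carrier among high-depth samples
  hd <- highDepthSamples(design)
  for (spc in inPat) {
    cand <- hd[sp[hd] == spc]
    if (length(cand) && all(g[cand] == 0L)) {
      pick <- sample(cand, 1)
      g[pick] <- if (pick == refSample) 1L else sample(1:2, 1)
    }
  }
  g
}

#' Plant structural variants and define per-sample diploid genotypes
#'
#' Chooses deletion intervals (a configured fraction placed exactly over
#' annotated class II repeat copies, the rest over random background of
#' 1-25 kb), TE insertion points with element sequences drawn from the
#' library (class I and II), assigns each variant a species-pattern category,
#' a fixation status and per-sample zygosities consistent with the pattern
#' (the reference individual carries only heterozygous variants unless a
#' reference-error fraction is configured), and keeps all variants at least
#' `exclusion` bp apart.
#'
#' @param toy output of [buildToyGenome()].
#' @param design a [StudyDesign-class].
#' @param seed integer RNG seed.
#' @return list: `truth` (data.table: variant_id, type, chrom, start, end,
#'   len, teFamily, teClass, pattern, fixed; deletion coordinates are the
#'   reference interval, insertion start == end is the base after which the
#'   element is inserted), `genotypes` (variants x samples integer matrix of
#'   carrier allele counts), `hapOfHet` (same shape; which haplotype, 1 or 2,
#'   carries a heterozygous variant).
#' @export
plantStructuralVariants <- function(toy, design = StudyDesign(), seed = 1L) {
  set.seed(seed)
  p <- toy$params
  clen <- p$chromLengths
  excl_gr <- GRanges()
  okPlace <- function(chrom, st, en) {
    cand <- GRanges(chrom, IRanges(st, en))
    length(suppressWarnings(findOverlaps(cand + p$exclusion, excl_gr))) == 0L
  }
  rows <- list()
  addRow <- function(type, chrom, st, en, fam) {
    excl_gr <<- suppressWarnings(c(excl_gr, GRanges(chrom, IRanges(st, en))))
    rows[[length(rows) + 1L]] <<- data.table(
      type = type, chrom = chrom, start = as.integer(st),
      end = as.integer(en),
      len = if (type == "deletion") as.integer(en - st + 1L) else
        as.integer(Biostrings::width(toy$teLibrary[fam])),
      teFamily = if (is.na(fam)) NA_character_ else fam,
      teClass = if (is.na(fam)) "none" else unname(toy$teClass[fam]))
  }

  # TE-related deletions over class II repeat copies
  rep2 <- toy$repeats[toy$repeats$class == "II" &
                      width(toy$repeats) >= p$delRange[1] &
                      width(toy$repeats) <= p$delRange[2]]
  nTeDel <- min(round(p$teDelFraction * p$nDeletions), length(rep2))
  if (nTeDel > 0) {
    pick <- sample(length(rep2), nTeDel)
    for (i in pick) {
      r <- rep2[i]
      if (!okPlace(as.character(seqnames(r)), start(r), end(r))) next
      addRow("deletion", as.character(seqnames(r)), start(r), end(r),
             r$family)
    }
  }
  # background deletions
  tries <- 0
  while (sum(vapply(rows, function(r) r$type == "deletion", TRUE)) <
         p$nDeletions) {
    tries <- tries + 1
    if (tries > 200 * p$nDeletions)
      stop("cannot place requested deletions within retry budget")
    L <- round(exp(runif(1, log(p$delRange[1]), log(p$delRange[2]))))
    ci <- sample(length(clen), 1)
    if (clen[ci] < L + 2000) next
    st <- sample.int(as.integer(clen[ci] - L - 1000L), 1) + 500L
    if (!okPlace(names(clen)[ci], st, st + L - 1L)) next
    addRow("deletion", names(clen)[ci], st, st + L - 1L, NA_character_)
  }
  # TE insertions: points need uniquely alignable flanks, so sites inside
  # repeats of multi-copy families (where anchors cannot map uniquely)
  # are avoided
  multiFam <- names(which(table(toy$repeats$family) > 1))
  noAnchor <- toy$repeats[toy$repeats$family %in% multiFam] +
    round(p$insertMean)
  tries <- 0
  nIns <- 0L
  classI <- names(toy$teClass)[toy$teClass == "I"]
  classII <- names(toy$teClass)[toy$teClass == "II"]
  while (nIns < p$nInsertions) {
    tries <- tries + 1
    if (tries > 200 * p$nInsertions)
      stop("cannot place requested insertions within retry budget")
    fam <- if (runif(1) < 0.84 && length(classI)) sample(classI, 1) else
      sample(c(classI, classII), 1)
    ci <- sample(length(clen), 1)
    pos <- sample.int(as.integer(clen[ci] - 2000L), 1) + 1000L
    if (!okPlace(names(clen)[ci], pos, pos)) next
    if (length(suppressWarnings(findOverlaps(
      GRanges(names(clen)[ci], IRanges(pos, pos)), noAnchor))) > 0) next
    addRow("insertion", names(clen)[ci], pos, pos, fam)
    nIns <- nIns + 1L
  }
  truth <- rbindlist(rows)
  sampN <- sampleNames(design)
  if (nrow(truth) == 0L) {
    truth <- data.table(variant_id = character(), type = character(),
                        chrom = character(), start = integer(),
                        end = integer(), len = integer(),
                        teFamily = character(), teClass = character(),
                        pattern = character(), fixed = logical())
    geno <- matrix(0L, 0L, length(sampN),
                   dimnames = list(character(), sampN))
    return(list(truth = truth, genotypes = geno, hapOfHet = geno))
  }
  truth[, variant_id := sprintf("%s%03d", ifelse(type == "deletion",
                                                 "DEL", "INS"), seq_len(.N))]
  data.table::setcolorder(truth, "variant_id")

  # species patterns, fixation, per-sample zygosity
  probs <- list(deletion = p$delPatternProbs, insertion = p$insPatternProbs)
  pfix <- c(deletion = p$pFixedDel, insertion = p$pFixedIns)
  refS <- design@referenceSample
  geno <- matrix(0L, nrow(truth), length(sampN),
                 dimnames = list(truth$variant_id, sampN))
  pat <- character(nrow(truth)); fx <- logical(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    pr <- probs[[truth$type[i]]]
    pat[i] <- sample(names(pr), 1, prob = pr)
    canFix <- !grepl("Pt", pat[i]) || runif(1) < p$referenceErrorFraction
    fx[i] <- canFix && runif(1) < pfix[[truth$type[i]]]
    geno[i, ] <- samplePatternGeno(pat[i], design, fx[i], refS)
  }
  truth[, pattern := pat]
  truth[, fixed := fx]
  hap <- matrix(0L, nrow(truth), length(sampN),
                dimnames = dimnames(geno))
  hap[geno == 1L] <- sample(1:2, sum(geno == 1L), replace = TRUE)
  list(truth = truth, genotypes = geno, hapOfHet = hap)
}

# blocks mapping one haplotype's coordinates to the reference:
# columns hs/he (haplotype), rs (reference start; NA for inserted blocks),
# type ("ref"/"ins"), fam, off (offset into the TE element)
hapBlocks <- function(chromLen, events) {
  # events: data.table(type, start, end, fam) sorted by start, non-overlapping
  hs <- integer(); he <- integer(); rs <- integer(); tp <- character()
  fam <- character(); off <- integer()
  cur_r <- 1L; cur_h <- 1L
  addB <- function(n, rstart, type, fm, of) {
    hs <<- c(hs, cur_h); he <<- c(he, cur_h + n - 1L)
    rs <<- c(rs, rstart); tp <<- c(tp, type)
    fam <<- c(fam, fm); off <<- c(off, of)
    cur_h <<- cur_h + n
  }
  if (nrow(events)) {
    for (i in seq_len(nrow(events))) {
      ev <- events[i]
      if (ev$type == "deletion") {
        n <- ev$start - cur_r
        if (n > 0) addB(n, cur_r, "ref", NA_character_, NA_integer_)
        cur_r <- ev$end + 1L
      } else {
        n <- ev$start - cur_r + 1L
        if (n > 0) addB(n, cur_r, "ref", NA_character_, NA_integer_)
        addB(ev$len, NA_integer_, "ins", ev$fam, 1L)
        cur_r <- ev$start + 1L
      }
    }
  }
  if (cur_r <= chromLen)
    addB(chromLen - cur_r + 1L, cur_r, "ref", NA_character_, NA_integer_)
  data.table(hs = hs, he = he, rs = rs, type = tp, fam = fam, off = off)
}

#' Emulate paired-end read alignment for one sample
#'
#' Samples fragments uniformly along each diploid haplotype at the sample's
#' target depth and places each read on the reference analytically through
#' the planted-variant ledger: pairs spanning a deletion acquire inflated
#' insert sizes; reads falling inside inserted TE sequence become unaligned
#' "mobile" mates (sequence retained); reads crossing a variant junction are
#' treated as clipped (unaligned); reads wholly inside a repeat whose family
#' occurs more than once in the reference get mapping quality 0 and lose the
#' uniqueness flag, all others get 60.
#'
#' @param toy output of [buildToyGenome()].
#' @param planted output of [plantStructuralVariants()].
#' @param sample sample id (must appear in the planted genotype matrix).
#' @param depth target sequencing depth (x) for this sample.
#' @param seed integer RNG seed.
#' @return an alignment `data.table` (see [readAlignmentTsv()] for columns).
#' @export
simulateReadAlignments <- function(toy, planted, sample, depth = 30,
                                   seed = 1L) {
  if (depth <= 0) stop("depth must be positive")
  set.seed(seed)
  p <- toy$params
  rl <- p$readLength
  geno <- planted$genotypes[, sample]
  hapof <- planted$hapOfHet[, sample]
  truth <- planted$truth
  lens <- setNames(Biostrings::width(toy$teLibrary), names(toy$teLibrary))

  multi_fams <- names(which(table(toy$repeats$family) > 1))
  multi_rep <- toy$repeats[toy$repeats$family %in% multi_fams]
  mrep <- as.data.table(multi_rep)[, .(chrom = as.character(seqnames),
                                       start, end)]
  data.table::setkey(mrep, chrom, start, end)

  out <- list()
  fragBase <- 0L
  for (hap in 1:2) {
    carried <- names(geno)[geno == 2L | (geno == 1L & hapof == hap)]
    carried <- truth$variant_id %in% carried
    for (ci in seq_along(toy$genome)) {
      chromName <- names(toy$genome)[ci]
      ev <- truth[carried & truth$chrom == chromName,
                  .(type, start, end, len, fam = teFamily)]
      setorder(ev, start)
      bl <- hapBlocks(Biostrings::width(toy$genome)[ci], ev)
      hapLen <- bl$he[nrow(bl)]
      nf <- round((depth / 2) * hapLen / (2 * rl))
      if (nf == 0) next
      ins <- pmax(2L * rl, round(rnorm(nf, p$insertMean, p$insertSd)))
      fs <- floor(runif(nf, 1, hapLen - ins + 1))
      ok <- fs >= 1 & fs + ins - 1 <= hapLen
      fs <- as.integer(fs[ok]); ins <- as.integer(ins[ok]); nf <- sum(ok)
      r1s <- fs; r1e <- fs + rl - 1L
      r2s <- fs + ins - rl; r2e <- fs + ins - 1L

      mapRead <- function(a, b) {
        i <- findInterval(a, bl$hs)
        inside <- b <= bl$he[i]
        typ <- bl$type[i]
        refs <- bl$rs[i] + (a - bl$hs[i])
        list(
          aligned = inside & typ == "ref",
          mobile = inside & typ == "ins",
          refStart = ifelse(inside & typ == "ref", refs, NA_integer_),
          fam = ifelse(inside & typ == "ins", bl$fam[i], NA_character_),
          famOff = ifelse(inside & typ == "ins", a - bl$hs[i] + 1L,
                          NA_integer_))
      }
      m1 <- mapRead(r1s, r1e); m2 <- mapRead(r2s, r2e)

      mobSeq <- function(m) {
        s <- rep(NA_character_, nf)
        w <- which(m$mobile)
        if (length(w)) {
          s[w] <- as.character(subseq(toy$teLibrary[m$fam[w]],
                                      start = m$famOff[w],
                                      width = rl))
        }
        s
      }
      seq1 <- mobSeq(m1); seq2 <- mobSeq(m2)

      st1 <- m1$refStart; en1 <- st1 + rl - 1L
      st2 <- m2$refStart; en2 <- st2 + rl - 1L
      both <- m1$aligned & m2$aligned
      isz <- ifelse(both, en2 - st1 + 1L, NA_integer_)

      mq <- function(st, en, aligned) {
        q <- ifelse(aligned, 60L, NA_integer_)
        if (nrow(mrep)) {
          w <- which(aligned)
          if (length(w)) {
            qdt <- data.table(chrom = chromName, start = st[w], end = en[w])
            ov <- foverlaps(qdt, mrep, type = "within", nomatch = NULL,
                            which = TRUE)
            q[w[unique(ov$xid)]] <- 0L
          }
        }
        q
      }
      q1 <- mq(st1, en1, m1$aligned); q2 <- mq(st2, en2, m2$aligned)

      fid <- fragBase + seq_len(nf)
      fragBase <- fragBase + nf
      mk <- function(rd, al, st, en, strand, q, sq, mal, mst, mstr) {
        data.table(
          frag = fid, read = rd, sample_id = sample,
          chrom = ifelse(al, chromName, NA_character_),
          start = ifelse(al, st, NA_integer_),
          end = ifelse(al, en, NA_integer_),
          strand = ifelse(al, strand, NA_character_),
          mapq = q,
          mateChrom = ifelse(mal, chromName, NA_character_),
          mateStart = ifelse(mal, mst, NA_integer_),
          mateStrand = ifelse(mal, mstr, NA_character_),
          isize = isz,
          uniq = al & !is.na(q) & q > 0L,
          aligned = al,
          seq = sq)
      }
      out[[length(out) + 1L]] <- mk(1L, m1$aligned, st1, en1, "+", q1, seq1,
                                    m2$aligned, st2, "-")
      out[[length(out) + 1L]] <- mk(2L, m2$aligned, st2, en2, "-", q2, seq2,
                                    m1$aligned, st1, "+")
    }
  }
  rbindlist(out)
}

#' Simulate per-gene fragment counts under planted copy numbers
#'
#' Counts are negative-binomial with mean `baseMean * copyNumber/2 *
#' sizeFactor` and dispersion `alpha`; `alpha = 0` degenerates to Poisson.
#'
#' @param copyNumbers genes x samples matrix of copy numbers (2 = reference).
#' @param baseMeans per-gene baseline mean count (at copy number 2, size
#'   factor 1).
#' @param sizeFactors per-sample size factors.
#' @param alpha NB dispersion (scalar or per gene), >= 0.
#' @param seed integer RNG seed.
#' @return an integer matrix of counts, genes x samples.
#' @export
simulateGeneCounts <- function(copyNumbers, baseMeans,
                               sizeFactors = rep(1, ncol(copyNumbers)),
                               alpha = 0.05, seed = 1L) {
  if (any(copyNumbers < 0)) stop("copy numbers must be non-negative")
  if (any(alpha < 0)) stop("dispersion must be non-negative")
  set.seed(seed)
  ng <- nrow(copyNumbers); ns <- ncol(copyNumbers)
  mu <- sweep((copyNumbers / 2) * baseMeans, 2, sizeFactors, `*`)
  al <- rep(alpha, length.out = ng)
  cnt <- matrix(0L, ng, ns, dimnames = dimnames(copyNumbers))
  for (j in seq_len(ns)) {
    m <- mu[, j]
    pois <- al == 0 | m == 0
    cnt[pois, j] <- rpois(sum(pois), m[pois])
    if (any(!pois))
      cnt[!pois, j] <- rnbinom(sum(!pois), mu = m[!pois],
                               size = 1 / al[!pois])
  }
  cnt
}

#' Pool per-sample alignments at equal representation
#'
#' Downsamples each sample's fragments without replacement to the count
#' matching `targetDepth`, then concatenates while keeping the origin sample
#' id. A sample already at or below the target is used in full (with a
#' warning when below).
#'
#' @param alnList named list of alignment `data.table`s, one per sample.
#' @param genomeLength total reference length (bp).
#' @param targetDepth per-sample target depth in the pool (x).
#' @param readLength read length (bp).
#' @param seed integer RNG seed.
#' @return a single pooled alignment `data.table`.
#' @export
buildPool <- function(alnList, genomeLength, targetDepth = 5,
                      readLength = 100L, seed = 1L) {
  if (length(alnList) == 0L) stop("need at least one sample")
  set.seed(seed)
  targetFrags <- round(targetDepth * genomeLength / (2 * readLength))
  pooled <- lapply(alnList, function(a) {
    fr <- unique(a$frag)
    if (length(fr) < targetFrags) {
      warning("sample below target pool depth; used in full")
      return(a)
    }
    if (length(fr) == targetFrags) return(a)
    keep <- sample(fr, targetFrags)
    a[frag %in% keep]
  })
  rbindlist(pooled)
}

#' Simulate ortholog CDS pairs with chosen synonymous/non-synonymous divergence
#'
#' Generates stop-free coding sequences and derives the ortholog by planting
#' transition substitutions: at sites where the transition is synonymous with
#' per-site probability `dsTarget`, and at sites where it is non-synonymous
#' with probability `dnTarget`. Realized substitution counts are recorded as
#' truth.
#'
#' @param n number of pairs.
#' @param nCodons codons per sequence (>= 50, so >= 150 bases).
#' @param dnTarget,dsTarget per-site substitution probabilities (recycled to
#'   length `n`).
#' @param seed integer RNG seed.
#' @return list: `cds1`, `cds2` (DNAStringSet), `truth` (data.table with
#'   planted and realized counts).
#' @export
simulateOrthologCds <- function(n, nCodons = 100L, dnTarget = 0.05,
                                dsTarget = 0.15, seed = 1L) {
  if (nCodons * 3L < 150L) stop("sequences must be at least 150 bases")
  set.seed(seed)
  dnTarget <- rep(dnTarget, length.out = n)
  dsTarget <- rep(dsTarget, length.out = n)
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  s1 <- s2 <- character(n)
  nsyn <- nnon <- integer(n)
  for (i in seq_len(n)) {
    cod <- sample(sense, nCodons, replace = TRUE)
    x <- strsplit(paste(cod, collapse = ""), "")[[1]]
    y <- x
    ks <- 0L; kn <- 0L
    for (pos in seq_along(x)) {
      b <- x[pos]; tb <- TRANSITION[[b]]
      ci <- (pos - 1L) %/% 3L
      off <- (pos - 1L) %% 3L + 1L
      codon <- paste(x[(ci * 3L + 1L):(ci * 3L + 3L)], collapse = "")
      alt <- codon; substr(alt, off, off) <- tb
      if (code[[alt]] == "*") next
      # the evolving codon (earlier substitutions applied) must stay sense
      cur <- paste(y[(ci * 3L + 1L):(ci * 3L + 3L)], collapse = "")
      curAlt <- cur; substr(curAlt, off, off) <- tb
      if (code[[curAlt]] == "*") next
      syn <- code[[alt]] == code[[codon]]
      pr <- if (syn) dsTarget[i] else dnTarget[i]
      if (runif(1) < pr) {
        y[pos] <- tb
        if (syn) ks <- ks + 1L else kn <- kn + 1L
      }
    }
    s1[i] <- paste(x, collapse = ""); s2[i] <- paste(y, collapse = "")
    nsyn[i] <- ks; nnon[i] <- kn
  }
  ids <- sprintf("pair%03d", seq_len(n))
  list(cds1 = DNAStringSet(setNames(s1, ids)),
       cds2 = DNAStringSet(setNames(s2, ids)),
       truth = data.table(pair_id = ids, dnTarget = dnTarget,
                          dsTarget = dsTarget, synSubs = nsyn,
                          nonSynSubs = nnon))
}

#' Plant genic copy-number truth
#'
#' Selects `nCnvGenes` genes and assigns altered copy numbers (0, 1, 3 or 4)
#' to a random non-empty subset of samples; all other entries are 2.
#'
#' @param geneIds character vector of gene ids.
#' @param samples character vector of sample ids.
#' @param nCnvGenes number of copy-variable genes.
#' @param seed integer RNG seed.
#' @return genes x samples integer matrix of copy numbers.
#' @export
plantCnvTruth <- function(geneIds, samples, nCnvGenes = 40L, seed = 1L) {
  set.seed(seed)
  cn <- matrix(2L, length(geneIds), length(samples),
               dimnames = list(geneIds, samples))
  pick <- sample(length(geneIds), min(nCnvGenes, length(geneIds)))
  for (g in pick) {
    k <- sample(seq_len(max(1L, length(samples) - 1L)), 1)
    who <- sample(samples, k)
    cn[g, who] <- sample(c(0L, 1L, 3L, 4L), 1)
  }
  cn
}

#' Run the full synthetic study
#'
#' Convenience wrapper: builds the toy genome, plants variants, simulates
#' alignments for every high-depth sample and pool member, builds the pool,
#' plants CNV truth and simulates gene counts.
#'
#' @param params a [simParams()] list.
#' @param design a [StudyDesign-class].
#' @param seed integer RNG seed (sub-seeds are derived per stage).
#' @return a list with `toy`, `design`, `planted`, `alignments` (named list,
#'   high-depth samples), `poolAlignments` (NULL if the design has no pool),
#'   `cnvTruth`, `counts`, `baseMeans`.
#' @export
simulateStudy <- function(params = simParams(), design = StudyDesign(),
                          seed = 1L) {
  toy <- buildToyGenome(params, seed = seed)
  planted <- plantStructuralVariants(toy, design, seed = seed + 1L)
  dp <- targetDepth(design)
  aln <- list()
  for (k in seq_along(sampleNames(design))) {
    s <- sampleNames(design)[k]
    aln[[s]] <- simulateReadAlignments(toy, planted, s, depth = dp[s],
                                       seed = seed + 10L + k)
  }
  pool_ids <- poolSamples(design)
  poolAln <- if (length(pool_ids)) {
    buildPool(aln[pool_ids], sum(params$chromLengths),
              targetDepth = params$poolDepth,
              readLength = params$readLength, seed = seed + 2L)
  } else NULL
  hd <- highDepthSamples(design)
  set.seed(seed + 3L)
  baseMeans <- exp(rnorm(length(toy$genes$gene_id), params$baseMeanLog,
                         params$baseMeanSd))
  names(baseMeans) <- toy$genes$gene_id
  cnv <- plantCnvTruth(toy$genes$gene_id, hd, params$nCnvGenes,
                       seed = seed + 4L)
  counts <- simulateGeneCounts(cnv, baseMeans, alpha = params$dispersion,
                               seed = seed + 5L)
  list(toy = toy, design = design, planted = planted,
       alignments = aln[hd], poolAlignments = poolAln,
       cnvTruth = cnv, counts = counts, baseMeans = baseMeans)
}

#' Reconstruct haplotype sequences for a sample
#'
#' Applies the planted deletions and insertions carried by each haplotype to
#' the reference sequence. Used to verify that every planted variant is
#' realized.
#'
#' @param toy output of [buildToyGenome()].
#' @param planted output of [plantStructuralVariants()].
#' @param sample sample id.
#' @return list of two `DNAStringSet`s (haplotype 1 and 2).
#' @export
buildHaplotypes <- function(toy, planted, sample) {
  geno <- planted$genotypes[, sample]
  hapof <- planted$hapOfHet[, sample]
  truth <- planted$truth
  lapply(1:2, function(hap) {
    carried <- names(geno)[geno == 2L | (geno == 1L & hapof == hap)]
    seqs <- lapply(names(toy$genome), function(chrom) {
      ev <- truth[variant_id %in% carried & truth$chrom == chrom]
      setorder(ev, start)
      s <- as.character(toy$genome[[chrom]])
      if (nrow(ev) == 0) return(DNAString(s))
      pieces <- character(); cur <- 1L
      for (i in seq_len(nrow(ev))) {
        if (ev$type[i] == "deletion") {
          pieces <- c(pieces, substr(s, cur, ev$start[i] - 1L))
          cur <- ev$end[i] + 1L
        } else {
          pieces <- c(pieces, substr(s, cur, ev$start[i]),
                      as.character(toy$teLibrary[[ev$teFamily[i]]]))
          cur <- ev$start[i] + 1L
        }
      }
      pieces <- c(pieces, substr(s, cur, nchar(s)))
      DNAString(paste(pieces, collapse = ""))
    })
    DNAStringSet(setNames(seqs, names(toy$genome)))
  })
}
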