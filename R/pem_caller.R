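#' Pair up alignment records
#'
#' Joins read 1 and read 2 of each fragment into one row with suffixed
#' columns (`start1`, `end1`, `mapq1`, ... / `start2`, ...).
#'
#' @param aln alignment `data.table` (see [readAlignmentTsv()]).
#' @return a `data.table`, one row per fragment.
#' @export
pairAlignments <- function(aln) {
  r1 <- aln[read == 1L, .(sample_id, frag, chrom1 = chrom, start1 = start,
                          end1 = end, strand1 = strand, mapq1 = mapq,
                          uniq1 = uniq, aligned1 = aligned, seq1 = seq)]
  r2 <- aln[read == 2L, .(sample_id, frag, chrom2 = chrom, start2 = start,
                          end2 = end, strand2 = strand, mapq2 = mapq,
                          uniq2 = uniq, aligned2 = aligned, seq2 = seq)]
  merge(r1, r2, by = c("sample_id", "frag"))
}

#' Estimate the insert-size model from concordant pairs
#'
#' Median and MAD (scaled to sd) of the inferred insert size over pairs with
#' both reads aligned to the same chromosome in FR orientation.
#'
#' @param pairs output of [pairAlignments()].
#' @param minPairs minimum concordant pairs required.
#' @return c(mean = , sd = ).
#' @export
estimateInsertModel <- function(pairs, minPairs = 100L) {
  cand <- pairs[aligned1 & aligned2 & chrom1 == chrom2 &
                  strand1 != strand2]
  spans <- pmax(cand$end1, cand$end2) - pmin(cand$start1, cand$start2) + 1L
  # trim gross outliers (deletion-spanning pairs) before moments
  med <- median(spans); mad <- stats::mad(spans)
  core <- spans[abs(spans - med) <= 10 * max(mad, 1)]
  if (length(core) < minPairs)
    stop("fewer than ", minPairs, " concordant pairs for model estimation")
  c(mean = median(core), sd = stats::mad(core))
}

#' Label read pairs by paired-end mapping signature
#'
#' Pairs whose inferred insert exceeds `mean + 3 sd` are deletion-type;
#' pairs with exactly one uniquely aligned read whose mate is unaligned are
#' anchor-type (the anchor flanks a putative insertion, the unaligned mate is
#' the "mobile" read whose sequence is retained); everything else with both
#' reads aligned in FR orientation is concordant.
#'
#' @param aln alignment `data.table` or a pre-built pair table.
#' @param model `c(mean=, sd=)` insert model; estimated from the data via
#'   [estimateInsertModel()] when `NULL`.
#' @return list with `pairs` (the pair table with a `type` column and, for
#'   deletion-type pairs, `lend` / `rstart`, the inner edges of the left and
#'   right reads; for anchors, `anchorStart`/`anchorEnd`/`anchorStrand`/
#'   `anchorMapq`/`mobileSeq`) and `model`.
#' @export
findDiscordantPairs <- function(aln, model = NULL) {
  pairs <- if ("read" %in% names(aln)) pairAlignments(aln) else copy(aln)
  if (is.null(model)) model <- estimateInsertModel(pairs)
  cutoff <- model[["mean"]] + 3 * model[["sd"]]

  both <- pairs$aligned1 & pairs$aligned2 &
    !is.na(pairs$chrom1) & !is.na(pairs$chrom2) &
    pairs$chrom1 == pairs$chrom2 & pairs$strand1 != pairs$strand2
  span <- rep(NA_integer_, nrow(pairs))
  span[both] <- pmax(pairs$end1, pairs$end2)[both] -
    pmin(pairs$start1, pairs$start2)[both] + 1L
  # inner edges: end of the plus-strand read, start of the minus-strand read
  lend <- rep(NA_integer_, nrow(pairs))
  rstart <- rep(NA_integer_, nrow(pairs))
  plus1 <- both & pairs$strand1 == "+"
  lend[plus1] <- pairs$end1[plus1]; rstart[plus1] <- pairs$start2[plus1]
  minus1 <- both & pairs$strand1 == "-"
  lend[minus1] <- pairs$end2[minus1]; rstart[minus1] <- pairs$start1[minus1]

  anchor1 <- pairs$aligned1 & pairs$uniq1 & !pairs$aligned2
  anchor2 <- pairs$aligned2 & pairs$uniq2 & !pairs$aligned1

  type <- rep("other", nrow(pairs))
  type[both] <- "concordant"
  type[both & span > cutoff & lend < rstart] <- "del"
  type[anchor1 | anchor2] <- "anchor"

  pairs[, `:=`(
    type = type, span = span, lend = lend, rstart = rstart,
    chrom = fifelse(both, chrom1,
                    fifelse(anchor1, chrom1,
                            fifelse(anchor2, chrom2, chrom1))),
    anchorStart = fifelse(anchor1, start1, fifelse(anchor2, start2,
                                                   NA_integer_)),
    anchorEnd = fifelse(anchor1, end1, fifelse(anchor2, end2, NA_integer_)),
    anchorStrand = fifelse(anchor1, strand1,
                           fifelse(anchor2, strand2, NA_character_)),
    anchorMapq = fifelse(anchor1, mapq1, fifelse(anchor2, mapq2,
                                                 NA_integer_)),
    mobileSeq = fifelse(anchor1, seq2, fifelse(anchor2, seq1,
                                               NA_character_)))]
  list(pairs = pairs, model = model)
}

clusterIntervals <- function(starts, ends) {
  ir <- IRanges(starts, ends)
  red <- IRanges::reduce(ir)
  S4Vectors::subjectHits(findOverlaps(ir, red, select = "all"))
}

#' Deletion detector A (cluster-of-discordant-pairs, breakpoint = inner edges)
#'
#' Clusters deletion-type pairs whose implied deleted intervals overlap;
#' breakpoints are the innermost read edges of the cluster. Calls are kept
#' when the length lies in `lenRange`, the supporting pair count is at least
#' `minSupport`, and the median mapping quality of the supporting reads is at
#' least `minMedianMapq`.
#'
#' @param pairs labeled pair table (from [findDiscordantPairs()]).
#' @param minSupport minimum supporting pairs (default 5).
#' @param lenRange deletion length range kept (default 1-25 kb).
#' @param minMedianMapq median-MAPQ filter (default 20).
#' @return `data.table` of calls: sample_id, chrom, start, end, len, support,
#'   medmapq, detector.
#' @export
callDeletionsDetectorA <- function(pairs, minSupport = 5L,
                                   lenRange = c(1000L, 25000L),
                                   minMedianMapq = 20) {
  dp <- pairs[type == "del" & rstart - 1L >= lend + 1L]
  if (nrow(dp) == 0L) return(emptyDelCalls("A"))
  out <- dp[, {
    cl <- clusterIntervals(lend + 1L, rstart - 1L)
    .SD[, .(start = max(lend) + 1L, end = min(rstart) - 1L,
            support = .N, medmapq = median(c(mapq1, mapq2))),
        by = .(cluster = cl)]
  }, by = .(sample_id, chrom)]
  out[, len := end - start + 1L]
  out <- out[len >= lenRange[1] & len <= lenRange[2] &
               support >= minSupport & medmapq >= minMedianMapq]
  out[, cluster := NULL]
  out[, detector := "A"]
  setorder(out, sample_id, chrom, start)
  out[]
}

emptyDelCalls <- function(det) {
  data.table(sample_id = character(), chrom = character(),
             start = integer(), end = integer(), len = integer(),
             support = integer(), medmapq = numeric(), detector = det)
}

#' Deletion detector B (breakpoint intervals, reported at interval centers)
#'
#' Same clustering as detector A, but each cluster yields left/right
#' breakpoint *intervals* (the geometric intersection of the pair-compatible
#' regions, bounded by the maximum concordant gap) whose central points are
#' reported as the breakpoints. No mapping-quality filter is applied;
#' support must reach `minSupport` and the length must lie in `lenRange`.
#'
#' @param pairs labeled pair table.
#' @param model insert model `c(mean=, sd=)` bounding the concordant span.
#' @inheritParams callDeletionsDetectorA
#' @return `data.table` of calls as in [callDeletionsDetectorA()].
#' @export
callDeletionsDetectorB <- function(pairs, model, minSupport = 5L,
                                   lenRange = c(1000L, 25000L)) {
  dp <- pairs[type == "del" & rstart - 1L >= lend + 1L]
  if (nrow(dp) == 0L) return(emptyDelCalls("B"))
  maxSpan <- model[["mean"]] + 3 * model[["sd"]]
  dp[, `:=`(rl1 = end1 - start1 + 1L, rl2 = end2 - start2 + 1L)]
  out <- dp[, {
    cl <- clusterIntervals(lend + 1L, rstart - 1L)
    .SD[, {
      gmax <- as.integer(maxSpan) - rl1 - rl2
      lLo <- max(lend) + 1L; lHi <- min(lend + gmax)
      rHi <- min(rstart) - 1L; rLo <- max(rstart - gmax)
      if (lHi < lLo) lHi <- lLo
      if (rLo > rHi) rLo <- rHi
      .(start = as.integer(round((lLo + lHi) / 2)),
        end = as.integer(round((rLo + rHi) / 2)),
        support = .N, medmapq = median(c(mapq1, mapq2)))
    }, by = .(cluster = cl)]
  }, by = .(sample_id, chrom)]
  out[, len := end - start + 1L]
  out <- out[len >= lenRange[1] & len <= lenRange[2] &
               support >= minSupport]
  out[, cluster := NULL]
  out[, detector := "B"]
  setorder(out, sample_id, chrom, start)
  out[]
}

#' Merge the two deletion detectors within a sample
#'
#' Calls from detectors A and B whose +/- `ci` bp confidence windows overlap
#' at both breakpoints are combined into a single event that takes detector
#' A's breakpoints (A was measured to be the more accurate breakpoint
#' estimator); unmerged calls from either detector are kept as they are.
#'
#' @param callsA,callsB call tables from the two detectors (one sample).
#' @param ci confidence-interval half-width in bp (default 250).
#' @return merged `data.table` of calls; `detector` is "both" for combined
#'   events.
#' @export
mergeDetectors <- function(callsA, callsB, ci = 250L) {
  a <- copy(callsA); b <- copy(callsB)
  if (nrow(a) == 0L && nrow(b) == 0L) return(emptyDelCalls("both"))
  usedB <- rep(FALSE, nrow(b))
  if (nrow(a) && nrow(b)) {
    for (i in seq_len(nrow(a))) {
      cand <- which(!usedB & b$sample_id == a$sample_id[i] &
                      b$chrom == a$chrom[i] &
                      abs(b$start - a$start[i]) <= 2L * ci &
                      abs(b$end - a$end[i]) <= 2L * ci)
      if (length(cand)) {
        j <- cand[which.min(abs(b$start[cand] - a$start[i]))]
        usedB[j] <- TRUE
        a$support[i] <- max(a$support[i], b$support[j])
        a$detector[i] <- "both"
      }
    }
  }
  out <- rbind(a, b[!usedB])
  setorder(out, sample_id, chrom, start)
  out[]
}

#' Call deletions in one sample (detector A + detector B, merged)
#'
#' @param pairs labeled pair table for one sample.
#' @param model insert model.
#' @param ci detector-merge confidence interval (bp).
#' @inheritParams callDeletionsDetectorA
#' @return merged per-sample deletion calls.
#' @export
callDeletions <- function(pairs, model, minSupport = 5L,
                          lenRange = c(1000L, 25000L), minMedianMapq = 20,
                          ci = 250L) {
  a <- callDeletionsDetectorA(pairs, minSupport, lenRange, minMedianMapq)
  b <- callDeletionsDetectorB(pairs, model, minSupport, lenRange)
  mergeDetectors(a, b, ci)
}

clusterPositions <- function(pos, gap) {
  o <- order(pos)
  cl <- cumsum(c(1L, diff(pos[o]) > gap))
  cl[order(o)]
}

classifyMobileReads <- function(seqs, teLibrary, teSuperfamily,
                                identity = 0.8, maxReads = 20L) {
  none <- list(label = "unclassified", family = NA_character_)
  seqs <- seqs[!is.na(seqs)]
  if (length(seqs) == 0L || length(teLibrary) == 0L) return(none)
  if (length(seqs) > maxReads) seqs <- seqs[seq_len(maxReads)]
  votes <- character(); famVotes <- character()
  for (s in seqs) {
    mm <- floor((1 - identity) * nchar(s))
    hitF <- vcountPattern(s, teLibrary, max.mismatch = mm) > 0
    hitR <- vcountPattern(as.character(reverseComplement(DNAString(s))),
                          teLibrary, max.mismatch = mm) > 0
    fams <- names(teLibrary)[hitF | hitR]
    if (length(fams)) {
      votes <- c(votes, unique(unname(teSuperfamily[fams])))
      famVotes <- c(famVotes, fams)
    }
  }
  if (length(votes) == 0L) return(none)
  ftab <- sort(table(famVotes), decreasing = TRUE)
  fam <- names(ftab)[1]
  tab <- sort(table(votes), decreasing = TRUE)
  if (length(tab) > 1L && tab[1] == tab[2])
    return(list(label = "unknown", family = fam))
  list(label = names(tab)[1], family = fam)
}

#' Detect TE insertions from anchor/mobile clusters
#'
#' Anchor reads are clustered by position and strand; a site is called when a
#' forward-strand cluster and a downstream reverse-strand cluster - the two
#' clusters pointing toward each other across the insertion site - each reach
#' `minAnchors` anchors with a gap of at most the insert mean. The insertion
#' interval runs from the right edge of the forward cluster to the left edge
#' of the reverse cluster. The element class is the majority vote of the
#' mobile mates matched against the TE database at `identity` ungapped
#' identity over the read (ties give "unknown", no match "unclassified").
#'
#' @param pairs labeled pair table for one sample.
#' @param teLibrary `DNAStringSet` TE database (library entries, optionally
#'   augmented with classified deletion sequences).
#' @param teSuperfamily named character vector, database entry -> superfamily
#'   label.
#' @param model insert model `c(mean=, sd=)`.
#' @param minAnchors minimum anchors per cluster side (default 3).
#' @param identity minimum ungapped identity for a mobile-read match.
#' @return `data.table`: sample_id, chrom, start, end (insertion interval),
#'   nLeft, nRight, teClass (superfamily label), class ("I"/"II"/
#'   "unclassified").
#' @export
detectTeInsertions <- function(pairs, teLibrary, teSuperfamily, model,
                               minAnchors = 3L, identity = 0.8) {
  if (length(teLibrary) == 0L) stop("TE database is empty")
  anc <- pairs[type == "anchor"]
  res <- list()
  gap <- model[["mean"]]
  for (ch in unique(anc$chrom)) {
    fw <- anc[chrom == ch & anchorStrand == "+"]
    rv <- anc[chrom == ch & anchorStrand == "-"]
    if (nrow(fw) == 0L || nrow(rv) == 0L) next
    fw[, cluster := clusterPositions(anchorEnd, gap)]
    rv[, cluster := clusterPositions(anchorStart, gap)]
    fc <- fw[, .(edge = max(anchorEnd), n = .N), by = cluster]
    rc <- rv[, .(edge = min(anchorStart), n = .N), by = cluster]
    fc <- fc[n >= minAnchors]; rc <- rc[n >= minAnchors]
    if (nrow(fc) == 0L || nrow(rc) == 0L) next
    usedR <- rep(FALSE, nrow(rc))
    for (i in seq_len(nrow(fc))) {
      cand <- which(!usedR & rc$edge >= fc$edge[i] - 50L &
                      rc$edge - fc$edge[i] <= gap)
      if (length(cand) == 0L) next
      j <- cand[which.min(rc$edge[cand])]
      usedR[j] <- TRUE
      mob <- c(fw[cluster == fc$cluster[i], mobileSeq],
               rv[cluster == rc$cluster[j], mobileSeq])
      cls <- classifyMobileReads(mob, teLibrary, teSuperfamily, identity)
      res[[length(res) + 1L]] <- data.table(
        sample_id = anc$sample_id[1], chrom = ch,
        start = min(fc$edge[i], rc$edge[j]),
        end = max(fc$edge[i], rc$edge[j]),
        nLeft = fc$n[i], nRight = rc$n[j],
        teClass = cls$label, class = classOfSuperfamily(cls$label),
        teFamily = cls$family,
        elementLen = if (is.na(cls$family)) NA_integer_ else
          Biostrings::width(teLibrary[cls$family]))
    }
  }
  if (length(res) == 0L)
    return(data.table(sample_id = character(), chrom = character(),
                      start = integer(), end = integer(), nLeft = integer(),
                      nRight = integer(), teClass = character(),
                      class = character(), teFamily = character(),
                      elementLen = integer()))
  out <- rbindlist(res)
  setorder(out, chrom, start)
  out[]
}

# supporting / informative counts at a deletion
delSupportCounts <- function(pairs, ch, L, R, gmax) {
  sub <- pairs[chrom == ch & !is.na(lend) & lend >= L - gmax & lend < L]
  supp <- sum(sub$type == "del" & sub$rstart > R & sub$rstart <= R + gmax)
  conc <- sum(sub$type == "concordant" & sub$rstart > L)
  c(supp = supp, conc = conc)
}

# supporting / informative counts at an insertion interval [S, E]
insSupportCounts <- function(pairs, ch, S, E, gmax) {
  sub <- pairs[chrom == ch &
                 ((type == "anchor" &
                     ((anchorStrand == "+" & anchorEnd >= S - gmax &
                         anchorEnd <= E + 20L) |
                        (anchorStrand == "-" & anchorStart >= S - 20L &
                           anchorStart <= E + gmax))) |
                    (type == "concordant" & !is.na(lend) & lend < S &
                       rstart > E))]
  nL <- sum(sub$type == "anchor" & sub$anchorStrand == "+")
  nR <- sum(sub$type == "anchor" & sub$anchorStrand == "-")
  conc <- sum(sub$type == "concordant")
  c(supp = (nL + nR) / 2, conc = conc)
}

genotypeFromFraction <- function(supp, conc, minDepth = 5L) {
  depth <- round(supp + conc)
  if (depth < minDepth) return(list(call = "no_call", f = NA_real_))
  f <- supp / (supp + conc)
  call <- if (f < 0.2) "non_carrier" else if (f <= 0.8) "het" else "hom"
  list(call = call, f = f)
}

#' Genotype one variant in one sample by supporting-read fraction
#'
#' The supporting-read fraction f is the ratio of variant-supporting
#' fragments to informative fragments (supporting plus reference-concordant
#' fragments whose inner gap spans the breakpoint). Samples with informative
#' depth below `minDepth` get no call; otherwise f < 0.2 is a non-carrier,
#' 0.2-0.8 a heterozygous carrier and > 0.8 a homozygous carrier.
#'
#' @param pairs labeled pair table for the sample.
#' @param chrom,start,end variant coordinates (deletion interval or insertion
#'   interval).
#' @param type "deletion" or "insertion".
#' @param model insert model.
#' @param minDepth minimum informative depth for a call (default 5).
#' @return list with `call` and `f`.
#' @export
genotypeVariant <- function(pairs, chrom, start, end, type, model,
                            minDepth = 5L) {
  gmax <- model[["mean"]] + 3 * model[["sd"]]
  cnt <- if (type == "deletion")
    delSupportCounts(pairs, chrom, start, end, gmax)
  else insSupportCounts(pairs, chrom, start, end, gmax)
  genotypeFromFraction(cnt[["supp"]], cnt[["conc"]], minDepth)
}

#' Merge per-sample calls into a unified catalogue
#'
#' Single-linkage chaining of calls whose breakpoint confidence windows
#' (+/- `ci` bp) overlap at both sides; each merged event takes the
#' coordinates of the member call with the highest support (ties broken by
#' leftmost coordinate), so the catalogue is invariant to sample order.
#'
#' @param calls rbind-ed per-sample call table (columns sample_id, chrom,
#'   start, end, support).
#' @param ci confidence-interval half-width: 500 bp for deletions, 250 bp
#'   for insertions.
#' @param type variant type recorded in the catalogue.
#' @return `data.table`: variant_id, chrom, start, end, len, type, support,
#'   nSamples.
#' @export
mergeAcrossSamples <- function(calls, ci = 500L, type = "deletion") {
  if (nrow(calls) == 0L)
    return(data.table(variant_id = character(), chrom = character(),
                      start = integer(), end = integer(), len = integer(),
                      type = character(), support = integer(),
                      nSamples = integer()))
  x <- copy(calls)
  setorder(x, chrom, start, end, sample_id)
  n <- nrow(x)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    j <- i - 1L
    while (j >= 1L && x$chrom[j] == x$chrom[i] &&
           x$start[i] - x$start[j] <= 2L * ci) {
      if (abs(x$end[i] - x$end[j]) <= 2L * ci) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
      j <- j - 1L
    }
  }
  root <- vapply(seq_len(n), find, 1L)
  x[, cluster := root]
  hasLen <- "len" %in% names(x)
  out <- x[, {
    best <- order(-support, start)[1]
    .(chrom = chrom[best], start = start[best], end = end[best],
      support = support[best], nSamples = data.table::uniqueN(sample_id),
      len = if (hasLen) len[best] else end[best] - start[best] + 1L)
  }, by = cluster]
  out[, cluster := NULL]
  setorder(out, chrom, start)
  out[, `:=`(type = type,
             variant_id = sprintf("%s%03d",
                                  ifelse(type == "deletion", "MDEL", "MINS"),
                                  seq_len(.N)))]
  data.table::setcolorder(out, c("variant_id", "chrom", "start", "end",
                                 "len", "type", "support", "nSamples"))
  out[]
}

#' Genotype a merged catalogue across samples
#'
#' @param catalogue merged call table from [mergeAcrossSamples()] (deletions
#'   and insertions may be rbind-ed).
#' @param pairsList named list of labeled pair tables, one per sample.
#' @param model insert model.
#' @param minDepth minimum informative depth (default 5).
#' @return an [SvCatalogue-class].
#' @export
genotypeCatalogue <- function(catalogue, pairsList, model, minDepth = 5L) {
  samples <- names(pairsList)
  n <- nrow(catalogue)
  geno <- matrix("no_call", n, length(samples),
                 dimnames = list(catalogue$variant_id, samples))
  fr <- matrix(NA_real_, n, length(samples),
               dimnames = dimnames(geno))
  for (s in samples) {
    prs <- pairsList[[s]]
    for (i in seq_len(n)) {
      g <- genotypeVariant(prs, catalogue$chrom[i], catalogue$start[i],
                           catalogue$end[i], catalogue$type[i], model,
                           minDepth)
      geno[i, s] <- g$call
      fr[i, s] <- g$f
    }
  }
  calls <- GRanges(catalogue$chrom,
                   IRanges(catalogue$start, pmax(catalogue$start,
                                                 catalogue$end)))
  calls$variant_id <- catalogue$variant_id
  calls$type <- catalogue$type
  calls$svlen <- catalogue$len
  calls$support <- catalogue$support
  SvCatalogue(calls, geno, fr)
}

#' Estimate variant frequencies in the low-depth pool
#'
#' The pooled frequency of each catalogue variant is the ratio of supporting
#' to informative fragments across the whole pool; variants with frequency
#' above 0.9 are flagged as fixed in the pool.
#'
#' @param poolPairs labeled pair table of the pooled alignments.
#' @param catalogue merged call table (with `type` column).
#' @param model insert model.
#' @return `data.table`: variant_id, type, frequency (NA when no informative
#'   fragments), informative, fixedInPool.
#' @export
estimatePoolFrequency <- function(poolPairs, catalogue, model) {
  gmax <- model[["mean"]] + 3 * model[["sd"]]
  res <- lapply(seq_len(nrow(catalogue)), function(i) {
    cnt <- if (catalogue$type[i] == "deletion")
      delSupportCounts(poolPairs, catalogue$chrom[i], catalogue$start[i],
                       catalogue$end[i], gmax)
    else insSupportCounts(poolPairs, catalogue$chrom[i], catalogue$start[i],
                          catalogue$end[i], gmax)
    tot <- cnt[["supp"]] + cnt[["conc"]]
    data.table(variant_id = catalogue$variant_id[i],
               type = catalogue$type[i],
               frequency = if (tot > 0) cnt[["supp"]] / tot else NA_real_,
               informative = tot,
               fixedInPool = tot > 0 && cnt[["supp"]] / tot > 0.9)
  })
  rbindlist(res)
}

#' Run the full PEM calling pipeline on a set of samples
#'
#' Labels pairs, calls deletions (both detectors, merged) and TE insertions
#' per sample, merges across samples (500 bp confidence interval for
#' deletions, 250 bp for insertions) and genotypes every sample at every
#' merged event.
#'
#' @param alnList named list of alignment tables, one per sample.
#' @param teLibrary,teSuperfamily TE database for mobile-read classification.
#' @param model insert model (estimated from the first sample when NULL).
#' @param minSupport,minMedianMapq,lenRange deletion filters.
#' @param minAnchors insertion cluster minimum.
#' @param ciDel,ciIns cross-sample merge confidence intervals (bp).
#' @return list: `catalogue` (SvCatalogue), `calls` (merged call table),
#'   `pairs` (per-sample labeled pair tables), `model`.
#' @export
callStructuralVariants <- function(alnList, teLibrary, teSuperfamily,
                                   model = NULL, minSupport = 5L,
                                   minMedianMapq = 20,
                                   lenRange = c(1000L, 25000L),
                                   minAnchors = 3L, ciDel = 500L,
                                   ciIns = 250L) {
  pairsList <- list()
  delCalls <- list(); insCalls <- list()
  for (s in names(alnList)) {
    fd <- findDiscordantPairs(alnList[[s]], model)
    if (is.null(model)) model <- fd$model
    pairsList[[s]] <- fd$pairs
    delCalls[[s]] <- callDeletions(fd$pairs, model, minSupport, lenRange,
                                   minMedianMapq)
    ins <- detectTeInsertions(fd$pairs, teLibrary, teSuperfamily, model,
                              minAnchors)
    ins[, support := nLeft + nRight]
    insCalls[[s]] <- ins
  }
  mdel <- mergeAcrossSamples(rbindlist(delCalls), ci = ciDel,
                             type = "deletion")
  # insertion length is the matched element's length (the inserted
  # sequence), not the width of the predicted interval
  insAll <- rbindlist(insCalls)
  insAll[, len := fifelse(is.na(elementLen), end - start + 1L, elementLen)]
  mins <- mergeAcrossSamples(
    insAll[, .(sample_id, chrom, start, end, support, len)],
    ci = ciIns, type = "insertion")
  merged <- rbind(mdel, mins)
  catalogue <- genotypeCatalogue(merged, pairsList, model)
  list(catalogue = catalogue, calls = merged, pairs = pairsList,
       model = model, insCallsPerSample = rbindlist(insCalls))
}
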