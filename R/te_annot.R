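# Karlin-Altschul parameters for +1/-2 ungapped nucleotide scoring
KA_LAMBDA <- 1.33271
KA_K <- 0.62101

#' Seeded ungapped local alignment with Karlin-Altschul E-values
#'
#' Finds exact seed words shared by query and subject, extends each seed
#' ungapped in both directions with an X-drop criterion under +1/-2 scoring,
#' and reports the distinct high-scoring segment pairs with their bit scores
#' and E-values.
#'
#' @param query,subject character scalars (ACGT; the subject is also searched
#'   reverse-complemented).
#' @param word seed word length (default 11).
#' @param xdrop score drop-off that stops the extension (default 20).
#' @param maxE keep HSPs with E-value at most this (default 10).
#' @return `data.table`: qstart, qend, sstart, send, length, matches, score,
#'   bitScore, evalue, strand.
#' @export
ungappedLocalHits <- function(query, subject, word = 11L, xdrop = 20,
                              maxE = 10) {
  res <- list()
  for (str in c("+", "-")) {
    subj <- if (str == "+") subject else
      as.character(reverseComplement(DNAString(subject)))
    h <- ungappedHitsOneStrand(query, subj, word, xdrop)
    if (nrow(h)) {
      if (str == "-") {
        sl <- nchar(subject)
        tmp <- h$sstart
        h[, sstart := sl - send + 1L]
        h[, send := sl - tmp + 1L]
      }
      h[, strand := str]
      res[[str]] <- h
    }
  }
  if (length(res) == 0L)
    return(data.table(qstart = integer(), qend = integer(),
                      sstart = integer(), send = integer(),
                      length = integer(), matches = integer(),
                      score = numeric(), bitScore = numeric(),
                      evalue = numeric(), strand = character()))
  out <- rbindlist(res)
  m <- nchar(query); n <- nchar(subject)
  out[, bitScore := (KA_LAMBDA * score - log(KA_K)) / log(2)]
  out[, evalue := KA_K * m * n * exp(-KA_LAMBDA * score)]
  out <- out[evalue <= maxE]
  setorder(out, evalue)
  out[]
}

ungappedHitsOneStrand <- function(query, subject, word, xdrop) {
  m <- nchar(query); n <- nchar(subject)
  empty <- data.table(qstart = integer(), qend = integer(),
                      sstart = integer(), send = integer(),
                      length = integer(), matches = integer(),
                      score = numeric())
  if (m < word || n < word) return(empty)
  qw <- substring(query, 1:(m - word + 1L), word:m)
  sw <- substring(subject, 1:(n - word + 1L), word:n)
  qdt <- data.table(w = qw, qpos = seq_along(qw))
  sdt <- data.table(w = sw, spos = seq_along(sw))
  seeds <- merge(qdt, sdt, by = "w", allow.cartesian = TRUE)
  if (nrow(seeds) == 0L) return(empty)
  seeds[, diag := qpos - spos]
  setorder(seeds, diag, qpos)
  # keep one seed per run of consecutive seeds on a diagonal
  seeds <- seeds[c(TRUE, !(diff(diag) == 0L & diff(qpos) <= word))]

  qv <- strsplit(query, "")[[1]]
  sv <- strsplit(subject, "")[[1]]
  covered <- list()   # per-diagonal extents already produced
  out <- list()
  for (k in seq_len(nrow(seeds))) {
    qp <- seeds$qpos[k]; sp <- seeds$spos[k]; dg <- seeds$diag[k]
    key <- as.character(dg)
    prev <- covered[[key]]
    if (!is.null(prev) && any(qp >= prev[, 1] & qp <= prev[, 2])) next
    # extend right from end of word
    i <- qp + word; j <- sp + word
    sc <- word; best <- sc; bi <- qp + word - 1L
    while (i <= m && j <= n) {
      sc <- sc + if (qv[i] == sv[j]) 1 else -2
      if (sc > best) { best <- sc; bi <- i }
      if (best - sc > xdrop) break
      i <- i + 1L; j <- j + 1L
    }
    qend <- bi
    # extend left from start of word
    i <- qp - 1L; j <- sp - 1L
    sc <- best; bestL <- sc; bj <- qp
    while (i >= 1L && j >= 1L) {
      sc <- sc + if (qv[i] == sv[j]) 1 else -2
      if (sc > bestL) { bestL <- sc; bj <- i }
      if (bestL - sc > xdrop) break
      i <- i - 1L; j <- j - 1L
    }
    qstart <- bj
    len <- qend - qstart + 1L
    matches <- (bestL + 2 * len) / 3   # s = x - 2(len - x) => x = (s+2len)/3
    out[[length(out) + 1L]] <- data.table(
      qstart = qstart, qend = qend, sstart = qstart - dg,
      send = qend - dg, length = len, matches = round(matches),
      score = bestL)
    covered[[key]] <- rbind(prev, c(qstart, qend))
  }
  rbindlist(out)
}

hitCoverage <- function(hits, qlen) {
  if (nrow(hits) == 0L) return(0)
  sum(IRanges::width(IRanges::reduce(IRanges(hits$qstart, hits$qend)))) /
    qlen
}

scanAgainstDb <- function(seq, db, maxE = 10) {
  res <- lapply(names(db), function(nm) {
    h <- ungappedLocalHits(seq, as.character(db[[nm]]), maxE = maxE)
    if (nrow(h)) h[, entry := nm]
    h
  })
  rbindlist(res[vapply(res, nrow, 0L) > 0])
}

#' Classify a deletion sequence by the three-step repeat cascade
#'
#' Step 1 labels the deletion from the reference repeat annotation when
#' annotated repeat bases of one superfamily cover at least
#' `annotationOverlap` of the deletion. Step 2 scans the sequence against the
#' curated TE library and labels it when local hits tile at least
#' `libraryCoverage` of its length. Step 3 runs the homology search against
#' the full TE database (library plus any additional classified sequences) at
#' E <= `evalue`, labeling on at least 80% length coverage or on coverage of
#' both 400 bp extremities (sequences shorter than 800 bp can only satisfy
#' the length rule). Sequences surviving all three steps are unclassified.
#' A sequence classifiable at an earlier step never reaches a later one; the
#' evidence step is recorded.
#'
#' @param chrom,start,end deletion interval on the reference.
#' @param genome reference `DNAStringSet`.
#' @param repeats repeat-annotation `GRanges` with a `superfamily` column.
#' @param teLibrary curated TE library `DNAStringSet`.
#' @param teSuperfamily named character, library entry -> superfamily.
#' @param extraDb optional additional database entries (`DNAStringSet`) with
#'   superfamily labels in `extraSuperfamily`.
#' @param extraSuperfamily named character for `extraDb`.
#' @param annotationOverlap step-1 reciprocal coverage threshold
#'   (default 0.5).
#' @param libraryCoverage step-2 coverage threshold (default 0.8).
#' @param evalue step-3 E-value threshold (default 1e-20).
#' @return list: `superfamily`, `class` ("I"/"II"/"unclassified"),
#'   `evidence` ("annotation-overlap", "library-scan", "homology-search" or
#'   "none").
#' @export
classifyDeletionSequence <- function(chrom, start, end, genome, repeats,
                                     teLibrary, teSuperfamily,
                                     extraDb = NULL, extraSuperfamily = NULL,
                                     annotationOverlap = 0.5,
                                     libraryCoverage = 0.8,
                                     evalue = 1e-20) {
  len <- end - start + 1L
  delGr <- GRanges(chrom, IRanges(start, end))
  # step 1: annotation overlap
  ov <- findOverlaps(delGr, repeats)
  if (length(ov)) {
    hits <- repeats[S4Vectors::subjectHits(ov)]
    ivs <- IRanges::pintersect(ranges(hits),
                               rep(ranges(delGr), length(hits)))
    cov <- tapply(IRanges::width(ivs), hits$superfamily, sum)
    best <- names(cov)[which.max(cov)]
    if (max(cov) / len >= annotationOverlap) {
      return(list(superfamily = best, class = classOfSuperfamily(best),
                  evidence = "annotation-overlap"))
    }
  }
  seq <- as.character(subseq(genome[[chrom]], start, end))
  # step 2: library scan, coverage-based
  h2 <- scanAgainstDb(seq, teLibrary, maxE = 1e-5)
  if (nrow(h2) && hitCoverage(h2, len) >= libraryCoverage) {
    best <- bestEntry(h2)
    sf <- unname(teSuperfamily[best])
    return(list(superfamily = sf, class = classOfSuperfamily(sf),
                evidence = "library-scan"))
  }
  # step 3: homology search against the full database
  db <- teLibrary; sfmap <- teSuperfamily
  if (!is.null(extraDb) && length(extraDb)) {
    db <- c(db, extraDb)
    sfmap <- c(sfmap, extraSuperfamily)
  }
  h3 <- scanAgainstDb(seq, db, maxE = evalue)
  if (nrow(h3)) {
    covAll <- hitCoverage(h3, len)
    endsOk <- len >= 800L &&
      hitCoverage(h3, len) > 0 &&
      coversInterval(h3, 1L, 400L) && coversInterval(h3, len - 399L, len)
    if (covAll >= 0.8 || endsOk) {
      best <- bestEntry(h3)
      sf <- unname(sfmap[best])
      return(list(superfamily = sf, class = classOfSuperfamily(sf),
                  evidence = "homology-search"))
    }
  }
  list(superfamily = "unclassified", class = "unclassified",
       evidence = "none")
}

# tie-break: highest bit score, then longest coverage, then label
bestEntry <- function(hits) {
  agg <- hits[, .(bs = max(bitScore), cov = sum(length)), by = entry]
  setorder(agg, -bs, -cov, entry)
  agg$entry[1]
}

coversInterval <- function(hits, lo, hi) {
  red <- IRanges::reduce(IRanges(hits$qstart, hits$qend))
  any(IRanges::start(red) <= lo & IRanges::end(red) >= hi)
}

#' Annotate a deletion catalogue with TE classes
#'
#' Runs [classifyDeletionSequence()] on every deletion in a merged catalogue.
#'
#' @param catalogue merged call table (rows with `type == "deletion"`).
#' @param genome,repeats,teLibrary,teSuperfamily see
#'   [classifyDeletionSequence()].
#' @param ... passed through to [classifyDeletionSequence()].
#' @return the catalogue with added columns `superfamily`, `teClass` and
#'   `evidence`.
#' @export
annotateDeletions <- function(catalogue, genome, repeats, teLibrary,
                              teSuperfamily, ...) {
  del <- catalogue[catalogue$type == "deletion"]
  out <- copy(catalogue)
  out[, `:=`(superfamily = NA_character_, teClass = NA_character_,
             evidence = NA_character_)]
  for (i in which(out$type == "deletion")) {
    cl <- classifyDeletionSequence(out$chrom[i], out$start[i], out$end[i],
                                   genome, repeats, teLibrary,
                                   teSuperfamily, ...)
    out$superfamily[i] <- cl$superfamily
    out$teClass[i] <- cl$class
    out$evidence[i] <- cl$evidence
  }
  out[]
}

#' Kimura two-parameter distance between two aligned sequences
#'
#' Computes the transition fraction P and transversion fraction Q over the
#' ungapped columns of the alignment and returns
#' K = -1/2 ln((1 - 2P - Q) sqrt(1 - 2Q)).
#' Saturated alignments (either logarithm argument non-positive) are an
#' error.
#'
#' @param a,b aligned sequences (character scalars of equal length; `-`
#'   marks gaps, gap columns are excluded).
#' @return list: `K`, `P`, `Q`, `sites` (ungapped columns compared).
#' @export
k2pDistance <- function(a, b) {
  x <- strsplit(toupper(a), "")[[1]]
  y <- strsplit(toupper(b), "")[[1]]
  if (length(x) != length(y))
    stop("aligned sequences must have equal length")
  keep <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n == 0L) stop("no ungapped columns to compare")
  diff <- x != y
  ts <- diff & TRANSITION[x] == y
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stop("saturated alignment: K2P distance undefined")
  list(K = -0.5 * log(w1 * sqrt(w2)), P = P, Q = Q, sites = n)
}

#' LTR insertion time from terminal-repeat divergence
#'
#' T = K / (2k) with K the K2P distance between the element's 5' and 3' LTRs
#' and k the substitution rate per site per year.
#'
#' @param K K2P distance (substitutions/site), >= 0.
#' @param rate substitution rate k (default 4.72e-9 /site/year).
#' @return insertion time in years.
#' @export
ltrInsertionTime <- function(K, rate = 4.72e-9) {
  if (any(K < 0)) stop("K must be non-negative")
  if (rate <= 0) stop("substitution rate must be positive")
  K / (2 * rate)
}

#' Date a set of LTR elements from their terminal repeats
#'
#' Aligns each element's 5' and 3' LTRs (global alignment when lengths
#' differ), computes the K2P distance and converts it to years.
#'
#' @param ltr5,ltr3 character vectors of LTR sequences (parallel).
#' @param ids element ids.
#' @param rate substitution rate (default 4.72e-9).
#' @return `data.table`: id, P, Q, K, T (years); saturated pairs get NA.
#' @export
dateLtrElements <- function(ltr5, ltr3, ids = seq_along(ltr5),
                            rate = 4.72e-9) {
  res <- lapply(seq_along(ltr5), function(i) {
    a <- ltr5[i]; b <- ltr3[i]
    if (nchar(a) != nchar(b)) {
      pa <- Biostrings::pairwiseAlignment(DNAString(a), DNAString(b),
                                          type = "global")
      a <- as.character(Biostrings::alignedPattern(pa))
      b <- as.character(Biostrings::alignedSubject(pa))
    }
    k <- tryCatch(k2pDistance(a, b), error = function(e) NULL)
    if (is.null(k))
      return(data.table(id = ids[i], P = NA_real_, Q = NA_real_,
                        K = NA_real_, T = NA_real_))
    data.table(id = ids[i], P = k$P, Q = k$Q, K = k$K,
               T = ltrInsertionTime(k$K, rate))
  })
  rbindlist(res)
}

#' Compare insertion-age distributions of SV-associated and other elements
#'
#' Two-sided two-sample Kolmogorov-Smirnov test on the insertion times of
#' LTR elements associated with detected deletions (SV-LTR) versus the rest
#' (noSV-LTR).
#'
#' @param svTimes,noSvTimes numeric vectors of insertion times (>= 2 each).
#' @return list: `D`, `p`.
#' @export
compareAgeDistributions <- function(svTimes, noSvTimes) {
  if (length(svTimes) < 2L || length(noSvTimes) < 2L)
    stop("each group needs at least two elements")
  kt <- suppressWarnings(ks.test(svTimes, noSvTimes,
                                 alternative = "two.sided"))
  list(D = unname(kt$statistic), p = kt$p.value)
}
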