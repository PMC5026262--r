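#' Genes affected by catalogued variants
#'
#' A gene is affected by a deletion on any overlap with the deletion
#' interval, and by an insertion only when the entire predicted insertion
#' interval lies within the gene.
#'
#' @param catalogue merged call table (`chrom`, `start`, `end`, `type`) or
#'   an [SvCatalogue-class].
#' @param genes `GRanges` with `gene_id`.
#' @return character vector of affected gene ids.
#' @export
affectedGenes <- function(catalogue, genes) {
  if (is(catalogue, "SvCatalogue")) {
    gr <- svCalls(catalogue)
    typ <- gr$type
  } else {
    gr <- GRanges(catalogue$chrom, IRanges(catalogue$start, catalogue$end))
    typ <- catalogue$type
  }
  del <- gr[typ == "deletion"]
  ins <- gr[typ == "insertion"]
  hitDel <- findOverlaps(del, genes)
  hitIns <- findOverlaps(ins, genes, type = "within")
  sort(unique(genes$gene_id[c(S4Vectors::subjectHits(hitDel),
                              S4Vectors::subjectHits(hitIns))]))
}

#' Randomization test of variant placement against gene overlap
#'
#' Transfers the detected variants (lengths preserved) to uniformly random
#' locations, each within a single chromosome, `n` times; the number of
#' affected genes per replicate gives the null distribution, an empirical
#' 2.5/97.5% confidence interval and a two-ish-sided verdict on the observed
#' count.
#'
#' @param catalogue merged call table with `chrom`, `start`, `end`, `type`.
#' @param chromLengths named vector of chromosome lengths.
#' @param genes `GRanges` with `gene_id`.
#' @param n replicates (default 100).
#' @param seed RNG seed.
#' @return list: `observed`, `nullMean`, `ci`, `pLower`, `pUpper` (each the
#'   as-or-more-extreme permutation probability), `replicates`.
#' @export
randomizeVariantPlacement <- function(catalogue, chromLengths, genes,
                                      n = 100L, seed = 1L) {
  set.seed(seed)
  lens <- catalogue$end - catalogue$start + 1L
  if (any(lens > max(chromLengths)))
    stop("a variant is longer than every chromosome")
  observed <- length(affectedGenes(catalogue, genes))
  nv <- nrow(catalogue)
  reps <- integer(n)
  for (r in seq_len(n)) {
    ok <- chromLengths
    chrPick <- sample(names(chromLengths), nv, replace = TRUE,
                      prob = chromLengths)
    # redraw chromosomes too short for the variant
    for (i in which(lens > chromLengths[chrPick])) {
      fit <- names(chromLengths)[chromLengths >= lens[i]]
      chrPick[i] <- sample(fit, 1)
    }
    st <- floor(runif(nv, 1, chromLengths[chrPick] - lens + 2))
    sim <- data.table(chrom = chrPick, start = as.integer(st),
                      end = as.integer(st + lens - 1L),
                      type = catalogue$type)
    reps[r] <- length(affectedGenes(sim, genes))
  }
  list(observed = observed, nullMean = mean(reps),
       ci = unname(quantile(reps, c(0.025, 0.975))),
       pLower = (sum(reps <= observed) + 1) / (n + 1),
       pUpper = (sum(reps >= observed) + 1) / (n + 1),
       replicates = reps)
}

#' Poisson enrichment of event counts in genomic windows
#'
#' Tests each window's event count against a Poisson null with mean equal to
#' the average events per window (genome-wide, or per chromosome when
#' `scope = "chromosome"`), p = P(X >= observed), Benjamini-Hochberg
#' adjusted across windows.
#'
#' @param windows `GRanges` of tiling windows.
#' @param counts integer events per window (parallel to `windows`).
#' @param lambda Poisson mean; computed from `counts` when NULL.
#' @param scope "genome" or "chromosome" for the lambda computation.
#' @param threshold significance cutoff on adjusted p (default 0.05).
#' @return `data.table`: chrom, start, end, count, lambda, pvalue, padj,
#'   significant.
#' @export
poissonWindowEnrichment <- function(windows, counts, lambda = NULL,
                                    scope = c("genome", "chromosome"),
                                    threshold = 0.05) {
  scope <- match.arg(scope)
  dt <- data.table(chrom = as.character(seqnames(windows)),
                   start = start(windows), end = end(windows),
                   count = counts)
  if (is.null(lambda)) {
    if (scope == "genome") {
      dt[, lambda := mean(count)]
    } else {
      dt[, lambda := mean(count), by = chrom]
    }
  } else {
    dt[, lambda := lambda]
  }
  dt[, pvalue := ppois(count - 1L, lambda, lower.tail = FALSE)]
  dt[lambda == 0, pvalue := fifelse(count > 0, 0, 1)]  # degenerate null
  dt[, padj := p.adjust(pvalue, "BH")]
  dt[, significant := padj < threshold]
  dt[]
}

#' Window repetitiveness score from k-mer occurrences
#'
#' Scores each window by the mean genome-wide occurrence count of its
#' k-mers (canonical, strand-collapsed): unique sequence scores about 1,
#' high-copy repeats score their copy number.
#'
#' @param genome `DNAStringSet`.
#' @param windows `GRanges` of windows.
#' @param k k-mer length (default 20).
#' @return numeric vector of scores, parallel to `windows`.
#' @export
windowRepetitiveness <- function(genome, windows, k = 20L) {
  allK <- list()
  for (ci in seq_along(genome)) {
    s <- as.character(genome[[ci]])
    n <- nchar(s)
    if (n < k) next
    allK[[names(genome)[ci]]] <- substring(s, 1:(n - k + 1L), k:(n))
  }
  km <- unlist(allK, use.names = FALSE)
  rc <- as.character(reverseComplement(DNAStringSet(km)))
  canon <- pmin(km, rc)
  tab <- data.table(kmer = canon)[, .N, by = kmer]
  setkey(tab, kmer)
  # per-window mean occurrence
  offs <- cumsum(c(0L, vapply(allK, length, 0L)))
  names(offs) <- c(names(allK), "_end")
  vapply(seq_along(windows), function(i) {
    ch <- as.character(seqnames(windows))[i]
    lo <- start(windows)[i]; hi <- min(end(windows)[i] - k + 1L,
                                       offs[[which(names(offs) == ch) + 1]] -
                                         offs[[ch]])
    if (hi < lo) return(NA_real_)
    idx <- offs[[ch]] + (lo:hi)
    mean(tab[.(canon[idx]), N])
  }, 0)
}

#' Contrast window repetitiveness between INDEL-carrying and empty windows
#'
#' Two-sided Wilcoxon-Mann-Whitney test of the repetitiveness score between
#' windows carrying at least `t` events and windows carrying none, for each
#' threshold in `thresholds`, BH-adjusted across the threshold family.
#'
#' @param scores per-window repetitiveness (see [windowRepetitiveness()]).
#' @param counts per-window event counts.
#' @param thresholds integer vector of minimum event counts to test.
#' @return `data.table`: threshold, nCarrying, nEmpty, W, pvalue, padj
#'   (NA rows when either group is empty).
#' @export
windowRepetitivenessContrast <- function(scores, counts,
                                         thresholds = c(1L, 6L, 7L)) {
  res <- lapply(thresholds, function(t) {
    hi <- scores[counts >= t & !is.na(scores)]
    lo <- scores[counts == 0L & !is.na(scores)]
    if (length(hi) == 0L || length(lo) == 0L)
      return(data.table(threshold = t, nCarrying = length(hi),
                        nEmpty = length(lo), W = NA_real_,
                        pvalue = NA_real_))
    wt <- suppressWarnings(wilcox.test(hi, lo, alternative = "two.sided"))
    data.table(threshold = t, nCarrying = length(hi), nEmpty = length(lo),
               W = unname(wt$statistic), pvalue = wt$p.value)
  })
  out <- rbindlist(res)
  out[, padj := p.adjust(pvalue, "BH")]
  out[]
}

#' Clustering test for genic CNVs
#'
#' Observed statistic: the number of CNV genes lying in windows containing
#' two or more CNV genes. The null re-assigns the CNV labels uniformly
#' across all genes `sims` times; p = (#replicates >= observed + 1)/(sims+1).
#'
#' @param cnvGenes character vector of CNV gene ids.
#' @param genes `GRanges` with `gene_id` (gene midpoints place genes in
#'   windows).
#' @param windows `GRanges` tiling windows.
#' @param sims replicates (default 10000).
#' @param seed RNG seed.
#' @return list: `observed`, `nullMean`, `p`, `replicates`.
#' @export
cnvClusterTest <- function(cnvGenes, genes, windows, sims = 10000L,
                           seed = 1L) {
  set.seed(seed)
  mids <- GRanges(seqnames(genes),
                  IRanges(mid(ranges(genes)), width = 1L))
  winOf <- findOverlaps(mids, windows, select = "first")
  isCnv <- genes$gene_id %in% cnvGenes
  nCnv <- sum(isCnv)
  clustered <- function(sel) {
    t <- tabulate(winOf[sel], nbins = length(windows))
    sum(t[t >= 2L])
  }
  if (nCnv < 2L)
    return(list(observed = 0L, nullMean = 0, p = 1, replicates = integer()))
  observed <- clustered(isCnv)
  reps <- vapply(seq_len(sims), function(i) {
    clustered(sample.int(length(genes), nCnv))
  }, 0L)
  list(observed = observed, nullMean = mean(reps),
       p = (sum(reps >= observed) + 1) / (sims + 1), replicates = reps)
}

#' Chi-square test of genic-CNV distance to the nearest telomere
#'
#' Distance is from the gene midpoint to the nearer chromosome end, binned
#' at 1 Mb with distances above 10 Mb pooled (11 bins). Expected counts are
#' the total CNVs multiplied by the proportion of all genes per bin; bins
#' with expected counts below 1 are merged with their neighbor.
#'
#' @param cnvGenes character vector of CNV gene ids.
#' @param genes `GRanges` with `gene_id`.
#' @param chromLengths named chromosome lengths.
#' @param bin bin width (default 1 Mb).
#' @param poolOver pool distances above this (default 10 Mb).
#' @return list: `chisq`, `df`, `p`, `table` (`data.table`: bin, observed,
#'   expected, residual), `merged` (whether bins were merged).
#' @export
telomereDistanceTest <- function(cnvGenes, genes, chromLengths,
                                 bin = 1e6, poolOver = 10e6) {
  mids <- mid(ranges(genes))
  chr <- as.character(seqnames(genes))
  dist <- pmin(mids - 1, chromLengths[chr] - mids)
  nb <- as.integer(poolOver / bin) + 1L
  bins <- pmin(floor(dist / bin), nb - 1L) + 1L
  isCnv <- genes$gene_id %in% cnvGenes
  obs <- tabulate(bins[isCnv], nbins = nb)
  prop <- tabulate(bins, nbins = nb) / length(genes)
  expd <- sum(isCnv) * prop
  lab <- c(paste0(seq_len(nb - 1L) - 1L, "-", seq_len(nb - 1L), "Mb"),
           paste0(">", poolOver / 1e6, "Mb"))
  keep <- expd > 0 | obs > 0
  obs <- obs[keep]; expd <- expd[keep]; lab <- lab[keep]
  merged <- FALSE
  while (length(expd) > 1L && any(expd < 1)) {
    merged <- TRUE
    i <- which(expd < 1)[1]
    j <- if (i == length(expd)) i - 1L else i + 1L
    expd[j] <- expd[j] + expd[i]; obs[j] <- obs[j] + obs[i]
    lab[j] <- paste(lab[min(i, j)], lab[max(i, j)], sep = "+")
    expd <- expd[-i]; obs <- obs[-i]; lab <- lab[-i]
  }
  if (length(expd) < 2L)
    return(list(chisq = 0, df = 0L, p = NA_real_,
                table = data.table(bin = lab, observed = obs,
                                   expected = expd, residual = 0),
                merged = merged))
  chisq <- sum((obs - expd)^2 / expd)
  df <- length(expd) - 1L
  list(chisq = chisq, df = df,
       p = pchisq(chisq, df, lower.tail = FALSE),
       table = data.table(bin = lab, observed = obs, expected = expd,
                          residual = (obs - expd) / sqrt(expd)),
       merged = merged)
}

#' FPKM expression profiles
#'
#' FPKM = fragments / (transcript kb x million mapped fragments); a gene is
#' expressed (experimentally verified) when FPKM exceeds zero in at least
#' one tissue.
#'
#' @param counts integer matrix, genes x tissues.
#' @param transcriptLengths per-gene transcript length (bp, > 0).
#' @param totals per-tissue mapped fragments (column sums when NULL).
#' @return list: `fpkm` (matrix), `meanFpkm` (per gene), `expressed`
#'   (logical per gene).
#' @export
computeFpkm <- function(counts, transcriptLengths, totals = NULL) {
  if (any(transcriptLengths <= 0)) stop("transcript lengths must be positive")
  if (is.null(totals)) totals <- colSums(counts)
  fpkm <- sweep(counts / (transcriptLengths / 1e3), 2,
                pmax(totals, 1) / 1e6, `/`)
  fpkm[, totals == 0] <- 0   # a tissue with no mapped fragments
  list(fpkm = fpkm, meanFpkm = rowMeans(fpkm),
       expressed = rowSums(fpkm > 0) > 0)
}

#' Randomization test for a mean contrast against random gene subsets
#'
#' Compares the mean of the affected-gene values to the distribution of
#' means of `s` equally sized subsets drawn without replacement from the
#' full gene set. p = (#replicates as or more extreme in the tested
#' direction + 1)/(s + 1). `literal = TRUE` instead applies the printed
#' bookkeeping r = s - q, p = (r + 1)/(s + 1) with q the count of replicates
#' beyond the observed mean in the tested direction.
#'
#' @param affectedValues numeric values of the affected genes (non-empty).
#' @param allValues numeric values of the complete gene set.
#' @param s replicates (default 10000).
#' @param direction "lower" or "higher": the tested tail.
#' @param literal use the literal r = s - q convention.
#' @param seed RNG seed.
#' @return list: `observed`, `nullMean`, `p`, `replicates`.
#' @export
randomizationMeanTest <- function(affectedValues, allValues, s = 10000L,
                                  direction = c("lower", "higher"),
                                  literal = FALSE, seed = 1L) {
  direction <- match.arg(direction)
  if (length(affectedValues) == 0L) stop("affected set is empty")
  set.seed(seed)
  observed <- mean(affectedValues)
  k <- length(affectedValues)
  reps <- vapply(seq_len(s), function(i) {
    mean(allValues[sample.int(length(allValues), k)])
  }, 0)
  q <- if (direction == "lower") sum(reps <= observed) else
    sum(reps >= observed)
  p <- if (literal) (s - q + 1) / (s + 1) else (q + 1) / (s + 1)
  list(observed = observed, nullMean = mean(reps), p = p, replicates = reps)
}

#' Fisher over-representation of annotation terms in a gene subset
#'
#' One-sided (over-representation) Fisher exact test per term present in the
#' subset, from the 2x2 table of subset membership versus term membership
#' over the background; BH-FDR adjusted, significant at adjusted p below
#' `threshold`.
#'
#' @param subset character vector of subset gene ids (must be contained in
#'   `background`).
#' @param background character vector of background gene ids.
#' @param geneTerms `data.table`/data.frame with columns `gene_id`, `term`.
#' @param threshold significance cutoff (default 0.05).
#' @return `data.table`: term, subsetWith, subsetTotal, bgWith, bgTotal,
#'   pvalue, padj, significant.
#' @export
fisherTermEnrichment <- function(subset, background, geneTerms,
                                 threshold = 0.05) {
  if (!all(subset %in% background))
    stop("subset must be contained in the background")
  gt <- as.data.table(geneTerms)
  gt <- gt[gene_id %in% background]
  terms <- unique(gt[gene_id %in% subset, term])
  if (length(terms) == 0L)
    return(data.table(term = character(), subsetWith = integer(),
                      subsetTotal = integer(), bgWith = integer(),
                      bgTotal = integer(), pvalue = numeric(),
                      padj = numeric(), significant = logical()))
  n <- length(background); m <- length(subset)
  res <- lapply(terms, function(tm) {
    withTerm <- unique(gt[term == tm, gene_id])
    a <- sum(subset %in% withTerm)
    K <- length(withTerm)
    tab <- matrix(c(a, m - a, K - a, n - m - (K - a)), 2, 2)
    p <- fisher.test(tab, alternative = "greater")$p.value
    data.table(term = tm, subsetWith = a, subsetTotal = m, bgWith = K,
               bgTotal = n, pvalue = p)
  })
  out <- rbindlist(res)
  out[, padj := p.adjust(pvalue, "BH")]
  out[, significant := padj < threshold]
  setorder(out, pvalue)
  out[]
}
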