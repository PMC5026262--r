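#' Count uniquely aligned fragments per gene
#'
#' Each fragment (pair counted once) built from its uniquely aligned reads is
#' assigned to the gene it overlaps; fragments overlapping two or more genes
#' are assigned to none (union-style ambiguity discard). Non-unique reads are
#' excluded entirely.
#'
#' @param aln alignment `data.table` (one or more samples).
#' @param genes `GRanges` with a `gene_id` column.
#' @return integer matrix of fragment counts, genes x samples.
#' @export
countFragmentsPerGene <- function(aln, genes) {
  if (length(genes) == 0L) stop("gene set is empty")
  rd <- aln[aligned == TRUE & uniq == TRUE & !is.na(chrom)]
  frg <- rd[, .(chrom = chrom[1], start = min(start), end = max(end),
                ok = data.table::uniqueN(chrom) == 1L),
            by = .(sample_id, frag)]
  frg <- frg[ok == TRUE]
  samples <- sort(unique(aln$sample_id))
  cnt <- matrix(0L, length(genes), length(samples),
                dimnames = list(genes$gene_id, samples))
  if (nrow(frg) == 0L) return(cnt)
  fgr <- GRanges(frg$chrom, IRanges(frg$start, frg$end))
  nhit <- countOverlaps(fgr, genes)
  ov <- findOverlaps(fgr, genes)
  keep <- nhit[S4Vectors::queryHits(ov)] == 1L
  qh <- S4Vectors::queryHits(ov)[keep]
  sh <- S4Vectors::subjectHits(ov)[keep]
  tab <- table(factor(genes$gene_id[sh], levels = genes$gene_id),
               factor(frg$sample_id[qh], levels = samples))
  cnt[] <- as.integer(tab)
  cnt
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over genes (restricted to
#' genes with non-zero counts in every sample) of the ratio of the gene's
#' count to its across-sample geometric mean.
#'
#' @param counts integer matrix, genes x samples (>= 2 samples).
#' @return named numeric vector of size factors.
#' @export
estimateSizeFactorsMatrix <- function(counts) {
  if (ncol(counts) < 2L) stop("need at least two samples")
  use <- rowSums(counts == 0) == 0L
  if (!any(use)) stop("no gene with non-zero counts in all samples")
  logc <- log(counts[use, , drop = FALSE])
  logGeo <- rowMeans(logc)
  apply(logc, 2, function(x) exp(median(x - logGeo)))
}

#' Method-of-moments dispersion with a fitted mean-dispersion trend
#'
#' Per-gene raw dispersion alpha = max(0, (var - mean) / mean^2) from
#' size-factor-normalized counts, smoothed by fitting the parametric trend
#' alpha(mu) = a0 / mu + a1 over genes with positive raw estimates; the final
#' per-gene value is the maximum of the raw estimate and the fitted trend
#' (a conservative choice for the pairwise test).
#'
#' With `sharingMode = "maximum"` the per-gene value is the maximum of the
#' raw estimate and the fitted trend (conservative); with `"fit-only"` the
#' fitted trend is used alone — the appropriate mode when every sample is
#' its own condition, since a gene's own copy-number signal otherwise
#' inflates its raw estimate and masks the very difference under test.
#'
#' @param counts integer matrix, genes x samples (>= 2 samples).
#' @param sizeFactors per-sample size factors (estimated when NULL).
#' @param sharingMode "maximum" (default) or "fit-only".
#' @return list: `alpha` (per-gene), `raw`, `fitted`, `trend` (coefficients
#'   a0, a1), `mu` (per-gene normalized mean).
#' @export
estimateDispersionMoM <- function(counts, sizeFactors = NULL,
                                  sharingMode = c("maximum", "fit-only")) {
  sharingMode <- match.arg(sharingMode)
  if (ncol(counts) < 2L) stop("need at least two samples")
  if (is.null(sizeFactors)) sizeFactors <- estimateSizeFactorsMatrix(counts)
  norm <- sweep(counts, 2, sizeFactors, `/`)
  mu <- rowMeans(norm)
  v <- apply(norm, 1, stats::var)
  raw <- ifelse(mu > 0, pmax(0, (v - mu) / mu^2), 0)
  # trend fitted on all expressed genes; one trimming pass guards the fit
  # against genes whose variance is dominated by real copy-number signal
  fitIdx <- which(mu > 0)
  a0 <- 0; a1 <- 0
  if (length(fitIdx) >= 3L) {
    x <- 1 / mu[fitIdx]; y <- raw[fitIdx]
    fit <- lm(y ~ x)
    r <- stats::resid(fit)
    keep <- abs(r) <= 3 * max(stats::mad(r), 1e-8)
    if (sum(keep) >= 3L) fit <- lm(y[keep] ~ x[keep])
    a1 <- max(0, coef(fit)[1]); a0 <- max(0, coef(fit)[2])
  }
  fitted <- ifelse(mu > 0, a0 / mu + a1, 0)
  alpha <- if (sharingMode == "maximum") pmax(raw, fitted) else fitted
  list(alpha = alpha, raw = raw, fitted = fitted,
       trend = c(a0 = unname(a0), a1 = unname(a1)), mu = mu)
}

#' Exact conditional negative-binomial test for one gene, two samples
#'
#' Conditions on the total k = kA + kB and sums, over the k + 1 possible
#' splits (a, k - a), the NB probabilities not exceeding that of the observed
#' split, normalized by the total: the two-sided exact construction with
#' means sA mu and sB mu (mu the pooled normalized mean) and common
#' dispersion alpha; alpha = 0 uses the Poisson limit.
#'
#' @param kA,kB observed counts.
#' @param sA,sB size factors.
#' @param alpha NB dispersion (>= 0).
#' @return two-sided p-value (1 when kA + kB == 0).
#' @export
nbExactTest <- function(kA, kB, sA = 1, sB = 1, alpha = 0) {
  k <- kA + kB
  if (k == 0L) return(1)
  mu <- (kA / sA + kB / sB) / 2
  a <- 0:k
  dens <- function(x, m) {
    if (alpha > 0) dnbinom(x, mu = m, size = 1 / alpha) else dpois(x, m)
  }
  p <- dens(a, sA * mu) * dens(k - a, sB * mu)
  tot <- sum(p)
  if (tot == 0) return(1)
  pobs <- p[kA + 1L]
  min(1, sum(p[p <= pobs * (1 + 1e-7)]) / tot)
}

#' Call genic CNVs by all pairwise differential-coverage tests
#'
#' For every unordered sample pair, each gene is tested with
#' [nbExactTest()]; p-values are Benjamini-Hochberg adjusted (per pair by
#' default, or across all pairs with `bhScope = "global"`), significance is
#' called at adjusted p below `threshold`, and the gene-level union over
#' pairs forms the genic CNV set. Direction is the sign of the normalized
#' count ratio (gain means the second sample of the pair is higher).
#'
#' @param counts integer matrix, genes x samples.
#' @param sizeFactors per-sample size factors (estimated when NULL).
#' @param alpha per-gene dispersions (estimated by [estimateDispersionMoM()]
#'   when NULL).
#' @param threshold adjusted-p significance cutoff (default 0.05).
#' @param bhScope "pair" or "global" multiple-testing scope.
#' @return list: `results` (`data.table`: gene_id, sampleA, sampleB, pvalue,
#'   padj, direction, significant), `cnvGenes` (union gene set),
#'   `sizeFactors`, `alpha`.
#' @export
callGenicCnvs <- function(counts, sizeFactors = NULL, alpha = NULL,
                          threshold = 0.05, bhScope = c("pair", "global")) {
  bhScope <- match.arg(bhScope)
  if (ncol(counts) < 2L) stop("need at least two samples")
  if (is.null(sizeFactors)) sizeFactors <- estimateSizeFactorsMatrix(counts)
  # every sample is its own condition in the pairwise design, so the
  # trend-only dispersion is used (see estimateDispersionMoM)
  if (is.null(alpha))
    alpha <- estimateDispersionMoM(counts, sizeFactors,
                                   sharingMode = "fit-only")$alpha
  alpha <- rep(alpha, length.out = nrow(counts))
  samples <- colnames(counts)
  prs <- utils::combn(samples, 2)
  res <- list()
  for (pidx in seq_len(ncol(prs))) {
    sa <- prs[1, pidx]; sb <- prs[2, pidx]
    kA <- counts[, sa]; kB <- counts[, sb]
    pv <- vapply(seq_len(nrow(counts)), function(g) {
      nbExactTest(kA[g], kB[g], sizeFactors[sa], sizeFactors[sb], alpha[g])
    }, 0)
    nr <- (kB / sizeFactors[sb] + 0.5) / (kA / sizeFactors[sa] + 0.5)
    res[[pidx]] <- data.table(
      gene_id = rownames(counts), sampleA = sa, sampleB = sb, pvalue = pv,
      direction = ifelse(nr > 1, "gain", "loss"))
  }
  res <- rbindlist(res)
  if (bhScope == "pair") {
    res[, padj := p.adjust(pvalue, "BH"), by = .(sampleA, sampleB)]
  } else {
    res[, padj := p.adjust(pvalue, "BH")]
  }
  res[, significant := padj < threshold]
  list(results = res[],
       cnvGenes = sort(unique(res[significant == TRUE, gene_id])),
       sizeFactors = sizeFactors, alpha = alpha)
}
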