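genoIsCarrier <- function(g) g == "het" | g == "hom"

#' Classify variants by species pattern
#'
#' A variant's pattern is the set of species containing at least one carrier
#' (heterozygous or homozygous). Because the design holds more *P. nigra*
#' than *P. deltoides* accessions, the classification is additionally
#' performed for every combination of only two Pn accessions and the
#' per-category tallies are averaged across combinations. A variant is fixed
#' when it is homozygous in every carrier and has no non-carrier among the
#' genotyped samples of its pattern species.
#'
#' @param genotypes variants x samples matrix of genotype codes ("no_call",
#'   "non_carrier", "het", "hom") or of integer allele counts 0/1/2.
#' @param design a [StudyDesign-class]; only high-depth samples are used.
#' @return list: `perVariant` (`data.table`: variant_id, pattern, fixed;
#'   pattern "none" for all-no-call variants), `comboLabels` (variants x
#'   combinations matrix of per-combination patterns), `categoryMeans`
#'   (named numeric: average variant count per category across
#'   combinations).
#' @export
classifySpeciesPattern <- function(genotypes, design) {
  if (is.numeric(genotypes)) {
    g <- matrix(c("non_carrier", "het", "hom")[genotypes + 1L],
                nrow(genotypes), dimnames = dimnames(genotypes))
  } else g <- genotypes
  hd <- intersect(highDepthSamples(design), colnames(g))
  g <- g[, hd, drop = FALSE]
  sp <- speciesOf(design)[hd]
  pnS <- hd[sp == "Pn"]; otherS <- hd[sp != "Pn"]
  combos <- if (length(pnS) >= 2L) utils::combn(pnS, 2L,
                                                simplify = FALSE) else
    list(pnS)
  patOf <- function(cols) {
    carrier <- genoIsCarrier(g[, cols, drop = FALSE])
    apply(carrier, 1, function(cr) {
      spcs <- unique(sp[cols][cr])
      if (length(spcs) == 0L) return("none")
      paste(intersect(c("Pn", "Pd", "Pt"), spcs), collapse = "/")
    })
  }
  comboLabels <- vapply(combos, function(two) patOf(c(two, otherS)),
                        character(nrow(g)))
  if (is.null(dim(comboLabels)))
    comboLabels <- matrix(comboLabels, nrow = nrow(g))
  colnames(comboLabels) <- vapply(combos, paste, "", collapse = "+")
  rownames(comboLabels) <- rownames(g)
  overall <- patOf(hd)
  carrier <- genoIsCarrier(g)
  fixed <- vapply(seq_len(nrow(g)), function(i) {
    cr <- carrier[i, ]
    if (!any(cr)) return(FALSE)
    if (any(g[i, cr] != "hom")) return(FALSE)
    spcs <- unique(sp[cr])
    all(g[i, sp %in% spcs & g[i, ] != "no_call"] == "hom")
  }, TRUE)
  cats <- c(PATTERN_LEVELS, "none")
  catMeans <- rowMeans(apply(comboLabels, 2, function(cl)
    table(factor(cl, levels = cats))))
  list(perVariant = data.table(variant_id = rownames(g), pattern = overall,
                               fixed = fixed),
       comboLabels = comboLabels, categoryMeans = catMeans)
}

#' Pooled-frequency spectrum
#'
#' Histogram of pooled variant frequencies and the fraction of variants with
#' frequency strictly above 0.9 (fixed in the pool), per variant type.
#'
#' @param poolFreq output of [estimatePoolFrequency()].
#' @return `data.table`: type, n, fixedFraction, plus histogram counts in
#'   attributes-free long columns `bin`, `binCount` via a second table in
#'   the returned list: `summary` and `spectrum`.
#' @export
poolFrequencySpectrum <- function(poolFreq) {
  pf <- poolFreq[!is.na(frequency)]
  summary <- pf[, .(n = .N, fixedFraction = mean(frequency > 0.9)),
                by = type]
  brk <- seq(0, 1, 0.1)
  spectrum <- pf[, {
    h <- hist(pmin(frequency, 1), breaks = brk, plot = FALSE)
    .(bin = sprintf("(%.1f,%.1f]", head(brk, -1), brk[-1]),
      binCount = h$counts)
  }, by = type]
  list(summary = summary, spectrum = spectrum)
}

#' Compose the pan-genome from a variant catalogue
#'
#' pan = reference span + inserted-sequence span. The dispensable fraction
#' is the merged deletion span plus the insertion span, excluding variants
#' carried homozygously by every genotyped accession (treated as reference
#' artifacts, hence core); core = pan - dispensable. Contributions partition
#' the dispensable variants by species pattern (species-specific categories
#' and a pooled "shared" category) as fractions of the pan-genome.
#'
#' @param catalogue an [SvCatalogue-class] (or a merged call table plus
#'   `genotypes`).
#' @param design a [StudyDesign-class].
#' @param referenceMb reference genome span in Mb.
#' @param genotypes optional genotype matrix when `catalogue` is a table.
#' @return a [PanGenomeSummary-class].
#' @export
composePanGenome <- function(catalogue, design, referenceMb,
                             genotypes = NULL) {
  if (is(catalogue, "SvCatalogue")) {
    calls <- as.data.table(svCalls(catalogue))
    setnames(calls, "seqnames", "chrom")
    calls[, variant_id := svCalls(catalogue)$variant_id]
    geno <- svGenotypes(catalogue)
  } else {
    calls <- as.data.table(catalogue)
    geno <- genotypes
  }
  hd <- intersect(highDepthSamples(design), colnames(geno))
  gh <- geno[, hd, drop = FALSE]
  # reference artifacts: homozygous in every genotyped accession
  allHom <- apply(gh, 1, function(r) {
    gt <- r[r != "no_call"]
    length(gt) > 0 && all(gt == "hom")
  })
  pat <- classifySpeciesPattern(gh, design)$perVariant
  keep <- !allHom & pat$pattern != "none"
  del <- calls[type == "deletion"][keep[calls$type == "deletion"]]
  ins <- calls[type == "insertion"][keep[calls$type == "insertion"]]
  delSpanMb <- if (nrow(del))
    sum(width(mergeIntervals(GRanges(del$chrom,
                                     IRanges(del$start, del$end))))) / 1e6
  else 0
  insAllMb <- sum(calls[type == "insertion", svlen]) / 1e6
  insMb <- if (nrow(ins)) sum(ins$svlen) / 1e6 else 0
  contributions <- numeric()
  if (any(keep)) {
    spanOf <- function(sel) {
      d <- del[del$variant_id %in% pat$variant_id[sel]]
      i <- ins[ins$variant_id %in% pat$variant_id[sel]]
      ds <- if (nrow(d))
        sum(width(mergeIntervals(GRanges(d$chrom,
                                         IRanges(d$start, d$end))))) / 1e6
      else 0
      ds + (if (nrow(i)) sum(i$svlen) / 1e6 else 0)
    }
    cats <- list(`Pn-specific` = "Pn", `Pd-specific` = "Pd",
                 `Pt-specific` = "Pt")
    contributions <- vapply(cats, function(p)
      spanOf(keep & pat$pattern == p), 0)
    contributions["shared"] <- spanOf(keep & !pat$pattern %in%
                                        unlist(cats))
  }
  panGenomeFromSpans(referenceMb, insAllMb, delSpanMb,
                     excludedMb = insAllMb - insMb,
                     contributionsMb = contributions)
}

#' Pan-genome composition from spans
#'
#' Pure bookkeeping: pan = reference + insertions; dispensable = deletion
#' span + insertion span - the span of all-accession-homozygous variants
#' (`excludedMb`); core = pan - dispensable.
#'
#' @param referenceMb,insertionMb,deletionMb spans in Mb.
#' @param excludedMb span excluded from the dispensable fraction (reference
#'   artifacts), Mb.
#' @param contributionsMb optional named per-category spans (Mb), reported
#'   as fractions of the pan-genome.
#' @return a [PanGenomeSummary-class].
#' @export
panGenomeFromSpans <- function(referenceMb, insertionMb, deletionMb,
                               excludedMb = 0, contributionsMb = numeric()) {
  pan <- referenceMb + insertionMb
  disp <- max(0, deletionMb + insertionMb - excludedMb)
  core <- pan - disp
  new("PanGenomeSummary",
      referenceMb = referenceMb, insertionMb = insertionMb,
      deletionMb = deletionMb, panMb = pan, coreMb = core,
      dispensableMb = disp, coreFraction = core / pan,
      dispensableFraction = disp / pan,
      contributions = if (length(contributionsMb))
        contributionsMb / pan else numeric())
}

#' Gene dispensability report
#'
#' Fractions of annotated genes (i) overlapped by a deletion that is
#' homozygous in at least one accession (dispensable genes) and (ii)
#' detected as genic CNVs (copy-variable genes). Deletions affect a gene on
#' any overlap; insertions only when the whole insertion interval lies
#' within the gene.
#'
#' @param catalogue an [SvCatalogue-class].
#' @param genes `GRanges` with `gene_id`.
#' @param cnvGenes character vector of CNV gene ids.
#' @return `data.table`: class, nGenes, fraction.
#' @export
geneDispensabilityReport <- function(catalogue, genes, cnvGenes) {
  calls <- svCalls(catalogue)
  geno <- svGenotypes(catalogue)
  anyHom <- apply(geno, 1, function(r) any(r == "hom"))
  delHom <- calls[calls$type == "deletion" & anyHom]
  homDeleted <- unique(genes$gene_id[
    S4Vectors::subjectHits(findOverlaps(delHom, genes))])
  nTot <- length(genes)
  data.table(
    class = c("homozygously_deleted", "copy_variable"),
    nGenes = c(length(homDeleted), length(unique(cnvGenes))),
    fraction = c(length(homDeleted), length(unique(cnvGenes))) / nTot)
}
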