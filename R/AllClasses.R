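#' Study design: samples, species and pool membership
#'
#' Describes the sequenced panel: which accessions belong to which species,
#' which are high-depth individuals and which form the low-depth pool, and
#' the per-sample target sequencing depth. The default mirrors a panel of
#' four *P. nigra* (Pn), two *P. deltoides* (Pd) and the reference-species
#' *P. trichocarpa* (Pt) individual, plus an optional Pn discovery pool.
#'
#' @slot samples character vector of sample identifiers (unique).
#' @slot species character vector, same length, species code per sample
#'   (e.g. "Pn", "Pd", "Pt").
#' @slot pool logical vector, same length; `TRUE` for low-depth pool members.
#' @slot depth numeric vector, same length; target sequencing depth (x).
#' @slot referenceSample sample id of the individual the reference genome was
#'   built from ("" if none); that sample can only carry heterozygous variants
#'   relative to the reference.
#'
#' @examples
#' d <- StudyDesign()
#' sampleNames(d)
#' speciesOf(d)
#' @export
setClass("StudyDesign", representation(
  samples = "character",
  species = "character",
  pool = "logical",
  depth = "numeric",
  referenceSample = "character"
))

setValidity("StudyDesign", function(object) {
  n <- length(object@samples)
  if (anyDuplicated(object@samples)) return("sample ids must be unique")
  if (length(object@species) != n || length(object@pool) != n ||
      length(object@depth) != n)
    return("species, pool and depth must match samples in length")
  if (any(object@depth <= 0)) return("depths must be positive")
  if (nzchar(object@referenceSample) &&
      !object@referenceSample %in% object@samples)
    return("referenceSample must be one of the samples")
  TRUE
})

#' Construct a StudyDesign
#'
#' @param nPn,nPd,nPt number of high-depth samples per species.
#' @param poolSize number of low-depth pool accessions (species Pn).
#' @param depth target depth for high-depth samples (x).
#' @param poolDepth target depth for pool members (x).
#' @return A [StudyDesign-class] object. The Pt sample is marked as the
#'   reference individual.
#' @export
StudyDesign <- function(nPn = 4L, nPd = 2L, nPt = 1L, poolSize = 0L,
                        depth = 30, poolDepth = 5) {
  samples <- c(
    if (nPn) paste0("Pn", seq_len(nPn)),
    if (nPd) paste0("Pd", seq_len(nPd)),
    if (nPt) paste0("Pt", seq_len(nPt)),
    if (poolSize) paste0("pool", seq_len(poolSize))
  )
  species <- c(rep("Pn", nPn), rep("Pd", nPd), rep("Pt", nPt),
               rep("Pn", poolSize))
  pool <- c(rep(FALSE, nPn + nPd + nPt), rep(TRUE, poolSize))
  dp <- c(rep(depth, nPn + nPd + nPt), rep(poolDepth, poolSize))
  new("StudyDesign", samples = samples, species = species, pool = pool,
      depth = dp, referenceSample = if (nPt) "Pt1" else "")
}

#' @describeIn StudyDesign-class sample identifiers
#' @param object,x a `StudyDesign`
#' @export
setGeneric("sampleNames", function(object) standardGeneric("sampleNames"))

#' @rdname StudyDesign-class
#' @export
setMethod("sampleNames", "StudyDesign", function(object) object@samples)

#' @describeIn StudyDesign-class species code per sample (named)
#' @export
setGeneric("speciesOf", function(object) standardGeneric("speciesOf"))

#' @rdname StudyDesign-class
#' @export
setMethod("speciesOf", "StudyDesign",
          function(object) setNames(object@species, object@samples))

#' @describeIn StudyDesign-class logical pool-membership flags (named)
#' @export
setGeneric("isPoolMember", function(object) standardGeneric("isPoolMember"))

#' @rdname StudyDesign-class
#' @export
setMethod("isPoolMember", "StudyDesign",
          function(object) setNames(object@pool, object@samples))

#' @describeIn StudyDesign-class target depth per sample (named)
#' @export
setGeneric("targetDepth", function(object) standardGeneric("targetDepth"))

#' @rdname StudyDesign-class
#' @export
setMethod("targetDepth", "StudyDesign",
          function(object) setNames(object@depth, object@samples))

#' @describeIn StudyDesign-class high-depth (non-pool) sample ids
#' @export
highDepthSamples <- function(x) x@samples[!x@pool]

#' @describeIn StudyDesign-class pool sample ids
#' @export
poolSamples <- function(x) x@samples[x@pool]

setMethod("show", "StudyDesign", function(object) {
  tab <- table(object@species[!object@pool])
  cat("StudyDesign:", sum(!object@pool), "high-depth samples (",
      paste(names(tab), tab, sep = "=", collapse = ", "), "),",
      sum(object@pool), "pool members\n")
  if (nzchar(object@referenceSample))
    cat("  reference individual:", object@referenceSample, "\n")
})

#' Structural-variant catalogue with per-sample genotypes
#'
#' Holds a merged catalogue of structural-variant calls as a [GRanges] plus
#' per-sample genotype and supporting-read-fraction matrices. Genotype codes
#' are `"no_call"`, `"non_carrier"`, `"het"`, `"hom"` following the
#' supporting-read-fraction thresholds (f < 0.2 non-carrier, 0.2-0.8
#' heterozygous, > 0.8 homozygous, depth < 5 no call).
#'
#' @slot calls `GRanges` with metadata columns `variant_id`, `type`
#'   ("deletion"/"insertion"), `svlen`, `support`.
#' @slot genotypes character matrix, variants x samples.
#' @slot supportFraction numeric matrix, variants x samples (NA when no call).
#' @export
setClass("SvCatalogue", representation(
  calls = "GRanges",
  genotypes = "matrix",
  supportFraction = "matrix"
))

setValidity("SvCatalogue", function(object) {
  n <- length(object@calls)
  if (nrow(object@genotypes) != n || nrow(object@supportFraction) != n)
    return("genotype matrices must have one row per call")
  if (!identical(dim(object@genotypes), dim(object@supportFraction)))
    return("genotypes and supportFraction must have identical dimensions")
  if (!all(c("variant_id", "type", "svlen", "support") %in%
           names(mcols(object@calls))))
    return("calls must carry variant_id, type, svlen and support columns")
  ok <- object@genotypes %in% c("no_call", "non_carrier", "het", "hom")
  if (!all(ok)) return("invalid genotype code")
  TRUE
})

#' Construct an SvCatalogue
#' @param calls `GRanges` of merged calls (see [SvCatalogue-class]).
#' @param genotypes,supportFraction variants x samples matrices.
#' @return An [SvCatalogue-class] object.
#' @export
SvCatalogue <- function(calls, genotypes, supportFraction) {
  new("SvCatalogue", calls = calls, genotypes = genotypes,
      supportFraction = supportFraction)
}

#' @describeIn SvCatalogue-class the calls as a `GRanges`
#' @param object,x an `SvCatalogue`
#' @export
setGeneric("svCalls", function(object) standardGeneric("svCalls"))

#' @rdname SvCatalogue-class
#' @export
setMethod("svCalls", "SvCatalogue", function(object) object@calls)

#' @describeIn SvCatalogue-class genotype matrix (variants x samples)
#' @export
setGeneric("svGenotypes", function(object) standardGeneric("svGenotypes"))

#' @rdname SvCatalogue-class
#' @export
setMethod("svGenotypes", "SvCatalogue", function(object) object@genotypes)

#' @describeIn SvCatalogue-class supporting-read-fraction matrix
#' @export
setGeneric("svSupportFraction",
           function(object) standardGeneric("svSupportFraction"))

#' @rdname SvCatalogue-class
#' @export
setMethod("svSupportFraction", "SvCatalogue",
          function(object) object@supportFraction)

setMethod("show", "SvCatalogue", function(object) {
  tab <- table(mcols(object@calls)$type)
  cat("SvCatalogue:", length(object@calls), "variants (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ") x",
      ncol(object@genotypes), "samples\n")
})

#' Pan-genome composition summary
#'
#' Sizes (Mb) and fractions of the pan-genome implied by a structural-variant
#' catalogue: pan = reference span + inserted-sequence span; the dispensable
#' fraction is the variant sequence present in some but not all accessions;
#' core = pan - dispensable. Per-category contributions partition the
#' dispensable fraction by species pattern.
#'
#' @slot referenceMb,insertionMb,deletionMb,panMb,coreMb,dispensableMb sizes in Mb.
#' @slot coreFraction,dispensableFraction fractions of the pan-genome.
#' @slot contributions named numeric vector of pan-genome fractions per
#'   species-pattern category (species-specific and shared).
#' @export
setClass("PanGenomeSummary", representation(
  referenceMb = "numeric", insertionMb = "numeric", deletionMb = "numeric",
  panMb = "numeric", coreMb = "numeric", dispensableMb = "numeric",
  coreFraction = "numeric", dispensableFraction = "numeric",
  contributions = "numeric"
))

setValidity("PanGenomeSummary", function(object) {
  if (abs(object@panMb - (object@referenceMb + object@insertionMb)) > 1e-8)
    return("pan must equal reference + insertion span")
  if (abs(object@coreMb + object@dispensableMb - object@panMb) > 1e-8)
    return("core + dispensable must equal pan")
  TRUE
})

setMethod("show", "PanGenomeSummary", function(object) {
  fm <- function(x) format(signif(x, 4), big.mark = ",")
  cat(sprintf("Pan-genome: %s Mb (reference %s + insertions %s)\n",
              fm(object@panMb), fm(object@referenceMb),
              fm(object@insertionMb)))
  cat(sprintf("  core:        %s Mb (%.1f%%)\n", fm(object@coreMb),
              100 * object@coreFraction))
  cat(sprintf("  dispensable: %s Mb (%.1f%%)\n", fm(object@dispensableMb),
              100 * object@dispensableFraction))
  if (length(object@contributions)) {
    cat("  contributions (% of pan):",
        paste(sprintf("%s=%.1f", names(object@contributions),
                      100 * object@contributions), collapse = ", "), "\n")
  }
})

#' @describeIn PanGenomeSummary-class sizes as a named numeric vector (Mb)
#' @param object a `PanGenomeSummary`
#' @export
setGeneric("panSizes", function(object) standardGeneric("panSizes"))

#' @rdname PanGenomeSummary-class
#' @export
setMethod("panSizes", "PanGenomeSummary", function(object) {
  c(reference = object@referenceMb, insertion = object@insertionMb,
    deletion = object@deletionMb, pan = object@panMb, core = object@coreMb,
    dispensable = object@dispensableMb)
})
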