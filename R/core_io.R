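#' Load a reference genome from FASTA
#'
#' Reads every record as a chromosome, folds the sequence to upper case and
#' rejects characters outside the {A,C,G,T,N} alphabet. Chromosome names must
#' be unique.
#'
#' @param path path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by chromosome.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "ACGTACGT"), fa)
#' loadGenome(fa)
#' @export
loadGenome <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA: ", path)
  names(raw) <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(names(raw)))
    stop("duplicate chromosome names in ", path)
  chr <- toupper(as.character(raw))
  bad <- grepl("[^ACGTN]", chr)
  if (any(bad))
    stop("non-ACGTN characters in record(s): ",
         paste(names(raw)[bad], collapse = ", "))
  DNAStringSet(setNames(chr, names(raw)))
}

#' Write a genome (or any named sequence set) to FASTA
#' @param genome a `DNAStringSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenome <- function(genome, path) {
  writeXStringSet(genome, path)
  invisible(path)
}

#' Seqinfo for a genome
#' @param genome a named `DNAStringSet`.
#' @return a [GenomeInfoDb::Seqinfo] with one entry per chromosome.
#' @export
genomeSeqinfo <- function(genome) {
  Seqinfo(seqnames = names(genome), seqlengths = width(genome))
}

#' Load gene models from GFF3
#'
#' Parses gene, mRNA, exon, CDS and UTR features into one gene model per
#' gene. Introns are derived as the gaps between exons within each gene.
#' A child feature extending outside its gene is a format error.
#'
#' @param path path to a GFF3 file.
#' @return A list with elements `genes` (a `GRanges` with `gene_id` and
#'   `transcript_length` metadata columns) and `features` (a `GRanges` with
#'   `gene_id` and `type` in CDS / intron / five_prime_UTR / three_prime_UTR).
#' @export
loadAnnotation <- function(path) {
  gff <- rtracklayer::import(path, format = "gff3")
  types <- as.character(gff$type)
  genes <- gff[types == "gene"]
  if (length(genes) == 0L) stop("no gene features in ", path)
  gid <- if (!is.null(genes$ID)) as.character(genes$ID) else
    as.character(genes$Name)
  mcols(genes) <- NULL
  genes$gene_id <- gid

  kid_types <- c("exon", "CDS", "five_prime_UTR", "three_prime_UTR")
  kids <- gff[types %in% kid_types]
  # resolve each child to its gene: Parent may point at the mRNA
  mrna <- gff[types == "mRNA"]
  mrna_parent <- setNames(
    vapply(mrna$Parent, function(p) as.character(p)[1], ""),
    as.character(mrna$ID))
  kid_parent <- vapply(kids$Parent, function(p) as.character(p)[1], "")
  kid_gene <- ifelse(kid_parent %in% names(mrna_parent),
                     mrna_parent[kid_parent], kid_parent)
  keep <- kid_gene %in% gid
  kids <- kids[keep]; kid_gene <- kid_gene[keep]

  gmap <- setNames(seq_along(genes), gid)
  gi <- gmap[kid_gene]
  if (any(start(kids) < start(genes)[gi] | end(kids) > end(genes)[gi]))
    stop("child feature outside its gene interval")

  out <- GRanges()
  feat_list <- list()
  ktype <- as.character(kids$type)
  for (tp in c("CDS", "five_prime_UTR", "three_prime_UTR")) {
    sel <- ktype == tp
    if (any(sel)) {
      g <- granges(kids[sel])
      g$gene_id <- kid_gene[sel]
      g$type <- tp
      feat_list[[tp]] <- g
    }
  }
  # introns: per-gene gaps between exons
  exn <- kids[ktype == "exon"]
  exg <- kid_gene[ktype == "exon"]
  tlen <- setNames(numeric(length(genes)), gid)
  if (length(exn)) {
    spl <- split(ranges(exn), exg)
    red <- lapply(spl, IRanges::reduce)
    tlen[names(red)] <- vapply(red, function(r) sum(IRanges::width(r)), 0)
    intr <- lapply(names(red), function(g) {
      r <- red[[g]]
      if (length(r) < 2L) return(IRanges())
      IRanges(start = head(end(r), -1L) + 1L, end = tail(start(r), -1L) - 1L)
    })
    ni <- vapply(intr, length, 0L)
    if (sum(ni)) {
      gg <- rep(names(red), ni)
      chr <- as.character(seqnames(genes))[gmap[gg]]
      ig <- GRanges(chr, do.call(c, intr),
                    strand = strand(genes)[gmap[gg]])
      ig$gene_id <- gg
      ig$type <- "intron"
      feat_list[["intron"]] <- ig
    }
  }
  tlen[tlen == 0] <- width(genes)[gmap[names(tlen)[tlen == 0]]]
  genes$transcript_length <- as.integer(tlen[gid])
  features <- if (length(feat_list)) {
    unname(do.call(c, unname(feat_list)))
  } else GRanges(gene_id = character(), type = character())
  list(genes = genes, features = features)
}

#' Write gene models to GFF3
#'
#' Emits gene, mRNA and exon/CDS/UTR rows in standard 1-based GFF3, the
#' inverse of [loadAnnotation()].
#'
#' @param ann a list as returned by [loadAnnotation()] (introns are omitted;
#'   they are re-derived on load).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAnnotation <- function(ann, path) {
  genes <- ann$genes
  feats <- ann$features[ann$features$type != "intron"]
  lines <- c("##gff-version 3")
  for (i in seq_along(genes)) {
    g <- genes[i]
    gid <- g$gene_id
    chr <- as.character(seqnames(g)); st <- as.character(strand(g))
    lines <- c(lines,
      sprintf("%s\tPanSV\tgene\t%d\t%d\t.\t%s\t.\tID=%s", chr, start(g),
              end(g), st, gid),
      sprintf("%s\tPanSV\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.1;Parent=%s", chr,
              start(g), end(g), st, gid, gid))
    f <- feats[feats$gene_id == gid]
    # exons = gene span minus introns; reconstruct from non-intron features
    exn <- IRanges::reduce(ranges(ann$features[
      ann$features$gene_id == gid & ann$features$type != "intron"]))
    if (length(exn) == 0L) exn <- ranges(g)
    for (j in seq_along(exn)) {
      lines <- c(lines, sprintf("%s\tPanSV\texon\t%d\t%d\t.\t%s\t.\tParent=%s.1",
                                chr, start(exn)[j], end(exn)[j], st, gid))
    }
    for (j in seq_along(f)) {
      ph <- if (f$type[j] == "CDS") "0" else "."
      lines <- c(lines, sprintf("%s\tPanSV\t%s\t%d\t%d\t.\t%s\t%s\tParent=%s.1",
                                chr, f$type[j], start(f)[j], end(f)[j], st,
                                ph, gid))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Merge intervals within a gap tolerance
#'
#' Unions maximal chains of intervals whose gaps are at most `slack` bases,
#' per chromosome. Output is sorted and disjoint.
#'
#' @param gr a `GRanges` (strand is ignored).
#' @param slack maximum gap (bp) bridged when merging; must be >= 0.
#' @return A `GRanges` of merged intervals with a `totalSpan` attribute-free
#'   design: use `sum(width(x))` for the span.
#' @examples
#' gr <- GRanges("chr1", IRanges(c(10, 25), c(19, 29)))
#' mergeIntervals(gr, slack = 5)
#' @export
mergeIntervals <- function(gr, slack = 0L) {
  if (slack < 0) stop("slack must be non-negative")
  GenomicRanges::reduce(gr, min.gapwidth = slack + 1L, ignore.strand = TRUE)
}

#' Tile a genome into fixed-width windows
#'
#' Each chromosome is covered by `ceiling(length / width)` windows; the last
#' window is truncated at the chromosome end so the windows partition the
#' genome exactly.
#'
#' @param genome a `DNAStringSet` or a named vector of chromosome lengths.
#' @param width window width in bp (> 0); typical tracks use 250 kb or 2 Mb.
#' @return A `GRanges` of windows.
#' @export
tileWindows <- function(genome, width) {
  if (width <= 0) stop("width must be positive")
  sl <- if (is.numeric(genome)) genome else
    setNames(Biostrings::width(genome), names(genome))
  GenomicRanges::tileGenome(sl, tilewidth = width,
                            cut.last.tile.in.chrom = TRUE)
}

#' Index assembly gaps (runs of N)
#'
#' Runs of `N` of at least `minLength` bases flag likely scaffolding gaps in
#' the reference; deletions called homozygous in the reference individual and
#' coinciding with such runs are suspect assembly artifacts.
#'
#' @param genome a `DNAStringSet`.
#' @param minLength minimum run length (default 100).
#' @return A `GRanges` of N runs.
#' @export
findAssemblyGaps <- function(genome, minLength = 100L) {
  hits <- lapply(seq_along(genome), function(i) {
    m <- IRanges::reduce(as(matchPattern("N", genome[[i]]), "IRanges"))
    m[IRanges::width(m) >= minLength]
  })
  n <- vapply(hits, length, 0L)
  GRanges(rep(names(genome), n), do.call(c, hits))
}

ALN_COLS <- c("frag", "read", "sample_id", "chrom", "start", "end", "strand",
              "mapq", "mateChrom", "mateStart", "mateStrand", "isize",
              "uniq", "aligned", "seq")

#' Read alignment records from the package's TSV dialect
#'
#' One row per read with 1-based closed coordinates; columns `frag` (fragment
#' id), `read` (1/2), `sample_id`, `chrom`, `start`, `end`, `strand`, `mapq`,
#' `mateChrom`, `mateStart`, `mateStrand`, `isize` (fragment span, defined
#' only when both reads align to the same chromosome), `uniq` (uniquely
#' aligned), `aligned`, and `seq` (read sequence, kept for unaligned mobile
#' reads, else NA). Unaligned reads have NA coordinates.
#'
#' @param path TSV path.
#' @return a `data.table` of alignment records.
#' @export
readAlignmentTsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", na.strings = c("NA", "."),
                          colClasses = list(character = c("sample_id",
                            "chrom", "strand", "mateChrom", "mateStrand",
                            "seq")))
  miss <- setdiff(ALN_COLS, names(dt))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  dt
}

#' Write alignment records to TSV
#' @param aln alignment `data.table` (see [readAlignmentTsv()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAlignmentTsv <- function(aln, path) {
  data.table::fwrite(aln[, ALN_COLS, with = FALSE], path, sep = "\t",
                     na = "NA", quote = FALSE)
  invisible(path)
}

#' Read alignment records from a SAM text file
#'
#' Parses the 11 mandatory SAM columns into the package's alignment-record
#' table. Uniqueness is taken from MAPQ > 0; fragment ids come from QNAME.
#' Only primary records are kept.
#'
#' @param path path to a SAM file.
#' @param sample sample id to assign to every record.
#' @return a `data.table` of alignment records (see [readAlignmentTsv()]).
#' @export
readAlignmentSam <- function(path, sample) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "@")]
  if (length(ln) == 0L)
    return(data.table(frag = integer(), read = integer(),
                      sample_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), mapq = integer(),
                      mateChrom = character(), mateStart = integer(),
                      mateStrand = character(), isize = integer(),
                      uniq = logical(), aligned = logical(),
                      seq = character()))
  f <- data.table::tstrsplit(ln, "\t", fixed = TRUE, keep = 1:10)
  flag <- as.integer(f[[2]])
  keep <- bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L
  qname <- f[[1]][keep]; flag <- flag[keep]
  rname <- f[[3]][keep]; pos <- as.integer(f[[4]][keep])
  mapq <- as.integer(f[[5]][keep]); cigar <- f[[6]][keep]
  rnext <- f[[7]][keep]; pnext <- as.integer(f[[8]][keep])
  tlen <- as.integer(f[[9]][keep]); sq <- f[[10]][keep]
  unmapped <- bitwAnd(flag, 4L) != 0L | rname == "*"
  # reference span from CIGAR M/D/N/=/X
  span <- vapply(cigar, function(cg) {
    if (cg == "*") return(NA_integer_)
    n <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
    op <- regmatches(cg, gregexpr("[A-Z=]", cg))[[1]]
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, 0L, USE.NAMES = FALSE)
  rd <- ifelse(bitwAnd(flag, 128L) != 0L, 2L, 1L)
  mchrom <- ifelse(rnext == "=", rname, rnext)
  mchrom[mchrom == "*"] <- NA_character_
  data.table(
    frag = as.integer(factor(qname, levels = unique(qname))),
    read = rd, sample_id = sample,
    chrom = ifelse(unmapped, NA_character_, rname),
    start = ifelse(unmapped, NA_integer_, pos),
    end = ifelse(unmapped, NA_integer_, pos + span - 1L),
    strand = ifelse(unmapped, NA_character_,
                    ifelse(bitwAnd(flag, 16L) != 0L, "-", "+")),
    mapq = ifelse(unmapped, NA_integer_, mapq),
    mateChrom = mchrom,
    mateStart = ifelse(bitwAnd(flag, 8L) != 0L, NA_integer_, pnext),
    mateStrand = ifelse(bitwAnd(flag, 8L) != 0L, NA_character_,
                        ifelse(bitwAnd(flag, 32L) != 0L, "-", "+")),
    isize = ifelse(is.na(tlen) | tlen == 0L, NA_integer_, abs(tlen)),
    uniq = !unmapped & mapq > 0L,
    aligned = !unmapped,
    seq = ifelse(sq == "*", NA_character_, sq)
  )
}
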