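# degeneracy class (0, 2 or 4) of each position of each sense codon:
# 4-fold if all three changes are synonymous, 0-fold if none is,
# 2-fold otherwise (three-fold degenerate sites are grouped with two-fold)
codonDegeneracy <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    code <- Biostrings::GENETIC_CODE
    bases <- c("A", "C", "G", "T")
    codons <- names(code)
    deg <- matrix(NA_integer_, length(codons), 3,
                  dimnames = list(codons, NULL))
    for (cd in codons) {
      if (code[[cd]] == "*") next
      for (pos in 1:3) {
        nsyn <- 0L
        for (b in setdiff(bases, substr(cd, pos, pos))) {
          alt <- cd
          substr(alt, pos, pos) <- b
          if (code[[alt]] != "*" && code[[alt]] == code[[cd]])
            nsyn <- nsyn + 1L
        }
        deg[cd, pos] <- if (nsyn == 3L) 4L else if (nsyn == 0L) 0L else 2L
      }
    }
    cache <<- deg
    deg
  }
})

#' Li-style dN/dS from an aligned in-frame CDS pair
#'
#' Sites are classed by codon degeneracy (non-degenerate, two-fold including
#' three-fold, four-fold), averaging the class over the two codons at each
#' position. Transitions and transversions per class are K2P-corrected
#' (A = transition component, B = transversion component) and combined as
#' dS = (L2 A2 + L4 A4) / (L2 + L4) + B4 and
#' dN = A0 + (L0 B0 + L2 B2) / (L0 + L2): at four-fold sites every change is
#' synonymous, at non-degenerate sites none is, and at two-fold sites
#' transitions are synonymous while transversions are not. The estimator is
#' unbiased in the sense that site classes, not raw codon counts, weight the
#' per-class distances.
#'
#' @param a,b aligned coding sequences (equal length, in frame). Codons with
#'   gaps or ambiguous bases are skipped; the remaining alignment must cover
#'   at least `minBases` bases.
#' @param minBases minimum aligned CDS length (default 150).
#' @return list: `dN`, `dS`, `ratio` (NA when dS is 0 or undefined), `L`
#'   (site counts per class), and per-class transition/transversion
#'   fractions. Saturated classes give NA components.
#' @export
dnds <- function(a, b, minBases = 150L) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) stop("aligned sequences must have equal length")
  if (nchar(a) %% 3L != 0L) stop("alignment length must be a multiple of 3")
  deg <- codonDegeneracy()
  code <- Biostrings::GENETIC_CODE
  ca <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  cb <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
  valid <- ca %in% rownames(deg) & cb %in% rownames(deg)
  stopA <- valid & code[ca] == "*"
  stopB <- valid & code[cb] == "*"
  if (any(head(stopA, -1L)) || any(head(stopB, -1L)))
    stop("internal stop codon")
  okc <- valid & !stopA & !stopB
  ca <- ca[okc]; cb <- cb[okc]
  if (length(ca) * 3L < minBases)
    stop("aligned in-frame CDS shorter than ", minBases, " bases")

  L <- c(`0` = 0, `2` = 0, `4` = 0)
  S <- c(`0` = 0, `2` = 0, `4` = 0)   # transitions
  V <- c(`0` = 0, `2` = 0, `4` = 0)   # transversions
  for (i in seq_along(ca)) {
    c1 <- ca[i]; c2 <- cb[i]
    for (pos in 1:3) {
      k1 <- as.character(deg[c1, pos]); k2 <- as.character(deg[c2, pos])
      L[k1] <- L[k1] + 0.5; L[k2] <- L[k2] + 0.5
      b1 <- substr(c1, pos, pos); b2 <- substr(c2, pos, pos)
      if (b1 != b2) {
        if (TRANSITION[[b1]] == b2) {
          S[k1] <- S[k1] + 0.5; S[k2] <- S[k2] + 0.5
        } else {
          V[k1] <- V[k1] + 0.5; V[k2] <- V[k2] + 0.5
        }
      }
    }
  }
  P <- ifelse(L > 0, S / L, 0)
  Q <- ifelse(L > 0, V / L, 0)
  A <- B <- setNames(rep(NA_real_, 3), names(L))
  for (j in names(L)) {
    w1 <- 1 - 2 * P[j] - Q[j]; w2 <- 1 - 2 * Q[j]
    if (w1 > 0 && w2 > 0) {
      A[j] <- 0.5 * log(1 / w1) - 0.25 * log(w2)
      B[j] <- 0.5 * log(1 / w2)
    }
  }
  dS <- if (L["2"] + L["4"] > 0)
    (L["2"] * A["2"] + L["4"] * A["4"]) / (L["2"] + L["4"]) + B["4"]
  else NA_real_
  dN <- if (L["0"] + L["2"] > 0)
    A["0"] + (L["0"] * B["0"] + L["2"] * B["2"]) / (L["0"] + L["2"])
  else NA_real_
  ratio <- if (!is.na(dS) && !is.na(dN) && dS > 0) dN / dS else NA_real_
  list(dN = unname(dN), dS = unname(dS), ratio = unname(ratio),
       L = L, P = P, Q = Q)
}

#' dN/dS for a set of ortholog pairs
#'
#' Applies [dnds()] to parallel sequence sets, rejecting pairs that fail the
#' frame/stop/length preconditions with the reason recorded.
#'
#' @param cds1,cds2 `DNAStringSet`s (parallel, aligned pairs).
#' @param minBases minimum aligned CDS length.
#' @return `data.table`: pair_id, dN, dS, ratio, status ("ok" or the
#'   rejection reason).
#' @export
dndsPairs <- function(cds1, cds2, minBases = 150L) {
  ids <- names(cds1)
  if (is.null(ids)) ids <- sprintf("pair%03d", seq_along(cds1))
  res <- lapply(seq_along(cds1), function(i) {
    out <- tryCatch(
      dnds(as.character(cds1[[i]]), as.character(cds2[[i]]), minBases),
      error = function(e) conditionMessage(e))
    if (is.character(out))
      return(data.table(pair_id = ids[i], dN = NA_real_, dS = NA_real_,
                        ratio = NA_real_, status = out))
    data.table(pair_id = ids[i], dN = out$dN, dS = out$dS,
               ratio = out$ratio, status = "ok")
  })
  rbindlist(res)
}
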