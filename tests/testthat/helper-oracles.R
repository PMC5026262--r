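# constructed-cluster builders and independent brute-force oracles shared
# by the module tests and the acceptance suite

# cluster of discordant pairs spanning a deletion [delStart, delEnd]:
# plus reads end just before delStart, minus reads start just after delEnd
delCluster <- function(n, delStart, delEnd, chrom = "chr1", mapq = 60L,
                       sample_id = "S1", rl = 100L, offset0 = 10L) {
  rbindlist(lapply(seq_len(n), function(i) {
    off1 <- offset0 + 17L * (i - 1L)
    off2 <- offset0 + 13L * (i - 1L)
    s1 <- delStart - off1 - rl
    s2 <- delEnd + off2 + 1L
    span <- (s2 + rl - 1L) - s1 + 1L
    rbind(alnRow(1000L + i, 1L, sample_id, chrom, s1, s1 + rl - 1L, "+",
                 mapq = mapq, mateStart = s2, mateStrand = "-",
                 isize = span),
          alnRow(1000L + i, 2L, sample_id, chrom, s2, s2 + rl - 1L, "-",
                 mapq = mapq, mateStart = s1, mateStrand = "+",
                 isize = span))
  }))
}

labelPairs <- function(aln, model = testModel) {
  findDiscordantPairs(rbind(backgroundPairs(), aln), model)$pairs
}

mkCall <- function(start, end, detector, support = 10L, sample_id = "S1",
                   chrom = "chr1") {
  data.table(sample_id = sample_id, chrom = chrom, start = as.integer(start),
             end = as.integer(end), len = as.integer(end - start + 1L),
             support = as.integer(support), medmapq = 60,
             detector = detector)
}

# independent NB pmf (no dnbinom) for the exact-test oracle
nbPmf <- function(x, mu, size) {
  exp(lgamma(x + size) - lgamma(size) - lfactorial(x) +
        size * log(size / (size + mu)) + x * log(mu / (size + mu)))
}

oracleNbTest <- function(kA, kB, sA, sB, alpha) {
  k <- kA + kB
  if (k == 0) return(1)
  mu <- (kA / sA + kB / sB) / 2
  probs <- numeric(k + 1)
  for (a in 0:k) {
    pa <- if (alpha > 0) nbPmf(a, sA * mu, 1 / alpha) else
      exp(-sA * mu) * (sA * mu)^a / factorial(a)
    pb <- if (alpha > 0) nbPmf(k - a, sB * mu, 1 / alpha) else
      exp(-sB * mu) * (sB * mu)^(k - a) / factorial(k - a)
    probs[a + 1] <- pa * pb
  }
  sum(probs[probs <= probs[kA + 1] * (1 + 1e-7)]) / sum(probs)
}

# explicit-loop dN/dS recount from the genetic code
oracleDnds <- function(a, b) {
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  ts <- c(A = "G", G = "A", C = "T", T = "C")
  degOf <- function(codon, pos) {
    n <- 0
    for (x in setdiff(bases, substr(codon, pos, pos))) {
      alt <- codon; substr(alt, pos, pos) <- x
      if (code[[alt]] != "*" && code[[alt]] == code[[codon]]) n <- n + 1
    }
    if (n == 3) "4" else if (n == 0) "0" else "2"
  }
  L <- c(`0` = 0, `2` = 0, `4` = 0)
  S <- L; V <- L
  for (i in seq(1, nchar(a), 3)) {
    c1 <- substr(a, i, i + 2); c2 <- substr(b, i, i + 2)
    for (pos in 1:3) {
      k1 <- degOf(c1, pos); k2 <- degOf(c2, pos)
      L[k1] <- L[k1] + 0.5; L[k2] <- L[k2] + 0.5
      b1 <- substr(c1, pos, pos); b2 <- substr(c2, pos, pos)
      if (b1 != b2) {
        if (ts[[b1]] == b2) { S[k1] <- S[k1] + 0.5; S[k2] <- S[k2] + 0.5 }
        else { V[k1] <- V[k1] + 0.5; V[k2] <- V[k2] + 0.5 }
      }
    }
  }
  P <- S / pmax(L, 1e-12); Q <- V / pmax(L, 1e-12)
  A <- 0.5 * log(1 / (1 - 2 * P - Q)) - 0.25 * log(1 - 2 * Q)
  B <- 0.5 * log(1 / (1 - 2 * Q))
  list(dS = unname((L["2"] * A["2"] + L["4"] * A["4"]) /
                     (L["2"] + L["4"]) + B["4"]),
       dN = unname(A["0"] + (L["0"] * B["0"] + L["2"] * B["2"]) /
                     (L["0"] + L["2"])))
}
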