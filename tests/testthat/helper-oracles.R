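# Independent oracles used across tests.  These re-derive expected values
# by brute force or closed form, without touching the implementation paths
# they check.

# per-site unbiased heterozygosity, written as an explicit loop
oracle_pi_site <- function(dosages, ploidy = 2) {
  d <- dosages[!is.na(dosages)]
  n_al <- ploidy * length(d)
  if (n_al < 2) return(0)
  alt <- sum(d)
  p <- alt / n_al
  2 * p * (1 - p) * n_al / (n_al - 1)
}

# Weir-Cockerham per-site components, transcribed independently from the
# estimator's definition (two subpopulations)
oracle_wc_site <- function(g1, g2) {
  g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
  n <- c(length(g1), length(g2))
  if (any(n < 1)) return(c(0, 0, 0))
  p <- c(sum(g1) / (2 * n[1]), sum(g2) / (2 * n[2]))
  h <- c(mean(g1 == 1), mean(g2 == 1))
  r <- 2
  nbar <- mean(n)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  if (nc <= 0 || nbar <= 1) return(c(0, 0, 0))
  pbar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / sum(n)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) /
                        (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r -
                                hbar * (2 * nbar - 1) / (4 * nbar))
  c(a, b, hbar / 2)
}

# standalone codon table translation (independent of Biostrings)
ORACLE_CODONS <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
  CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
  TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
  GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
  AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
  CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

oracle_translate <- function(dna) {
  n <- nchar(dna) - nchar(dna) %% 3
  if (n < 3) return("")
  cod <- substring(dna, seq(1, n, 3), seq(3, n, 3))
  paste(ORACLE_CODONS[cod], collapse = "")
}

# CDS of a gene-model row extracted directly from its genome
oracle_cds <- function(gene, genome) {
  cd <- gene$cds[[1]]
  s <- unclass(genome)[[gene$chromosome]]
  paste(substring(s, cd[, "start"] + 1, cd[, "end"]), collapse = "")
}

# closed-form K2P from transition/transversion proportions
oracle_k2p <- function(P, Q) -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))

# exhaustive two-pass one-to-one filtering on a small block set: maximise
# total score among subsets non-overlapping on ref, then on qry
oracle_one_to_one_score <- function(blocks) {
  score <- (blocks$ref_end - blocks$ref_start) * blocks$identity
  n <- nrow(blocks)
  tol <- 25 # junction-jitter tolerance shared with the implementation
  compat <- function(idx, s, e, ch) {
    if (length(idx) < 2) return(TRUE)
    for (i in seq_along(idx)[-1]) for (j in seq_len(i - 1)) {
      a <- idx[i]; b <- idx[j]
      if (ch[a] == ch[b] && s[a] < e[b] - tol && s[b] < e[a] - tol)
        return(FALSE)
    }
    TRUE
  }
  best_subset <- function(cand, s, e, ch) {
    best <- integer(0); best_w <- 0
    for (m in seq_len(2^length(cand)) - 1) {
      idx <- cand[bitwAnd(m, 2^(seq_along(cand) - 1)) > 0]
      if (!compat(idx, s, e, ch)) next
      w <- sum(score[idx])
      if (w > best_w) { best_w <- w; best <- idx }
    }
    list(idx = best, w = best_w)
  }
  p1 <- best_subset(seq_len(n), blocks$ref_start, blocks$ref_end,
                    blocks$ref_chrom)
  p2 <- best_subset(p1$idx, blocks$qry_start, blocks$qry_end,
                    blocks$qry_chrom)
  p2$w
}

# exhaustive maximum-weight strictly-increasing forward chain
oracle_global_chain_weight <- function(blocks) {
  fw <- which(blocks$orientation == "forward")
  score <- (blocks$ref_end - blocks$ref_start) * blocks$identity
  best <- 0
  for (m in seq_len(2^length(fw)) - 1) {
    idx <- fw[bitwAnd(m, 2^(seq_along(fw) - 1)) > 0]
    if (length(idx) == 0) next
    idx <- idx[order(blocks$ref_start[idx])]
    ok <- TRUE
    if (length(idx) > 1) {
      for (i in seq_along(idx)[-1]) {
        if (blocks$ref_start[idx[i]] < blocks$ref_end[idx[i - 1]] - 25 ||
            blocks$qry_start[idx[i]] < blocks$qry_end[idx[i - 1]] - 25) {
          ok <- FALSE; break
        }
      }
    }
    if (ok) best <- max(best, sum(score[idx]))
  }
  best
}

# small deterministic block tibble builder
toy_block <- function(rs, re, qs, qe, ident = 1, ori = "forward",
                      rc = "c1", qc = "c1") {
  tibble::tibble(ref_chrom = rc, ref_start = rs, ref_end = re,
                 qry_chrom = qc, qry_start = qs, qry_end = qe,
                 orientation = ori, identity = ident,
                 ref_aln = NA_character_, qry_aln = NA_character_)
}
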