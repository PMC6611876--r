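# Minimal whole-genome aligner: unique k-mer anchors, greedy collinear
# chaining, base-level block alignment of inter-anchor gaps, plus the two
# filtering modes (one-to-one and global-collinear) the structural-variation
# scan builds on.  Interchangeable with imported aligner output read by
# read_alignment_table().

#' Align two genomes by anchor seeding and chaining
#'
#' Anchors are maximal exact matches seeded at k-mers that occur exactly
#' once in the reference (both strands of the query are scanned).  Anchors
#' are chained greedily by diagonal proximity with gaps at most
#' `max_anchor_gap` on both genomes and consistent orientation; each chain
#' becomes an alignment block whose inter-anchor gaps are closed by global
#' alignment (match +1, mismatch -1, gap -2).  Blocks shorter than
#' `min_block` on the reference are discarded.
#'
#' @param ref,qry `genome_set` objects.
#' @param k anchor k-mer length (15-31; a free parameter, default 21).
#' @param max_anchor_gap largest gap bridged within a chain, bp.  Gaps
#'   larger than this split blocks, leaving the intervening sequence
#'   unaligned (where presence-absence calling picks it up).
#' @param min_block minimum reference-span length of a reported block, bp.
#' @return tibble of alignment blocks (see [read_alignment_table()]) with
#'   `ref_aln`/`qry_aln` holding the gapped base-level alignment; reverse
#'   blocks store ascending coordinates plus `orientation = "reverse"`, and
#'   their `qry_aln` is written on the reverse-complemented query strand.
#' @export
seed_and_chain <- function(ref, qry, k = 21, max_anchor_gap = 100,
                           min_block = 200) {
  stopifnot(k >= 15, k <= 31)
  if (length(ref) == 0 || length(qry) == 0) abort("empty genome")
  if (all(genome_lengths(ref) < k) || all(genome_lengths(qry) < k)) {
    warn("genome shorter than k; no anchors")
    return(block_tibble())
  }
  out <- list()
  for (rc in names(ref)) {
    rseq <- unclass(ref)[[rc]]
    for (qc in names(qry)) {
      qseq <- unclass(qry)[[qc]]
      if (nchar(rseq) < k || nchar(qseq) < k) next
      qlen <- nchar(qseq)
      anc <- cpp_find_anchors(rseq, qseq, as.integer(k))
      if (nrow(anc) == 0) next
      qrc <- NULL
      for (ori in unique(anc$orientation)) {
        a <- anc[anc$orientation == ori, , drop = FALSE]
        # oriented query coordinate: ascending along the strand aligned to ref
        qpos <- if (ori == 0) a$qry_start else qlen - (a$qry_start + a$length)
        cid <- cpp_chain_anchors(a$ref_start, qpos, a$length,
                                 max_anchor_gap, as.integer(k))
        qseq_o <- if (ori == 0) qseq else {
          if (is.null(qrc)) qrc <- cpp_revcomp(qseq)
          qrc
        }
        for (id in unique(cid)) {
          sel <- cid == id
          al <- cpp_chain_alignment(rseq, qseq_o, a$ref_start[sel], qpos[sel],
                                    a$length[sel])
          if (al$ref_end - al$ref_start < min_block) next
          qs <- al$qry_start; qe <- al$qry_end
          if (ori == 1) { tmp <- qlen - qe; qe <- qlen - qs; qs <- tmp }
          out[[length(out) + 1]] <- block_tibble(
            ref_chrom = rc, ref_start = al$ref_start, ref_end = al$ref_end,
            qry_chrom = qc, qry_start = qs, qry_end = qe,
            orientation = if (ori == 0) "forward" else "reverse",
            identity = al$matches / max(al$columns, 1),
            ref_aln = al$ref_aln, qry_aln = al$qry_aln)
        }
      }
    }
  }
  if (length(out) == 0) return(block_tibble())
  bind_rows(out) %>% arrange(.data$ref_chrom, .data$ref_start)
}

block_score <- function(blocks)
  (blocks$ref_end - blocks$ref_start) * blocks$identity

# Weighted interval scheduling: maximum total score among blocks
# non-overlapping on the side given by (start, end), allowing `tol` bp of
# overlap (anchors extended across a junction can spill a few bases into
# the neighbouring block).  Ties resolved toward longer blocks, then
# smaller start (deterministic).
wis_keep <- function(start, end, score, len, tol = 25) {
  n <- length(start)
  if (n <= 1) return(rep(TRUE, n))
  ord <- order(end, -len, start)
  s <- start[ord]; e <- end[ord]; w <- score[ord]
  prev <- findInterval(s + tol + 0.5, e) # last j with e[j] <= s[i] + tol
  opt <- numeric(n); take <- logical(n)
  choose <- integer(n)
  for (i in seq_len(n)) {
    with_i <- w[i] + if (prev[i] > 0) opt[prev[i]] else 0
    without <- if (i > 1) opt[i - 1] else 0
    if (with_i >= without) { opt[i] <- with_i; choose[i] <- 1 }
    else opt[i] <- without
  }
  i <- n
  while (i > 0) {
    if (choose[i] == 1) { take[i] <- TRUE; i <- prev[i] }
    else i <- i - 1
  }
  keep <- logical(n)
  keep[ord] <- take
  keep
}

#' One-to-one block filtering
#'
#' Two-pass weighted interval scheduling that maximises total
#' length-times-identity among blocks non-overlapping on the reference and
#' then again on the query.  Rearrangements (order or orientation changes)
#' are permitted; the result is a subset of the input.  Mirrors the
#' one-to-one filtering mode of whole-genome aligner post-processing.
#'
#' @param blocks block tibble.
#' @return filtered block tibble.
#' @export
filter_one_to_one <- function(blocks) {
  if (nrow(blocks) == 0) return(blocks)
  sc <- block_score(blocks)
  len <- blocks$ref_end - blocks$ref_start
  keep <- rep(FALSE, nrow(blocks))
  for (ch in unique(blocks$ref_chrom)) {
    i <- which(blocks$ref_chrom == ch)
    keep[i] <- wis_keep(blocks$ref_start[i], blocks$ref_end[i], sc[i], len[i])
  }
  b2 <- blocks[keep, , drop = FALSE]
  sc2 <- block_score(b2)
  len2 <- b2$ref_end - b2$ref_start
  keep2 <- rep(FALSE, nrow(b2))
  for (ch in unique(b2$qry_chrom)) {
    i <- which(b2$qry_chrom == ch)
    keep2[i] <- wis_keep(b2$qry_start[i], b2$qry_end[i], sc2[i], len2[i])
  }
  b2[keep2, , drop = FALSE]
}

#' Global collinear filtering
#'
#' For each reference chromosome, the maximum-weight chain of forward
#' blocks strictly increasing in both reference and query coordinates
#' (weighted longest increasing subsequence, weight = reference length x
#' identity) against its best-matching query chromosome.  Blocks outside
#' the chain are dropped; no rearrangement survives.  Mirrors the global
#' (collinear-only) filtering mode.
#'
#' @param blocks block tibble.
#' @return the collinear backbone: a subset of `blocks`.
#' @export
filter_global <- function(blocks) {
  if (nrow(blocks) == 0) return(blocks)
  best_rows <- list()
  for (rc in unique(blocks$ref_chrom)) {
    best <- NULL; best_w <- -Inf
    for (qc in unique(blocks$qry_chrom[blocks$ref_chrom == rc])) {
      i <- which(blocks$ref_chrom == rc & blocks$qry_chrom == qc &
                   blocks$orientation == "forward")
      if (length(i) == 0) next
      b <- blocks[i, , drop = FALSE]
      ord <- order(b$ref_start, b$ref_end)
      b <- b[ord, , drop = FALSE]; idx <- i[ord]
      w <- block_score(b)
      n <- nrow(b)
      opt <- numeric(n); prev <- integer(n)
      for (j in seq_len(n)) {
        opt[j] <- w[j]; prev[j] <- 0
        cand <- which(b$ref_end[seq_len(j - 1)] <= b$ref_start[j] + 25 &
                        b$qry_end[seq_len(j - 1)] <= b$qry_start[j] + 25)
        if (length(cand) > 0) {
          kbest <- cand[which.max(opt[cand])]
          opt[j] <- w[j] + opt[kbest]; prev[j] <- kbest
        }
      }
      jj <- which.max(opt)
      total <- opt[jj]
      chain <- integer(0)
      while (jj > 0) { chain <- c(idx[jj], chain); jj <- prev[jj] }
      if (total > best_w) { best_w <- total; best <- chain }
    }
    if (!is.null(best)) best_rows[[rc]] <- best
  }
  sel <- sort(unlist(best_rows))
  blocks[sel, , drop = FALSE]
}

# Align a short sequence against a genome via exact-match segments: returns
# coverage (chained-span fraction of the sequence) and identity
# (matched-base fraction within the chained span) of the best target
# chromosome.  Used by the presence-absence rejection filter.
align_region_to_genome <- function(seq, genome, k = 15, min_seed = 20,
                                   chain_gap = 200, max_occ = 8) {
  n <- nchar(seq)
  best <- c(coverage = 0, identity = 0)
  if (n == 0 || grepl("^N+$", seq)) return(best)
  for (ch in names(genome)) {
    seg <- cpp_exact_segments(unclass(genome)[[ch]], seq, as.integer(k),
                              as.integer(min_seed), as.integer(max_occ))
    if (nrow(seg) == 0) next
    seg <- seg[order(seg$qry_start), , drop = FALSE]
    # chain query-side segments with gaps <= chain_gap
    gap <- c(Inf, seg$qry_start[-1] - cummax(seg$qry_end)[-nrow(seg)])
    grp <- cumsum(gap > chain_gap)
    spans <- tapply(seq_len(nrow(seg)), grp, function(i)
      c(min(seg$qry_start[i]), max(seg$qry_end[i]),
        sum(seg$qry_end[i] - seg$qry_start[i])))
    span_len <- sum(vapply(spans, function(x) x[2] - x[1], 0))
    matched <- sum(vapply(spans, function(x) min(x[3], x[2] - x[1]), 0))
    cand <- c(coverage = span_len / n,
              identity = if (span_len > 0) matched / span_len else 0)
    if (cand["coverage"] * cand["identity"] >
        best["coverage"] * best["identity"]) best <- cand
  }
  best
}
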