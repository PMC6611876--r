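# Homoeologous-introgression detection: 5-kb bins of a subgenome scored by
# the ratio of alignment coverage against the two ancestor genomes.

#' Score subgenome bins for homoeologous introgression
#'
#' Each 5-kb bin of the subgenome is aligned to both ancestor genomes by
#' exact-match seeding (seeds of at least `min_seed` bp, either strand).
#' Two coverage notions are computed per ancestor: span coverage (fraction
#' of the bin inside chained seed spans - the retention measure) and match
#' coverage (fraction of the bin inside exact seed matches - the ratio
#' measure, which keeps contrast between closely and distantly related
#' ancestors).  A bin whose span coverage is below `min_target_cov` against
#' both ancestors is unresolved; otherwise it is called introgressed when
#' the other/own match-coverage ratio reaches `ratio_min`, or when own
#' coverage is zero with other span coverage at least `min_target_cov`
#' (the strongest possible signal; flagged), and native otherwise.
#'
#' @param subgenome `genome_set` of the focal subgenome.
#' @param own_ancestor,other_ancestor ancestor `genome_set`s (same-ancestry
#'   and other-ancestry).
#' @param bin bin width in bp (default 5000).
#' @param min_ident minimum identity of counted alignments; exact seed
#'   matches satisfy any threshold at or below 1.
#' @param min_seed minimum seed length in bp (default 50).
#' @param min_target_cov retention threshold on span coverage (default 0.7).
#' @param ratio_min introgression ratio threshold (default 1.5).
#' @param chain_gap largest gap bridged when chaining seeds into spans, bp.
#' @return tibble of bins: `chromosome`, `start`, `end`, `cov_own`,
#'   `cov_other` (match coverages), `span_own`, `span_other`, `ratio`,
#'   `call` in {introgressed, native, unresolved}, `flag`.
#' @export
score_bins <- function(subgenome, own_ancestor, other_ancestor, bin = 5000,
                       min_ident = 0.9, min_seed = 50, min_target_cov = 0.7,
                       ratio_min = 1.5, chain_gap = 500) {
  stopifnot(min_ident <= 1, min_seed >= 15)
  k <- as.integer(min(25, min_seed))
  cat_genome <- function(g) paste(unclass(g), collapse = strrep("N", 60))
  own_cat <- cat_genome(own_ancestor)
  other_cat <- cat_genome(other_ancestor)
  out <- list()
  for (ch in names(subgenome)) {
    q <- unclass(subgenome)[[ch]]
    n <- nchar(q)
    seg_own <- cpp_exact_segments(own_cat, q, k, as.integer(min_seed), 8L)
    seg_other <- cpp_exact_segments(other_cat, q, k, as.integer(min_seed), 8L)
    cover <- function(seg, chaingap) {
      if (nrow(seg) == 0) return(IRanges::IRanges())
      r <- IRanges::reduce(iranges_of(seg$qry_start, seg$qry_end))
      if (chaingap > 0)
        r <- IRanges::reduce(r, min.gapwidth = chaingap)
      r
    }
    match_own <- cover(seg_own, 0); match_other <- cover(seg_other, 0)
    span_own <- cover(seg_own, chain_gap); span_other <- cover(seg_other, chain_gap)
    starts <- seq(0, n - 1, by = bin)
    bins <- tibble(chromosome = ch, start = starts,
                   end = pmin(starts + bin, n))
    frac_in <- function(r, s, e) {
      if (length(r) == 0) return(rep(0, length(s)))
      q <- iranges_of(s, e)
      ov <- IRanges::findOverlaps(q, r)
      w <- IRanges::width(IRanges::pintersect(
        q[S4Vectors::queryHits(ov)], r[S4Vectors::subjectHits(ov)]))
      out <- rep(0, length(s))
      agg <- tapply(w, S4Vectors::queryHits(ov), sum)
      out[as.integer(names(agg))] <- agg
      out / (e - s)
    }
    bins$cov_own <- frac_in(match_own, bins$start, bins$end)
    bins$cov_other <- frac_in(match_other, bins$start, bins$end)
    bins$span_own <- frac_in(span_own, bins$start, bins$end)
    bins$span_other <- frac_in(span_other, bins$start, bins$end)
    # N fraction per bin
    nn <- vapply(seq_len(nrow(bins)), function(i)
      grepl("^N*$", gsub("[ACGT]", "", substr(q, bins$start[i] + 1, bins$end[i]))) &&
        !grepl("[ACGT]", substr(q, bins$start[i] + 1, bins$end[i])),
      logical(1))
    bins$flag <- ifelse(bins$end - bins$start < bin, "terminal", "")
    bins$flag[nn] <- paste0(bins$flag[nn], ";all_N")
    bins$ratio <- ifelse(bins$cov_own > 0, bins$cov_other / bins$cov_own,
                         ifelse(bins$cov_other > 0, Inf, 0))
    call <- rep("native", nrow(bins))
    unres <- (bins$span_own < min_target_cov &
                bins$span_other < min_target_cov) | nn
    intro <- !unres &
      ((is.finite(bins$ratio) & bins$ratio >= ratio_min) |
         (bins$cov_own == 0 & bins$span_other >= min_target_cov &
            bins$cov_other > 0))
    call[intro] <- "introgressed"
    call[unres] <- "unresolved"
    zero_denom <- intro & bins$cov_own == 0
    bins$flag[zero_denom] <- paste0(bins$flag[zero_denom], ";zero_own_coverage")
    bins$call <- call
    out[[length(out) + 1]] <- bins
  }
  bind_rows(out)
}

#' Per-chromosome introgressed-length summary
#' @param bins tibble from [score_bins()].
#' @return tibble: chromosome, n introgressed bins, introgressed Mb.
#' @export
summarise_introgression <- function(bins) {
  bins %>% filter(.data$call == "introgressed") %>%
    group_by(.data$chromosome) %>%
    summarise(n_bins = dplyr::n(),
              introgressed_mb = sum(.data$end - .data$start) / 1e6,
              .groups = "drop")
}
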