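# Allelic/non-allelic partition of one-to-one alignment blocks, inversion
# and translocation classification and merging, and SNP/small-indel calling
# with a buffering filter.

#' Partition one-to-one blocks into allelic and non-allelic sets
#'
#' A one-to-one block is allelic when at least half of its reference span
#' is covered by the global collinear chain of its chromosome pair and its
#' orientation agrees with the chain (forward); all other blocks are
#' non-allelic and feed rearrangement classification.
#'
#' @param one2one one-to-one filtered block tibble ([filter_one_to_one()]).
#' @param global_chain collinear backbone ([filter_global()]).
#' @return list with tibbles `allelic` and `nonallelic` (disjoint; their
#'   union is `one2one`).
#' @export
partition_allelic <- function(one2one, global_chain) {
  if (nrow(one2one) == 0)
    return(list(allelic = one2one, nonallelic = one2one))
  is_allelic <- vapply(seq_len(nrow(one2one)), function(i) {
    b <- one2one[i, ]
    if (b$orientation != "forward") return(FALSE)
    g <- global_chain %>%
      filter(.data$ref_chrom == b$ref_chrom, .data$qry_chrom == b$qry_chrom)
    if (nrow(g) == 0) return(FALSE)
    covered_fraction(b$ref_start, b$ref_end, g$ref_start, g$ref_end) >= 0.5
  }, logical(1))
  list(allelic = one2one[is_allelic, , drop = FALSE],
       nonallelic = one2one[!is_allelic, , drop = FALSE])
}

#' Classify non-allelic blocks as inversions or translocations
#'
#' Each non-allelic block is classified from its flanking allelic context
#' on the reference chromosome: a block whose query chromosome differs from
#' the chromosome its flanks map to is an inter-chromosomal translocation;
#' otherwise a reverse-orientation block is an inversion and a forward one
#' an intra-chromosomal translocation (order-inconsistent placement).
#' Blocks with no allelic neighbour on either side fall back to the
#' chromosome-level majority context and are flagged low confidence.
#'
#' @param partition result of [partition_allelic()].
#' @return tibble of unmerged rearranged regions: `kind`, `ref_chrom`,
#'   `ref_start`, `ref_end`, `qry_chrom`, `qry_start`, `qry_end`,
#'   `total_length`, `n_blocks`, `confidence`.
#' @export
classify_rearrangements <- function(partition) {
  na_b <- partition$nonallelic
  al <- partition$allelic
  if (nrow(na_b) == 0)
    return(tibble(kind = character(), ref_chrom = character(),
                  ref_start = double(), ref_end = double(),
                  qry_chrom = character(), qry_start = double(),
                  qry_end = double(), total_length = double(),
                  n_blocks = integer(), confidence = character()))
  rows <- purrr::map(seq_len(nrow(na_b)), function(i) {
    b <- na_b[i, ]
    ctx <- al %>% filter(.data$ref_chrom == b$ref_chrom)
    left <- ctx %>% filter(.data$ref_end <= b$ref_start) %>%
      arrange(desc(.data$ref_end)) %>% utils::head(1)
    right <- ctx %>% filter(.data$ref_start >= b$ref_end) %>%
      arrange(.data$ref_start) %>% utils::head(1)
    flanks <- bind_rows(left, right)
    if (nrow(flanks) > 0) {
      context_chrom <- names(sort(table(flanks$qry_chrom), decreasing = TRUE))[1]
      confidence <- "high"
    } else if (nrow(ctx) > 0) {
      context_chrom <- names(sort(table(ctx$qry_chrom), decreasing = TRUE))[1]
      confidence <- "low"
    } else {
      context_chrom <- b$ref_chrom
      confidence <- "low"
    }
    kind <- if (b$qry_chrom != context_chrom) "inter_translocation"
      else if (b$orientation == "reverse") "inversion"
      else "intra_translocation"
    tibble(kind = kind, ref_chrom = b$ref_chrom, ref_start = b$ref_start,
           ref_end = b$ref_end, qry_chrom = b$qry_chrom,
           qry_start = b$qry_start, qry_end = b$qry_end,
           total_length = b$ref_end - b$ref_start, n_blocks = 1L,
           confidence = confidence)
  })
  bind_rows(rows) %>% arrange(.data$ref_chrom, .data$ref_start)
}

#' Merge neighbouring rearranged regions of the same kind
#'
#' Same-kind regions on the same chromosome pair whose reference and query
#' gaps are both at most `join_gap` are unioned into one rearranged region.
#' Counts are monotonically non-increasing in `join_gap`.
#'
#' @param regions tibble from [classify_rearrangements()], sorted by
#'   reference coordinate.
#' @param join_gap largest bridged gap, bp (default 50 kb).
#' @return merged region tibble; `total_length` is the summed member
#'   reference length, `n_blocks` the member count.
#' @export
merge_rearranged <- function(regions, join_gap = 5e4) {
  if (nrow(regions) <= 1) return(regions)
  regions <- regions %>% arrange(.data$kind, .data$ref_chrom, .data$qry_chrom,
                                 .data$ref_start)
  out <- list(); cur <- regions[1, ]
  for (i in seq(2, nrow(regions))) {
    b <- regions[i, ]
    same <- b$kind == cur$kind && b$ref_chrom == cur$ref_chrom &&
      b$qry_chrom == cur$qry_chrom
    rgap <- b$ref_start - cur$ref_end
    qgap <- max(b$qry_start, cur$qry_start) - min(b$qry_end, cur$qry_end)
    if (same && rgap <= join_gap && qgap <= join_gap) {
      cur$ref_end <- max(cur$ref_end, b$ref_end)
      cur$ref_start <- min(cur$ref_start, b$ref_start)
      cur$qry_start <- min(cur$qry_start, b$qry_start)
      cur$qry_end <- max(cur$qry_end, b$qry_end)
      cur$total_length <- cur$total_length + b$total_length
      cur$n_blocks <- cur$n_blocks + b$n_blocks
      cur$confidence <- if (cur$confidence == "high" && b$confidence == "high")
        "high" else "low"
    } else {
      out[[length(out) + 1]] <- cur
      cur <- b
    }
  }
  out[[length(out) + 1]] <- cur
  bind_rows(out) %>% arrange(.data$ref_chrom, .data$ref_start)
}

#' Call SNPs and small indels from base-aligned allelic blocks
#'
#' SNPs and short indels are read from the alignment columns of each
#' allelic block.  SNPs and single-base indels are retained only when their
#' distance to the nearest other variant and to the block edge is at least
#' `buffer_min` (the buffering semantics of whole-genome-aligner SNP
#' output).  Indels of 2-100 bp are additionally emitted from the length
#' difference of the inter-block gap between mutually consistent adjacent
#' allelic blocks; longer events are left to presence-absence calling.
#'
#' @param allelic_blocks base-aligned allelic block tibble.
#' @param buffer_min minimum distance in bp (default 20).
#' @param ref_genome,qry_genome optional `genome_set`s used to fill indel
#'   alleles for inter-block gap events (otherwise `N`s).
#' @return variant tibble: `kind`, `ref_chrom`, `ref_pos`, `ref_allele`,
#'   `alt_allele`, `length`, `buffer_distance`, sorted and VCF-writable via
#'   [write_vcf()].
#' @export
call_variants <- function(allelic_blocks, buffer_min = 20,
                          ref_genome = NULL, qry_genome = NULL) {
  if (nrow(allelic_blocks) == 0)
    return(tibble(kind = character(), ref_chrom = character(),
                  ref_pos = double(), ref_allele = character(),
                  alt_allele = character(), length = double(),
                  buffer_distance = double()))
  if (anyNA(allelic_blocks$ref_aln)) {
    bad <- which(is.na(allelic_blocks$ref_aln))[1]
    abort(paste0("block ", allelic_blocks$ref_chrom[bad], ":",
                 allelic_blocks$ref_start[bad], "-",
                 allelic_blocks$ref_end[bad], " has no base alignment"))
  }
  col_vars <- purrr::map(seq_len(nrow(allelic_blocks)), function(i) {
    b <- allelic_blocks[i, ]
    v <- cpp_alignment_variants(b$ref_aln, b$qry_aln, b$ref_start)
    if (nrow(v) == 0) return(NULL)
    as_tibble(v) %>%
      mutate(ref_chrom = b$ref_chrom,
             length = pmax(nchar(.data$ref_allele), nchar(.data$alt_allele)),
             edge_dist = pmin(.data$ref_pos - b$ref_start,
                              b$ref_end - .data$ref_pos))
  })
  v <- bind_rows(col_vars)
  gap_vars <- inter_block_gap_indels(allelic_blocks, ref_genome, qry_genome)
  if (nrow(v) == 0 && nrow(gap_vars) == 0)
    return(tibble(kind = character(), ref_chrom = character(),
                  ref_pos = double(), ref_allele = character(),
                  alt_allele = character(), length = double(),
                  buffer_distance = double()))
  if (nrow(v) > 0) {
    v <- v %>% arrange(.data$ref_chrom, .data$ref_pos) %>%
      group_by(.data$ref_chrom) %>%
      mutate(nn = pmin(c(Inf, diff(.data$ref_pos)),
                       c(diff(.data$ref_pos), Inf))) %>%
      ungroup() %>%
      mutate(buffer_distance = pmin(.data$nn, .data$edge_dist)) %>%
      select(-"nn", -"edge_dist", -"column")
    small <- v$kind == "snp" | v$length == 1
    v <- v %>%
      filter(!small | .data$buffer_distance >= buffer_min) %>%
      filter(.data$length <= 100)
  }
  out <- bind_rows(v, gap_vars) %>%
    arrange(.data$ref_chrom, .data$ref_pos) %>%
    select("kind", "ref_chrom", "ref_pos", "ref_allele", "alt_allele",
           "length", "buffer_distance")
  out
}

# 2-100 bp indels implied by gap-length differences between mutually
# consistent adjacent allelic blocks (the GAP class of unaligned regions).
inter_block_gap_indels <- function(blocks, ref_genome, qry_genome) {
  empty <- tibble(kind = character(), ref_chrom = character(),
                  ref_pos = double(), ref_allele = character(),
                  alt_allele = character(), length = double(),
                  buffer_distance = double())
  if (nrow(blocks) < 2) return(empty)
  rows <- list()
  for (rc in unique(blocks$ref_chrom)) {
    b <- blocks %>%
      filter(.data$ref_chrom == rc, .data$orientation == "forward") %>%
      arrange(.data$ref_start)
    if (nrow(b) < 2) next
    for (i in seq_len(nrow(b) - 1)) {
      l <- b[i, ]; r <- b[i + 1, ]
      if (l$qry_chrom != r$qry_chrom) next
      rgap <- r$ref_start - l$ref_end
      qgap <- r$qry_start - l$qry_end
      if (rgap < 0 || qgap < 0) next # not mutually consistent
      d <- qgap - rgap
      if (abs(d) < 2 || abs(d) > 100) next
      if (d > 0) { # insertion in query
        alt <- if (!is.null(qry_genome))
          genome_slice(qry_genome, l$qry_chrom, l$qry_end + rgap,
                       l$qry_end + qgap)
          else strrep("N", d)
        rows[[length(rows) + 1]] <- tibble(
          kind = "insertion", ref_chrom = rc, ref_pos = r$ref_start,
          ref_allele = "", alt_allele = alt, length = d,
          buffer_distance = NA_real_)
      } else { # deletion from reference
        ref_al <- if (!is.null(ref_genome))
          genome_slice(ref_genome, rc, l$ref_end + qgap, r$ref_start)
          else strrep("N", -d)
        rows[[length(rows) + 1]] <- tibble(
          kind = "deletion", ref_chrom = rc, ref_pos = l$ref_end + qgap,
          ref_allele = ref_al, alt_allele = "", length = -d,
          buffer_distance = NA_real_)
      }
    }
  }
  if (length(rows) == 0) empty else bind_rows(rows)
}

#' Per-genome rearrangement summary
#'
#' @param regions merged region tibble.
#' @return tibble with one row per kind: count and total Mb.
#' @export
summarise_rearrangements <- function(regions) {
  regions %>% group_by(.data$kind) %>%
    summarise(n = dplyr::n(), total_mb = sum(.data$total_length) / 1e6,
              .groups = "drop")
}
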