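# Presence-absence variation: unaligned-region categorisation, the
# coverage/identity rejection filter against the counterpart genome, and
# PAV-gene assignment.

#' Categorise unaligned regions of the carrier genome
#'
#' The complement of the aligned (one-to-one) spans on each carrier
#' chromosome is labelled from its flanking blocks, specific before
#' generic: GAP (between two mutually consistent allelic blocks), INV /
#' SEQ / JMP (a flank is a rearranged block - inverted, inter-chromosomal,
#' or intra-chromosomal respectively), DUP (the flanking reference
#' interval re-uses already-aligned sequence), BRK otherwise.  Regions of
#' at most 100 bp are dropped (below the presence-absence length floor).
#'
#' @param partition result of [partition_allelic()] for the
#'   carrier-vs-counterpart comparison, with the carrier as the query
#'   genome.
#' @param carrier the carrier `genome_set` (the genome whose unaligned
#'   sequence is a candidate presence region).
#' @return tibble of unfiltered regions: `carrier`, `chromosome`, `start`,
#'   `end`, `category`, `counterpart_coverage`, `counterpart_identity`,
#'   `retained` (the last three `NA` until [filter_pav()]).
#' @export
categorize_unaligned <- function(partition, carrier) {
  blocks <- bind_rows(partition$allelic, partition$nonallelic)
  rearr <- classify_rearrangements(partition)
  lens <- genome_lengths(carrier)
  allelic_ids <- seq_len(nrow(partition$allelic))
  rows <- list()
  for (ch in names(lens)) {
    b <- blocks %>% filter(.data$qry_chrom == ch) %>% arrange(.data$qry_start)
    cov <- IRanges::reduce(iranges_of(b$qry_start, b$qry_end))
    gaps <- IRanges::gaps(cov, start = 1L, end = lens[[ch]])
    if (length(gaps) == 0) next
    g_start <- IRanges::start(gaps) - 1
    g_end <- IRanges::end(gaps)
    for (j in seq_along(g_start)) {
      s <- g_start[j]; e <- g_end[j]
      if (e - s <= 100) next
      left <- b %>% filter(.data$qry_end <= s) %>%
        arrange(desc(.data$qry_end)) %>% utils::head(1)
      right <- b %>% filter(.data$qry_start >= e) %>%
        arrange(.data$qry_start) %>% utils::head(1)
      cat <- flank_category(left, right, partition, rearr)
      rows[[length(rows) + 1]] <- tibble(
        carrier = attr(carrier, "assembly_id"), chromosome = ch,
        start = s, end = e, category = cat,
        counterpart_coverage = NA_real_, counterpart_identity = NA_real_,
        retained = NA)
    }
  }
  if (length(rows) == 0)
    return(tibble(carrier = character(), chromosome = character(),
                  start = double(), end = double(), category = character(),
                  counterpart_coverage = double(),
                  counterpart_identity = double(), retained = logical()))
  bind_rows(rows)
}

# Category decision for one unaligned region from its flanking blocks.
flank_category <- function(left, right, partition, rearr) {
  is_allelic <- function(bl) {
    if (nrow(bl) == 0) return(FALSE)
    any(partition$allelic$ref_chrom == bl$ref_chrom &
          partition$allelic$ref_start == bl$ref_start &
          partition$allelic$qry_start == bl$qry_start)
  }
  rearr_kind <- function(bl) {
    if (nrow(bl) == 0) return(NA_character_)
    hit <- rearr %>% filter(.data$ref_chrom == bl$ref_chrom,
                            .data$ref_start == bl$ref_start,
                            .data$qry_start == bl$qry_start)
    if (nrow(hit) == 0) NA_character_ else hit$kind[1]
  }
  la <- is_allelic(left); ra <- is_allelic(right)
  # GAP: two mutually consistent allelic flanks (a few bp of junction
  # jitter from maximal anchor extension is tolerated)
  if (la && ra && left$ref_chrom == right$ref_chrom &&
      left$ref_end <= right$ref_start + 25) return("GAP")
  kinds <- c(rearr_kind(left), rearr_kind(right))
  if ("inversion" %in% kinds) return("INV")
  if ("inter_translocation" %in% kinds) return("SEQ")
  if ("intra_translocation" %in% kinds) return("JMP")
  # DUP: allelic flanks whose reference intervals overlap (re-used sequence)
  if (la && ra && left$ref_chrom == right$ref_chrom &&
      left$ref_end > right$ref_start + 25) return("DUP")
  "BRK"
}

#' Reject presence regions that match the counterpart genome
#'
#' Each region's sequence is aligned to the counterpart genome (exact-match
#' seeding and chaining); a region whose best alignment has coverage above
#' `min_cov` and identity above `min_ident` also exists there and is marked
#' `retained = FALSE`; all other regions are unique presence regions
#' (`retained = TRUE`).  All-N regions are dropped as unresolvable
#' (`retained = FALSE`, category flagged).
#'
#' @param regions tibble from [categorize_unaligned()].
#' @param carrier carrier `genome_set` (source of region sequence).
#' @param counterpart counterpart `genome_set`.
#' @param min_cov,min_ident rejection thresholds (defaults 0.5 / 0.9: a
#'   region is non-unique only when coverage > 50 percent and identity >
#'   90 percent).
#' @return `regions` with `counterpart_coverage`, `counterpart_identity`
#'   and `retained` filled.
#' @export
filter_pav <- function(regions, carrier, counterpart,
                       min_cov = 0.5, min_ident = 0.9) {
  if (nrow(regions) == 0) return(regions)
  for (i in seq_len(nrow(regions))) {
    seq <- genome_slice(carrier, regions$chromosome[i], regions$start[i],
                        regions$end[i])
    if (grepl("^N+$", seq)) {
      regions$counterpart_coverage[i] <- NA_real_
      regions$counterpart_identity[i] <- NA_real_
      regions$retained[i] <- FALSE
      regions$category[i] <- paste0(regions$category[i], ";all_N")
      next
    }
    hit <- align_region_to_genome(seq, counterpart)
    regions$counterpart_coverage[i] <- hit["coverage"]
    regions$counterpart_identity[i] <- hit["identity"]
    regions$retained[i] <- !(hit["coverage"] > min_cov &&
                               hit["identity"] > min_ident)
  }
  regions
}

#' Genes residing in retained presence-absence regions
#'
#' A gene is a PAV gene when at least `min_cds_frac` of its CDS length lies
#' within retained presence regions of its carrier genome.
#'
#' @param pavs filtered region tibble ([filter_pav()]).
#' @param genes gene-model tibble on carrier coordinates
#'   ([read_gene_models()]).
#' @param min_cds_frac CDS-overlap threshold (default 0.8).
#' @return character vector of gene ids.
#' @export
pav_genes <- function(pavs, genes, min_cds_frac = 0.8) {
  kept <- pavs %>% filter(.data$retained)
  if (nrow(kept) == 0 || nrow(genes) == 0) return(character(0))
  hits <- vapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    cds <- g$cds[[1]]
    p <- kept %>% filter(.data$chromosome == g$chromosome)
    if (nrow(p) == 0) return(0)
    total <- sum(cds[, "end"] - cds[, "start"])
    cov <- sum(vapply(seq_len(nrow(cds)), function(j)
      covered_fraction(cds[j, "start"], cds[j, "end"], p$start, p$end) *
        (cds[j, "end"] - cds[j, "start"]), 0))
    cov / total
  }, 0)
  genes$gene_id[hits >= min_cds_frac]
}

#' Per-chromosome presence-absence summary
#' @param pavs filtered region tibble.
#' @return tibble: chromosome, category, n, total bp (retained regions).
#' @export
summarise_pavs <- function(pavs) {
  pavs %>% filter(.data$retained) %>%
    group_by(.data$chromosome, .data$category) %>%
    summarise(n = dplyr::n(), total_bp = sum(.data$end - .data$start),
              .groups = "drop")
}
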