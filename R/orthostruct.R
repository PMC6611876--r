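# Classification of orthologous gene pairs into a structural-variation
# taxonomy: structurally conserved, large-effect mutation, or large
# structural variation, from a base-level alignment of the genic region
# (gene body plus 2-kb flanks) and a comparison of the two gene models.
# Ortholog pairing itself is supplied by the caller (or by the simulator);
# orthology inference is not re-implemented here.

# Extract a gene's genic region plus flanks in forward gene orientation.
# Returns local 0-based coordinates of exons/cds on the extracted sequence.
gene_context <- function(gene, genome, flank = 2000) {
  ex <- gene$exons[[1]]; cd <- gene$cds[[1]]
  chrom_len <- genome_lengths(genome)[[gene$chromosome]]
  g_start <- min(ex[, "start"]); g_end <- max(ex[, "end"])
  up <- min(flank, g_start); down <- min(flank, chrom_len - g_end)
  truncated <- up < flank || down < flank
  seq <- genome_slice(genome, gene$chromosome, g_start - up, g_end + down)
  loc <- function(m) cbind(start = m[, "start"] - (g_start - up),
                           end = m[, "end"] - (g_start - up))
  ex_l <- loc(ex); cd_l <- loc(cd)
  if (gene$strand == "-") {
    n <- nchar(seq)
    seq <- cpp_revcomp(seq)
    flip <- function(m) {
      out <- cbind(start = n - m[, "end"], end = n - m[, "start"])
      out[order(out[, "start"]), , drop = FALSE]
    }
    ex_l <- flip(ex_l); cd_l <- flip(cd_l)
    tmp <- up; up <- down; down <- tmp
  }
  list(seq = seq, exons = ex_l, cds = cd_l, flank_up = up, flank_down = down,
       gene_start = up, gene_end = nchar(seq) - down, truncated = truncated)
}

cds_sequence <- function(ctx) {
  paste(substring(ctx$seq, ctx$cds[, "start"] + 1, ctx$cds[, "end"]),
        collapse = "")
}

translate_dna <- function(dna) {
  n <- nchar(dna) - nchar(dna) %% 3
  if (n < 3) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(substr(dna, 1, n)),
                                     if.fuzzy.codon = "X"))
}

#' Align an orthologous gene pair over its genic region
#'
#' Globally aligns the genic region of gene A (gene body plus up to `flank`
#' bp of both flanks) to that of gene B, in forward gene orientation, and
#' assigns each variant to a sub-region of gene A: upstream or downstream
#' flank, CDS exon, UTR exon, or intron.
#'
#' @param gene_a,gene_b one-row gene-model tibbles ([read_gene_models()]).
#' @param genome_a,genome_b the corresponding `genome_set`s.
#' @param flank flank width in bp (default 2000).
#' @return list with `variants` (tibble: kind, pos \[A-local\], ref_allele,
#'   alt_allele, region), `ctx_a`/`ctx_b` (local gene contexts), `a2b`
#'   (A-position to B-position map, `NA` where A is deleted in B) and
#'   `flags` (`truncated_flank`, `unalignable`).
#' @export
align_gene_pair <- function(gene_a, genome_a, gene_b, genome_b, flank = 2000) {
  ctx_a <- gene_context(gene_a, genome_a, flank)
  ctx_b <- gene_context(gene_b, genome_b, flank)
  flags <- character(0)
  if (ctx_a$truncated || ctx_b$truncated) flags <- c(flags, "truncated_flank")
  cds_a <- cds_sequence(ctx_a)
  if (nchar(cds_a) < 3 || substr(cds_a, 1, 3) != "ATG")
    return(list(variants = NULL, ctx_a = ctx_a, ctx_b = ctx_b, a2b = NULL,
                flags = c(flags, "unalignable")))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(ctx_a$seq), Biostrings::DNAString(ctx_b$seq),
    type = "global", gapOpening = 6, gapExtension = 1)
  pa <- as.character(Biostrings::alignedPattern(aln))
  sa <- as.character(Biostrings::alignedSubject(aln))
  v <- as_tibble(cpp_alignment_variants(pa, sa, 0))
  # A-position -> B-position map
  cols_a <- strsplit(pa, "")[[1]] != "-"
  cols_b <- strsplit(sa, "")[[1]] != "-"
  bpos <- cumsum(cols_b) - 1
  a2b <- ifelse(cols_b[cols_a], bpos[cols_a], NA_real_)
  region_of <- function(pos) {
    vapply(pos, function(p) {
      if (p < ctx_a$gene_start) return("upstream")
      if (p >= ctx_a$gene_end) return("downstream")
      in_cds <- any(p >= ctx_a$cds[, "start"] & p < ctx_a$cds[, "end"])
      if (in_cds) return("exon_cds")
      in_ex <- any(p >= ctx_a$exons[, "start"] & p < ctx_a$exons[, "end"])
      if (in_ex) return("utr")
      "intron"
    }, character(1))
  }
  if (nrow(v) > 0) {
    v <- v %>% select(-"column") %>%
      dplyr::rename(pos = "ref_pos") %>%
      mutate(region = region_of(.data$pos))
  } else {
    v <- tibble(kind = character(), pos = double(), ref_allele = character(),
                alt_allele = character(), region = character())
  }
  list(variants = v, ctx_a = ctx_a, ctx_b = ctx_b, a2b = a2b, flags = flags)
}

#' Annotate gene-pair effects
#'
#' Computes the effect-label set for one aligned orthologous pair by
#' translating both CDS and inspecting the gene models: synonymous and
#' missense substitutions, in-frame and frameshift CDS indels, start- and
#' stop-codon changes (premature gain or terminal loss, one label with a
#' sub-flag), splice-donor/acceptor dinucleotide changes (canonical GT/AG
#' only; non-canonical reference introns are flagged, not classified),
#' unequal exon counts, and whole CDS segments absent from the counterpart
#' alignment.
#'
#' @param pair result of [align_gene_pair()].
#' @return character vector of effect labels (empty set means no genic
#'   variation), with attribute `flags`.
#' @export
annotate_effects <- function(pair) {
  if ("unalignable" %in% pair$flags)
    return(structure(character(0), flags = pair$flags))
  v <- pair$variants
  eff <- character(0)
  flags <- pair$flags
  ctx_a <- pair$ctx_a; ctx_b <- pair$ctx_b
  if (nrow(v) == 0) eff <- c(eff, "no_genic_variation")
  if (!any(v$region %in% c("exon_cds", "intron", "utr")))
    eff <- c(eff, "no_cds_intron_variation")
  if (!any(v$region == "exon_cds")) eff <- c(eff, "no_cds_variation")

  cds_a <- cds_sequence(ctx_a); cds_b <- cds_sequence(ctx_b)
  prot_a <- translate_dna(cds_a); prot_b <- translate_dna(cds_b)
  if (grepl("\\*", substr(prot_a, 1, nchar(prot_a) - 1)))
    return(structure(character(0), flags = c(flags, "internal_stop_in_reference")))

  cds_vars <- v %>% filter(.data$region == "exon_cds")
  indels <- cds_vars %>% filter(.data$kind != "snp")
  if (nrow(indels) > 0) {
    lens <- nchar(indels$ref_allele) + nchar(indels$alt_allele)
    eff <- c(eff, ifelse(lens %% 3 == 0, "inframe_indel", "frameshift_indel"))
    eff <- unique(eff)
  }
  if (substr(cds_b, 1, 3) != "ATG") eff <- c(eff, "start_codon")
  # stop codon: premature stop in B, or terminal stop lost
  body_b <- substr(prot_b, 1, max(nchar(prot_b) - 1, 0))
  premature <- grepl("\\*", body_b)
  term_a <- substr(prot_a, nchar(prot_a), nchar(prot_a)) == "*"
  term_b <- substr(prot_b, nchar(prot_b), nchar(prot_b)) == "*"
  if (premature || (term_a && !term_b)) {
    eff <- c(eff, "stop_codon")
    flags <- c(flags, if (premature) "premature_stop" else "stop_lost")
  }
  # protein comparison when no structural upheaval
  if (nchar(prot_a) == nchar(prot_b)) {
    if (prot_a != prot_b && !premature) eff <- c(eff, "missense")
    if (prot_a == prot_b && cds_a != cds_b) eff <- c(eff, "same_sense")
  }
  # splice sites: canonical GT/AG of each reference intron vs counterpart
  introns_of <- function(ctx) {
    ex <- ctx$exons
    if (nrow(ex) < 2) return(NULL)
    cbind(start = ex[-nrow(ex), "end"], end = ex[-1, "start"])
  }
  in_a <- introns_of(ctx_a); in_b <- introns_of(ctx_b)
  if (!is.null(in_a) && !is.null(in_b) && nrow(in_a) == nrow(in_b)) {
    for (i in seq_len(nrow(in_a))) {
      don_a <- substr(ctx_a$seq, in_a[i, "start"] + 1, in_a[i, "start"] + 2)
      acc_a <- substr(ctx_a$seq, in_a[i, "end"] - 1, in_a[i, "end"])
      don_b <- substr(ctx_b$seq, in_b[i, "start"] + 1, in_b[i, "start"] + 2)
      acc_b <- substr(ctx_b$seq, in_b[i, "end"] - 1, in_b[i, "end"])
      if (don_a != "GT" || acc_a != "AG") {
        flags <- c(flags, "noncanonical_intron")
        next
      }
      if (don_b != "GT") eff <- c(eff, "splice_donor")
      if (acc_b != "AG") eff <- c(eff, "splice_acceptor")
    }
  }
  if (nrow(ctx_a$exons) != nrow(ctx_b$exons)) eff <- c(eff, "exon_count_change")
  # CDS segment entirely absent from the counterpart alignment
  if (!is.null(pair$a2b)) {
    for (i in seq_len(nrow(ctx_a$cds))) {
      idx <- seq(ctx_a$cds[i, "start"] + 1, ctx_a$cds[i, "end"])
      if (mean(is.na(pair$a2b[idx])) >= 0.8) {
        eff <- c(eff, "cds_missing")
        break
      }
    }
  }
  structure(unique(eff), flags = unique(flags))
}

#' Classify a pair from its effect labels
#'
#' Precedence: large structural variation (exon-count change or missing
#' CDS) over large-effect mutation (frameshift, start/stop codon, splice
#' site) over structurally conserved.
#'
#' @param effects character vector from [annotate_effects()].
#' @return one of `"large_structural_variation"`, `"large_effect"`,
#'   `"structurally_conserved"`.
#' @export
classify_pair <- function(effects) {
  if (any(effects %in% c("exon_count_change", "cds_missing")))
    return("large_structural_variation")
  if (any(effects %in% c("frameshift_indel", "start_codon", "stop_codon",
                         "splice_donor", "splice_acceptor")))
    return("large_effect")
  "structurally_conserved"
}

#' Call one orthologous gene pair
#'
#' @inheritParams align_gene_pair
#' @param syntenic logical: does the pair sit in a syntenic block.
#' @param subgenome subgenome tag (e.g. `"At"`, `"Dt"`).
#' @return one-row tibble: gene ids, syntenic, subgenome, `effects`
#'   (list-column), `category`, `flags`.
#' @export
call_ortho_pair <- function(gene_a, genome_a, gene_b, genome_b,
                            flank = 2000, syntenic = TRUE, subgenome = "At") {
  pair <- align_gene_pair(gene_a, genome_a, gene_b, genome_b, flank)
  eff <- annotate_effects(pair)
  excluded <- any(attr(eff, "flags") %in%
                    c("unalignable", "internal_stop_in_reference"))
  tibble(gene_a = gene_a$gene_id, gene_b = gene_b$gene_id,
         syntenic = syntenic, subgenome = subgenome,
         effects = list(as.character(eff)),
         category = if (excluded) NA_character_ else classify_pair(eff),
         flags = list(as.character(attr(eff, "flags"))))
}

#' Percentage as printed in the pair-taxonomy report
#'
#' @param count,total integers.
#' @return `100 * count / total` rounded to two decimals.
#' @export
ortho_percent <- function(count, total) round(100 * count / total, 2)

#' Tabulate ortholog calls into the nested taxonomy report
#'
#' Counts and column percentages (two decimals) per syntenic status and
#' subgenome, with the nested rows of the pair taxonomy: conserved pairs
#' split into those without/with amino-acid changes (and their sub-rows),
#' large-effect rows per label, and large-structural rows.  A flat
#' one-row-per-effect view is included alongside the nested one, since
#' effect labels can co-occur.
#'
#' @param calls tibble of [call_ortho_pair()] rows.
#' @return tibble: `syntenic`, `subgenome`, `row`, `nested_under`, `n`,
#'   `percent`.
#' @export
tabulate_ortho <- function(calls) {
  calls <- calls %>% filter(!is.na(.data$category))
  if (nrow(calls) == 0)
    return(tibble(syntenic = logical(), subgenome = character(),
                  row = character(), nested_under = character(),
                  n = integer(), percent = double()))
  has <- function(d, lab) vapply(d$effects, function(e) lab %in% e, logical(1))
  calls %>% group_by(.data$syntenic, .data$subgenome) %>%
    dplyr::group_modify(function(d, key) {
      total <- nrow(d)
      cons <- d %>% filter(.data$category == "structurally_conserved")
      no_aa <- cons %>% filter(!has(., "missense"), !has(., "inframe_indel"))
      with_aa <- cons %>% filter(has(., "missense") | has(., "inframe_indel"))
      le <- d %>% filter(.data$category == "large_effect")
      lsv <- d %>% filter(.data$category == "large_structural_variation")
      row <- function(name, under, n)
        tibble(row = name, nested_under = under, n = as.integer(n),
               percent = ortho_percent(n, total))
      bind_rows(
        row("structurally_conserved", NA, nrow(cons)),
        row("without_aa_substitution", "structurally_conserved", nrow(no_aa)),
        row("no_cds_variation", "without_aa_substitution",
            sum(has(no_aa, "no_cds_variation"))),
        row("no_cds_intron_variation", "without_aa_substitution",
            sum(has(no_aa, "no_cds_intron_variation"))),
        row("no_genic_variation", "without_aa_substitution",
            sum(has(no_aa, "no_genic_variation"))),
        row("same_sense", "without_aa_substitution", sum(has(no_aa, "same_sense"))),
        row("with_aa_change", "structurally_conserved", nrow(with_aa)),
        row("missense", "with_aa_change", sum(has(with_aa, "missense"))),
        row("inframe_indel", "with_aa_change", sum(has(with_aa, "inframe_indel"))),
        row("large_effect", NA, nrow(le)),
        row("frameshift_indel", "large_effect", sum(has(le, "frameshift_indel"))),
        row("start_codon", "large_effect", sum(has(le, "start_codon"))),
        row("stop_codon", "large_effect", sum(has(le, "stop_codon"))),
        row("splice_acceptor", "large_effect", sum(has(le, "splice_acceptor"))),
        row("splice_donor", "large_effect", sum(has(le, "splice_donor"))),
        row("large_structural_variation", NA, nrow(lsv)),
        row("cds_missing", "large_structural_variation", sum(has(lsv, "cds_missing"))),
        row("total", NA, total))
    }) %>% ungroup()
}

# ---- synthetic gene pairs -------------------------------------------------

#' Simulate an orthologous gene pair with a requested effect
#'
#' Builds a random multi-exon gene (ATG start, TAA stop, canonical GT/AG
#' introns, stop-free frame) on a small chromosome, then derives the
#' counterpart by applying one requested lesion.  Used to validate effect
#' annotation against brute-force translation oracles.
#'
#' @param effect one of `"none"`, `"upstream_snp"`, `"intron_snp"`,
#'   `"same_sense"`, `"missense"`, `"inframe_indel"`, `"frameshift_indel"`,
#'   `"start_codon"`, `"stop_codon"`, `"splice_donor"`,
#'   `"splice_acceptor"`, `"cds_missing"`, `"exon_count_change"`.
#' @param n_exons,exon_codons,intron_len gene geometry.
#' @param flank_len flanking sequence on the chromosome, bp.
#' @param seed integer seed.
#' @return list: `gene_a`, `genome_a`, `gene_b`, `genome_b`.
#' @export
simulate_gene_pair <- function(effect = "none", n_exons = 3, exon_codons = 40,
                               intron_len = 120, flank_len = 500, seed = 1) {
  with_substream(seed, paste0("gene_pair_", effect), {
    codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                c("A", "C", "G", "T")), 1, paste, collapse = "")
    safe <- setdiff(codons, c("TAA", "TAG", "TGA", "ATG"))
    exon_seqs <- lapply(seq_len(n_exons), function(i)
      paste(sample(safe, exon_codons, TRUE), collapse = ""))
    exon_seqs[[1]] <- paste0("ATG", substr(exon_seqs[[1]], 4,
                                           nchar(exon_seqs[[1]])))
    last <- exon_seqs[[n_exons]]
    exon_seqs[[n_exons]] <- paste0(substr(last, 1, nchar(last) - 3), "TAA")
    intron_seq <- function() paste0(
      "GT", gsub("(AG)", "AC", random_dna(intron_len - 4, 0.35)), "AG")
    introns <- replicate(n_exons - 1, intron_seq())
    up <- random_dna(flank_len, 0.35); down <- random_dna(flank_len, 0.35)
    body <- character(0)
    exon_iv <- matrix(0, n_exons, 2, dimnames = list(NULL, c("start", "end")))
    pos <- flank_len
    for (i in seq_len(n_exons)) {
      exon_iv[i, ] <- c(pos, pos + nchar(exon_seqs[[i]]))
      body <- c(body, exon_seqs[[i]])
      pos <- pos + nchar(exon_seqs[[i]])
      if (i < n_exons) {
        body <- c(body, introns[i])
        pos <- pos + nchar(introns[i])
      }
    }
    chrom <- paste0(up, paste(body, collapse = ""), down)
    gene <- tibble(gene_id = "gA", chromosome = "c1", strand = "+",
                   exons = list(exon_iv), cds = list(exon_iv))
    genome_a <- genome_set(c(c1 = chrom), "A")

    # lesion on the counterpart
    seq_b <- chrom
    exon_b <- exon_iv
    edit_at <- function(seq, pos, old_len, new) # 0-based splice
      paste0(substr(seq, 1, pos), new, substr(seq, pos + old_len + 1, nchar(seq)))
    shift_after <- function(iv, pos, delta) {
      iv[, "start"] <- iv[, "start"] + ifelse(iv[, "start"] > pos, delta, 0)
      iv[, "end"] <- iv[, "end"] + ifelse(iv[, "end"] > pos, delta, 0)
      iv
    }
    mid <- exon_iv[n_exons, "start"] + 3 * floor(exon_codons / 2) # codon start
    if (effect == "upstream_snp") {
      p <- flank_len - 200
      old <- substr(seq_b, p + 1, p + 1)
      seq_b <- edit_at(seq_b, p, 1, setdiff(c("A", "C", "G", "T"), old)[1])
    } else if (effect == "intron_snp") {
      p <- exon_iv[1, "end"] + 50
      old <- substr(seq_b, p + 1, p + 1)
      seq_b <- edit_at(seq_b, p, 1, setdiff(c("A", "C", "G", "T"), old)[1])
    } else if (effect == "same_sense") {
      seq_b <- edit_at(seq_b, mid, 3, "CTA") # plant Leu codon
      chrom <- edit_at(chrom, mid, 3, "CTG") # synonymous in A
      genome_a <- genome_set(c(c1 = chrom), "A")
    } else if (effect == "missense") {
      seq_b <- edit_at(seq_b, mid, 3, "GAT") # Asp
      chrom <- edit_at(chrom, mid, 3, "GCT") # Ala in A
      genome_a <- genome_set(c(c1 = chrom), "A")
    } else if (effect == "inframe_indel") {
      seq_b <- edit_at(seq_b, mid, 3, "")
      exon_b <- shift_after(exon_b, mid, -3)
    } else if (effect == "frameshift_indel") {
      seq_b <- edit_at(seq_b, mid, 0, "ACGT")
      exon_b <- shift_after(exon_b, mid, 4)
    } else if (effect == "start_codon") {
      p <- exon_iv[1, "start"]
      seq_b <- edit_at(seq_b, p + 2, 1, "A") # ATG -> ATA
    } else if (effect == "stop_codon") {
      p <- exon_iv[n_exons, "end"] - 3
      seq_b <- edit_at(seq_b, p, 1, "C") # TAA -> CAA (stop lost)
    } else if (effect == "splice_donor") {
      p <- exon_iv[1, "end"]
      seq_b <- edit_at(seq_b, p + 1, 1, "C") # GT -> GC
    } else if (effect == "splice_acceptor") {
      p <- exon_iv[2, "start"] - 1
      seq_b <- edit_at(seq_b, p, 1, "A") # AG -> AA
    } else if (effect == "cds_missing") {
      s <- exon_iv[2, "start"]; e <- exon_iv[2, "end"]
      seq_b <- edit_at(seq_b, s, e - s, "")
      exon_b <- shift_after(exon_b, s, -(e - s))[-2, , drop = FALSE]
    } else if (effect == "exon_count_change") {
      # annotate an internal cut of exon 2 as an intron (sequence unchanged)
      cut <- exon_iv[2, "start"] + 3 * 10
      exon_b <- rbind(exon_b[1, , drop = FALSE],
                      c(exon_b[2, "start"], cut), c(cut + 30, exon_b[2, "end"]),
                      exon_b[-c(1, 2), , drop = FALSE])
      rownames(exon_b) <- NULL
      colnames(exon_b) <- c("start", "end")
    }
    gene_b <- tibble(gene_id = "gB", chromosome = "c1", strand = "+",
                     exons = list(exon_b), cds = list(exon_b))
    list(gene_a = gene, genome_a = genome_a, gene_b = gene_b,
         genome_b = genome_set(c(c1 = seq_b), "B"))
  })
}
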