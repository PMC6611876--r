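# Synthetic genomes, panels, mate pairs and genetic maps with known truth.
#
# Genome B is derived from genome A by (i) engineered structural events at
# requested coordinates, and (ii) background point mutations and small
# indels planted outside the engineered spans (plus a 100-bp margin) so that
# truth breakpoints stay exact and recoverable by direct string comparison.

#' Structural-event requests for the genome simulator
#'
#' @param chrom chromosome name (on genome A).
#' @param start,end 0-based half-open span on genome A.
#' @param dest_pos 0-based insertion point for translocations.
#' @param dest_chrom destination chromosome for inter-chromosomal moves.
#' @return a request list understood by [simulate_genome_pair()].
#' @export
sv_inversion <- function(chrom, start, end)
  list(kind = "inversion", chrom = chrom, start = start, end = end)

#' @rdname sv_inversion
#' @export
sv_intra_translocation <- function(chrom, start, end, dest_pos)
  list(kind = "intra_translocation", chrom = chrom, start = start, end = end,
       dest_chrom = chrom, dest_pos = dest_pos)

#' @rdname sv_inversion
#' @export
sv_inter_translocation <- function(chrom, start, end, dest_chrom, dest_pos)
  list(kind = "inter_translocation", chrom = chrom, start = start, end = end,
       dest_chrom = dest_chrom, dest_pos = dest_pos)

#' @rdname sv_inversion
#' @param carrier which genome uniquely carries the sequence: `"B"` plants a
#'   novel insertion into genome B at `start`; `"A"` deletes the span
#'   `[start, start + length)` of A from B, leaving it A-specific.
#' @param length inserted/deleted length in bp (> 100).
#' @export
pav_event <- function(carrier, chrom, start, length)
  list(kind = "pav", carrier = carrier, chrom = chrom, start = start,
       length = length)

# ---- piece-list machinery ------------------------------------------------

new_piece <- function(chrom, start, end, strand = "+", seq = NA_character_,
                      event = NA_character_) {
  list(chrom = chrom, start = start, end = end, strand = strand, seq = seq,
       event = event)
}

piece_len <- function(p) if (!is.na(p$seq)) nchar(p$seq) else p$end - p$start

# Split the untouched "+" piece containing A-coordinate `pos` (on chromosome
# `chrom`) at that point.  Positions inside engineered pieces are invalid.
split_pieces_at <- function(pieces, chrom, pos) {
  out <- list()
  for (p in pieces) {
    if (is.na(p$seq) && p$strand == "+" && is.na(p$event) &&
        p$chrom == chrom && pos > p$start && pos < p$end) {
      out <- c(out, list(new_piece(chrom, p$start, pos)),
               list(new_piece(chrom, pos, p$end)))
    } else out <- c(out, list(p))
  }
  out
}

# Remove pieces of the untouched span [s, e) on `chrom`; returns
# list(pieces = remaining, removed = removed pieces in order).
remove_span <- function(pieces, chrom, s, e) {
  pieces <- split_pieces_at(pieces, chrom, s)
  pieces <- split_pieces_at(pieces, chrom, e)
  keep <- list(); removed <- list()
  for (p in pieces) {
    inside <- is.na(p$seq) && p$chrom == chrom && is.na(p$event) &&
      p$start >= s && p$end <= e
    if (inside) removed <- c(removed, list(p)) else keep <- c(keep, list(p))
  }
  list(pieces = keep, removed = removed)
}

# Insert `newpieces` at A-coordinate `pos` on `chrom`.
insert_at <- function(pieces, chrom, pos, newpieces) {
  pieces <- split_pieces_at(pieces, chrom, pos)
  out <- list(); done <- FALSE
  for (p in pieces) {
    if (!done && is.na(p$seq) && p$chrom == chrom && is.na(p$event) &&
        p$start == pos) {
      out <- c(out, newpieces, list(p)); done <- TRUE
    } else out <- c(out, list(p))
  }
  if (!done) { # pos at chromosome end
    out <- c(out, newpieces)
  }
  out
}

# ---- edit planting -------------------------------------------------------

# Apply SNP/indel edits (tibble: pos [0-based, chromosome-local], kind,
# payload) to the substring [s, e) of sequence `seq`.
render_with_edits <- function(seq, s, e, edits) {
  if (nrow(edits) == 0) return(substr(seq, s + 1, e))
  edits <- edits %>% arrange(.data$pos)
  segs <- character(0)
  cur <- s
  for (i in seq_len(nrow(edits))) {
    p <- edits$pos[i]
    if (p > cur) segs <- c(segs, substr(seq, cur + 1, p))
    if (edits$kind[i] == "snp") {
      segs <- c(segs, edits$payload[i]); cur <- p + 1
    } else if (edits$kind[i] == "insertion") {
      segs <- c(segs, edits$payload[i]); cur <- p
    } else { # deletion of nchar(payload) bases
      cur <- p + nchar(edits$payload[i])
    }
  }
  if (cur < e) segs <- c(segs, substr(seq, cur + 1, e))
  paste(segs, collapse = "")
}

#' Simulate a diverged genome pair with engineered structural events
#'
#' Genome A is random DNA (35% GC, the ballpark of plant nuclear genomes);
#' genome B is A with the requested inversions (reverse-complemented in
#' place), intra-/inter-chromosomal translocations and presence-absence
#' events applied, then point mutations and 1-10 bp indels planted at the
#' given per-bp rates outside the engineered spans.  The returned truth set
#' records exact 0-based breakpoints on both genomes.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_len chromosome length in bp.
#' @param snp_rate,indel_rate per-bp background mutation rates (in
#'   \[0, 0.05\]).
#' @param sv_spec list of [sv_inversion()]/[sv_intra_translocation()]/
#'   [sv_inter_translocation()] requests.
#' @param pav_spec list of [pav_event()] requests.
#' @param seed integer seed; the same seed gives byte-identical output.
#' @return list with `genome_a`, `genome_b` ([genome_set()]s) and `truth`, a
#'   list of tibbles: `engineered_svs` (kind, ref span, qry span,
#'   orientation), `engineered_pavs` (carrier and spans on both genomes) and
#'   `planted_variants` (kind, ref_chrom, ref_pos, ref_allele, alt_allele).
#' @export
simulate_genome_pair <- function(n_chrom = 2, chrom_len = 5e6,
                                 snp_rate = 0.01, indel_rate = 5e-4,
                                 sv_spec = list(), pav_spec = list(),
                                 seed = 1) {
  stopifnot(snp_rate >= 0, snp_rate <= 0.05, indel_rate >= 0,
            indel_rate <= 0.05, chrom_len > 0, n_chrom >= 1)
  chroms <- paste0("chr", seq_len(n_chrom))

  a_seqs <- with_substream(seed, "genome_a", {
    setNames(lapply(chroms, function(ch) random_dna(chrom_len, gc = 0.35)),
             chroms)
  })

  # reserved zones (A coordinates) where no background mutation may fall
  reserved <- tibble(chromosome = character(), start = double(), end = double())
  add_zone <- function(chrom, s, e)
    reserved <<- bind_rows(reserved, tibble(chromosome = chrom, start = s, end = e))
  for (ev in sv_spec) {
    add_zone(ev$chrom, ev$start, ev$end)
    if (!is.null(ev$dest_pos)) add_zone(ev$dest_chrom, ev$dest_pos, ev$dest_pos + 1)
  }
  for (ev in pav_spec) {
    if (ev$length <= 100) abort("PAV events must be longer than 100 bp")
    if (ev$carrier == "A") add_zone(ev$chrom, ev$start, ev$start + ev$length)
    else add_zone(ev$chrom, ev$start, ev$start + 1)
  }
  # non-overlap + flank validation
  if (nrow(reserved) > 1) {
    for (ch in unique(reserved$chromosome)) {
      z <- reserved %>% filter(.data$chromosome == ch) %>% arrange(.data$start)
      if (nrow(z) > 1 && any(z$start[-1] < z$end[-nrow(z)]))
        abort(paste("overlapping engineered spans on", ch))
    }
  }
  if (nrow(reserved) > 0 &&
      any(reserved$start < 1000 | reserved$end > chrom_len - 1000))
    abort("engineered spans need >= 1 kb flanks inside the chromosome")

  # background edits per chromosome, outside reserved zones (+100 bp margin)
  margin <- 100
  edits <- with_substream(seed, "background_edits", {
    setNames(lapply(chroms, function(ch) {
      z <- reserved %>% filter(.data$chromosome == ch)
      excluded <- function(pos) {
        if (nrow(z) == 0) return(rep(FALSE, length(pos)))
        out <- rep(FALSE, length(pos))
        for (i in seq_len(nrow(z)))
          out <- out | (pos >= z$start[i] - margin & pos < z$end[i] + margin)
        out
      }
      snp_pos <- which(runif(chrom_len) < snp_rate) - 1
      ind_pos <- which(runif(chrom_len) < indel_rate) - 1
      snp_pos <- snp_pos[!excluded(snp_pos)]
      ind_pos <- ind_pos[!excluded(ind_pos)]
      # keep indels clear of the chromosome ends and of each other
      ind_pos <- ind_pos[ind_pos > 50 & ind_pos < chrom_len - 50]
      if (length(ind_pos) > 1) ind_pos <- ind_pos[c(TRUE, diff(ind_pos) > 30)]
      snp_pos <- setdiff(snp_pos, unlist(lapply(ind_pos, function(p) p + (-15:15))))
      seq <- a_seqs[[ch]]
      bases <- c("A", "C", "G", "T")
      snp_ref <- if (length(snp_pos)) substring(seq, snp_pos + 1, snp_pos + 1)
        else character(0)
      new <- vapply(snp_ref, function(b)
        sample(setdiff(bases, b), 1), character(1), USE.NAMES = FALSE)
      snp_ed <- tibble(pos = snp_pos, kind = "snp",
                       payload = as.character(new), ref = snp_ref)
      ind_kind <- if (length(ind_pos))
        sample(c("insertion", "deletion"), length(ind_pos), TRUE) else character(0)
      ind_len <- if (length(ind_pos)) sample(1:10, length(ind_pos), TRUE)
        else integer(0)
      ind_payload <- vapply(seq_along(ind_pos), function(i) {
        if (ind_kind[i] == "insertion") random_dna(ind_len[i], gc = 0.35)
        else substring(seq, ind_pos[i] + 1, ind_pos[i] + ind_len[i])
      }, character(1))
      ind_ed <- tibble(pos = ind_pos, kind = ind_kind, payload = ind_payload,
                       ref = as.character(ifelse(ind_kind == "deletion",
                                                 ind_payload, "")))
      bind_rows(snp_ed, ind_ed) %>% arrange(.data$pos)
    }), chroms)
  })

  # engineered surgery on piece lists (pure A coordinates)
  plists <- setNames(lapply(chroms, function(ch)
    list(new_piece(ch, 0, chrom_len))), chroms)
  sv_truth <- list(); pav_truth <- list()
  ev_id <- 0
  novel_seqs <- with_substream(seed, "pav_sequences", {
    lapply(pav_spec, function(ev)
      if (ev$carrier == "B") random_dna(ev$length, gc = 0.40) else NA_character_)
  })
  for (ev in sv_spec) {
    ev_id <- ev_id + 1
    id <- paste0("sv", ev_id)
    if (ev$kind == "inversion") {
      r <- remove_span(plists[[ev$chrom]], ev$chrom, ev$start, ev$end)
      inv <- rev(lapply(r$removed, function(p) {
        p$strand <- "-"; p$event <- id; p
      }))
      plists[[ev$chrom]] <- insert_at(r$pieces, ev$chrom, ev$end, inv)
      sv_truth[[id]] <- tibble(sv_id = id, kind = "inversion",
                               ref_chrom = ev$chrom, ref_start = ev$start,
                               ref_end = ev$end, qry_chrom = ev$chrom,
                               orientation = "reverse")
    } else {
      r <- remove_span(plists[[ev$chrom]], ev$chrom, ev$start, ev$end)
      moved <- lapply(r$removed, function(p) { p$event <- id; p })
      plists[[ev$chrom]] <- r$pieces
      plists[[ev$dest_chrom]] <- insert_at(plists[[ev$dest_chrom]],
                                           ev$dest_chrom, ev$dest_pos, moved)
      sv_truth[[id]] <- tibble(sv_id = id, kind = ev$kind,
                               ref_chrom = ev$chrom, ref_start = ev$start,
                               ref_end = ev$end, qry_chrom = ev$dest_chrom,
                               orientation = "forward")
    }
  }
  for (i in seq_along(pav_spec)) {
    ev <- pav_spec[[i]]
    ev_id <- ev_id + 1
    id <- paste0("pav", ev_id)
    if (ev$carrier == "B") {
      np <- new_piece(ev$chrom, ev$start, ev$start, seq = novel_seqs[[i]],
                      event = id)
      plists[[ev$chrom]] <- insert_at(plists[[ev$chrom]], ev$chrom, ev$start,
                                      list(np))
      pav_truth[[id]] <- tibble(pav_id = id, carrier = "B",
                                a_chrom = ev$chrom, a_start = ev$start,
                                a_end = ev$start, b_chrom = ev$chrom,
                                length = ev$length)
    } else {
      r <- remove_span(plists[[ev$chrom]], ev$chrom, ev$start,
                       ev$start + ev$length)
      plists[[ev$chrom]] <- r$pieces
      pav_truth[[id]] <- tibble(pav_id = id, carrier = "A",
                                a_chrom = ev$chrom, a_start = ev$start,
                                a_end = ev$start + ev$length,
                                b_chrom = ev$chrom, length = ev$length)
    }
  }

  # render B and locate event spans on B
  b_seqs <- list(); b_span <- list()
  for (ch in chroms) {
    offset <- 0; segs <- character(0)
    for (p in plists[[ch]]) {
      if (!is.na(p$seq)) s <- p$seq
      else {
        ed <- edits[[p$chrom]] %>%
          filter(.data$pos >= p$start, .data$pos < p$end) %>%
          mutate(pos = .data$pos) # chromosome-local already
        s <- render_with_edits(a_seqs[[p$chrom]], p$start, p$end, ed)
        if (p$strand == "-") s <- cpp_revcomp(s)
      }
      L <- nchar(s)
      if (!is.na(p$event)) {
        prev <- b_span[[p$event]]
        if (is.null(prev)) b_span[[p$event]] <- c(offset, offset + L, match(ch, chroms))
        else b_span[[p$event]] <- c(min(prev[1], offset),
                                    max(prev[2], offset + L), prev[3])
      }
      segs <- c(segs, s)
      offset <- offset + L
    }
    b_seqs[[ch]] <- paste(segs, collapse = "")
  }

  svs <- bind_rows(sv_truth)
  if (nrow(svs) > 0) {
    svs$qry_start <- unname(vapply(svs$sv_id, function(id) b_span[[id]][1], 0))
    svs$qry_end <- unname(vapply(svs$sv_id, function(id) b_span[[id]][2], 0))
    svs$qry_chrom <- unname(vapply(svs$sv_id,
                                   function(id) chroms[b_span[[id]][3]], ""))
  } else {
    svs <- tibble(sv_id = character(), kind = character(),
                  ref_chrom = character(), ref_start = double(),
                  ref_end = double(), qry_chrom = character(),
                  orientation = character(), qry_start = double(),
                  qry_end = double())
  }
  pavs <- bind_rows(pav_truth)
  if (nrow(pavs) > 0) {
    pavs$b_start <- unname(vapply(pavs$pav_id, function(id) {
      sp <- b_span[[id]]; if (is.null(sp)) NA_real_ else sp[1]
    }, 0))
    pavs$b_end <- unname(vapply(pavs$pav_id, function(id) {
      sp <- b_span[[id]]; if (is.null(sp)) NA_real_ else sp[2]
    }, 0))
  } else {
    pavs <- tibble(pav_id = character(), carrier = character(),
                   a_chrom = character(), a_start = double(), a_end = double(),
                   b_chrom = character(), length = double(),
                   b_start = double(), b_end = double())
  }
  planted <- bind_rows(lapply(chroms, function(ch) {
    e <- edits[[ch]]
    if (nrow(e) == 0) return(NULL)
    tibble(kind = e$kind, ref_chrom = ch, ref_pos = e$pos,
           ref_allele = ifelse(e$kind == "insertion", "", e$ref),
           alt_allele = ifelse(e$kind == "deletion", "",
                               ifelse(e$kind == "snp", e$payload, e$payload)))
  }))
  if (is.null(planted) || nrow(planted) == 0)
    planted <- tibble(kind = character(), ref_chrom = character(),
                      ref_pos = double(), ref_allele = character(),
                      alt_allele = character())

  list(genome_a = genome_set(unlist(a_seqs), "A"),
       genome_b = genome_set(unlist(b_seqs), "B"),
       truth = list(engineered_svs = svs, engineered_pavs = pavs,
                    planted_variants = planted))
}

#' Simulate an accession panel split by an inversion allele
#'
#' Emulates a diversity panel in which two groups of accessions carry
#' alternative alleles of a large inversion: sites inside the inversion are
#' differentiated between groups and have reduced within-group diversity,
#' and a fraction of them segregate in only one group.  Accessions are
#' inbred-like (mostly homozygous dosages 0/2 with a low heterozygote and
#' missing rate), as for cotton cultivars.
#'
#' @param n_ref_like,n_alt_like group sizes (defaults mirror a 66/348
#'   panel split).
#' @param n_sites number of biallelic sites (>= 10).
#' @param group_private_fraction fraction of inside-inversion sites private
#'   to one group.
#' @param inside_inversion_diversity_scale multiplier in \[0,1\]; 1 leaves
#'   inside sites drawn from the shared frequency vector (null), 0 makes
#'   them monomorphic within each group.
#' @param chrom_len chromosome length in bp.
#' @param inversion_span 0-based half-open span of the inversion.
#' @param het_rate,miss_rate per-call heterozygote and missing rates.
#' @param seed integer seed.
#' @return list with `panel` (a genotype matrix object: `accessions`,
#'   `sites`, `genotypes`, `groups`) and `truth` (group labels, inversion
#'   span, per-site inside flag).
#' @export
simulate_panel <- function(n_ref_like = 66, n_alt_like = 348, n_sites = 2000,
                           group_private_fraction = 0.3,
                           inside_inversion_diversity_scale = 0.2,
                           chrom_len = 5e7,
                           inversion_span = c(2e7, 3e7),
                           het_rate = 0.02, miss_rate = 0.02, seed = 1) {
  stopifnot(n_ref_like >= 2, n_alt_like >= 2,
            group_private_fraction >= 0, group_private_fraction <= 1,
            inside_inversion_diversity_scale >= 0,
            inside_inversion_diversity_scale <= 1)
  if (n_sites < 10) abort("n_sites must be >= 10")
  acc <- c(sprintf("R%03d", seq_len(n_ref_like)),
           sprintf("Z%03d", seq_len(n_alt_like)))
  grp <- setNames(rep(c("ref_like", "alt_like"), c(n_ref_like, n_alt_like)), acc)
  with_substream(seed, "panel", {
    pos <- sort(sample.int(chrom_len, n_sites)) - 1
    inside <- pos >= inversion_span[1] & pos < inversion_span[2]
    p_shared <- runif(n_sites, 0.05, 0.95)
    w <- 1 - inside_inversion_diversity_scale
    p_ref <- p_shared; p_alt <- p_shared
    d_ref <- rbinom(n_sites, 1, 0.5); d_alt <- 1 - d_ref
    p_ref[inside] <- (1 - w) * p_shared[inside] + w * d_ref[inside]
    p_alt[inside] <- (1 - w) * p_shared[inside] + w * d_alt[inside]
    priv <- inside & runif(n_sites) < group_private_fraction
    priv_side <- rbinom(n_sites, 1, 0.5) # 1 -> private to ref group
    p_ref[priv & priv_side == 0] <- 0
    p_alt[priv & priv_side == 1] <- 0
    geno <- matrix(NA_integer_, nrow = length(acc), ncol = n_sites,
                   dimnames = list(acc, NULL))
    for (i in seq_along(acc)) {
      p <- if (grp[i] == "ref_like") p_ref else p_alt
      dose <- 2L * rbinom(n_sites, 1, p)
      het <- runif(n_sites) < het_rate & dose == 2L # residual heterozygosity
      dose[het] <- 1L
      dose[runif(n_sites) < miss_rate] <- NA_integer_
      geno[i, ] <- dose
    }
    ref_base <- sample(c("A", "C", "G", "T"), n_sites, TRUE)
    alt_base <- vapply(ref_base, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1),
      USE.NAMES = FALSE)
    sites <- tibble(chromosome = "A08", position = pos,
                    ref = ref_base, alt = alt_base)
    panel <- genotype_matrix(acc, sites, geno, groups = grp)
    list(panel = panel,
         truth = list(groups = grp, inversion_span = inversion_span,
                      inside = inside))
  })
}

#' Simulate a subgenome and two ancestor genomes with planted introgressions
#'
#' The subgenome is random DNA; the same-ancestry ancestor diverges from it
#' by `own_divergence` point mutations per bp and the other-ancestry
#' ancestor by `other_divergence`, except inside the requested swap spans,
#' where the two rates are exchanged - emulating segments of the subgenome
#' whose sequence derives from the other ancestor (homoeologous
#' introgression).  Divergence is point mutation only, so bin coverage has
#' exact expectations.
#'
#' @param n_chrom,chrom_len subgenome geometry.
#' @param own_divergence,other_divergence per-bp divergence to the two
#'   ancestors (defaults 0.02 / 0.05).
#' @param swaps tibble (`chrom`, `start`, `end`) of introgressed spans
#'   (0-based half-open), or `NULL`.
#' @param seed integer seed.
#' @return list: `subgenome`, `own_ancestor`, `other_ancestor`
#'   (`genome_set`s) and `truth` (the swap tibble).
#' @export
simulate_introgression_set <- function(n_chrom = 1, chrom_len = 2e6,
                                       own_divergence = 0.02,
                                       other_divergence = 0.05,
                                       swaps = NULL, seed = 1) {
  stopifnot(own_divergence >= 0, other_divergence >= 0,
            own_divergence <= 0.2, other_divergence <= 0.2)
  chroms <- paste0("chr", seq_len(n_chrom))
  if (is.null(swaps))
    swaps <- tibble(chrom = character(), start = double(), end = double())
  with_substream(seed, "introgression", {
    sub <- setNames(lapply(chroms, function(ch) random_dna(chrom_len, 0.35)),
                    chroms)
    bases <- c("A", "C", "G", "T")
    mutate_at_rate <- function(seq, rate_vec) {
      pos <- which(runif(nchar(seq)) < rate_vec)
      if (length(pos) == 0) return(seq)
      x <- strsplit(seq, "")[[1]]
      x[pos] <- vapply(x[pos], function(b) sample(setdiff(bases, b), 1),
                       character(1), USE.NAMES = FALSE)
      paste(x, collapse = "")
    }
    own <- list(); other <- list()
    for (ch in chroms) {
      inside <- rep(FALSE, chrom_len)
      sw <- swaps[swaps$chrom == ch, , drop = FALSE]
      for (i in seq_len(nrow(sw)))
        inside[seq(sw$start[i] + 1, sw$end[i])] <- TRUE
      own[[ch]] <- mutate_at_rate(sub[[ch]], ifelse(inside, other_divergence,
                                                    own_divergence))
      other[[ch]] <- mutate_at_rate(sub[[ch]], ifelse(inside, own_divergence,
                                                      other_divergence))
    }
    list(subgenome = genome_set(unlist(sub), "At"),
         own_ancestor = genome_set(unlist(own), "A2"),
         other_ancestor = genome_set(unlist(other), "D5"),
         truth = swaps)
  })
}

#' Simulate mate pairs around structural-variant breakpoints
#'
#' Fragments are drawn uniformly around each breakpoint from the chosen
#' haplotype; both mates are reported at their mapped positions and strands
#' on the reference haplotype.  When `inversions` is supplied the haplotype
#' differs from the reference by those inverted spans and mates falling
#' inside them are mapped through the inversion (position reflected, strand
#' flipped).  Reads that would cross a breakpoint itself are redrawn, as a
#' mapper would clip them.
#'
#' @param genome reference-haplotype `genome_set` (used for contig lengths).
#' @param breakpoints tibble with `chrom`, `pos` (0-based) and optional
#'   `sv_id`.
#' @param n_pairs pairs per breakpoint.
#' @param insert_mean,insert_sd insert-size distribution (bp);
#'   `insert_mean > 2 * read_len`.
#' @param read_len read length in bp.
#' @param inversions optional tibble (`chrom`, `start`, `end`) of spans
#'   inverted in the sampled haplotype relative to the reference.
#' @param seed integer seed.
#' @return tibble: `pair_id`, `sv_id`, `chrom`, `pos1`, `strand1`, `pos2`,
#'   `strand2` (0-based leftmost mapped base of each mate).
#' @export
simulate_mate_pairs <- function(genome, breakpoints, n_pairs = 20,
                                insert_mean = 5000, insert_sd = 400,
                                read_len = 150, inversions = NULL, seed = 1) {
  stopifnot(insert_mean > 2 * read_len)
  lens <- genome_lengths(genome)
  if (!"sv_id" %in% names(breakpoints))
    breakpoints$sv_id <- paste0("bp", seq_len(nrow(breakpoints)))
  map_read <- function(chrom, hstart, hend, strand) {
    # map a read on the haplotype to reference coordinates
    if (!is.null(inversions)) {
      iv <- inversions[inversions$chrom == chrom, , drop = FALSE]
      for (j in seq_len(nrow(iv))) {
        s <- iv$start[j]; e <- iv$end[j]
        if (hstart >= s && hend <= e) {
          new_start <- s + e - hend
          return(c(new_start, if (strand == "+") -1 else 1))
        }
        if (hstart < e && hend > s) return(NULL) # crosses a junction
      }
    }
    c(hstart, if (strand == "+") 1 else -1)
  }
  rows <- list()
  with_substream(seed, "mate_pairs", {
    for (b in seq_len(nrow(breakpoints))) {
      ch <- breakpoints$chrom[b]; bp <- breakpoints$pos[b]
      if (bp < read_len || bp > lens[[ch]] - read_len) {
        warn(paste("breakpoint", breakpoints$sv_id[b],
                   "too close to contig end; skipped"))
        next
      }
      got <- 0; tries <- 0
      while (got < n_pairs && tries < n_pairs * 50) {
        tries <- tries + 1
        ins <- round(rnorm(1, insert_mean, insert_sd))
        if (ins < 2 * read_len) next
        frag_start <- round(runif(1, bp - ins, bp))
        frag_end <- frag_start + ins
        if (frag_start < 0 || frag_end > lens[[ch]]) next
        m1 <- map_read(ch, frag_start, frag_start + read_len, "+")
        m2 <- map_read(ch, frag_end - read_len, frag_end, "-")
        if (is.null(m1) || is.null(m2)) next
        got <- got + 1
        rows[[length(rows) + 1]] <- tibble(
          pair_id = paste0(breakpoints$sv_id[b], "_", got),
          sv_id = breakpoints$sv_id[b], chrom = ch,
          pos1 = m1[1], strand1 = if (m1[2] > 0) "+" else "-",
          pos2 = m2[1], strand2 = if (m2[2] > 0) "+" else "-")
      }
    }
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0)
    out <- tibble(pair_id = character(), sv_id = character(),
                  chrom = character(), pos1 = double(), strand1 = character(),
                  pos2 = double(), strand2 = character())
  out
}

#' Simulate a RIL genetic map with recombination suppression
#'
#' Bins are evenly spaced along the chromosome; centimorgan increments
#' follow the baseline rate, scaled by `suppression_factor` for the part of
#' each inter-bin interval inside the suppressed span.  The map is
#' deterministic given its parameters so that window statistics have exact
#' expectations.
#'
#' @param chrom_len chromosome length in bp.
#' @param n_bins number of map bins (>= 10).
#' @param baseline_rate recombination rate in cM/Mb.
#' @param suppressed_span 0-based half-open span with suppressed
#'   recombination, or `NULL`.
#' @param suppression_factor multiplier in \[0,1\] applied inside the span.
#' @param chromosome chromosome name.
#' @return tibble: `chromosome`, `position` (bp, 0-based), `cm` (cumulative).
#' @export
simulate_ril_map <- function(chrom_len = 5e7, n_bins = 100,
                             baseline_rate = 1,
                             suppressed_span = NULL,
                             suppression_factor = 1,
                             chromosome = "A08") {
  stopifnot(n_bins >= 10, suppression_factor >= 0, suppression_factor <= 1)
  pos <- round(seq(0, chrom_len, length.out = n_bins))
  seg_rate_cm <- function(s, e) {
    base <- (e - s) / 1e6 * baseline_rate
    if (is.null(suppressed_span)) return(base)
    ov <- max(0, min(e, suppressed_span[2]) - max(s, suppressed_span[1]))
    ((e - s - ov) + ov * suppression_factor) / 1e6 * baseline_rate
  }
  inc <- vapply(seq_len(n_bins - 1), function(i)
    seg_rate_cm(pos[i], pos[i + 1]), 0)
  tibble(chromosome = chromosome, position = pos, cm = c(0, cumsum(inc)))
}
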