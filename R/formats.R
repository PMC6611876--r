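# Readers and writers for the external text formats the pipeline touches.
# Files speak 1-based inclusive coordinates (coords dialect, VCF, GFF3) or
# their format's native convention (PAF, BED: 0-based half-open); everything
# in memory is 0-based half-open.

block_tibble <- function(ref_chrom = character(), ref_start = double(),
                         ref_end = double(), qry_chrom = character(),
                         qry_start = double(), qry_end = double(),
                         orientation = character(), identity = double(),
                         ref_aln = NA_character_, qry_aln = NA_character_) {
  tibble(ref_chrom = ref_chrom, ref_start = ref_start, ref_end = ref_end,
         qry_chrom = qry_chrom, qry_start = qry_start, qry_end = qry_end,
         orientation = orientation, identity = identity,
         ref_aln = ref_aln, qry_aln = qry_aln)
}

#' Read an alignment table (show-coords dialect or PAF)
#'
#' Accepts either the 13-column tab-separated `show-coords -rclTH` dialect
#' (1-based inclusive; a descending query interval marks a reverse hit) or
#' PAF (0-based half-open with an explicit strand column).  Both are
#' normalised to the package's internal block representation: 0-based
#' half-open ascending spans plus an orientation flag.
#'
#' @param path alignment table file.
#' @return tibble of alignment blocks with columns `ref_chrom`, `ref_start`,
#'   `ref_end`, `qry_chrom`, `qry_start`, `qry_end`, `orientation`
#'   (`"forward"`/`"reverse"`), `identity` (proportion in \[0,1\]) and empty
#'   `ref_aln`/`qry_aln` placeholders for base-level alignments.
#' @export
read_alignment_table <- function(path) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(block_tibble())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol1 <- length(fields[[1]])
  is_paf <- ncol1 >= 12 && fields[[1]][5] %in% c("+", "-")
  rows <- purrr::map(fields, function(f) {
    if (is_paf) {
      qs <- as.double(f[3]); qe <- as.double(f[4])
      ts <- as.double(f[8]); te <- as.double(f[9])
      if (anyNA(c(qs, qe, ts, te)) || qs < 0 || ts < 0 || qe > as.double(f[2]) ||
          te > as.double(f[7])) return(NULL)
      tibble(ref_chrom = f[6], ref_start = ts, ref_end = te,
             qry_chrom = f[1], qry_start = qs, qry_end = qe,
             orientation = if (f[5] == "-") "reverse" else "forward",
             identity = as.double(f[10]) / max(as.double(f[11]), 1))
    } else {
      s1 <- as.double(f[1]); e1 <- as.double(f[2])
      s2 <- as.double(f[3]); e2 <- as.double(f[4])
      if (anyNA(c(s1, e1, s2, e2)) || min(s1, e1, s2, e2) < 1) return(NULL)
      tibble(ref_chrom = f[12], ref_start = s1 - 1, ref_end = e1,
             qry_chrom = f[13],
             qry_start = min(s2, e2) - 1, qry_end = max(s2, e2),
             orientation = if (s2 > e2) "reverse" else "forward",
             identity = as.double(f[7]) / 100)
    }
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0)
    warn(paste(dropped, "row(s) with invalid coordinates rejected"))
  out <- bind_rows(rows)
  if (nrow(out) == 0) return(block_tibble())
  out$ref_aln <- NA_character_
  out$qry_aln <- NA_character_
  out
}

#' Write alignment blocks as a show-coords-style table
#'
#' Emits the 13-column tab-separated dialect read by
#' [read_alignment_table()], converting back to 1-based inclusive
#' coordinates and writing reverse blocks with a descending query interval.
#'
#' @param blocks block tibble.
#' @param path output path.
#' @param ref_lengths,qry_lengths optional named lengths used for the LEN/COV
#'   columns; 0 when unknown.
#' @return `path`, invisibly.
#' @export
write_alignment_table <- function(blocks, path,
                                  ref_lengths = NULL, qry_lengths = NULL) {
  rl <- function(ch) if (is.null(ref_lengths)) 0 else unname(ref_lengths[ch])
  ql <- function(ch) if (is.null(qry_lengths)) 0 else unname(qry_lengths[ch])
  lines <- purrr::pmap_chr(blocks, function(ref_chrom, ref_start, ref_end,
                                            qry_chrom, qry_start, qry_end,
                                            orientation, identity, ...) {
    rev <- identical(orientation, "reverse")
    s2 <- if (rev) qry_end else qry_start + 1
    e2 <- if (rev) qry_start + 1 else qry_end
    lr <- rl(ref_chrom); lq <- ql(qry_chrom)
    paste(ref_start + 1, ref_end, s2, e2,
          ref_end - ref_start, qry_end - qry_start,
          sprintf("%.2f", identity * 100), lr, lq,
          sprintf("%.2f", if (lr > 0) 100 * (ref_end - ref_start) / lr else 0),
          sprintf("%.2f", if (lq > 0) 100 * (qry_end - qry_start) / lq else 0),
          ref_chrom, qry_chrom, sep = "\t")
  })
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Only `gene`, `mRNA`, `exon` and `CDS` features are used.  When a gene has
#' several mRNAs the one with the longest total CDS is kept.
#'
#' @param path GFF3 file.
#' @return tibble with one row per gene: `gene_id`, `chromosome`, `strand`,
#'   and list-columns `exons` and `cds` of 0-based half-open interval
#'   matrices (columns `start`, `end`).
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  f <- f[vapply(f, length, integer(1)) == 9L]
  df <- tibble(
    chromosome = vapply(f, `[`, "", 1), type = vapply(f, `[`, "", 3),
    start = as.double(vapply(f, `[`, "", 4)) - 1,
    end = as.double(vapply(f, `[`, "", 5)),
    strand = vapply(f, `[`, "", 7), attr = vapply(f, `[`, "", 9))
  get_attr <- function(a, key)
    stringr::str_match(a, paste0("(?:^|;)", key, "=([^;]+)"))[, 2]
  mrna <- df %>% filter(.data$type == "mRNA") %>%
    mutate(id = get_attr(.data$attr, "ID"), parent = get_attr(.data$attr, "Parent"))
  parts <- df %>% filter(.data$type %in% c("exon", "CDS")) %>%
    mutate(parent = get_attr(.data$attr, "Parent"))
  genes <- df %>% filter(.data$type == "gene") %>%
    mutate(gene_id = get_attr(.data$attr, "ID"))
  rows <- purrr::pmap(list(genes$gene_id, genes$chromosome, genes$strand),
                      function(gid, chrom, strand) {
    tx <- mrna %>% filter(.data$parent == gid)
    pick <- function(tid) {
      p <- parts %>% filter(.data$parent == tid)
      list(exons = p %>% filter(.data$type == "exon"),
           cds = p %>% filter(.data$type == "CDS"))
    }
    if (nrow(tx) == 0) return(NULL)
    cand <- purrr::map(tx$id, pick)
    cds_len <- vapply(cand, function(x) sum(x$cds$end - x$cds$start), double(1))
    best <- cand[[which.max(cds_len)]]
    mk <- function(d) {
      d <- d %>% arrange(.data$start)
      cbind(start = d$start, end = d$end)
    }
    tibble(gene_id = gid, chromosome = chrom, strand = strand,
           exons = list(mk(best$exons)), cds = list(mk(best$cds)))
  })
  bind_rows(rows)
}

#' Write gene models to GFF3
#'
#' @param genes gene-model tibble as returned by [read_gene_models()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    ex <- g$exons[[1]]; cd <- g$cds[[1]]
    span_s <- min(ex[, "start"], cd[, "start"]) + 1
    span_e <- max(ex[, "end"], cd[, "end"])
    tid <- paste0(g$gene_id, ".1")
    lines <- c(lines,
      paste(g$chromosome, "polysv", "gene", span_s, span_e, ".", g$strand, ".",
            paste0("ID=", g$gene_id), sep = "\t"),
      paste(g$chromosome, "polysv", "mRNA", span_s, span_e, ".", g$strand, ".",
            paste0("ID=", tid, ";Parent=", g$gene_id), sep = "\t"),
      vapply(seq_len(nrow(ex)), function(j)
        paste(g$chromosome, "polysv", "exon", ex[j, "start"] + 1, ex[j, "end"],
              ".", g$strand, ".", paste0("Parent=", tid), sep = "\t"), ""),
      vapply(seq_len(nrow(cd)), function(j)
        paste(g$chromosome, "polysv", "CDS", cd[j, "start"] + 1, cd[j, "end"],
              ".", g$strand, "0", paste0("Parent=", tid), sep = "\t"), ""))
  }
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write variant calls to VCF v4.2
#'
#' Indels are left-anchored on the preceding reference base when the carrier
#' genome is supplied (standard VCF convention); without a genome the anchor
#' base is written as `N`.
#'
#' @param variants variant tibble (`kind`, `ref_chrom`, `ref_pos`,
#'   `ref_allele`, `alt_allele`).
#' @param path output path.
#' @param genome optional `genome_set` for anchor bases and contig headers.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, genome = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=polysv")
  if (!is.null(genome))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(genome),
                          genome_lengths(genome)))
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  v <- variants %>% arrange(.data$ref_chrom, .data$ref_pos)
  body <- purrr::pmap_chr(
    list(v$kind, v$ref_chrom, v$ref_pos, v$ref_allele, v$alt_allele),
    function(kind, chrom, pos, ref, alt) {
      if (kind == "snp") {
        p <- pos + 1
      } else {
        anchor <- if (!is.null(genome) && pos >= 1)
          genome_slice(genome, chrom, pos - 1, pos) else "N"
        ref <- paste0(anchor, ref)
        alt <- paste0(anchor, alt)
        p <- pos # anchor base is pos-1 0-based -> pos 1-based
      }
      paste(chrom, p, ".", ref, alt, ".", "PASS", ".", sep = "\t")
    })
  readr::write_lines(c(hdr, body), path)
  invisible(path)
}

#' Syntactic VCF lint
#'
#' Checks for a `##fileformat` header, a `#CHROM` column line, and positions
#' sorted within each chromosome.
#'
#' @param path VCF file.
#' @return `TRUE` invisibly if the file passes; otherwise an error.
#' @export
lint_vcf <- function(path) {
  lines <- readr::read_lines(path)
  if (!startsWith(lines[1], "##fileformat=VCF"))
    abort("missing ##fileformat header")
  chrom_line <- which(startsWith(lines, "#CHROM"))
  if (length(chrom_line) != 1) abort("missing #CHROM header line")
  body <- lines[-seq_len(chrom_line)]
  body <- body[nzchar(body)]
  if (length(body) > 0) {
    f <- strsplit(body, "\t", fixed = TRUE)
    chrom <- vapply(f, `[`, "", 1)
    pos <- as.double(vapply(f, `[`, "", 2))
    ok <- tapply(pos, chrom, function(p) !is.unsorted(p))
    if (!all(ok)) abort("positions not sorted within chromosome")
  }
  invisible(TRUE)
}

#' Write a genotype panel to VCF v4.2
#'
#' @param panel genotype matrix object (see [simulate_panel()]): list with
#'   `sites` tibble (`chromosome`, `position` 0-based, `ref`, `alt`),
#'   `genotypes` accession x site matrix of alt-dosage codes 0/1/2/NA, and
#'   `accessions`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  hdr <- c("##fileformat=VCFv4.2", "##source=polysv",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", panel$accessions), collapse = "\t"))
  gt_code <- function(d) {
    out <- rep("./.", length(d))
    out[!is.na(d) & d == 0] <- "0/0"
    out[!is.na(d) & d == 1] <- "0/1"
    out[!is.na(d) & d == 2] <- "1/1"
    out
  }
  ord <- order(panel$sites$chromosome, panel$sites$position)
  body <- vapply(ord, function(j) {
    s <- panel$sites[j, ]
    paste(c(s$chromosome, s$position + 1, ".", s$ref, s$alt, ".", "PASS", ".",
            "GT", gt_code(panel$genotypes[, j])), collapse = "\t")
  }, character(1))
  readr::write_lines(c(hdr, body), path)
  invisible(path)
}

#' Read a genotype panel from VCF
#'
#' Biallelic SNP records with GT fields; diploid genotypes become alt-allele
#' dosages 0/1/2, `./.` becomes `NA`.
#'
#' @param path VCF file.
#' @return genotype matrix object (list with `accessions`, `sites`,
#'   `genotypes`, `groups = NULL`).
#' @export
read_panel_vcf <- function(path) {
  lines <- readr::read_lines(path)
  chrom_line <- which(startsWith(lines, "#CHROM"))
  if (length(chrom_line) != 1) abort("missing #CHROM header line")
  cols <- strsplit(lines[chrom_line], "\t", fixed = TRUE)[[1]]
  accessions <- cols[-(1:9)]
  body <- lines[-seq_len(chrom_line)]
  body <- body[nzchar(body)]
  f <- strsplit(body, "\t", fixed = TRUE)
  keep <- vapply(f, function(x) nchar(x[4]) == 1 && nchar(x[5]) == 1 &&
                   x[5] %in% c("A", "C", "G", "T"), logical(1))
  f <- f[keep]
  sites <- tibble(
    chromosome = vapply(f, `[`, "", 1),
    position = as.double(vapply(f, `[`, "", 2)) - 1,
    ref = vapply(f, `[`, "", 4), alt = vapply(f, `[`, "", 5))
  geno <- vapply(f, function(x) {
    gt <- sub(":.*$", "", x[-(1:9)])
    a <- substr(gt, 1, 1); b <- substr(gt, 3, 3)
    d <- suppressWarnings(as.integer(a) + as.integer(b))
    d
  }, integer(length(accessions)))
  geno <- matrix(geno, nrow = length(accessions),
                 dimnames = list(accessions, NULL))
  genotype_matrix(accessions, sites, geno)
}

#' Write intervals to BED
#'
#' BED is natively 0-based half-open, matching internal coordinates.
#'
#' @param x tibble with `chromosome`, `start`, `end` and optionally `name`
#'   and `score` columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  name <- if ("name" %in% names(x)) x$name else "."
  score <- if ("score" %in% names(x)) x$score else 0
  readr::write_lines(
    paste(x$chromosome, format(x$start, scientific = FALSE, trim = TRUE),
          format(x$end, scientific = FALSE, trim = TRUE), name, score,
          sep = "\t"), path)
  invisible(path)
}

#' Read a BED file
#' @param path BED file.
#' @return tibble with `chromosome`, `start`, `end`, `name`, `score`.
#' @export
read_bed <- function(path) {
  f <- strsplit(readr::read_lines(path), "\t", fixed = TRUE)
  f <- f[vapply(f, length, integer(1)) >= 3]
  tibble(chromosome = vapply(f, `[`, "", 1),
         start = as.double(vapply(f, `[`, "", 2)),
         end = as.double(vapply(f, `[`, "", 3)),
         name = vapply(f, function(x) if (length(x) >= 4) x[4] else ".", ""),
         score = vapply(f, function(x)
           if (length(x) >= 5) suppressWarnings(as.double(x[5])) else 0, 0))
}

#' Read a mate-pair table
#'
#' Tab-separated with header: `pair_id`, `chrom`, `pos1`, `strand1`, `pos2`,
#' `strand2` (positions 1-based leftmost mapped base in the file; 0-based in
#' memory).
#'
#' @param path TSV file.
#' @return tibble of pairs with 0-based positions.
#' @export
read_mate_pairs <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  d %>% mutate(pos1 = .data$pos1 - 1, pos2 = .data$pos2 - 1)
}

#' Write a mate-pair table
#' @param pairs tibble with 0-based `pos1`, `pos2`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mate_pairs <- function(pairs, path) {
  pairs %>% mutate(pos1 = .data$pos1 + 1, pos2 = .data$pos2 + 1) %>%
    readr::write_tsv(path)
  invisible(path)
}

#' Read a genetic map
#'
#' Tab-separated with header: `chromosome`, `position` (bp, 1-based in the
#' file), `cm` (cumulative centimorgans).
#'
#' @param path TSV file.
#' @return tibble with 0-based `position` and `cm`.
#' @export
read_genetic_map <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE) %>%
    mutate(position = .data$position - 1)
}

#' Write a genetic map
#' @param map tibble with 0-based `position` and cumulative `cm`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genetic_map <- function(map, path) {
  map %>% mutate(position = .data$position + 1) %>% readr::write_tsv(path)
  invisible(path)
}
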