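# Panel-scale analyses: site filtering, inversion-breakpoint genotyping
# from mate-pair mappings, windowed diversity/differentiation/haplotype
# statistics, private-SNP accounting, neighbor-joining grouping and
# recombination-rate windows.

#' Construct a genotype matrix
#'
#' @param accessions accession ids.
#' @param sites tibble: `chromosome`, `position` (0-based), `ref`, `alt`.
#' @param genotypes accessions x sites integer matrix of alt-allele dosages
#'   (0, 1, 2 or `NA`).
#' @param groups optional named vector accession -> group label.
#' @param ploidy 2 (dosages 0/1/2) or 1 (haploid, dosages 0/1).
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(accessions, sites, genotypes, groups = NULL,
                            ploidy = 2) {
  stopifnot(nrow(genotypes) == length(accessions),
            ncol(genotypes) == nrow(sites), ploidy %in% c(1, 2))
  ord <- order(sites$chromosome, sites$position)
  structure(list(accessions = accessions, sites = sites[ord, , drop = FALSE],
                 genotypes = genotypes[, ord, drop = FALSE], groups = groups,
                 ploidy = ploidy),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix>", length(x$accessions), "accessions x",
      nrow(x$sites), "sites\n")
  invisible(x)
}

#' Filter panel sites on frequency, heterozygosity and missingness
#'
#' @param m `genotype_matrix`.
#' @param maf_min minimum minor-allele frequency over non-missing calls.
#' @param het_max maximum heterozygote fraction over non-missing calls.
#' @param miss_max maximum missing-call fraction.
#' @return filtered `genotype_matrix`.
#' @export
filter_sites <- function(m, maf_min = 0.05, het_max = 0.10, miss_max = 0.10) {
  g <- m$genotypes
  nmiss <- colMeans(is.na(g))
  nm <- colSums(!is.na(g))
  p <- colSums(g, na.rm = TRUE) / (2 * pmax(nm, 1))
  maf <- pmin(p, 1 - p)
  het <- colSums(g == 1, na.rm = TRUE) / pmax(nm, 1)
  keep <- maf >= maf_min & het <= het_max & nmiss <= miss_max & nm > 0
  if (!any(keep)) warn("all sites removed by filters")
  genotype_matrix(m$accessions, m$sites[keep, , drop = FALSE],
                  g[, keep, drop = FALSE], m$groups, m$ploidy %||% 2)
}

#' Genotype inversion breakpoints from mate-pair mappings
#'
#' A pair spans a breakpoint when its mates map on opposite sides of it.  A
#' spanning pair with inward orientation (`+` on the left mate, `-` on the
#' right) and an implied insert within `insert_mean +/- 4 insert_sd` is
#' concordant (reference-like evidence); a spanning pair with same-strand
#' mates or an out-of-range separation is discordant (alternative-allele
#' evidence).  An allele is assigned only when the evidence is unanimous
#' and reaches `min_support`; anything else is unassigned.
#'
#' @param pairs mate-pair tibble ([read_mate_pairs()] columns, plus an
#'   optional `accession` column).
#' @param breakpoints tibble: `chrom`, `pos`, `sv_id`.
#' @param insert_mean,insert_sd library insert distribution, bp.
#' @param read_len read length, bp.
#' @param min_support minimum unanimous pair count (default 2).
#' @param genome optional reference `genome_set`; when given, breakpoints
#'   outside it are a hard error.
#' @return tibble: `accession`, `sv_id`, `allele` in {ref_like, alt_like,
#'   unassigned}, `n_span_concordant`, `n_span_discordant`.
#' @export
genotype_breakpoints <- function(pairs, breakpoints, insert_mean = 5000,
                                 insert_sd = 400, read_len = 150,
                                 min_support = 2, genome = NULL) {
  if (!is.null(genome)) {
    lens <- genome_lengths(genome)
    bad <- !(breakpoints$chrom %in% names(lens)) |
      breakpoints$pos >= lens[breakpoints$chrom] | breakpoints$pos < 0
    if (any(bad))
      abort(paste("breakpoint absent from reference:",
                  paste(breakpoints$sv_id[bad], collapse = ", ")))
  }
  if (!"accession" %in% names(pairs)) pairs$accession <- "acc1"
  out <- list()
  for (acc in unique(pairs$accession)) {
    pa <- pairs %>% filter(.data$accession == acc)
    for (b in seq_len(nrow(breakpoints))) {
      bp <- breakpoints$pos[b]; ch <- breakpoints$chrom[b]
      p <- pa %>% filter(.data$chrom == ch)
      left <- pmin(p$pos1, p$pos2); right <- pmax(p$pos1, p$pos2)
      ls <- ifelse(p$pos1 <= p$pos2, p$strand1, p$strand2)
      rs <- ifelse(p$pos1 <= p$pos2, p$strand2, p$strand1)
      span <- (left + read_len) <= bp & right >= bp
      sep <- right + read_len - left
      inward <- ls == "+" & rs == "-"
      in_range <- abs(sep - insert_mean) <= 4 * insert_sd
      conc <- span & inward & in_range
      disc <- span & (ls == rs | !in_range)
      n_c <- sum(conc); n_d <- sum(disc)
      allele <- if (n_c >= min_support && n_d == 0) "ref_like"
        else if (n_d >= min_support && n_c == 0) "alt_like"
        else "unassigned"
      out[[length(out) + 1]] <- tibble(
        accession = acc, sv_id = breakpoints$sv_id[b], allele = allele,
        n_span_concordant = n_c, n_span_discordant = n_d)
    }
  }
  bind_rows(out)
}

#' Combine per-breakpoint calls into one accession call
#'
#' @param calls tibble from [genotype_breakpoints()].
#' @return tibble: `accession`, `allele` (`"conflict"` when assigned
#'   breakpoints disagree, `"unassigned"` when none is assigned).
#' @export
combine_breakpoint_calls <- function(calls) {
  calls %>% group_by(.data$accession) %>%
    summarise(allele = {
      a <- unique(.data$allele[.data$allele != "unassigned"])
      if (length(a) == 0) "unassigned"
      else if (length(a) > 1) "conflict"
      else a
    }, .groups = "drop")
}

# sliding windows over one chromosome's site values: sum of `val` per
# window divided by `denom` (window bp if NULL).
slide_sum <- function(pos, val, chrom_end, window, step) {
  starts <- seq(0, max(0, chrom_end - 1), by = step)
  cs <- c(0, cumsum(val))
  lo <- findInterval(starts - 0.5, pos)      # sites with pos < start
  hi <- findInterval(starts + window - 0.5, pos) # sites with pos < start+window
  tibble(start = starts, end = starts + window,
         sum = cs[hi + 1] - cs[lo + 1], n_sites = hi - lo)
}

site_allele_stats <- function(g, ploidy = 2) {
  nm <- colSums(!is.na(g))
  n_al <- ploidy * nm
  p <- colSums(g, na.rm = TRUE) / pmax(n_al, 1)
  list(n_al = n_al, p = p)
}

#' Windowed nucleotide diversity
#'
#' Per-site unbiased heterozygosity `2 p q n/(n-1)` over non-missing allele
#' counts, summed per sliding window and divided by the window width in bp.
#'
#' @param m `genotype_matrix` (>= 2 accessions).
#' @param window,step window and step size, bp (defaults 1 Mb / 10 kb).
#' @return tibble of window statistics: `chromosome`, `start`, `end`,
#'   `statistic = "pi"`, `value`, `n_sites`.
#' @export
pi_windows <- function(m, window = 1e6, step = 1e4) {
  stopifnot(length(m$accessions) >= 2)
  out <- list()
  for (ch in unique(m$sites$chromosome)) {
    i <- which(m$sites$chromosome == ch)
    st <- site_allele_stats(m$genotypes[, i, drop = FALSE], m$ploidy %||% 2)
    h <- ifelse(st$n_al > 1,
                2 * st$p * (1 - st$p) * st$n_al / (st$n_al - 1), 0)
    w <- slide_sum(m$sites$position[i], h, max(m$sites$position[i]) + 1,
                   window, step)
    out[[ch]] <- w %>% mutate(chromosome = ch, statistic = "pi",
                              value = .data$sum / window) %>%
      select("chromosome", "start", "end", "statistic", "value", "n_sites")
  }
  bind_rows(out)
}

# Weir-Cockerham variance components for one site, two groups.
# Returns c(a, b, c) or NULL when undefined.
wc_components <- function(g1, g2) {
  n1 <- sum(!is.na(g1)); n2 <- sum(!is.na(g2))
  if (n1 < 1 || n2 < 1) return(NULL)
  p1 <- mean(g1, na.rm = TRUE) / 2; p2 <- mean(g2, na.rm = TRUE) / 2
  h1 <- mean(g1 == 1, na.rm = TRUE); h2 <- mean(g2 == 1, na.rm = TRUE)
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  if (nc <= 0 || nbar <= 1) return(NULL)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a, b, cc)
}

#' Windowed Weir-Cockerham F_ST between two groups
#'
#' The weighted (ratio-of-sums) estimator: per-site variance components are
#' summed across the sites of each sliding window and the window value is
#' `sum(a) / sum(a + b + c)`.
#'
#' @param m `genotype_matrix`.
#' @param groups named vector accession -> group (exactly two groups, both
#'   with >= 2 accessions); defaults to `m$groups`.
#' @param window,step window and step size, bp (defaults 1 Mb / 100 kb).
#' @return tibble of window statistics (`statistic = "fst"`).
#' @export
fst_windows <- function(m, groups = NULL, window = 1e6, step = 1e5) {
  groups <- groups %||% m$groups
  if (is.null(groups)) abort("groups undefined")
  gl <- unique(groups[m$accessions])
  if (length(gl) != 2) abort("exactly two groups required")
  i1 <- which(groups[m$accessions] == gl[1])
  i2 <- which(groups[m$accessions] == gl[2])
  if (length(i1) < 2 || length(i2) < 2) abort("both groups need >= 2 accessions")
  out <- list()
  for (ch in unique(m$sites$chromosome)) {
    i <- which(m$sites$chromosome == ch)
    comp <- vapply(i, function(j) {
      x <- wc_components(m$genotypes[i1, j], m$genotypes[i2, j])
      if (is.null(x)) c(0, 0, 0) else x
    }, numeric(3))
    pos <- m$sites$position[i]
    wa <- slide_sum(pos, comp[1, ], max(pos) + 1, window, step)
    wabc <- slide_sum(pos, colSums(comp), max(pos) + 1, window, step)
    out[[ch]] <- wa %>%
      mutate(chromosome = ch, statistic = "fst",
             value = ifelse(wabc$sum > 0, .data$sum / wabc$sum, NA_real_)) %>%
      select("chromosome", "start", "end", "statistic", "value", "n_sites")
  }
  bind_rows(out)
}

# haplotype diversity of one site-window: clusters of identical genotype
# vectors; a missing call matches nothing, so accessions with missing data
# form singleton clusters.
hap_diversity <- function(g) {
  n <- nrow(g)
  if (n < 2) return(NA_real_)
  key <- apply(g, 1, paste, collapse = ",")
  key[apply(g, 1, anyNA)] <- paste0("__miss_", which(apply(g, 1, anyNA)))
  f <- table(key) / n
  n / (n - 1) * (1 - sum(f^2))
}

#' Windowed haplotype diversity
#'
#' Accessions are clustered by identical genotype vectors within
#' `cluster_window` (10 kb) windows; haplotype diversity of each cluster
#' window is `(n/(n-1)) (1 - sum f_i^2)` over cluster frequencies, and the
#' reported value per `avg_window` sliding window is the mean over the
#' cluster windows it contains (cluster windows without sites are skipped).
#' Apply [filter_sites()] (MAF >= 0.05) first.
#'
#' @param m `genotype_matrix`.
#' @param accessions optional subset of accessions (e.g. one group).
#' @param cluster_window,avg_window,step sizes in bp (defaults 10 kb / 1 Mb
#'   / 100 kb).
#' @return tibble of window statistics (`statistic = "hap_div"`; `n_sites`
#'   counts contributing cluster windows).
#' @export
hapdiv_windows <- function(m, accessions = NULL, cluster_window = 1e4,
                           avg_window = 1e6, step = 1e5) {
  rows <- if (is.null(accessions)) seq_along(m$accessions)
    else match(accessions, m$accessions)
  out <- list()
  for (ch in unique(m$sites$chromosome)) {
    i <- which(m$sites$chromosome == ch)
    pos <- m$sites$position[i]
    cw <- floor(pos / cluster_window)
    hd <- vapply(unique(cw), function(w) {
      j <- i[cw == w]
      hap_diversity(m$genotypes[rows, j, drop = FALSE])
    }, 0)
    hd_pos <- unique(cw) * cluster_window + cluster_window / 2
    ord <- order(hd_pos)
    hd <- hd[ord]; hd_pos <- hd_pos[ord]
    wsum <- slide_sum(hd_pos, hd, max(pos) + 1, avg_window, step)
    out[[ch]] <- wsum %>%
      mutate(chromosome = ch, statistic = "hap_div",
             value = ifelse(.data$n_sites > 0, .data$sum / .data$n_sites,
                            NA_real_)) %>%
      select("chromosome", "start", "end", "statistic", "value", "n_sites")
  }
  bind_rows(out)
}

#' Common and group-private segregating sites
#'
#' The larger group is down-sampled to the smaller's size; a segregating
#' site is common when polymorphic in both groups and private to the group
#' in which alone it is polymorphic.
#'
#' @param m `genotype_matrix`.
#' @param groups named vector accession -> group; defaults to `m$groups`.
#' @param seed seed for the down-sampling draw.
#' @return tibble: group labels, `common`, `private_<A>`, `private_<B>`,
#'   `segregating` counts.
#' @export
private_common_snps <- function(m, groups = NULL, seed = 1) {
  groups <- groups %||% m$groups
  if (is.null(groups)) abort("groups undefined")
  gl <- sort(unique(groups[m$accessions]))
  stopifnot(length(gl) == 2)
  i1 <- which(groups[m$accessions] == gl[1])
  i2 <- which(groups[m$accessions] == gl[2])
  k <- min(length(i1), length(i2))
  with_substream(seed, "private_snps", {
    i1 <- sort(sample(i1, k)); i2 <- sort(sample(i2, k))
  })
  poly <- function(idx) {
    g <- m$genotypes[idx, , drop = FALSE]
    alt <- colSums(g, na.rm = TRUE)
    tot <- (m$ploidy %||% 2) * colSums(!is.na(g))
    alt > 0 & alt < tot
  }
  p1 <- poly(i1); p2 <- poly(i2)
  tibble(group_a = gl[1], group_b = gl[2],
         common = sum(p1 & p2), private_a = sum(p1 & !p2),
         private_b = sum(!p1 & p2), segregating = sum(p1 | p2))
}

#' Neighbor-joining grouping of a panel
#'
#' Pairwise distance is the proportion of differing non-missing genotype
#' codes; the tree is canonical neighbor joining and the two-group cut is
#' the bipartition induced by the longest internal branch.
#'
#' @param m `genotype_matrix` (>= 3 accessions).
#' @return list: `tree` (an [ape::nj()] phylo), `two_cut` (named vector
#'   accession -> cluster 1/2; cluster 1 holds the alphabetically first
#'   accession), `dist` (the distance matrix).
#' @export
nj_groups <- function(m) {
  n <- length(m$accessions)
  stopifnot(n >= 3)
  g <- m$genotypes
  d <- matrix(0, n, n, dimnames = list(m$accessions, m$accessions))
  for (i in seq_len(n - 1)) {
    gi <- g[i, ]
    for (j in seq(i + 1, n)) {
      ok <- !is.na(gi) & !is.na(g[j, ])
      d[i, j] <- d[j, i] <- if (any(ok)) mean(gi[ok] != g[j, ][ok]) else 0
    }
  }
  tree <- ape::nj(stats::as.dist(d))
  ntip <- length(tree$tip.label)
  internal <- tree$edge[, 2] > ntip
  if (!any(internal)) {
    cut <- setNames(rep(1L, n), m$accessions)
    return(list(tree = tree, two_cut = cut, dist = d))
  }
  cand <- which(internal)
  e <- cand[which.max(tree$edge.length[cand])]
  # tips on the child side of edge e
  side <- integer(0)
  stack <- tree$edge[e, 2]
  while (length(stack) > 0) {
    node <- stack[1]; stack <- stack[-1]
    if (node <= ntip) side <- c(side, node)
    else stack <- c(stack, tree$edge[tree$edge[, 1] == node, 2])
  }
  in_side <- m$accessions %in% tree$tip.label[side]
  first <- order(m$accessions)[1]
  c1 <- if (in_side[first]) in_side else !in_side
  cut <- setNames(ifelse(c1, 1L, 2L), m$accessions)
  list(tree = tree, two_cut = cut, dist = d)
}

#' Recombination-rate windows from a genetic map
#'
#' Cumulative centimorgans are treated as a piecewise-linear function of
#' physical position through the map bins; each sliding window reports the
#' cM accumulated inside it divided by the window width in Mb (partial
#' inter-bin intervals pro-rated linearly).
#'
#' @param map genetic-map tibble (`chromosome`, `position` bp, `cm`).
#' @param window,step window and step, bp (defaults 1 Mb / 0.5 Mb).
#' @return list: `windows` (tibble of `statistic = "cm_per_mb"` rows) and
#'   `mean_cm_per_bin` (total map cM / number of bins).
#' @export
recomb_windows <- function(map, window = 1e6, step = 5e5) {
  out <- list()
  for (ch in unique(map$chromosome)) {
    mm <- map %>% filter(.data$chromosome == ch) %>% arrange(.data$position)
    if (is.unsorted(mm$cm)) {
      bad <- which(diff(mm$cm) < 0)[1] + 1
      abort(paste0("non-monotone cM at bin ", bad, " (", ch, ":",
                   mm$position[bad], ")"))
    }
    cm_at <- function(x) stats::approx(mm$position, mm$cm, xout = x,
                                       rule = 2)$y
    starts <- seq(0, max(mm$position), by = step)
    out[[ch]] <- tibble(
      chromosome = ch, start = starts, end = starts + window,
      statistic = "cm_per_mb",
      value = (cm_at(starts + window) - cm_at(starts)) / (window / 1e6),
      n_sites = vapply(starts, function(s)
        sum(mm$position >= s & mm$position < s + window), 0L))
  }
  total_cm <- map %>% group_by(.data$chromosome) %>%
    summarise(cm = max(.data$cm) - min(.data$cm), .groups = "drop")
  list(windows = bind_rows(out),
       mean_cm_per_bin = sum(total_cm$cm) / nrow(map))
}
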