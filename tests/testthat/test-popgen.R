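toy_matrix <- function(geno, pos = NULL, chrom = "c1", groups = NULL,
                       ploidy = 2) {
  n_sites <- ncol(geno)
  if (is.null(pos)) pos <- seq(0, by = 100, length.out = n_sites)
  acc <- rownames(geno) %||% paste0("a", seq_len(nrow(geno)))
  rownames(geno) <- acc
  sites <- tibble::tibble(chromosome = chrom, position = pos,
                          ref = "A", alt = "G")
  genotype_matrix(acc, sites, geno, groups = groups, ploidy = ploidy)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("site filters apply MAF, heterozygosity and missingness thresholds", {
  g <- rbind(a1 = c(0, 0, 0, 1, 2), a2 = c(0, 2, 1, 1, 0),
             a3 = c(0, 2, 1, 1, 2), a4 = c(0, 2, 1, NA, 0),
             a5 = c(2, 2, 1, NA, 2), a6 = c(0, 2, 1, 1, 0),
             a7 = c(0, 2, 1, 1, 2), a8 = c(0, 2, 1, 1, 0),
             a9 = c(0, 2, 1, 1, 2), a10 = c(0, 2, 1, 1, 0))
  m <- toy_matrix(g)
  f <- filter_sites(m, maf_min = 0.05, het_max = 0.10, miss_max = 0.10)
  # site1: maf 0.1 ok, het 0, miss 0 -> kept
  # site2: maf 0.1, het 0 -> kept; site3: het 90% -> removed
  # site4: 20% missing -> removed; site5: maf .45, het 10% -> kept
  expect_equal(f$sites$position, m$sites$position[c(1, 2, 5)])
  m2 <- toy_matrix(rbind(a1 = c(0, 2), a2 = c(0, 2)))
  expect_warning(f2 <- filter_sites(m2), "removed")
  expect_equal(nrow(f2$sites), 0)
})

test_that("windowed pi matches closed forms and the per-site oracle", {
  # two haploid accessions differing at one site in a 1-Mb window
  m <- toy_matrix(rbind(a1 = c(0L), a2 = c(1L)), pos = 500, ploidy = 1)
  p <- pi_windows(m, window = 1e6, step = 1e6)
  expect_equal(p$value[1], 1e-6)
  # monomorphic matrix: all windows zero
  mm <- toy_matrix(matrix(0L, 4, 10))
  expect_true(all(pi_windows(mm, 1e5, 1e4)$value == 0))
  # oracle equivalence on a random toy matrix, one window spanning all sites
  g <- withr::with_seed(31, matrix(sample(c(0L, 1L, 2L, NA), 200, TRUE,
                                          prob = c(.4, .1, .4, .1)),
                                   nrow = 8))
  m3 <- toy_matrix(g, pos = seq(0, by = 10, length.out = 25))
  p3 <- pi_windows(m3, window = 1000, step = 1000)
  oracle <- sum(vapply(seq_len(25), function(j) oracle_pi_site(g[, j]), 0)) / 1000
  expect_equal(p3$value[1], oracle, tolerance = 1e-12)
})

test_that("windowed F_ST matches limits and the variance-component oracle", {
  grp <- setNames(rep(c("X", "Y"), each = 4), paste0("a", 1:8))
  # groups fixed for alternative alleles: F_ST ~ 1
  g_fix <- rbind(matrix(0L, 4, 20), matrix(2L, 4, 20))
  rownames(g_fix) <- paste0("a", 1:8)
  f1 <- fst_windows(toy_matrix(g_fix, groups = grp), window = 1e4, step = 1e4)
  expect_equal(f1$value[1], 1)
  # both groups sampled from the same frequency vector: F_ST ~ 0
  g_null <- withr::with_seed(35, {
    p <- runif(300, 0.3, 0.7)
    t(vapply(p, function(pp) rbinom(8, 2, pp), integer(8)))
  })
  g_null <- t(g_null)
  rownames(g_null) <- paste0("a", 1:8)
  f0 <- fst_windows(toy_matrix(g_null, pos = seq(0, by = 10,
                                                 length.out = 300),
                               groups = grp),
                    window = 1e4, step = 1e4)
  expect_lt(abs(f0$value[1]), 0.05)
  # 20-site random matrix equals the independent oracle to 1e-10
  g <- withr::with_seed(32, matrix(sample(c(0L, 1L, 2L, NA), 160, TRUE,
                                          prob = c(.45, .1, .4, .05)),
                                   nrow = 8, dimnames = list(paste0("a", 1:8))))
  m <- toy_matrix(g, groups = grp)
  f <- fst_windows(m, window = 1e4, step = 1e4)
  comp <- vapply(seq_len(20), function(j)
    oracle_wc_site(g[1:4, j], g[5:8, j]), numeric(3))
  expect_equal(f$value[1], sum(comp[1, ]) / sum(comp), tolerance = 1e-10)
  expect_error(fst_windows(toy_matrix(g)), "groups")
})

test_that("haplotype diversity matches closed forms and is order-invariant", {
  # all accessions identical
  m_same <- toy_matrix(matrix(2L, 5, 8))
  hv <- hapdiv_windows(m_same, cluster_window = 1e4, avg_window = 1e4,
                       step = 1e4)
  expect_equal(hv$value[1], 0)
  # 4 accessions all distinct: (4/3)(1 - 4/16) = 1
  g4 <- rbind(a = c(0L, 0L), b = c(0L, 2L), c = c(2L, 0L), d = c(2L, 2L))
  hv4 <- hapdiv_windows(toy_matrix(g4), cluster_window = 1e4,
                        avg_window = 1e4, step = 1e4)
  expect_equal(hv4$value[1], 1)
  # invariance to accession order and site order within the window
  g <- withr::with_seed(33, matrix(sample(c(0L, 2L), 60, TRUE), nrow = 6,
                                   dimnames = list(paste0("a", 1:6))))
  m1 <- toy_matrix(g, pos = seq(0, 90, by = 10))
  m2 <- toy_matrix(g[sample(6), sample(10)], pos = seq(0, 90, by = 10))
  h1 <- hapdiv_windows(m1, 1e4, 1e4, 1e4)
  h2 <- hapdiv_windows(m2, 1e4, 1e4, 1e4)
  expect_equal(h1$value, h2$value)
})

test_that("private/common SNP accounting partitions segregating sites", {
  grp <- setNames(rep(c("X", "Y"), c(4, 6)), paste0("a", 1:10))
  g <- withr::with_seed(34, matrix(sample(c(0L, 2L), 300, TRUE,
                                          prob = c(.7, .3)), nrow = 10,
                                   dimnames = list(paste0("a", 1:10))))
  g[5:10, 1] <- 0L; g[5:10, 2] <- 0L  # sites 1-2 private to X (if X varies)
  g[1:4, 1] <- c(0L, 2L, 0L, 2L)
  g[1:4, 2] <- c(0L, 2L, 2L, 2L)
  m <- toy_matrix(g, groups = grp)
  pc <- private_common_snps(m, seed = 3)
  expect_equal(pc$common + pc$private_a + pc$private_b, pc$segregating)
  expect_gte(pc$private_a + pc$private_b, 2)
})

test_that("neighbor joining recovers the additive 3-taxon solution and group cuts", {
  # distances (2, 3, 3)/10: unique additive branch lengths 0.1, 0.1, 0.2
  g <- rbind(a = rep(0L, 10), b = rep(0L, 10), c = rep(0L, 10))
  g["b", 1:2] <- 2L          # d(a,b) = 2/10
  g["c", c(1, 3, 4)] <- 2L   # d(a,c) = 3/10, d(b,c) = 3/10
  m <- toy_matrix(g)
  nj <- nj_groups(m)
  bl <- setNames(nj$tree$edge.length[nj$tree$edge[, 2] <= 3],
                 nj$tree$tip.label[nj$tree$edge[nj$tree$edge[, 2] <= 3, 2]])
  expect_equal(unname(bl[c("a", "b", "c")]), c(0.1, 0.1, 0.2),
               tolerance = 1e-9)
  # two internally identical groups are separated exactly
  g2 <- rbind(matrix(0L, 4, 12), matrix(2L, 5, 12))
  rownames(g2) <- paste0("a", 1:9)
  cut <- nj_groups(toy_matrix(g2))$two_cut
  expect_equal(length(unique(cut[paste0("a", 1:4)])), 1)
  expect_equal(length(unique(cut[paste0("a", 5:9)])), 1)
  expect_false(cut[["a1"]] == cut[["a9"]])
})

test_that("breakpoint genotyping follows the unanimity and support rules", {
  mk_pairs <- function(n_conc, n_disc, bp = 5000) {
    conc <- if (n_conc > 0) tibble::tibble(
      pair_id = paste0("c", seq_len(n_conc)), sv_id = "sv", chrom = "c1",
      pos1 = bp - 2500, strand1 = "+", pos2 = bp + 2200, strand2 = "-")
      else NULL
    disc <- if (n_disc > 0) tibble::tibble(
      pair_id = paste0("d", seq_len(n_disc)), sv_id = "sv", chrom = "c1",
      pos1 = bp - 2500, strand1 = "+", pos2 = bp + 60000, strand2 = "+")
      else NULL
    dplyr::bind_rows(conc, disc)
  }
  bps <- tibble::tibble(chrom = "c1", pos = 5000, sv_id = "sv")
  call <- function(p) genotype_breakpoints(p, bps, insert_mean = 5000,
                                           insert_sd = 400)$allele
  expect_equal(call(mk_pairs(10, 0)), "ref_like")
  expect_equal(call(mk_pairs(0, 10)), "alt_like")
  expect_equal(call(mk_pairs(1, 0)), "unassigned") # below support floor
  expect_equal(call(mk_pairs(5, 1)), "unassigned") # not unanimous
  g <- genome_set(c(c1 = strrep("ACGT", 100)), "ref")
  expect_error(
    genotype_breakpoints(mk_pairs(3, 0),
                         tibble::tibble(chrom = "cX", pos = 10, sv_id = "s"),
                         genome = g),
    "absent from reference")
  cmb <- combine_breakpoint_calls(tibble::tibble(
    accession = "x", sv_id = c("sv1", "sv3"),
    allele = c("ref_like", "alt_like"),
    n_span_concordant = c(5, 0), n_span_discordant = c(0, 5)))
  expect_equal(cmb$allele, "conflict")
})

test_that("simulated panels genotype correctly at 10x spanning coverage", {
  g <- genome_set(c(c1 = withr::with_seed(4, paste(
    sample(c("A", "C", "G", "T"), 2e5, TRUE), collapse = ""))), "ref")
  bps <- tibble::tibble(chrom = "c1", pos = c(6e4, 1.4e5),
                        sv_id = c("svL", "svR"))
  inv <- tibble::tibble(chrom = "c1", start = 6e4, end = 1.4e5)
  panel <- dplyr::bind_rows(lapply(1:20, function(i) {
    alt <- i %% 2 == 0
    p <- simulate_mate_pairs(g, bps, n_pairs = 10,
                             inversions = if (alt) inv else NULL,
                             seed = 100 + i)
    p$accession <- sprintf("%s%02d", if (alt) "alt" else "ref", i)
    p
  }))
  calls <- genotype_breakpoints(panel, bps)
  truth <- ifelse(grepl("^alt", calls$accession), "alt_like", "ref_like")
  assigned <- calls$allele != "unassigned"
  expect_equal(sum(calls$allele[assigned] != truth[assigned]), 0)
  expect_gte(mean(calls$allele == truth), 0.95)
})

test_that("recombination windows pro-rate the map and report mean cM/bin", {
  m1 <- simulate_ril_map(chrom_len = 1e7, n_bins = 50, baseline_rate = 1)
  r <- recomb_windows(m1, window = 1e6, step = 5e5)
  inner <- r$windows$end <= 1e7
  expect_true(all(abs(r$windows$value[inner] - 1) < 1e-9))
  # printed-totals arithmetic: 3370.91 cM over 4482 bins -> 0.75 cM/bin
  m2 <- simulate_ril_map(chrom_len = 3370.91e6, n_bins = 4482,
                         baseline_rate = 1)
  expect_equal(round(recomb_windows(m2)$mean_cm_per_bin, 2), 0.75)
  # non-monotone map is a hard error naming the bin
  bad <- tibble::tibble(chromosome = "c1", position = c(0, 100, 200),
                        cm = c(0, 2, 1))
  expect_error(recomb_windows(bad), "non-monotone")
})
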