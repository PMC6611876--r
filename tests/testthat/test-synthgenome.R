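test_that("zero rates and empty specs give identical genomes and empty truth", {
  sim <- simulate_genome_pair(n_chrom = 1, chrom_len = 5e4, snp_rate = 0,
                              indel_rate = 0, seed = 3)
  expect_equal(unclass(sim$genome_a)[["chr1"]], unclass(sim$genome_b)[["chr1"]])
  expect_equal(nrow(sim$truth$engineered_svs), 0)
  expect_equal(nrow(sim$truth$planted_variants), 0)
})

test_that("an engineered inversion is the exact reverse complement in B", {
  sv <- list(sv_inversion("chr1", 3e5, 3.5e5))
  sim <- simulate_genome_pair(n_chrom = 1, chrom_len = 1e6, snp_rate = 0,
                              indel_rate = 0, sv_spec = sv, seed = 4)
  tr <- sim$truth$engineered_svs
  seg_a <- genome_slice(sim$genome_a, "chr1", 3e5, 3.5e5)
  seg_b <- genome_slice(sim$genome_b, "chr1", tr$qry_start, tr$qry_end)
  expect_identical(seg_b, revcomp(seg_a))
  # flanks untouched
  expect_identical(genome_slice(sim$genome_a, "chr1", 0, 3e5),
                   genome_slice(sim$genome_b, "chr1", 0, 3e5))
})

test_that("planted SNP counts follow the binomial expectation", {
  sim <- simulate_genome_pair(n_chrom = 1, chrom_len = 1e6, snp_rate = 1e-3,
                              indel_rate = 0, seed = 5)
  n <- sum(sim$truth$planted_variants$kind == "snp")
  expect_gt(n, 1000 - 95) # 3 sigma of Binomial(1e6, 1e-3)
  expect_lt(n, 1000 + 95)
  # every planted SNP really differs between the genomes at its position
  v <- sim$truth$planted_variants[sim$truth$planted_variants$kind == "snp", ]
  sel <- sample(seq_len(nrow(v)), 50)
  for (i in sel) {
    expect_identical(genome_slice(sim$genome_a, "chr1", v$ref_pos[i],
                                  v$ref_pos[i] + 1), v$ref_allele[i])
    expect_identical(genome_slice(sim$genome_b, "chr1", v$ref_pos[i],
                                  v$ref_pos[i] + 1), v$alt_allele[i])
  }
})

test_that("same seed gives byte-identical output; overlapping spans error", {
  s1 <- simulate_genome_pair(n_chrom = 1, chrom_len = 5e4, snp_rate = 1e-3,
                             indel_rate = 1e-4, seed = 9)
  s2 <- simulate_genome_pair(n_chrom = 1, chrom_len = 5e4, snp_rate = 1e-3,
                             indel_rate = 1e-4, seed = 9)
  expect_identical(unclass(s1$genome_b)[["chr1"]], unclass(s2$genome_b)[["chr1"]])
  expect_identical(s1$truth$planted_variants, s2$truth$planted_variants)
  expect_error(
    simulate_genome_pair(n_chrom = 1, chrom_len = 1e5,
                         sv_spec = list(sv_inversion("chr1", 1e4, 3e4),
                                        sv_inversion("chr1", 2e4, 4e4)),
                         seed = 1),
    "overlap")
  expect_error(
    simulate_genome_pair(n_chrom = 1, chrom_len = 1e5,
                         sv_spec = list(sv_inversion("chr1", 100, 5e4)),
                         seed = 1),
    "flank")
})

test_that("panel null model has near-zero differentiation", {
  ps <- simulate_panel(n_ref_like = 30, n_alt_like = 30, n_sites = 400,
                       group_private_fraction = 0,
                       inside_inversion_diversity_scale = 1, seed = 11)
  f <- fst_windows(ps$panel, window = 5e7, step = 5e7)
  expect_lt(abs(mean(f$value, na.rm = TRUE)), 0.02)
})

test_that("diversity scale 0 makes inside-inversion sites monomorphic per group", {
  ps <- simulate_panel(n_ref_like = 10, n_alt_like = 12, n_sites = 300,
                       group_private_fraction = 0,
                       inside_inversion_diversity_scale = 0,
                       het_rate = 0, miss_rate = 0, seed = 12)
  g <- ps$panel$genotypes
  inside <- ps$truth$inside
  for (grp in unique(ps$truth$groups)) {
    rows <- names(ps$truth$groups)[ps$truth$groups == grp]
    sub <- g[rows, inside, drop = FALSE]
    expect_true(all(apply(sub, 2, function(x) length(unique(x)) == 1)))
  }
})

test_that("mate pairs are concordant from the reference haplotype and discordant across inverted junctions", {
  g <- genome_set(c(c1 = strrep("ACGT", 25000)), "ref") # 1e5 bp
  bps <- tibble::tibble(chrom = "c1", pos = c(3e4, 7e4),
                        sv_id = c("l", "r"))
  ref_p <- simulate_mate_pairs(g, bps, n_pairs = 15, insert_mean = 4000,
                               insert_sd = 300, read_len = 100, seed = 2)
  expect_true(all(ref_p$strand1 == "+" & ref_p$strand2 == "-"))
  sep <- ref_p$pos2 - ref_p$pos1
  expect_true(all(abs(sep + 100 - 4000) <= 4 * 300))

  inv <- tibble::tibble(chrom = "c1", start = 3e4, end = 7e4)
  alt_p <- simulate_mate_pairs(g, bps, n_pairs = 15, insert_mean = 4000,
                               insert_sd = 300, read_len = 100,
                               inversions = inv, seed = 3)
  span_l <- pmin(alt_p$pos1, alt_p$pos2) < 3e4 &
    pmax(alt_p$pos1, alt_p$pos2) > 3e4
  expect_true(all(alt_p$strand1[span_l] == alt_p$strand2[span_l] |
                    abs(pmax(alt_p$pos1, alt_p$pos2)[span_l] -
                          pmin(alt_p$pos1, alt_p$pos2)[span_l]) > 4000 + 1200))
  expect_equal(nrow(simulate_mate_pairs(g, bps, n_pairs = 0, seed = 1)), 0)
})

test_that("RIL maps are monotone with exact totals and suppression", {
  m1 <- simulate_ril_map(chrom_len = 1e7, n_bins = 100, baseline_rate = 1)
  expect_false(is.unsorted(m1$cm))
  expect_equal(max(m1$cm), 10) # 1 cM/Mb over 10 Mb
  # bins every 1e5 bp align with the span edges, so the gain is exactly 0
  m0 <- simulate_ril_map(chrom_len = 1e7, n_bins = 101, baseline_rate = 1,
                         suppressed_span = c(4e6, 6e6),
                         suppression_factor = 0)
  gained <- m0$cm[m0$position == 6e6] - m0$cm[m0$position == 4e6]
  expect_equal(gained, 0)
  # factor 1 leaves the map uniform
  mu <- simulate_ril_map(chrom_len = 1e7, n_bins = 100, baseline_rate = 1,
                         suppressed_span = c(4e6, 6e6),
                         suppression_factor = 1)
  expect_equal(mu$cm, m1$cm)
})
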