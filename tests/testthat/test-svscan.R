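# shared medium-size fixture: 2 x 2 Mb pair with one event of each kind
svscan_fixture <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      svs <- list(sv_inversion("chr1", 6e5, 7e5),
                  sv_intra_translocation("chr1", 1.2e6, 1.24e6, 1.7e6),
                  sv_inter_translocation("chr2", 1.0e6, 1.04e6, "chr1", 3e5))
      sim <- simulate_genome_pair(n_chrom = 2, chrom_len = 2e6,
                                  snp_rate = 5e-3, indel_rate = 2e-4,
                                  sv_spec = svs, seed = 42)
      blocks <- seed_and_chain(sim$genome_a, sim$genome_b)
      o2o <- filter_one_to_one(blocks)
      part <- partition_allelic(o2o, filter_global(o2o))
      val <<- list(sim = sim, o2o = o2o, part = part)
    }
    val
  }
})

test_that("collinear SV-free pairs partition as fully allelic", {
  sim <- simulate_genome_pair(n_chrom = 1, chrom_len = 1e5, snp_rate = 2e-3,
                              indel_rate = 0, seed = 13)
  o2o <- filter_one_to_one(seed_and_chain(sim$genome_a, sim$genome_b))
  part <- partition_allelic(o2o, filter_global(o2o))
  expect_equal(nrow(part$nonallelic), 0)
  expect_equal(nrow(part$allelic), nrow(o2o))
  # degenerate: empty global chain pushes everything non-allelic
  part0 <- partition_allelic(o2o, o2o[0, ])
  expect_equal(nrow(part0$allelic), 0)
})

test_that("engineered rearrangements are classified with their true kind and span", {
  fx <- svscan_fixture()
  regs <- merge_rearranged(classify_rearrangements(fx$part), join_gap = 5e4)
  truth <- fx$sim$truth$engineered_svs
  expect_equal(nrow(regs), 3)
  for (i in seq_len(nrow(truth))) {
    hit <- regs[regs$kind == truth$kind[i] &
                  regs$ref_chrom == truth$ref_chrom[i], ]
    expect_equal(nrow(hit), 1)
    expect_lt(abs(hit$ref_start - truth$ref_start[i]), 22)
    expect_lt(abs(hit$ref_end - truth$ref_end[i]), 22)
    expect_equal(hit$qry_chrom, truth$qry_chrom[i])
  }
  # inversion span recovery >= 90%
  inv_t <- truth[truth$kind == "inversion", ]
  inv_r <- regs[regs$kind == "inversion", ]
  ov <- min(inv_r$ref_end, inv_t$ref_end) - max(inv_r$ref_start, inv_t$ref_start)
  expect_gt(ov / (inv_t$ref_end - inv_t$ref_start), 0.9)
})

test_that("region merging respects kind, gap threshold and monotonicity", {
  r <- tibble::tibble(
    kind = c("inversion", "inversion", "intra_translocation"),
    ref_chrom = "c1", ref_start = c(0, 15000, 40000),
    ref_end = c(10000, 25000, 50000), qry_chrom = "c1",
    qry_start = c(0, 15000, 70000), qry_end = c(10000, 25000, 80000),
    total_length = c(10000, 10000, 10000), n_blocks = 1L,
    confidence = "high")
  m <- merge_rearranged(r, join_gap = 5e4)
  expect_equal(nrow(m), 2) # the two inversions join; kinds never mix
  inv <- m[m$kind == "inversion", ]
  expect_equal(inv$ref_start, 0)
  expect_equal(inv$ref_end, 25000)
  expect_equal(inv$total_length, 20000)
  expect_equal(nrow(merge_rearranged(r, join_gap = 0)), 3) # identity at 0
  # counts monotone non-increasing in join_gap
  gaps <- c(0, 1000, 5000, 20000, 1e5)
  counts <- vapply(gaps, function(g) nrow(merge_rearranged(r, g)), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("non-allelic length is invariant to chromosome input order", {
  fx <- svscan_fixture()
  sim <- fx$sim
  rev_a <- sim$genome_a[rev(names(sim$genome_a))]
  rev_b <- sim$genome_b[rev(names(sim$genome_b))]
  o2o2 <- filter_one_to_one(seed_and_chain(rev_a, rev_b))
  part2 <- partition_allelic(o2o2, filter_global(o2o2))
  len <- function(p) sum(p$nonallelic$ref_end - p$nonallelic$ref_start)
  expect_equal(len(part2), len(fx$part))
})

test_that("variant calls with buffer 0 equal the positional diff oracle", {
  sim <- simulate_genome_pair(n_chrom = 1, chrom_len = 3e5, snp_rate = 2e-3,
                              indel_rate = 0, seed = 17)
  o2o <- filter_one_to_one(seed_and_chain(sim$genome_a, sim$genome_b))
  part <- partition_allelic(o2o, filter_global(o2o))
  v <- call_variants(part$allelic, buffer_min = 0)
  a <- strsplit(unclass(sim$genome_a)[["chr1"]], "")[[1]]
  b <- strsplit(unclass(sim$genome_b)[["chr1"]], "")[[1]]
  oracle <- which(a != b) - 1 # SNP-only divergence: positional diff
  expect_equal(sort(v$ref_pos[v$kind == "snp"]), as.double(sort(oracle)))
  expect_equal(v$alt_allele[order(v$ref_pos)], b[sort(oracle) + 1])
})

test_that("the buffering rule suppresses close and edge variants", {
  # hand-built alignment: two mismatches 10 bp apart, one isolated
  ref <- paste0(strrep("A", 40), "C", strrep("A", 9), "C", strrep("A", 60),
                "G", strrep("A", 40))
  qry <- gsub("C", "T", ref)
  qry <- sub("G", "C", qry)
  blk <- toy_block(0, nchar(ref), 0, nchar(ref), ident = 0.98)
  blk$ref_aln <- ref
  blk$qry_aln <- qry
  v0 <- call_variants(blk, buffer_min = 0)
  expect_equal(nrow(v0), 3)
  v20 <- call_variants(blk, buffer_min = 20)
  expect_equal(nrow(v20), 1) # the 10-bp-apart pair is gone
  expect_equal(v20$ref_pos, 111)
  expect_true(all(v20$buffer_distance >= 20))
  # missing base alignment is a hard error naming the block
  blk2 <- toy_block(0, 100, 0, 100)
  expect_error(call_variants(blk2), "no base alignment")
})

test_that("identical genomes yield zero variants and empty rearrangements", {
  sim <- simulate_genome_pair(n_chrom = 1, chrom_len = 5e4, snp_rate = 0,
                              indel_rate = 0, seed = 19)
  o2o <- filter_one_to_one(seed_and_chain(sim$genome_a, sim$genome_b))
  part <- partition_allelic(o2o, filter_global(o2o))
  expect_equal(nrow(call_variants(part$allelic)), 0)
  expect_equal(nrow(classify_rearrangements(part)), 0)
})
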