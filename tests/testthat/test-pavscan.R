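pav_fixture <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      pavs <- list(pav_event("B", "chr1", 6e5, 5000),
                   pav_event("A", "chr1", 1.4e6, 3000))
      sim <- simulate_genome_pair(n_chrom = 1, chrom_len = 2e6,
                                  snp_rate = 5e-3, indel_rate = 1e-4,
                                  pav_spec = pavs, seed = 23)
      run <- function(ref, qry) {
        o2o <- filter_one_to_one(seed_and_chain(ref, qry))
        partition_allelic(o2o, filter_global(o2o))
      }
      val <<- list(sim = sim, part_b = run(sim$genome_a, sim$genome_b),
                   part_a = run(sim$genome_b, sim$genome_a))
    }
    val
  }
})

test_that("identical genomes produce no presence regions", {
  sim <- simulate_genome_pair(n_chrom = 1, chrom_len = 5e4, snp_rate = 0,
                              indel_rate = 0, seed = 24)
  o2o <- filter_one_to_one(seed_and_chain(sim$genome_a, sim$genome_b))
  part <- partition_allelic(o2o, filter_global(o2o))
  expect_equal(nrow(categorize_unaligned(part, sim$genome_b)), 0)
})

test_that("engineered insertions are recovered as GAP regions with >= 90% reciprocal overlap", {
  fx <- pav_fixture()
  truth <- fx$sim$truth$engineered_pavs
  reg_b <- categorize_unaligned(fx$part_b, fx$sim$genome_b)
  tb <- truth[truth$carrier == "B", ]
  hit <- reg_b[reg_b$start < tb$b_end & reg_b$end > tb$b_start, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$category, "GAP")
  ov <- min(hit$end, tb$b_end) - max(hit$start, tb$b_start)
  expect_gt(ov / (tb$b_end - tb$b_start), 0.9)
  expect_gt(ov / (hit$end - hit$start), 0.9)
  # symmetry: the A-carrier deletion appears as A's presence region
  reg_a <- categorize_unaligned(fx$part_a, fx$sim$genome_a)
  ta <- truth[truth$carrier == "A", ]
  hit_a <- reg_a[reg_a$start < ta$a_end & reg_a$end > ta$a_start, ]
  expect_equal(nrow(hit_a), 1)
  ov_a <- min(hit_a$end, ta$a_end) - max(hit_a$start, ta$a_start)
  expect_gt(ov_a / (ta$a_end - ta$a_start), 0.9)
})

test_that("the rejection filter applies the coverage > 50% AND identity > 90% rule", {
  fx <- pav_fixture()
  reg_b <- categorize_unaligned(fx$part_b, fx$sim$genome_b)
  f <- filter_pav(reg_b, fx$sim$genome_b, fx$sim$genome_a)
  tb <- fx$sim$truth$engineered_pavs[fx$sim$truth$engineered_pavs$carrier == "B", ]
  novel <- f[f$start < tb$b_end & f$end > tb$b_start, ]
  expect_true(novel$retained) # random insert absent from counterpart
  expect_lt(novel$counterpart_coverage, 0.5)
  # a region occurring verbatim in the counterpart is rejected
  seq <- genome_slice(fx$sim$genome_a, "chr1", 1e5, 1.02e5)
  carrier <- genome_set(c(cx = seq), "carrier")
  reg <- tibble::tibble(carrier = "carrier", chromosome = "cx", start = 0,
                        end = 2000, category = "BRK",
                        counterpart_coverage = NA_real_,
                        counterpart_identity = NA_real_, retained = NA)
  fv <- filter_pav(reg, carrier, fx$sim$genome_a)
  expect_equal(fv$counterpart_coverage, 1)
  expect_equal(fv$counterpart_identity, 1)
  expect_false(fv$retained)
  # retained invariant: retained implies NOT(cov > .5 AND ident > .9)
  all_f <- dplyr::bind_rows(f, fv)
  expect_true(all(!all_f$retained |
                    !(all_f$counterpart_coverage > 0.5 &
                        all_f$counterpart_identity > 0.9)))
  # high identity over only 40% of the length: coverage fails, retained
  part_seq <- paste0(genome_slice(fx$sim$genome_a, "chr1", 2e5, 2.008e5),
                     withr::with_seed(5, paste(sample(c("A", "C", "G", "T"),
                                                      1200, TRUE),
                                               collapse = "")))
  carrier2 <- genome_set(c(cy = part_seq), "carrier2")
  reg2 <- tibble::tibble(carrier = "carrier2", chromosome = "cy", start = 0,
                         end = nchar(part_seq), category = "BRK",
                         counterpart_coverage = NA_real_,
                         counterpart_identity = NA_real_, retained = NA)
  f2 <- filter_pav(reg2, carrier2, fx$sim$genome_a)
  expect_lt(f2$counterpart_coverage, 0.5)
  expect_true(f2$retained)
  # all-N region is dropped and flagged
  carrier3 <- genome_set(c(cz = strrep("N", 500)), "carrier3")
  reg3 <- tibble::tibble(carrier = "carrier3", chromosome = "cz", start = 0,
                         end = 500, category = "BRK",
                         counterpart_coverage = NA_real_,
                         counterpart_identity = NA_real_, retained = NA)
  f3 <- filter_pav(reg3, carrier3, fx$sim$genome_a)
  expect_false(f3$retained)
  expect_match(f3$category, "all_N")
})

test_that("retained presence spans are disjoint", {
  fx <- pav_fixture()
  f <- filter_pav(categorize_unaligned(fx$part_b, fx$sim$genome_b),
                  fx$sim$genome_b, fx$sim$genome_a)
  kept <- f[f$retained, ]
  if (nrow(kept) > 1) {
    kept <- kept[order(kept$chromosome, kept$start), ]
    same <- kept$chromosome[-1] == kept$chromosome[-nrow(kept)]
    expect_true(all(!same | kept$start[-1] >= kept$end[-nrow(kept)]))
  }
  succeed()
})

test_that("PAV gene membership follows the CDS-fraction threshold", {
  pav <- tibble::tibble(carrier = "B", chromosome = "c1", start = 1000,
                        end = 5000, category = "GAP",
                        counterpart_coverage = 0, counterpart_identity = 0,
                        retained = TRUE)
  mk_gene <- function(id, s, e) tibble::tibble(
    gene_id = id, chromosome = "c1", strand = "+",
    exons = list(cbind(start = s, end = e)),
    cds = list(cbind(start = s, end = e)))
  genes <- dplyr::bind_rows(
    mk_gene("inside", 2000, 3000),    # fully inside
    mk_gene("edge10", 4900, 5900),    # 10% CDS overlap
    mk_gene("outside", 8000, 9000))
  expect_equal(pav_genes(pav, genes), "inside")
  expect_equal(pav_genes(pav, genes, min_cds_frac = 0.05),
               c("inside", "edge10"))
})
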