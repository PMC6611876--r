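test_that("single constructed lesions receive their expected label and category", {
  cases <- list(
    list(effect = "none", label = "no_genic_variation",
         category = "structurally_conserved"),
    list(effect = "upstream_snp", label = "no_cds_intron_variation",
         category = "structurally_conserved"),
    list(effect = "same_sense", label = "same_sense",
         category = "structurally_conserved"),
    list(effect = "missense", label = "missense",
         category = "structurally_conserved"),
    list(effect = "inframe_indel", label = "inframe_indel",
         category = "structurally_conserved"),
    list(effect = "frameshift_indel", label = "frameshift_indel",
         category = "large_effect"),
    list(effect = "start_codon", label = "start_codon",
         category = "large_effect"),
    list(effect = "stop_codon", label = "stop_codon",
         category = "large_effect"),
    list(effect = "splice_donor", label = "splice_donor",
         category = "large_effect"),
    list(effect = "splice_acceptor", label = "splice_acceptor",
         category = "large_effect"),
    list(effect = "cds_missing", label = "cds_missing",
         category = "large_structural_variation"),
    list(effect = "exon_count_change", label = "exon_count_change",
         category = "large_structural_variation"))
  for (cs in cases) {
    gp <- simulate_gene_pair(cs$effect, seed = 7)
    call <- call_ortho_pair(gp$gene_a, gp$genome_a, gp$gene_b, gp$genome_b,
                            flank = 300)
    expect_true(cs$label %in% call$effects[[1]],
                label = paste(cs$effect, "->", cs$label))
    expect_equal(call$category, cs$category, label = cs$effect)
  }
  # upstream-only change: not free of genic variation
  gp <- simulate_gene_pair("upstream_snp", seed = 8)
  eff <- call_ortho_pair(gp$gene_a, gp$genome_a, gp$gene_b, gp$genome_b,
                         flank = 300)$effects[[1]]
  expect_false("no_genic_variation" %in% eff)
  expect_true("no_cds_intron_variation" %in% eff)
})

test_that("effect annotation agrees with brute-force translation oracles", {
  mutable <- c("same_sense", "missense", "inframe_indel", "frameshift_indel",
               "start_codon", "stop_codon", "splice_donor", "splice_acceptor")
  n_per <- 63 # ~500 random pairs across the mutation classes
  for (eff in mutable) {
    for (seed in seq_len(n_per)) {
      gp <- simulate_gene_pair(eff, n_exons = 2 + seed %% 3,
                               exon_codons = 20 + seed %% 31, seed = seed)
      call <- call_ortho_pair(gp$gene_a, gp$genome_a, gp$gene_b,
                              gp$genome_b, flank = 200)
      labels <- call$effects[[1]]
      cds_a <- oracle_cds(gp$gene_a, gp$genome_a)
      cds_b <- oracle_cds(gp$gene_b, gp$genome_b)
      prot_a <- oracle_translate(cds_a); prot_b <- oracle_translate(cds_b)
      # oracle facts derived only from model + sequence, no alignment
      if (eff %in% c("inframe_indel", "frameshift_indel")) {
        d <- abs(nchar(cds_a) - nchar(cds_b))
        expected <- if (d %% 3 == 0) "inframe_indel" else "frameshift_indel"
        expect_true(expected %in% labels, label = paste(eff, seed))
      }
      if (eff == "same_sense") {
        expect_identical(prot_a, prot_b)
        expect_true("same_sense" %in% labels, label = paste(eff, seed))
      }
      if (eff == "missense") {
        expect_false(identical(prot_a, prot_b))
        expect_true("missense" %in% labels, label = paste(eff, seed))
      }
      if (eff == "start_codon") {
        expect_false(substr(cds_b, 1, 3) == "ATG")
        expect_true("start_codon" %in% labels, label = paste(eff, seed))
      }
      if (eff == "stop_codon") {
        body_b <- substr(prot_b, 1, nchar(prot_b) - 1)
        lost <- substr(prot_b, nchar(prot_b), nchar(prot_b)) != "*"
        expect_true(grepl("[*]", body_b) || lost)
        expect_true("stop_codon" %in% labels, label = paste(eff, seed))
      }
      if (eff %in% c("splice_donor", "splice_acceptor")) {
        expect_true(eff %in% labels, label = paste(eff, seed))
      }
      expect_equal(call$category, classify_pair(labels))
    }
  }
})

test_that("classification precedence follows structural > large-effect > conserved", {
  expect_equal(classify_pair(c("missense")), "structurally_conserved")
  expect_equal(classify_pair(c("inframe_indel", "same_sense")),
               "structurally_conserved")
  expect_equal(classify_pair(c("frameshift_indel", "missense")),
               "large_effect")
  expect_equal(classify_pair(c("cds_missing")), "large_structural_variation")
  expect_equal(classify_pair(c("frameshift_indel", "exon_count_change")),
               "large_structural_variation")
  expect_equal(classify_pair(character(0)), "structurally_conserved")
})

test_that("the report partitions calls and reproduces column percentages", {
  effects <- c("none", "missense", "missense", "frameshift_indel",
               "start_codon", "cds_missing", "same_sense", "splice_donor")
  calls <- dplyr::bind_rows(lapply(seq_along(effects), function(i) {
    gp <- simulate_gene_pair(effects[i], seed = 100 + i)
    call_ortho_pair(gp$gene_a, gp$genome_a, gp$gene_b, gp$genome_b,
                    flank = 200, syntenic = i %% 2 == 0, subgenome = "At")
  }))
  rep <- tabulate_ortho(calls)
  for (sy in unique(rep$syntenic)) {
    r <- rep[rep$syntenic == sy, ]
    total <- r$n[r$row == "total"]
    cats <- r$n[r$row %in% c("structurally_conserved", "large_effect",
                             "large_structural_variation")]
    expect_equal(sum(cats), total) # the three categories partition
    expect_equal(r$percent[r$row == "total"], 100)
    expect_equal(r$percent, ortho_percent(r$n, total))
  }
  # single call: 100.00%
  one <- tabulate_ortho(calls[1, ])
  expect_equal(one$percent[one$row == "total"], 100)
  expect_equal(nrow(tabulate_ortho(calls[0, ])), 0)
})

test_that("percentages re-derived from printed count/total pairs are exact", {
  expect_equal(ortho_percent(27428, 34243), 80.10)
  expect_equal(ortho_percent(4630, 34243), 13.52)
  expect_equal(ortho_percent(1, 1), 100.00)
})
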