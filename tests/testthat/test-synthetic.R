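# Synthetic-data generators: determinism, rate-zero behaviour, argument
# validation, ground-truth closure.

test_that("generators are deterministic for a fixed seed", {
  a <- generate_gene_catalog(2, 30, 10, 0.2, 0.2, seed = 1)
  b <- generate_gene_catalog(2, 30, 10, 0.2, 0.2, seed = 1)
  expect_identical(a, b)
  expect_identical(generate_copy_matrix(9, 50, 0.1, 8, seed = 3),
                   generate_copy_matrix(9, 50, 0.1, 8, seed = 3))
  expect_identical(generate_strain_matrix(20, 50, 0.7, 0, c(10, 10), seed = 5),
                   generate_strain_matrix(20, 50, 0.7, 0, c(10, 10), seed = 5))
  cds <- generate_cds_set(5, seed = 2)
  expect_identical(generate_variants(cds, 10, 0.02, 0.003, seed = 4),
                   generate_variants(cds, 10, 0.02, 0.003, seed = 4))
  pp <- list(g1 = c(benthic = 1, planktonic = 0.1))
  expect_identical(generate_hit_table(10, pp, seed = 6),
                   generate_hit_table(10, pp, seed = 6))
  des <- c(c1 = 2L, c2 = 2L)
  pu <- data.frame(family = "F0001", condition = "c1", log2fc = 2)
  expect_identical(generate_expression(10, des, pu, seed = 7),
                   generate_expression(10, des, pu, seed = 7))
})

test_that("serialized catalogs are byte-identical across repeated calls", {
  f1 <- tempfile(fileext = ".gff3"); f2 <- tempfile(fileext = ".gff3")
  write_catalog_gff3(generate_gene_catalog(2, 15, 6, 0.3, 0.3, seed = 9)$catalog, f1)
  write_catalog_gff3(generate_gene_catalog(2, 15, 6, 0.3, 0.3, seed = 9)$catalog, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("rate-zero catalog plants nothing and leaves no near tandem pair", {
  res <- generate_gene_catalog(1, 10, 5, 0, 0, seed = 7)
  expect_length(res$truth$tandem_arrays, 0)
  expect_length(res$truth$block_pairs, 0)
  g <- res$catalog$genes
  for (i in seq_len(nrow(g))) for (j in seq_len(nrow(g))) {
    if (i < j && g$scaffold[i] == g$scaffold[j] &&
        abs(g$rank[i] - g$rank[j]) <= 15)
      expect_false(identical(g$family[i], g$family[j]))
  }
})

test_that("catalog truth identifiers resolve against the emitted catalog", {
  res <- generate_gene_catalog(3, 40, 15, 0.25, 0.3, seed = 11)
  ids <- res$catalog$genes$gene
  for (arr in res$truth$tandem_arrays) {
    expect_true(all(arr %in% ids))
    expect_gte(length(arr), 2)
    sc <- unique(res$catalog$genes$scaffold[match(arr, ids)])
    expect_length(sc, 1)
  }
  for (bp in res$truth$block_pairs) {
    expect_gte(nrow(bp), 3)
    expect_true(all(c(bp$gene_a, bp$gene_b) %in% ids))
  }
})

test_that("copy-matrix generator validates arguments and honours rates", {
  expect_error(generate_copy_matrix(2, 10, 0.1, 8, seed = 1), "3")
  expect_error(generate_copy_matrix(9, 10, 0.1, -4, seed = 1), ">= 3")
  res0 <- generate_copy_matrix(9, 100, 0, 8, seed = 2)
  expect_length(res0$truth$expanded_family_ids, 0)
  res <- generate_copy_matrix(9, 200, 0.1, 8, seed = 3)
  expect_true(all(res$matrix >= 1))
  expect_true(all(res$truth$expanded_family_ids %in% rownames(res$matrix)))
})

test_that("strain-matrix generator validates fractions and clade sizes", {
  expect_error(generate_strain_matrix(10, 50, 0.8, 0.3, c(5, 5), seed = 1),
               "<= 1")
  expect_error(generate_strain_matrix(10, 50, 0.5, 0, c(4, 4), seed = 1),
               "sum")
  res <- generate_strain_matrix(10, 40, 1, 0, c(5, 5), seed = 2)
  pc <- classify_pan_genes(call_presence(res$coverage))
  expect_true(all(pc$genes$class == "core"))
})

test_that("variant generator honours zero targets and rejects bad input", {
  cds <- generate_cds_set(3, seed = 1)
  expect_equal(nrow(generate_variants(cds, 10, 0, 0, seed = 1)), 0)
  expect_error(generate_variants(cds, 1, 0.01, 0.01, seed = 1), ">= 2")
  bad <- c(gX = "ATGTAAAAATTT")  # TAA at codon 2 is internal
  expect_error(generate_variants(bad, 10, 0.01, 0.01, seed = 1),
               class = "internal_stop_error")
})

test_that("variant generator places SNPs only at positions of the dosed class", {
  cds <- generate_cds_set(10, seed = 3)
  vt <- generate_variants(cds, 20, 0.02, 0.005, seed = 3)
  for (i in seq_len(nrow(vt))) {
    ch <- benthoscan:::cds_change_classes(cds[[vt$gene[i]]])
    row <- ch[ch$pos == vt$pos[i] & ch$alt == vt$alt[i], ]
    expect_equal(row$effect, vt$effect[i])
    expect_equal(row$ref, vt$ref[i])
  }
  expect_true(all(vt$alt_count > 0 & vt$alt_count < vt$n_chrom))
})

test_that("hit-table generator gives saturated scores for probability one", {
  ht <- generate_hit_table(5, list(all = c(pennate = 1, centric = 1,
                                           benthic = 1, planktonic = 1,
                                           raphid = 1, araphid = 1)),
                           default_prob = 1, seed = 1)
  sv <- signature_values(clade_scores(ht))
  for (cl in c("pennate", "centric", "raphid", "araphid", "benthic",
               "planktonic"))
    expect_true(all(sv[[cl]] == 1))
  for (ax in c("pennate_signature", "raphid_signature", "benthic_signature"))
    expect_true(all(sv[[ax]] == 0))
  expect_error(generate_hit_table(5, list(a = c(benthic = 1.5)), seed = 1),
               "\\[0, 1\\]")
})

test_that("expression generator thresholds planted effects into DE calls", {
  des <- c(a = 2L, b = 2L, c = 2L)
  empty <- generate_expression(12, des, data.frame(family = character(),
                                                   condition = character(),
                                                   log2fc = numeric()),
                               seed = 1)
  expect_equal(nrow(empty$de_calls), 0)
  # |log2fc| <= 1 planted effects are not called
  weak <- generate_expression(12, des,
                              data.frame(family = "F0001", condition = "a",
                                         log2fc = 0.8), seed = 1)
  expect_equal(nrow(weak$de_calls), 0)
  strong <- generate_expression(12, des,
                                data.frame(family = "F0001", condition = "a",
                                           log2fc = -2), seed = 1)
  expect_true(all(strong$de_calls$direction == "down"))
  expect_true(all(abs(strong$de_calls$log2fc) > 1 & strong$de_calls$padj < 0.05))
  expect_error(generate_expression(12, c(a = 0L, b = 2L),
                                   data.frame(family = character(),
                                              condition = character(),
                                              log2fc = numeric()), seed = 1),
               "replicate")
})

test_that("dose-response: higher multipliers raise expansion detection", {
  rate_at <- function(mult) {
    hits <- 0; total <- 0
    for (s in 1:3) {
      res <- generate_copy_matrix(9, 100, 0.1, mult, seed = s)
      er <- detect_expansions(res$matrix)
      hits <- hits + sum(er$family[er$expanded] %in%
                           res$truth$expanded_family_ids)
      total <- total + length(res$truth$expanded_family_ids)
    }
    hits / total
  }
  expect_gte(rate_at(8), rate_at(3))
})
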