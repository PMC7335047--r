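# Nei-Gojobori site counting and frequency-corrected pi_N / pi_S.

test_that("site counting reproduces codon-table facts", {
  gg <- count_sites("GGG")            # 4-fold third position
  expect_equal(gg$L_S, 1)
  expect_equal(gg$L_N, 2)
  cds <- generate_cds_set(5, seed = 2)
  for (g in names(cds)) {
    sc <- count_sites(cds[[g]])
    expect_equal(sc$L_S + sc$L_N, nchar(cds[[g]]))
  }
  expect_error(count_sites("GGGA"), "multiple of 3")
  expect_error(count_sites("ATGTAAAAATTT"), class = "internal_stop_error")
})

test_that("site counts equal the brute-force 9-change enumeration", {
  cds <- generate_cds_set(8, seed = 13, len_range = c(20L, 60L))
  for (g in names(cds)) {
    o <- oracle_ng_sites(cds[[g]])
    sc <- count_sites(cds[[g]])
    expect_equal(sc$L_S, o$L_S)
    expect_equal(sc$L_N, o$L_N)
  }
})

test_that("callable masks restrict the counted sites", {
  sc_all <- count_sites("GGGGGG")
  mask <- c(rep(TRUE, 3), rep(FALSE, 3))
  sc_half <- count_sites("GGGGGG", mask)
  expect_equal(sc_half$L_S, sc_all$L_S / 2)
  expect_equal(sc_half$L_N + sc_half$L_S, 3)
  expect_error(count_sites("GGG", c(TRUE, TRUE)), "length")
})

test_that("per-SNP heterozygosity uses the unbiased frequency correction", {
  sites <- data.frame(gene = "g1", L_S = 75, L_N = 225)
  v <- data.frame(gene = "g1", pos = 3, effect = "synonymous",
                  alt_count = 2, n_chrom = 4)
  r <- pi_per_gene(v, sites)
  expect_equal(r$genes$pi_S, (4 / 3) * 0.5 / 75, tolerance = 1e-12)
  expect_equal(r$genes$pi_S, 0.008889, tolerance = 1e-4)
  expect_equal(r$genes$pi_N, 0)
  # no variants: zero diversity, undefined ratio
  r0 <- pi_per_gene(v[0, ], sites)
  expect_equal(r0$genes$pi_S, 0)
  expect_true(is.na(r0$genes$ratio))
  expect_error(pi_per_gene(data.frame(gene = "gX", pos = 1,
                                      effect = "synonymous", alt_count = 1,
                                      n_chrom = 4), sites), "site counts")
})

test_that("frequency-based pi equals mean pairwise haplotype differences", {
  # explicit haplotypes on 6 chromosomes, 3 segregating sites
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(3:8, 1)
    n_sites <- sample(2:5, 1)
    site_class <- sample(c("synonymous", "nonsynonymous"), n_sites,
                         replace = TRUE)
    hap <- matrix(0L, nrow = n, ncol = n_sites)
    counts <- integer(n_sites)
    for (s in seq_len(n_sites)) {
      counts[s] <- sample(seq_len(n - 1), 1)
      hap[sample(n, counts[s]), s] <- 1L
    }
    L_S <- 40; L_N <- 80
    sites <- data.frame(gene = "g", L_S = L_S, L_N = L_N)
    v <- data.frame(gene = "g", pos = seq_len(n_sites), effect = site_class,
                    alt_count = counts, n_chrom = n)
    r <- pi_per_gene(v, sites)
    o <- oracle_pi_pairwise(hap, site_class, L_S, L_N)
    expect_equal(r$genes$pi_S, o$pi_S, tolerance = 1e-12)
    expect_equal(r$genes$pi_N, o$pi_N, tolerance = 1e-12)
  }
})

test_that("multi-allelic sites sum pairwise heterozygosity terms", {
  sites <- data.frame(gene = "g", L_S = 30, L_N = 60)
  # two alternate alleles at one site: counts 2 and 1 of n = 6
  v <- data.frame(gene = "g", pos = c(9, 9), effect = "synonymous",
                  alt_count = c(2, 1), n_chrom = 6)
  r <- pi_per_gene(v, sites)
  p <- c(3, 2, 1) / 6
  expect_equal(r$genes$pi_S, (6 / 5) * (1 - sum(p^2)) / 30, tolerance = 1e-12)
})

test_that("group comparisons report medians and rank-sum p-values", {
  genes <- data.frame(gene = sprintf("g%03d", 1:40),
                      pi_N = 0.003, pi_S = 0.022)
  genes$ratio <- rep(seq(0.05, 0.5, length.out = 20), each = 2)
  res <- structure(list(genes = genes, summary = selection_summary(genes)),
                   class = "selection_result")
  grp <- setNames(rep(c("A", "B"), 20), genes$gene)
  cmp <- compare_groups(res, list(type = grp))
  expect_equal(cmp$median_a, cmp$median_b)
  expect_gt(cmp$p_value, 0.9)
  # planted 3x dosed difference separates groups
  set.seed(5)
  genes$ratio <- ifelse(grp[genes$gene] == "A", 0.45, 0.15) *
    exp(rnorm(40, 0, 0.2))
  res2 <- structure(list(genes = genes, summary = selection_summary(genes)),
                    class = "selection_result")
  cmp2 <- compare_groups(res2, list(type = grp))
  expect_gt(cmp2$median_a, cmp2$median_b)
  expect_lt(cmp2$p_value, 0.05)
  # single-member group: warning, no test row for it
  grp2 <- grp; grp2[1] <- "C"
  expect_warning(compare_groups(res2, list(type = grp2)), "C")
})

test_that("high-ratio candidates feed the enrichment test", {
  genes <- data.frame(gene = sprintf("g%03d", 1:60), pi_N = 0.01,
                      pi_S = 0.01)
  genes$ratio <- c(rep(2, 10), rep(0.1, 50))
  res <- structure(list(genes = genes, summary = selection_summary(genes)),
                   class = "selection_result")
  de <- data.frame(gene = sprintf("g%03d", c(1:8, 31:34)),
                   condition = "mating", direction = "up")
  fl <- flag_positive_candidates(res, de)
  expect_setequal(fl$candidates, sprintf("g%03d", 1:10))
  expect_true(fl$enrichment$enriched[fl$enrichment$label == "mating"])
  # no candidates above the cutoff
  fl0 <- flag_positive_candidates(res, de, ratio_cutoff = 10)
  expect_length(fl0$candidates, 0)
  expect_null(fl0$enrichment)
  # cutoff 0: every tested gene is a candidate
  fl_all <- flag_positive_candidates(res, de, ratio_cutoff = 0)
  expect_length(fl_all$candidates, 60)
  expect_equal(fl_all$enrichment$overlap, nrow(de))
})

test_that("doubling lengths and SNP density leaves mean pi stable", {
  cds <- generate_cds_set(40, seed = 17, len_range = c(100L, 300L))
  cds2 <- setNames(paste0(cds, cds), names(cds))
  s1 <- count_sites_set(cds); s2 <- count_sites_set(cds2)
  v1 <- generate_variants(cds, 48, 0.02, 0.004, seed = 18)
  v2 <- generate_variants(cds2, 48, 0.02, 0.004, seed = 19)
  r1 <- pi_per_gene(v1, s1); r2 <- pi_per_gene(v2, s2)
  expect_equal(r1$summary$mean_pi_S, r2$summary$mean_pi_S, tolerance = 0.2)
  expect_equal(r1$summary$mean_pi_N, r2$summary$mean_pi_N, tolerance = 0.25)
})
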