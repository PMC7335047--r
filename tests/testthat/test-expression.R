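# Expression filters, hypergeometric enrichment, pleiotropy and
# expression divergence.

mk_expr <- function(counts, tpm, conditions) {
  structure(list(counts = counts, tpm = tpm,
                 samples = data.frame(sample = colnames(counts),
                                      condition = conditions,
                                      stringsAsFactors = FALSE)),
            class = "expression_matrix")
}

test_that("expressed and retained filters sit exactly on their boundaries", {
  counts <- matrix(c(2000, 1000, 1000, 500,     # CPM > 1 in 4 samples
                     1500, 1200, 800,  0,       # CPM > 1 in 3 samples
                     1100, 900,  0,    0,       # CPM > 1 in 2 samples
                     0,    0,    0,    0,
                     900,  800,  700,  600),
                   nrow = 5, byrow = TRUE,
                   dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  tpm <- matrix(0, nrow = 5, ncol = 4, dimnames = dimnames(counts))
  tpm[1, 1] <- 2      # exactly at the cutoff: expressed
  tpm[2, 1] <- 1.99   # just below in every sample: not expressed
  tpm[5, ] <- 10
  ex <- apply_expression_filters(mk_expr(counts, tpm, rep(c("c1", "c2"), 2)))
  expect_true(ex$expressed[1])
  expect_false(ex$expressed[2])
  expect_true(ex$expressed[5])
  # manual CPM check: library sizes are colSums(counts)
  cpm_manual <- sweep(counts, 2, colSums(counts) / 1e6, "/")
  expect_equal(ex$cpm, cpm_manual)
  expect_equal(unname(ex$retained),
               unname(rowSums(cpm_manual > 1) >= 3))
  expect_true(ex$retained[2])    # exactly 3 samples
  expect_false(ex$retained[3])   # only 2 samples
})

test_that("hypergeometric p matches exact enumeration", {
  # universe 20, annotation 5, target 5, overlap 4
  e <- hypergeom_enrichment(paste0("g", 1:5),
                            list(A = paste0("g", c(1:4, 19))),
                            paste0("g", 1:20))
  expect_equal(e$p, 76 / 15504, tolerance = 1e-12)
  expect_equal(e$p, oracle_hypergeom(4, 5, 20, 5), tolerance = 1e-12)
  # overlap 0: p = 1
  e0 <- hypergeom_enrichment(paste0("g", 1:5),
                             list(B = paste0("g", 6:10)), paste0("g", 1:20))
  expect_equal(e0$p, 1)
  # min_hits: overlap 1 never enriched however small p is
  e1 <- hypergeom_enrichment("g1", list(C = "g1"), paste0("g", 1:1000))
  expect_lt(e1$p, 0.05)
  expect_false(e1$enriched)
  expect_error(hypergeom_enrichment("g1", list(A = "g1"), character(0)),
               "universe")
})

test_that("hypergeometric p equals enumeration on random small instances", {
  set.seed(31)
  for (rep in 1:25) {
    N <- sample(5:25, 1)
    uni <- paste0("g", seq_len(N))
    ann <- sample(uni, sample(1:N, 1))
    targ <- sample(uni, sample(1:N, 1))
    e <- hypergeom_enrichment(targ, list(x = ann), uni)
    expect_equal(e$p, oracle_hypergeom(length(intersect(targ, ann)),
                                       length(ann), N, length(targ)),
                 tolerance = 1e-12)
  }
})

test_that("q-values are BH-monotone and invariant to label order", {
  set.seed(17)
  uni <- paste0("g", 1:50)
  anns <- lapply(1:6, function(i) sample(uni, sample(5:20, 1)))
  names(anns) <- paste0("A", 1:6)
  targ <- sample(uni, 12)
  e <- hypergeom_enrichment(targ, anns, uni)
  expect_equal(e$q, p.adjust(e$p, "BH"))
  expect_true(all(e$q <= 1))
  ord <- order(e$p)
  expect_true(all(diff(e$q[ord]) >= -1e-12))
  e_rev <- hypergeom_enrichment(targ, rev(anns), uni)
  expect_equal(e_rev[match(e$label, e_rev$label), "q"], e$q)
})

test_that("pleiotropy boundaries fall at 7 and the specific cap at 2", {
  pairs <- rbind(
    data.frame(family = "F1", condition = paste0("c", 1:7)),
    data.frame(family = "F2", condition = paste0("c", 1:6)),
    data.frame(family = "F3", condition = "c1"),
    data.frame(family = "F4", condition = paste0("c", 1:2)))
  cl <- classify_pleiotropic(pairs)
  got <- setNames(cl$class, cl$family)
  expect_equal(unname(got[c("F1", "F2", "F3", "F4")]),
               c("pleiotropic", "neither", "condition-specific",
                 "condition-specific"))
})

test_that("a family planted up in 8 conditions is recovered as pleiotropic", {
  des <- setNames(rep(2L, 9), paste0("cond", 1:9))
  pu <- data.frame(family = "F0001", condition = paste0("cond", 1:8),
                   log2fc = 2.5)
  ge <- generate_expression(60, des, pu, seed = 9)
  fams <- split(names(ge$expr$gene_family), ge$expr$gene_family)
  up <- ge$de_calls[ge$de_calls$direction == "up", ]
  enr <- lapply(split(up$gene, up$condition), function(set)
    hypergeom_enrichment(set, fams, rownames(ge$expr$counts)))
  cl <- classify_pleiotropic(enr)
  expect_equal(cl$class[cl$family == "F0001"], "pleiotropic")
})

test_that("expression divergence scores anticorrelated clades as divergent", {
  tree <- ape::read.tree(text = "((g1,g2),(g3,g4));")
  conds <- rep(paste0("c", 1:4), each = 1)
  tpm <- rbind(g1 = c(10, 20, 30, 40), g2 = c(12, 22, 28, 44),
               g3 = c(40, 30, 20, 10), g4 = c(44, 28, 22, 12))
  colnames(tpm) <- paste0("s", 1:4)
  counts <- tpm
  expr <- mk_expr(counts, tpm, conds)
  dv <- expression_divergence(tree, expr)
  expect_equal(dv$nodes$divergent[dv$nodes$node == 5], TRUE)  # root
  expect_gt(dv$percent_divergent, 0)
  # identical profiles everywhere: nothing divergent
  tpm_flat <- matrix(rep(c(10, 20, 30, 40), each = 4), nrow = 4,
                     dimnames = dimnames(tpm))
  dv0 <- expression_divergence(tree, mk_expr(counts, tpm_flat, conds))
  expect_equal(dv0$percent_divergent, 0)
  expect_error(expression_divergence(ape::unroot(ape::rtree(5)), expr),
               "rooted")
  # fewer than min_members expressed leaves: not evaluated
  dv_na <- expression_divergence(tree, expr, min_members = 5)
  expect_true(is.na(dv_na$percent_divergent))
})

test_that("divergence calls ignore per-gene multiplicative scaling", {
  tree <- ape::read.tree(text = "((g1,g2),(g3,g4));")
  set.seed(3)
  tpm <- matrix(exp(rnorm(4 * 6, 3, 1)), nrow = 4,
                dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  expr <- mk_expr(tpm, tpm, rep(paste0("c", 1:3), 2))
  scaled <- expr
  scaled$tpm <- expr$tpm * c(2, 0.5, 10, 1)
  d1 <- expression_divergence(tree, expr, pseudocount = 0)
  d2 <- expression_divergence(tree, scaled, pseudocount = 0)
  expect_equal(d1$nodes$r, d2$nodes$r, tolerance = 1e-9)
  expect_equal(d1$percent_divergent, d2$percent_divergent)
})
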