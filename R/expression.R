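# Expression-atlas utilities: expressed/retained filters, hypergeometric
# family enrichment with Benjamini-Hochberg control, pleiotropy
# classification and expression-divergence scoring on family gene trees.

#' Flag expressed and analysis-retained genes
#'
#' A gene is expressed when its TPM is at least 2 in at least one sample;
#' it is retained for differential-expression analysis when its CPM
#' exceeds 1 in at least three samples (CPM computed per sample as
#' count / (library size / 1e6)).
#'
#' @param expr an `expression_matrix` (list with `counts`, `tpm`,
#'   `samples`; see [generate_expression()]).
#' @param tpm_cutoff,min_tpm_samples expressed rule (defaults: TPM >= 2 in
#'   >= 1 sample).
#' @param cpm_cutoff,min_cpm_samples retained rule (defaults: CPM > 1 in
#'   >= 3 samples).
#' @return `expr` with added logical vectors `expressed` and `retained`
#'   and the `cpm` matrix.
#' @export
apply_expression_filters <- function(expr, tpm_cutoff = 2,
                                     min_tpm_samples = 1,
                                     cpm_cutoff = 1, min_cpm_samples = 3) {
  cpm <- sweep(expr$counts, 2, colSums(expr$counts) / 1e6, "/")
  expr$cpm <- cpm
  expr$expressed <- rowSums(expr$tpm >= tpm_cutoff) >= min_tpm_samples
  expr$retained <- rowSums(cpm > cpm_cutoff) >= min_cpm_samples
  expr
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples,", length(unique(x$samples$condition)), "conditions\n")
  if (!is.null(x$expressed))
    cat("  expressed:", sum(x$expressed), " retained:", sum(x$retained), "\n")
  invisible(x)
}

#' Hypergeometric gene-set enrichment
#'
#' For each annotation label the overlap `k` between the target set and
#' the annotation set (both intersected with the universe) is tested with
#' the upper-tail hypergeometric probability `P(X >= k)`;
#' Benjamini-Hochberg q-values are computed over all labels tested in the
#' run. A label is enriched when `q < q_cutoff` and `k >= min_hits`.
#'
#' @param target character vector of genes (subset of `universe`).
#' @param annotations named list of character vectors (label -> gene set).
#' @param universe character vector of all considered genes.
#' @param min_hits minimum overlap for an enriched call (default 2).
#' @param q_cutoff q-value cutoff (default 0.05).
#' @return object of class `enrichment_result`: data.frame with `label`,
#'   `overlap`, `set_size`, `target_size`, `universe_size`, `p`, `q`,
#'   `enriched`.
#' @export
hypergeom_enrichment <- function(target, annotations, universe,
                                 min_hits = 2, q_cutoff = 0.05) {
  universe <- unique(universe)
  if (length(universe) == 0) stop_arg("empty universe")
  target <- unique(intersect(target, universe))
  rows <- lapply(names(annotations), function(lab) {
    ann <- unique(intersect(annotations[[lab]], universe))
    k <- length(intersect(target, ann))
    p <- stats::phyper(k - 1, length(ann), length(universe) - length(ann),
                       length(target), lower.tail = FALSE)
    data.frame(label = lab, overlap = k, set_size = length(ann),
               target_size = length(target),
               universe_size = length(universe), p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- stats::p.adjust(res$p, method = "BH")
  res$enriched <- res$q < q_cutoff & res$overlap >= min_hits
  structure(res, class = c("enrichment_result", "data.frame"))
}

#' Classify families as pleiotropic or condition-specific
#'
#' A family enriched in condition-upregulated gene sets under
#' `min_conditions` or more different conditions is pleiotropic; a family
#' enriched in at least one and at most `max_specific` conditions is
#' condition-specific; anything else is neither.
#'
#' @param enrichments named list (condition -> `enrichment_result` whose
#'   labels are families, from testing that condition's upregulated set),
#'   or a data.frame with columns `family` and `condition` listing
#'   enriched pairs.
#' @param min_conditions pleiotropy threshold (default 7).
#' @param max_specific maximum condition count for "condition-specific"
#'   (default 2).
#' @return data.frame with `family`, `n_conditions`, `class`.
#' @export
classify_pleiotropic <- function(enrichments, min_conditions = 7,
                                 max_specific = 2) {
  if (is.data.frame(enrichments)) {
    pairs <- unique(enrichments[, c("family", "condition")])
  } else {
    pairs <- do.call(rbind, lapply(names(enrichments), function(cn) {
      e <- enrichments[[cn]]
      hit <- e$label[e$enriched]
      if (length(hit) == 0) return(NULL)
      data.frame(family = hit, condition = cn, stringsAsFactors = FALSE)
    }))
  }
  if (is.null(pairs) || nrow(pairs) == 0)
    return(data.frame(family = character(), n_conditions = integer(),
                      class = character(), stringsAsFactors = FALSE))
  n <- tapply(pairs$condition, pairs$family, function(x) length(unique(x)))
  cls <- ifelse(n >= min_conditions, "pleiotropic",
                ifelse(n <= max_specific, "condition-specific", "neither"))
  data.frame(family = names(n), n_conditions = as.integer(n),
             class = unname(cls), stringsAsFactors = FALSE)
}

#' Expression divergence across a family gene tree
#'
#' For every internal node of a rooted family tree whose two child clades
#' both contain leaves with expression data, the Pearson correlation
#' between the child clades' mean log2(TPM + 1) condition profiles is
#' computed; the node is divergent when `r < r_cutoff`. The family
#' percentage is taken over evaluable nodes. Families with fewer than
#' `min_members` expressed leaves are not evaluated (NA).
#'
#' @param tree a rooted `phylo` object (tip labels are gene ids).
#' @param expr an `expression_matrix` with TPM.
#' @param r_cutoff correlation cutoff below which a node is called
#'   divergent (default 0.5).
#' @param min_members minimum leaves with expression (default 4).
#' @param pseudocount added to TPM before the log transform (default 1;
#'   with pseudocount 0 on strictly positive TPM the divergence calls are
#'   exactly invariant to per-gene multiplicative rescaling, since a
#'   per-gene factor only shifts the clade-mean log profile by a
#'   constant).
#' @return list with `percent_divergent`, `n_nodes` (evaluable nodes) and
#'   per-node data.frame `nodes` (`node`, `r`, `divergent`).
#' @export
expression_divergence <- function(tree, expr, r_cutoff = 0.5,
                                  min_members = 4, pseudocount = 1) {
  if (!inherits(tree, "phylo")) stop_arg("tree must be a phylo object")
  if (!ape::is.rooted(tree)) stop_arg("tree must be rooted")
  tips <- intersect(tree$tip.label, rownames(expr$tpm))
  if (length(tips) < min_members)
    return(list(percent_divergent = NA_real_, n_nodes = 0L,
                nodes = data.frame(node = integer(), r = numeric(),
                                   divergent = logical())))
  cond <- expr$samples$condition
  prof <- function(genes) {
    m <- log2(expr$tpm[genes, , drop = FALSE] + pseudocount)
    clade_mean <- colMeans(m)
    as.numeric(tapply(clade_mean, cond, mean))
  }
  ntip <- length(tree$tip.label)
  internal <- (ntip + 1L):(ntip + tree$Nnode)
  rows <- list()
  for (nd in internal) {
    children <- tree$edge[tree$edge[, 1] == nd, 2]
    if (length(children) < 2) next
    clades <- lapply(children, function(ch) {
      leaves <- if (ch <= ntip) ch else phangorn_descendants(tree, ch)
      intersect(tree$tip.label[leaves], tips)
    })
    clades <- clades[lengths(clades) > 0]
    if (length(clades) < 2) next
    r <- suppressWarnings(stats::cor(prof(clades[[1]]), prof(clades[[2]])))
    if (is.na(r)) next
    rows[[length(rows) + 1L]] <- data.frame(node = nd, r = r,
                                            divergent = r < r_cutoff)
  }
  nodes <- if (length(rows) == 0)
    data.frame(node = integer(), r = numeric(), divergent = logical())
  else do.call(rbind, rows)
  pct <- if (nrow(nodes) == 0) NA_real_ else 100 * mean(nodes$divergent)
  list(percent_divergent = pct, n_nodes = nrow(nodes), nodes = nodes)
}

# tip indices descending from an internal node
phangorn_descendants <- function(tree, node) {
  ntip <- length(tree$tip.label)
  out <- integer(0)
  stack <- node
  while (length(stack) > 0) {
    nd <- stack[[1]]; stack <- stack[-1]
    kids <- tree$edge[tree$edge[, 1] == nd, 2]
    out <- c(out, kids[kids <= ntip])
    stack <- c(stack, kids[kids > ntip])
  }
  out
}

#' Compare divergence percentages between family-size groups
#'
#' Two-sided Wilcoxon rank-sum test between the per-family divergence
#' percentages of two groups (e.g. small vs large families).
#'
#' @param pct_a,pct_b numeric vectors of family divergence percentages.
#' @return list with `median_a`, `median_b`, `p_value`.
#' @export
compare_divergence <- function(pct_a, pct_b) {
  p <- suppressWarnings(stats::wilcox.test(pct_a, pct_b,
                                           exact = FALSE)$p.value)
  list(median_a = stats::median(pct_a, na.rm = TRUE),
       median_b = stats::median(pct_b, na.rm = TRUE), p_value = p)
}
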