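# Pan-genome presence/absence calling, core/softcore/dispensable
# classification, accumulation curves, de novo gene deduplication and
# strain clustering on coverage profiles.

#' Call gene presence per strain from horizontal exon coverage
#'
#' A gene is absent from a strain when the horizontal coverage across all
#' of its exons is below the threshold (default `< 5%`), and present
#' otherwise (coverage `>= 0.05`).
#'
#' @param coverage numeric matrix genes x strains with values in \[0, 1\].
#' @param threshold presence threshold on coverage (default 0.05).
#' @return object of class `presence_absence`: list with `coverage`,
#'   logical `presence` matrix, `per_strain` present-gene counts, and any
#'   `clade`/`reference` attributes carried over from the coverage matrix.
#' @export
call_presence <- function(coverage, threshold = 0.05) {
  if (!is.matrix(coverage) || is.null(rownames(coverage)) ||
      is.null(colnames(coverage)))
    stop_arg("coverage must be a gene x strain matrix with dimnames")
  bad <- which(coverage < 0 | coverage > 1, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_arg(sprintf("coverage outside [0,1] at gene %s, strain %s",
                     rownames(coverage)[bad[1, 1]],
                     colnames(coverage)[bad[1, 2]]))
  presence <- coverage >= threshold
  structure(list(coverage = coverage, presence = presence,
                 per_strain = colSums(presence),
                 clade = attr(coverage, "clade"),
                 reference = attr(coverage, "reference")),
            class = "presence_absence")
}

#' @export
print.presence_absence <- function(x, ...) {
  cat("presence_absence:", nrow(x$presence), "pan genes x",
      ncol(x$presence), "strains; mean genes/strain",
      round(mean(x$per_strain)), "\n")
  invisible(x)
}

#' Pan-genome summary arithmetic
#'
#' Given core, softcore and dispensable gene counts (softcore being a
#' labeled subset of the dispensable fraction), computes the pan size and
#' the reported percentages: pan = core + dispensable; the core percentage
#' and dispensable percentage are relative to the pan size; the softcore
#' percentage likewise; `core_range_pct` is the
#' \[core, core + softcore\] percentage range.
#'
#' @param n_core,n_softcore,n_dispensable gene counts; `n_softcore` must
#'   not exceed `n_dispensable`.
#' @return list with `pan_size`, `pct_core`, `pct_dispensable`,
#'   `pct_softcore`, `core_range_pct` (length-2 vector).
#' @export
pan_summary <- function(n_core, n_softcore, n_dispensable) {
  if (n_softcore > n_dispensable)
    stop_arg("softcore is a subset of the dispensable fraction")
  pan <- n_core + n_dispensable
  list(pan_size = pan,
       pct_core = 100 * n_core / pan,
       pct_dispensable = 100 * n_dispensable / pan,
       pct_softcore = 100 * n_softcore / pan,
       core_range_pct = 100 * c(n_core, n_core + n_softcore) / pan)
}

#' Classify pan genes into core, softcore and dispensable
#'
#' Core genes are present in all strains. The remainder is the dispensable
#' fraction, within which softcore genes are present in at least
#' `ceiling(softcore_fraction * n_strains)` strains (">= 95% but not
#' all"). The headline core/dispensable split therefore counts softcore
#' genes as dispensable; the softcore count bounds the upper end of the
#' core range.
#'
#' @param pa a `presence_absence` from [call_presence()].
#' @param softcore_fraction strain fraction defining softcore (default
#'   0.95).
#' @return object of class `pan_classification`: data.frame `genes`
#'   (`gene`, `n_present`, `class` with softcore labeled) and a `summary`
#'   from [pan_summary()].
#' @export
classify_pan_genes <- function(pa, softcore_fraction = 0.95) {
  n_strains <- ncol(pa$presence)
  if (n_strains < 2) stop_arg("need >= 2 strains to classify pan genes")
  n_present <- rowSums(pa$presence)
  soft_min <- as.integer(ceiling(softcore_fraction * n_strains))
  class <- ifelse(n_present == n_strains, "core",
                  ifelse(n_present >= soft_min, "softcore", "dispensable"))
  genes <- data.frame(gene = rownames(pa$presence),
                      n_present = as.integer(n_present),
                      class = class, stringsAsFactors = FALSE)
  n_core <- sum(class == "core")
  n_soft <- sum(class == "softcore")
  n_disp <- sum(class != "core")  # softcore is part of the dispensable fraction
  structure(list(genes = genes,
                 summary = pan_summary(n_core, n_soft, n_disp)),
            class = "pan_classification")
}

#' @export
print.pan_classification <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "pan_classification: pan %d genes; core %.0f%%, dispensable %.0f%% (softcore %.1f%%), core range %.0f-%.0f%%\n",
    s$pan_size, s$pct_core, s$pct_dispensable, s$pct_softcore,
    s$core_range_pct[1], s$core_range_pct[2]))
  invisible(x)
}

#' Pan and core accumulation curves over random strain orderings
#'
#' For each permutation of strains the cumulative union (pan) and
#' intersection (core) of present gene sets is computed as strains are
#' added one by one; means and standard deviations per added-strain count
#' are reported.
#'
#' @param pa a `presence_absence`.
#' @param n_permutations number of random orderings (default 100).
#' @param seed integer seed.
#' @return data.frame with columns `k`, `pan_mean`, `pan_sd`, `core_mean`,
#'   `core_sd`; per-permutation trajectories in `attr(,"pan")` and
#'   `attr(,"core")` (k x permutation matrices).
#' @export
accumulation_curves <- function(pa, n_permutations = 100, seed = 1) {
  n_permutations <- check_count(n_permutations, "n_permutations")
  pres <- pa$presence
  n <- ncol(pres)
  if (n < 2) stop_arg("need >= 2 strains")
  with_seed(seed, {
    pan <- matrix(0L, nrow = n, ncol = n_permutations)
    core <- matrix(0L, nrow = n, ncol = n_permutations)
    for (p in seq_len(n_permutations)) {
      ord <- sample.int(n)
      u <- rep(FALSE, nrow(pres)); i <- rep(TRUE, nrow(pres))
      for (k in seq_len(n)) {
        u <- u | pres[, ord[k]]
        i <- i & pres[, ord[k]]
        pan[k, p] <- sum(u); core[k, p] <- sum(i)
      }
    }
    out <- data.frame(k = seq_len(n),
                      pan_mean = rowMeans(pan),
                      pan_sd = apply(pan, 1, stats::sd),
                      core_mean = rowMeans(core),
                      core_sd = apply(core, 1, stats::sd))
    attr(out, "pan") <- pan
    attr(out, "core") <- core
    out
  })
}

#' Deduplicate de novo-assembled genes by sequence identity
#'
#' Greedy clustering in decreasing length order (the CD-HIT strategy):
#' each gene, visited longest first, joins the first existing cluster
#' whose representative it matches at identity `>= threshold`, and
#' otherwise founds a new cluster. Representatives are the longest member
#' of each cluster by construction.
#'
#' @param identities data.frame of pairwise identities with columns
#'   `gene_a`, `gene_b`, `identity` in \[0, 1\] (unordered pairs; missing
#'   pairs are treated as below threshold).
#' @param lengths named numeric vector of gene lengths (every clustered
#'   gene needs one).
#' @param threshold identity threshold (default 0.95).
#' @return data.frame with `gene`, `representative`, `cluster`.
#' @export
dedup_de_novo_genes <- function(identities, lengths, threshold = 0.95) {
  if (nrow(identities) > 0 &&
      (any(identities$identity < 0) || any(identities$identity > 1)))
    stop_arg("identity values must lie in [0, 1]")
  genes <- unique(c(identities$gene_a, identities$gene_b, names(lengths)))
  missing <- setdiff(genes, names(lengths))
  if (length(missing) > 0)
    stop_arg("missing length for gene(s): ", paste(missing, collapse = ", "))
  key <- function(x, y) paste(pmin(x, y), pmax(x, y), sep = "\r")
  id_lookup <- stats::setNames(identities$identity,
                               key(identities$gene_a, identities$gene_b))
  ord <- genes[order(-lengths[genes], genes)]
  reps <- character(0)
  assign <- character(0)
  for (g in ord) {
    placed <- FALSE
    for (r in reps) {
      id <- id_lookup[key(g, r)]
      if (!is.na(id) && id >= threshold) {
        assign[g] <- r; placed <- TRUE; break
      }
    }
    if (!placed) { reps <- c(reps, g); assign[g] <- g }
  }
  data.frame(gene = ord, representative = assign[ord],
             cluster = match(assign[ord], reps), stringsAsFactors = FALSE)
}

#' Cluster strains by coverage profile
#'
#' Hierarchical clustering (average linkage on Euclidean distances between
#' strain coverage profiles), cut into `k` groups — the computation behind
#' coverage-heatmap strain dendrograms that recover population clades.
#'
#' @param pa a `presence_absence`.
#' @param k number of groups to cut the dendrogram into.
#' @return list with `hclust` (the tree) and `groups` (named membership
#'   vector) when `k` is given.
#' @export
cluster_strains <- function(pa, k = NULL) {
  d <- stats::dist(t(pa$coverage))
  hc <- stats::hclust(d, method = "average")
  groups <- if (!is.null(k)) stats::cutree(hc, k = k) else NULL
  list(hclust = hc, groups = groups)
}
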