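# Per-gene nucleotide diversity at synonymous and nonsynonymous sites.
#
# Sites are counted with the (unweighted) Nei-Gojobori scheme under the
# standard nuclear code: each coding position contributes f_s = (number of
# the three possible single-base changes that are synonymous)/3 synonymous
# sites and 1 - f_s nonsynonymous sites, so L_N + L_S equals the callable
# CDS length exactly. Changes creating a stop codon count as nonsynonymous.

BASES <- c("A", "C", "G", "T")

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

check_cds <- function(seq, gene = "<cds>") {
  seq <- toupper(as.character(seq))
  if (nchar(seq) %% 3 != 0)
    stop_arg("CDS length of ", gene, " is not a multiple of 3")
  if (!grepl("^[ACGT]+$", seq))
    stop_arg("CDS of ", gene, " contains non-ACGT characters")
  codons <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
  aa <- translate_codon(codons)
  internal <- aa[-length(aa)]
  if (any(internal == "*"))
    stop(structure(class = c("internal_stop_error", "error", "condition"),
                   list(message = paste0("internal stop codon in CDS of ", gene),
                        call = NULL)))
  seq
}

# Effect class of every possible single-base change, one row per
# (position, alternate base): pos, ref, alt, effect.
cds_change_classes <- function(seq) {
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  base <- strsplit(seq, "")[[1]]
  codon_idx <- (seq_len(n) - 1L) %/% 3L
  within <- (seq_len(n) - 1L) %% 3L + 1L
  codons <- substring(seq, codon_idx * 3L + 1L, codon_idx * 3L + 3L)
  aa <- translate_codon(codons)
  pos <- rep(seq_len(n), each = 4L)
  alt <- rep(BASES, times = n)
  keep <- alt != base[pos]
  pos <- pos[keep]; alt <- alt[keep]
  w <- within[pos]
  mut <- paste0(substr(codons[pos], 1L, w - 1L), alt,
                substring(codons[pos], w + 1L, 3L))
  data.frame(pos = pos, ref = base[pos], alt = alt,
             effect = ifelse(translate_codon(mut) == aa[pos],
                             "synonymous", "nonsynonymous"),
             stringsAsFactors = FALSE)
}

#' Count synonymous and nonsynonymous sites in a CDS
#'
#' Nei-Gojobori fractional site counting restricted to callable positions:
#' a position where `k` of its three possible single-base changes are
#' synonymous contributes `k/3` synonymous and `1 - k/3` nonsynonymous
#' sites. `L_N + L_S` equals the number of callable positions.
#'
#' @param cds character scalar or `DNAString`, length a multiple of 3 with
#'   no internal stop codon.
#' @param callable_mask logical vector, one entry per CDS base (default all
#'   callable).
#' @return list with `L_S`, `L_N` (fractional site counts) and
#'   `callable` (the mask used).
#' @export
count_sites <- function(cds, callable_mask = NULL) {
  seq <- check_cds(cds)
  n <- nchar(seq)
  if (is.null(callable_mask)) callable_mask <- rep(TRUE, n)
  if (length(callable_mask) != n)
    stop_arg("callable_mask length must equal CDS length")
  ch <- cds_change_classes(seq)
  syn_counts <- tapply(ch$effect == "synonymous", ch$pos, sum)
  syn_frac <- as.numeric(syn_counts[as.character(seq_len(n))]) / 3
  L_S <- sum(syn_frac[callable_mask])
  L_N <- sum((1 - syn_frac)[callable_mask])
  list(L_S = L_S, L_N = L_N, callable = callable_mask)
}

#' Site counts for a set of CDS sequences
#'
#' @param cds_set named character vector or `DNAStringSet`.
#' @param callable_masks optional named list of logical masks.
#' @return data.frame with columns `gene`, `L_S`, `L_N`.
#' @export
count_sites_set <- function(cds_set, callable_masks = NULL) {
  seqs <- as_cds_vector(cds_set)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop_arg("cds_set must have unique names")
  rows <- lapply(names(seqs), function(g) {
    sc <- count_sites(seqs[[g]], callable_masks[[g]])
    data.frame(gene = g, L_S = sc$L_S, L_N = sc$L_N,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Unbiased per-site expected heterozygosity from allele counts at one site:
# n/(n-1) * (1 - sum p_k^2), identical to the mean pairwise difference over
# all C(n,2) chromosome pairs.
site_heterozygosity <- function(alt_counts, n) {
  ref <- n - sum(alt_counts)
  if (ref < 0) stop_arg("allele counts exceed chromosome count")
  p <- c(ref, alt_counts) / n
  n / (n - 1) * (1 - sum(p^2))
}

#' Per-gene nucleotide diversity at nonsynonymous and synonymous sites
#'
#' For every SNP the frequency-corrected expected heterozygosity
#' `h = n/(n-1) * 2 p (1-p)` is computed from its alternate-allele count
#' (multi-allelic sites, i.e. several rows at one gene/position, use
#' `n/(n-1) * (1 - sum p_k^2)`). Per gene, `pi_S` is the sum of `h` over
#' synonymous SNPs divided by the synonymous site count `L_S`, and
#' likewise `pi_N` over `L_N`. The ratio `pi_N/pi_S` is undefined (NA)
#' when `pi_S = 0`.
#'
#' @param variants data.frame with columns `gene`, `pos`, `effect`
#'   ("synonymous"/"nonsynonymous"), `alt_count`, `n_chrom`.
#' @param sites data.frame with columns `gene`, `L_S`, `L_N` (from
#'   [count_sites_set()]); every variant's gene must be present.
#' @return object of class `selection_result`: per-gene data.frame
#'   (`gene`, `pi_N`, `pi_S`, `ratio`) plus a `summary` list with the
#'   genome-wide mean `pi_N`, mean `pi_S`, their ratio (the headline
#'   convention) and the mean of defined per-gene ratios.
#' @export
pi_per_gene <- function(variants, sites) {
  if (nrow(variants) > 0) {
    if (!all(c("gene", "pos", "effect", "alt_count", "n_chrom") %in%
             names(variants)))
      stop_arg("variants needs columns gene, pos, effect, alt_count, n_chrom")
    missing <- setdiff(unique(variants$gene), sites$gene)
    if (length(missing) > 0)
      stop_arg("variants reference genes without site counts: ",
               paste(utils::head(missing, 3), collapse = ", "))
    if (any(variants$alt_count <= 0) ||
        any(variants$alt_count >= variants$n_chrom))
      stop_arg("alt_count must satisfy 0 < alt_count < n_chrom")
  }
  res <- data.frame(gene = sites$gene, pi_N = 0, pi_S = 0,
                    stringsAsFactors = FALSE)
  if (nrow(variants) > 0) {
    for (cls in c("synonymous", "nonsynonymous")) {
      v <- variants[variants$effect == cls, , drop = FALSE]
      if (nrow(v) == 0) next
      key <- paste(v$gene, v$pos)
      h_site <- vapply(split(seq_len(nrow(v)), key), function(ix) {
        site_heterozygosity(v$alt_count[ix], v$n_chrom[ix][1])
      }, numeric(1))
      gene_of_site <- vapply(split(v$gene, key), `[`, character(1), 1)
      tot <- tapply(h_site, gene_of_site, sum)
      idx <- match(names(tot), res$gene)
      if (cls == "synonymous") res$pi_S[idx] <- as.numeric(tot) / sites$L_S[idx]
      else res$pi_N[idx] <- as.numeric(tot) / sites$L_N[idx]
    }
  }
  res$ratio <- ifelse(res$pi_S > 0, res$pi_N / res$pi_S, NA_real_)
  structure(list(
    genes = res,
    summary = selection_summary(res)
  ), class = "selection_result")
}

#' Genome-wide selection summary
#'
#' Reports the average nucleotide diversities and the ratio two ways: the
#' ratio of the mean `pi_N` to the mean `pi_S` (the headline convention)
#' and the mean of the defined per-gene ratios.
#'
#' @param genes per-gene data.frame with `pi_N`, `pi_S`, `ratio`.
#' @return list with `mean_pi_N`, `mean_pi_S`, `ratio_of_means`,
#'   `mean_of_ratios`.
#' @export
selection_summary <- function(genes) {
  m_n <- mean(genes$pi_N)
  m_s <- mean(genes$pi_S)
  list(mean_pi_N = m_n, mean_pi_S = m_s,
       ratio_of_means = if (m_s > 0) m_n / m_s else NA_real_,
       mean_of_ratios = mean(genes$ratio, na.rm = TRUE))
}

#' @export
print.selection_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "selection_result: %d genes; mean pi_N = %.4g, mean pi_S = %.4g, pi_N/pi_S = %.3g\n",
    nrow(x$genes), s$mean_pi_N, s$mean_pi_S, s$ratio_of_means))
  invisible(x)
}

#' Compare pi_N/pi_S between gene groups
#'
#' For each grouping factor, reports the median defined ratio per group and
#' two-sided Wilcoxon rank-sum p-values for every pair of groups. Groups
#' with fewer than 2 genes with a defined ratio are skipped with a warning.
#'
#' @param result a `selection_result`.
#' @param groupings named list of named character vectors (gene -> label),
#'   one per grouping (e.g. age class, core vs dispensable, duplicate type).
#' @return data.frame with columns `grouping`, `group_a`, `group_b`,
#'   `median_a`, `median_b`, `p_value`.
#' @export
compare_groups <- function(result, groupings) {
  genes <- result$genes
  out <- list()
  for (nm in names(groupings)) {
    lab <- groupings[[nm]]
    df <- genes[genes$gene %in% names(lab) & !is.na(genes$ratio), ]
    df$label <- lab[df$gene]
    counts <- table(df$label)
    small <- names(counts)[counts < 2]
    if (length(small) > 0) {
      warning("grouping '", nm, "': skipping group(s) with <2 ratio genes: ",
              paste(small, collapse = ", "), call. = FALSE)
      df <- df[!df$label %in% small, ]
    }
    gl <- sort(unique(df$label))
    if (length(gl) < 2) next
    for (i in seq_len(length(gl) - 1)) for (j in seq((i + 1), length(gl))) {
      a <- df$ratio[df$label == gl[i]]
      b <- df$ratio[df$label == gl[j]]
      p <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
      out[[length(out) + 1]] <- data.frame(
        grouping = nm, group_a = gl[i], group_b = gl[j],
        median_a = stats::median(a), median_b = stats::median(b),
        p_value = p, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(grouping = character(), group_a = character(),
                      group_b = character(), median_a = numeric(),
                      median_b = numeric(), p_value = numeric()))
  do.call(rbind, out)
}

#' Flag putative positively selected genes and test their enrichment in
#' condition-upregulated sets
#'
#' Candidates are genes with a defined `pi_N/pi_S >= ratio_cutoff`
#' (elevated ratios suggesting relaxed constraint or positive selection).
#' Each condition's upregulated gene set from the differential-expression
#' call table is tested for enrichment of candidates with the upper-tail
#' hypergeometric test of [hypergeom_enrichment()].
#'
#' @param result a `selection_result`.
#' @param de_calls data.frame with columns `gene`, `condition`, `direction`.
#' @param ratio_cutoff candidate threshold on the per-gene ratio (default 1).
#' @param universe gene universe; defaults to all genes with a defined ratio.
#' @return list with `candidates` (character vector) and `enrichment`
#'   (an `enrichment_result`, or NULL when there are no candidates).
#' @export
flag_positive_candidates <- function(result, de_calls, ratio_cutoff = 1.0,
                                     universe = NULL) {
  genes <- result$genes
  tested <- genes$gene[!is.na(genes$ratio)]
  if (is.null(universe)) universe <- tested
  cand <- genes$gene[!is.na(genes$ratio) & genes$ratio >= ratio_cutoff]
  if (length(cand) == 0)
    return(list(candidates = character(0), enrichment = NULL))
  up <- de_calls[de_calls$direction == "up", , drop = FALSE]
  sets <- split(up$gene, up$condition)
  enr <- hypergeom_enrichment(cand, sets, universe)
  list(candidates = cand, enrichment = enr)
}
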