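#' Gene catalog: ordered gene models with family assignment
#'
#' A `gene_catalog` holds the per-scaffold gene order and exon structure
#' that duplicate typing and coverage-based presence calling operate on.
#' It has two components: `genes`, one row per gene with its scaffold,
#' 0-based rank in the scaffold gene order, strand and family; and `exons`,
#' one row per exon with 1-based inclusive genomic spans (GFF3 convention).
#'
#' @param genes data.frame with columns `gene`, `scaffold`, `rank`
#'   (0-based, dense and unique per scaffold), `strand` ("+"/"-") and
#'   `family` (NA for genes without family assignment).
#' @param exons data.frame with columns `gene`, `start`, `end`; spans per
#'   gene must be sorted and non-overlapping.
#' @return an object of class `gene_catalog`.
#' @export
gene_catalog <- function(genes, exons) {
  need <- c("gene", "scaffold", "rank", "strand", "family")
  if (!all(need %in% names(genes)))
    stop_arg("`genes` needs columns: ", paste(need, collapse = ", "))
  if (!all(c("gene", "start", "end") %in% names(exons)))
    stop_arg("`exons` needs columns: gene, start, end")
  if (anyDuplicated(genes$gene))
    stop_arg("duplicate gene identifiers in catalog")
  for (sc in unique(genes$scaffold)) {
    r <- sort(genes$rank[genes$scaffold == sc])
    if (!identical(as.integer(r), seq_along(r) - 1L))
      stop_arg("ranks not dense/unique on scaffold ", sc)
  }
  if (!all(exons$gene %in% genes$gene))
    stop_arg("exon rows reference unknown genes")
  if (any(exons$start < 1) || any(exons$end < exons$start))
    stop_arg("invalid exon spans (1-based inclusive, end >= start)")
  sp <- split(exons, exons$gene)
  for (g in names(sp)) {
    e <- sp[[g]][order(sp[[g]]$start), ]
    if (nrow(e) > 1 && any(e$start[-1] <= e$end[-nrow(e)]))
      stop_arg("overlapping exons for gene ", g)
  }
  genes <- genes[order(genes$scaffold, genes$rank), ]
  rownames(genes) <- NULL
  structure(list(genes = genes, exons = exons), class = "gene_catalog")
}

#' @export
print.gene_catalog <- function(x, ...) {
  cat("gene_catalog:", nrow(x$genes), "genes on",
      length(unique(x$genes$scaffold)), "scaffold(s);",
      length(unique(stats::na.omit(x$genes$family))), "families\n")
  invisible(x)
}

#' Family sizes within a catalog
#'
#' @param catalog a [gene_catalog()].
#' @return named integer vector of member counts per family.
#' @export
family_sizes <- function(catalog) {
  fam <- catalog$genes$family
  table(fam[!is.na(fam)])
}
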