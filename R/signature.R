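# Clade homology signature scoring: per-gene presence scores across
# diatom clades and log2 signature ratios on the pennate/centric,
# raphid/araphid and benthic/planktonic axes.

SIGNATURE_AXES <- list(pennate = c("pennate", "centric"),
                       raphid = c("raphid", "araphid"),
                       benthic = c("benthic", "planktonic"))

#' Per-gene clade presence scores
#'
#' For each gene and clade, the score is the number of species in that
#' clade with a homologous hit divided by the clade census, so it ranges
#' from zero (no hits in the clade) to one (homologs in every clade
#' species).
#'
#' @param hits a `homolog_hits` object (see [generate_hit_table()]): binary
#'   `hits` matrix genes x species, a `species` data.frame with `major`,
#'   `raphe` and `habit` labels, and a `census`.
#' @return object of class `clade_scores`: data.frame with `gene` and one
#'   score column per clade, plus per-gene benthic hit-species counts in
#'   `attr(,"benthic_hits")`.
#' @export
clade_scores <- function(hits) {
  sp <- hits$species
  cl <- list(pennate = sp$major == "pennate",
             centric = sp$major == "centric",
             raphid = sp$raphe == "raphid",
             araphid = sp$raphe == "araphid",
             benthic = sp$habit == "benthic",
             planktonic = sp$habit == "planktonic")
  census <- vapply(cl, sum, integer(1))
  if (any(census == 0))
    stop_arg("empty clade(s) in census: ",
             paste(names(census)[census == 0], collapse = ", "))
  sc <- data.frame(gene = rownames(hits$hits), stringsAsFactors = FALSE)
  benthic_hits <- integer(nrow(sc))
  for (c_name in names(cl)) {
    n_hit <- rowSums(hits$hits[, cl[[c_name]], drop = FALSE])
    sc[[c_name]] <- n_hit / census[c_name]
    if (c_name == "benthic") benthic_hits <- as.integer(n_hit)
  }
  structure(sc, class = c("clade_scores", "data.frame"),
            census = census,
            benthic_hits = stats::setNames(benthic_hits, sc$gene))
}

#' Clade signatures from presence scores
#'
#' The pennate, raphid and benthic signatures are the log2 ratios of the
#' paired clade scores (pennate/centric, raphid/araphid,
#' benthic/planktonic). A positive numerator with a zero denominator gives
#' `+Inf` (absence from every species of the sister clade is maximal
#' evidence, not missing data), a zero numerator with a positive
#' denominator `-Inf`, and two zero scores an undefined signature (`NaN`).
#'
#' @param scores a `clade_scores` object.
#' @return the scores data.frame with added `pennate_signature`,
#'   `raphid_signature`, `benthic_signature` columns (class
#'   `clade_scores`).
#' @export
signature_values <- function(scores) {
  for (axis in names(SIGNATURE_AXES)) {
    num <- scores[[SIGNATURE_AXES[[axis]][1]]]
    den <- scores[[SIGNATURE_AXES[[axis]][2]]]
    scores[[paste0(axis, "_signature")]] <- log2(num / den)
  }
  scores
}

#' Call genes with a high clade signature
#'
#' Transcriptome hit tables cannot prove absence, so a signature alone is
#' not trusted: pennate and raphid flags require signature
#' `>= threshold` (including `+Inf`) AND genomic support from family
#' membership (all diatom genome homologs of the gene's family confined to
#' the claimed clade); benthic flags require signature `>= threshold` AND
#' hits in at least `min_benthic_hits` benthic species.
#'
#' @param table a `clade_scores` with signatures (see
#'   [signature_values()]).
#' @param family_clade_support named logical vector gene -> genomic
#'   support (recycled to all genes if a single value).
#' @param benthic_species_hits named integer vector gene -> benthic
#'   hit-species count; defaults to the counts recorded by
#'   [clade_scores()].
#' @param threshold signature threshold (default 3).
#' @param min_benthic_hits minimum benthic hit species (default 2).
#' @return data.frame with `gene`, logical `pennate_high`, `raphid_high`,
#'   `benthic_high`.
#' @export
call_high_signature <- function(table, family_clade_support = TRUE,
                                benthic_species_hits = NULL,
                                threshold = 3, min_benthic_hits = 2) {
  if (length(family_clade_support) == 1)
    family_clade_support <- stats::setNames(
      rep(family_clade_support, nrow(table)), table$gene)
  if (is.null(benthic_species_hits))
    benthic_species_hits <- attr(table, "benthic_hits")
  support <- family_clade_support[table$gene]
  support[is.na(support)] <- FALSE
  bh <- benthic_species_hits[table$gene]
  bh[is.na(bh)] <- 0L
  pass <- function(sig) !is.nan(sig) & sig >= threshold
  data.frame(
    gene = table$gene,
    pennate_high = pass(table$pennate_signature) & support,
    raphid_high = pass(table$raphid_signature) & support,
    benthic_high = pass(table$benthic_signature) & bh >= min_benthic_hits,
    stringsAsFactors = FALSE)
}

#' Concordance of high-signature calls between stringent and relaxed
#' homolog cutoffs
#'
#' For the genes flagged high under the stringent hit table, reports the
#' fraction whose signature under the relaxed hit table retains the same
#' positive trend (relaxed signature `> 0`), per axis. Undefined (NA)
#' when no gene is flagged on an axis.
#'
#' @param hits_strict,hits_relaxed `homolog_hits` over the same gene
#'   universe.
#' @param family_clade_support,threshold,min_benthic_hits passed to
#'   [call_high_signature()] on the stringent table.
#' @return named numeric vector (`pennate`, `raphid`, `benthic`) of
#'   concordance fractions.
#' @export
robustness_control <- function(hits_strict, hits_relaxed,
                               family_clade_support = TRUE,
                               threshold = 3, min_benthic_hits = 2) {
  if (!identical(rownames(hits_strict$hits), rownames(hits_relaxed$hits)))
    stop_arg("stringent and relaxed tables must share one gene universe")
  strict <- signature_values(clade_scores(hits_strict))
  relaxed <- signature_values(clade_scores(hits_relaxed))
  flags <- call_high_signature(strict, family_clade_support,
                               threshold = threshold,
                               min_benthic_hits = min_benthic_hits)
  out <- c(pennate = NA_real_, raphid = NA_real_, benthic = NA_real_)
  for (axis in names(out)) {
    f <- flags[[paste0(axis, "_high")]]
    if (!any(f)) next
    sig_rel <- relaxed[[paste0(axis, "_signature")]][f]
    out[axis] <- mean(!is.nan(sig_rel) & sig_rel > 0)
  }
  out
}
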