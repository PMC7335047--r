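# Readers and writers for the standard interchange formats: GFF3 via
# rtracklayer, FASTA via Biostrings, TSV tables via base R, and a
# documented minimal VCF dialect for annotated coding SNPs.

#' Write a gene catalog as GFF3
#'
#' Emits gene, mRNA, exon and CDS features (exon and CDS spans coincide
#' here because the catalog models CDS exons only), 1-based inclusive
#' coordinates. Family assignment travels separately (see
#' [write_family_tsv()]).
#'
#' @param catalog a [gene_catalog()].
#' @param path output file.
#' @export
write_catalog_gff3 <- function(catalog, path) {
  g <- catalog$genes
  ex <- catalog$exons
  feats <- list()
  for (i in seq_len(nrow(g))) {
    e <- ex[ex$gene == g$gene[i], , drop = FALSE]
    e <- e[order(e$start), ]
    id <- g$gene[i]
    cum <- cumsum(c(0L, e$end - e$start + 1L))[seq_len(nrow(e))]
    feats[[length(feats) + 1L]] <- data.frame(
      seqnames = g$scaffold[i],
      start = c(min(e$start), min(e$start), e$start, e$start),
      end = c(max(e$end), max(e$end), e$end, e$end),
      type = c("gene", "mRNA", rep("exon", nrow(e)), rep("CDS", nrow(e))),
      strand = g$strand[i],
      ID = c(id, paste0(id, ".1"),
             paste0(id, ".1.exon", seq_len(nrow(e))),
             paste0(id, ".1.cds", seq_len(nrow(e)))),
      Parent = c(NA, id, rep(paste0(id, ".1"), 2 * nrow(e))),
      phase = c(NA, NA, rep(NA, nrow(e)), (3L - cum %% 3L) %% 3L),
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, feats)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqnames,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- df$Parent
  S4Vectors::mcols(gr)$phase <- df$phase
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a gene catalog from GFF3 plus a family table
#'
#' Gene ranks are assigned densely per scaffold from the genomic order of
#' gene starts (0-based).
#'
#' @param gff_path GFF3 file with gene and exon features.
#' @param family_path optional TSV (columns `gene`, `family`); genes
#'   without an entry get NA.
#' @return a [gene_catalog()].
#' @export
read_catalog_gff3 <- function(gff_path, family_path = NULL) {
  gr <- rtracklayer::import(gff_path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  is_gene <- md$type == "gene"
  genes <- data.frame(
    gene = as.character(md$ID[is_gene]),
    scaffold = as.character(GenomicRanges::seqnames(gr)[is_gene]),
    start = GenomicRanges::start(gr)[is_gene],
    strand = as.character(GenomicRanges::strand(gr)[is_gene]),
    stringsAsFactors = FALSE)
  genes <- genes[order(genes$scaffold, genes$start), ]
  genes$rank <- unlist(lapply(split(genes$gene, genes$scaffold),
                              function(x) seq_along(x) - 1L), use.names = FALSE)
  fam <- rep(NA_character_, nrow(genes))
  if (!is.null(family_path)) {
    ft <- utils::read.delim(family_path, stringsAsFactors = FALSE)
    fam <- ft$family[match(genes$gene, ft$gene)]
  }
  genes$family <- fam
  is_ex <- md$type == "exon"
  parent <- as.character(unlist(md$Parent[is_ex]))
  exons <- data.frame(
    gene = sub("\\.1$", "", parent),
    start = GenomicRanges::start(gr)[is_ex],
    end = GenomicRanges::end(gr)[is_ex],
    stringsAsFactors = FALSE)
  gene_catalog(genes[, c("gene", "scaffold", "rank", "strand", "family")],
               exons)
}

#' Write a gene-to-family assignment TSV
#' @param catalog a [gene_catalog()].
#' @param path output file.
#' @export
write_family_tsv <- function(catalog, path) {
  g <- catalog$genes[!is.na(catalog$genes$family), c("gene", "family")]
  utils::write.table(g, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a numeric matrix (copy counts, coverage, hits, expression) as TSV
#' @param m matrix with dimnames; rows become the first column `id`.
#' @param path output file.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), as.data.frame(m),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a matrix TSV written by [write_matrix_tsv()]
#' @param path input file.
#' @return numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write CDS sequences as FASTA
#' @param cds_set named character vector or `DNAStringSet`.
#' @param path output file.
#' @export
write_cds_fasta <- function(cds_set, path) {
  seqs <- if (is.character(cds_set)) cds_set else
    stats::setNames(as.character(cds_set), names(cds_set))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read CDS sequences from FASTA
#' @param path input file.
#' @return named character vector.
#' @export
read_cds_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(dss), names(dss))
}

#' Write an annotated variant table as TSV
#' @param variants variant data.frame (see [generate_variants()]).
#' @param path output file.
#' @export
write_variants_tsv <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a variant TSV
#' @param path input file.
#' @return variant data.frame.
#' @export
read_variants_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write variants in a minimal VCF dialect
#'
#' One record per SNP: CHROM is the gene id, POS the 1-based position in
#' the spliced CDS, and INFO carries `EFF` (effect class), `AC` (alternate
#' allele count) and `AN` (called chromosome count).
#'
#' @param variants variant data.frame.
#' @param path output file.
#' @export
write_variants_vcf <- function(variants, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=EFF,Number=1,Type=String,Description=\"Coding effect class\">",
    "##INFO=<ID=AC,Number=1,Type=Integer,Description=\"Alternate allele count\">",
    "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Called chromosome count\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tEFF=%s;AC=%d;AN=%d",
                  variants$gene, as.integer(variants$pos), variants$ref,
                  variants$alt, variants$effect,
                  as.integer(variants$alt_count),
                  as.integer(variants$n_chrom))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read variants from the minimal VCF dialect
#' @param path input file.
#' @return variant data.frame.
#' @export
read_variants_vcf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0)
    return(data.frame(gene = character(), pos = integer(), ref = character(),
                      alt = character(), effect = character(),
                      alt_count = integer(), n_chrom = integer(),
                      stringsAsFactors = FALSE))
  f <- do.call(rbind, strsplit(lines, "\t"))
  info <- function(key) sub(sprintf(".*%s=([^;]+).*", key), "\\1", f[, 8])
  data.frame(gene = f[, 1], pos = as.integer(f[, 2]), ref = f[, 4],
             alt = f[, 5], effect = info("EFF"),
             alt_count = as.integer(info("AC")),
             n_chrom = as.integer(info("AN")), stringsAsFactors = FALSE)
}
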