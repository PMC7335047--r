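# Seeded generators for every input the pipeline consumes, with planted
# ground truth. All randomness flows through with_seed(); identical seeds
# give identical outputs.

new_truth <- function(...) {
  base <- list(expanded_family_ids = character(0),
               tandem_arrays = list(),
               block_pairs = list(),
               gene_class = character(0),
               per_gene_pi = NULL,
               clade_membership = character(0),
               de_truth = NULL)
  args <- list(...)
  base[names(args)] <- args
  structure(base, class = "synthetic_truth")
}

#' Generate a gene catalog with planted tandem arrays and collinear blocks
#'
#' Lays out `n_scaffolds * genes_per_scaffold` gene models. Planted tandem
#' arrays are runs of 2-4 consecutive same-family genes on one scaffold;
#' planted blocks copy a run of 3-5 family labels from one scaffold to
#' another (possibly order-inverted), yielding chains of anchor pairs at
#' unit gaps. Background genes draw a family from the configured pool only
#' when no copy of it lies within `tandem_gap` ranks on the same scaffold,
#' and otherwise found a fresh singleton family, so no unplanned tandem
#' array can arise. Exon spans are 1-based inclusive; CDS lengths are
#' multiples of 3 in 300-3000 nt.
#'
#' @param n_scaffolds,genes_per_scaffold,n_families positive counts;
#'   `n_families` is the pool of reusable (multi-copy) family identifiers.
#' @param tandem_rate,block_rate probabilities controlling the expected
#'   fraction of genes in planted tandem arrays and the expected number of
#'   planted blocks per scaffold.
#' @param seed integer seed.
#' @param tandem_gap maximum within-array rank gap honoured when planting.
#' @return list with `catalog` (a [gene_catalog()]) and `truth`
#'   (`synthetic_truth` with `tandem_arrays` and `block_pairs`).
#' @export
generate_gene_catalog <- function(n_scaffolds, genes_per_scaffold, n_families,
                                  tandem_rate, block_rate, seed,
                                  tandem_gap = 15) {
  n_scaffolds <- check_count(n_scaffolds, "n_scaffolds")
  genes_per_scaffold <- check_count(genes_per_scaffold, "genes_per_scaffold")
  n_families <- check_count(n_families, "n_families")
  tandem_rate <- check_prob(tandem_rate, "tandem_rate")
  block_rate <- check_prob(block_rate, "block_rate")
  with_seed(seed, {
    scafs <- sprintf("sc%02d", seq_len(n_scaffolds))
    fam <- matrix(NA_character_, nrow = genes_per_scaffold, ncol = n_scaffolds,
                  dimnames = list(NULL, scafs))
    gene_id <- function(s, pos) sprintf("%s_g%03d", s, pos)
    pool <- sprintf("F%04d", seq_len(n_families))
    pool_next <- 1L
    take_family <- function() {
      if (pool_next > length(pool)) return(NA_character_)
      f <- pool[pool_next]; pool_next <<- pool_next + 1L
      f
    }
    free_run <- function(col, len) {
      # random start of a run of `len` free slots, or NA
      free <- is.na(fam[, col])
      ok <- which(vapply(seq_len(genes_per_scaffold - len + 1L),
                         function(i) all(free[i:(i + len - 1L)]), logical(1)))
      if (length(ok) == 0) return(NA_integer_)
      ok[sample.int(length(ok), 1L)]
    }
    tandem_arrays <- list()
    for (s in scafs) {
      budget <- stats::rbinom(1L, genes_per_scaffold, tandem_rate)
      while (budget >= 2L) {
        m <- min(sample(2:4, 1L), budget)
        if (m < 2L) break
        start <- free_run(s, m)
        f <- take_family()
        if (is.na(start) || is.na(f)) break
        fam[start:(start + m - 1L), s] <- f
        tandem_arrays[[length(tandem_arrays) + 1L]] <-
          gene_id(s, start:(start + m - 1L))
        budget <- budget - m
      }
    }
    block_pairs <- list()
    if (n_scaffolds >= 2L) {
      n_blk <- stats::rbinom(1L, n_scaffolds, block_rate)
      for (b in seq_len(n_blk)) {
        len <- sample(3:5, 1L)
        pick <- sample(scafs, 2L)
        a <- free_run(pick[1], len); d <- free_run(pick[2], len)
        fams <- replicate(len, take_family())
        if (is.na(a) || is.na(d) || anyNA(fams)) break
        fam[a:(a + len - 1L), pick[1]] <- fams
        inverted <- stats::runif(1) < 0.5
        dest_fams <- if (inverted) rev(fams) else fams
        fam[d:(d + len - 1L), pick[2]] <- dest_fams
        src <- gene_id(pick[1], a:(a + len - 1L))
        dst <- gene_id(pick[2], d:(d + len - 1L))
        if (inverted) dst <- rev(dst)
        block_pairs[[length(block_pairs) + 1L]] <-
          data.frame(gene_a = src, gene_b = dst, stringsAsFactors = FALSE)
      }
    }
    # background fill: pool reuse only beyond tandem_gap on the same scaffold
    planted <- pool[seq_len(pool_next - 1L)]
    background_pool <- setdiff(pool, planted)
    uses <- stats::setNames(integer(length(background_pool)), background_pool)
    singleton_next <- 1L
    for (s in scafs) {
      for (pos in which(is.na(fam[, s]))) {
        lo <- max(1L, pos - tandem_gap); hi <- min(genes_per_scaffold, pos + tandem_gap)
        nearby <- fam[lo:hi, s]
        eligible <- setdiff(background_pool[uses < 2L], nearby[!is.na(nearby)])
        if (length(eligible) > 0 && stats::runif(1) < 0.35) {
          pickf <- eligible[sample.int(length(eligible), 1L)]
          uses[pickf] <- uses[pickf] + 1L
          fam[pos, s] <- pickf
        } else {
          fam[pos, s] <- sprintf("S%05d", singleton_next)
          singleton_next <- singleton_next + 1L
        }
      }
    }
    # gene models with exon structure
    rows <- list(); exon_rows <- list()
    for (s in scafs) {
      cursor <- 1L
      for (pos in seq_len(genes_per_scaffold)) {
        g <- gene_id(s, pos)
        n_ex <- sample(1:3, 1L)
        cds_len <- 3L * sample(100:1000, 1L)
        cuts <- if (n_ex > 1)
          sort(sample(seq_len(cds_len - 1L), n_ex - 1L)) else integer(0)
        ex_len <- diff(c(0L, cuts, cds_len))
        start <- cursor + sample(200:1000, 1L)
        for (k in seq_len(n_ex)) {
          exon_rows[[length(exon_rows) + 1L]] <- data.frame(
            gene = g, start = start, end = start + ex_len[k] - 1L,
            stringsAsFactors = FALSE)
          start <- start + ex_len[k] + sample(50:200, 1L)
        }
        cursor <- start
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, scaffold = s, rank = pos - 1L,
          strand = sample(c("+", "-"), 1L), family = fam[pos, s],
          stringsAsFactors = FALSE)
      }
    }
    catalog <- gene_catalog(do.call(rbind, rows), do.call(rbind, exon_rows))
    list(catalog = catalog,
         truth = new_truth(tandem_arrays = tandem_arrays,
                           block_pairs = block_pairs))
  })
}

#' Generate a multi-species family copy-number matrix with planted expansions
#'
#' Background copy counts are `1 + Poisson(0.5)` per family and species;
#' each planted family multiplies the focal species' background count by
#' `expansion_multiplier`.
#'
#' @param n_species number of species (>= 3; the Z-score is undefined below).
#' @param n_families number of families.
#' @param expansion_fraction probability that a family is planted expanded.
#' @param expansion_multiplier copy-count multiplier (>= 3) for planted
#'   families in the focal species.
#' @param seed integer seed.
#' @param focal focal species name (first column).
#' @return list with `matrix` (integer matrix families x species, the focal
#'   species stored in `attr(,"focal")`) and `truth` (planted family ids).
#' @export
generate_copy_matrix <- function(n_species, n_families, expansion_fraction,
                                 expansion_multiplier, seed,
                                 focal = "sp01") {
  n_species <- check_count(n_species, "n_species", min = 3L)
  n_families <- check_count(n_families, "n_families")
  expansion_fraction <- check_prob(expansion_fraction, "expansion_fraction")
  if (!is.numeric(expansion_multiplier) || length(expansion_multiplier) != 1L ||
      expansion_multiplier < 3)
    stop_arg("`expansion_multiplier` must be a single number >= 3")
  with_seed(seed, {
    species <- c(focal, sprintf("sp%02d", 1L + seq_len(n_species - 1L)))
    fams <- sprintf("F%04d", seq_len(n_families))
    m <- matrix(1L + stats::rpois(n_families * n_species, 0.5),
                nrow = n_families, dimnames = list(fams, species))
    planted <- fams[stats::runif(n_families) < expansion_fraction]
    m[planted, focal] <- as.integer(round(m[planted, focal] *
                                            expansion_multiplier))
    attr(m, "focal") <- focal
    list(matrix = m, truth = new_truth(expanded_family_ids = planted))
  })
}

#' Generate a strain presence/absence coverage matrix with planted classes
#'
#' Emulates horizontal exon coverage of reference genes across resequenced
#' strains. Core genes draw coverage in `[0.8, 1]` for every strain;
#' softcore genes are dropped (coverage `< 0.05`) in 1 to
#' `n - ceiling(0.95 n)` non-reference strains; dispensable genes are
#' dropped in a clade-correlated subset of at least
#' `n - ceiling(0.95 n) + 1` strains, drawn preferentially from one clade.
#' The first strain is the reference and has coverage 1 for every gene.
#'
#' @param n_strains,n_genes positive counts.
#' @param core_fraction,softcore_fraction planted class fractions
#'   (sum <= 1; the rest is dispensable).
#' @param clade_sizes integer vector summing to `n_strains`.
#' @param seed integer seed.
#' @return list with `coverage` (genes x strains matrix in \[0,1\] with
#'   `attr(,"clade")` strain labels and `attr(,"reference")`) and `truth`
#'   (`gene_class`, `clade_membership`).
#' @export
generate_strain_matrix <- function(n_strains, n_genes, core_fraction,
                                   softcore_fraction, clade_sizes, seed) {
  n_strains <- check_count(n_strains, "n_strains", min = 2L)
  n_genes <- check_count(n_genes, "n_genes")
  core_fraction <- check_prob(core_fraction, "core_fraction")
  softcore_fraction <- check_prob(softcore_fraction, "softcore_fraction")
  if (core_fraction + softcore_fraction > 1)
    stop_arg("core_fraction + softcore_fraction must be <= 1")
  if (sum(clade_sizes) != n_strains)
    stop_arg("clade_sizes must sum to n_strains")
  max_soft_absent <- n_strains - as.integer(ceiling(0.95 * n_strains))
  if (softcore_fraction > 0 && max_soft_absent < 1)
    stop_arg("too few strains for a softcore class at the 95% threshold")
  with_seed(seed, {
    strains <- sprintf("strain%02d", seq_len(n_strains))
    clade <- rep(sprintf("clade%d", seq_along(clade_sizes)), clade_sizes)
    names(clade) <- strains
    genes <- sprintf("gene%05d", seq_len(n_genes))
    n_core <- round(core_fraction * n_genes)
    n_soft <- round(softcore_fraction * n_genes)
    cls <- rep(c("core", "softcore", "dispensable"),
               c(n_core, n_soft, n_genes - n_core - n_soft))
    names(cls) <- genes
    cov <- matrix(stats::runif(n_genes * n_strains, 0.8, 1.0),
                  nrow = n_genes, dimnames = list(genes, strains))
    nonref <- strains[-1]
    min_disp_absent <- max_soft_absent + 1L
    for (g in genes[cls == "softcore"]) {
      k <- sample.int(max_soft_absent, 1L)
      cov[g, sample(nonref, k)] <- stats::runif(k, 0, 0.049)
    }
    for (g in genes[cls == "dispensable"]) {
      cl <- sample(unique(clade), 1L)
      cand <- setdiff(strains[clade == cl], strains[1])
      if (length(cand) < min_disp_absent)
        cand <- unique(c(cand, sample(nonref)))
      k <- max(min_disp_absent, stats::rbinom(1L, length(cand), 0.6))
      k <- min(k, length(cand))
      drop <- sample(cand, k)
      cov[g, drop] <- stats::runif(k, 0, 0.049)
    }
    cov[, 1] <- 1.0  # reference strain covers every reference gene
    attr(cov, "clade") <- clade
    attr(cov, "reference") <- strains[1]
    list(coverage = cov,
         truth = new_truth(gene_class = cls, clade_membership = clade))
  })
}

# Expected per-SNP heterozygosity under the generator's allele-frequency
# model: q ~ Beta(shape1, shape2) folded to the minor allele, allele count
# c = round(f * n) clamped to [1, floor(n/2)]. Computed exactly from the
# Beta CDF so SNP dosing is unbiased for the target pi.
expected_het <- function(n, shape1 = 1, shape2 = 3) {
  cmax <- floor(n / 2)
  probs <- numeric(cmax)
  mass_below <- function(f) {
    # P(min(q, 1-q) <= f)
    stats::pbeta(f, shape1, shape2) + (1 - stats::pbeta(1 - f, shape1, shape2))
  }
  lo <- 0
  for (c in seq_len(cmax)) {
    hi <- if (c == cmax) 0.5 else (c + 0.5) / n
    probs[c] <- mass_below(hi) - mass_below(lo)
    lo <- hi
  }
  probs <- probs / sum(probs)
  h <- vapply(seq_len(cmax), function(c) {
    p <- c / n
    n / (n - 1) * 2 * p * (1 - p)
  }, numeric(1))
  sum(probs * h)
}

#' Generate annotated coding SNPs with controlled synonymous and
#' nonsynonymous diversity
#'
#' For each CDS the effect class of every possible single-base change is
#' computed from the codon table; synonymous SNPs are only placed at
#' positions with a synonymous alternate allele (and dosed against the
#' Nei-Gojobori synonymous site count `L_S`), nonsynonymous SNPs likewise
#' against `L_N`. Minor allele frequencies are drawn from a Beta(1,3)
#' folded to the minor allele; the number of SNPs per gene is Poisson with
#' mean `target * L / E[h]`, where `E[h]` is the exact expected per-SNP
#' heterozygosity under that frequency model, so the expected estimated
#' `pi` equals the target.
#'
#' @param cds_set named character vector (or `DNAStringSet`) of CDS
#'   sequences; lengths multiples of 3, no internal stop codons.
#' @param n_chromosomes called chromosome count per site (>= 2).
#' @param target_pi_s,target_pi_n target per-site diversities (>= 0).
#' @param seed integer seed.
#' @return a variant table data.frame (`gene`, `pos`, `ref`, `alt`,
#'   `effect`, `alt_count`, `n_chrom`).
#' @export
generate_variants <- function(cds_set, n_chromosomes, target_pi_s,
                              target_pi_n, seed) {
  n_chromosomes <- check_count(n_chromosomes, "n_chromosomes", min = 2L)
  if (target_pi_s < 0 || target_pi_n < 0)
    stop_arg("targets must be >= 0")
  seqs <- as_cds_vector(cds_set)
  if (is.null(names(seqs))) stop_arg("cds_set must be named")
  empty <- data.frame(gene = character(), pos = integer(), ref = character(),
                      alt = character(), effect = character(),
                      alt_count = integer(), n_chrom = integer(),
                      stringsAsFactors = FALSE)
  if (target_pi_s == 0 && target_pi_n == 0) return(empty)
  eh <- expected_het(n_chromosomes)
  with_seed(seed, {
    rows <- list()
    for (g in names(seqs)) {
      seq <- check_cds(seqs[[g]], g)
      ch <- cds_change_classes(seq)
      sc <- count_sites(seq)
      used <- integer(0)
      for (cls in c("synonymous", "nonsynonymous")) {
        target <- if (cls == "synonymous") target_pi_s else target_pi_n
        L <- if (cls == "synonymous") sc$L_S else sc$L_N
        if (target == 0) next
        cand <- ch[ch$effect == cls & !(ch$pos %in% used), , drop = FALSE]
        pos_avail <- unique(cand$pos)
        m <- min(stats::rpois(1L, target * L / eh), length(pos_avail))
        if (m == 0) next
        at <- sample(pos_avail, m)
        for (p in at) {
          opts <- cand[cand$pos == p, , drop = FALSE]
          pick <- opts[sample.int(nrow(opts), 1L), ]
          q <- stats::rbeta(1, 1, 3)
          f <- min(q, 1 - q)
          cnt <- min(max(1L, as.integer(round(f * n_chromosomes))),
                     floor(n_chromosomes / 2))
          rows[[length(rows) + 1L]] <- data.frame(
            gene = g, pos = p, ref = pick$ref, alt = pick$alt,
            effect = cls, alt_count = cnt, n_chrom = n_chromosomes,
            stringsAsFactors = FALSE)
        }
        used <- c(used, at)
      }
    }
    if (length(rows) == 0) empty else do.call(rbind, rows)
  })
}

#' Generate random CDS sequences
#'
#' Open reading frames without internal stop codons, lengths multiples of 3
#' drawn in 300-3000 nt.
#'
#' @param n_genes number of sequences.
#' @param seed integer seed.
#' @param len_range CDS length range in codons.
#' @return named character vector.
#' @export
generate_cds_set <- function(n_genes, seed, len_range = c(100L, 1000L)) {
  n_genes <- check_count(n_genes, "n_genes")
  codons <- names(Biostrings::GENETIC_CODE)
  sense <- codons[Biostrings::GENETIC_CODE != "*"]
  with_seed(seed, {
    out <- vapply(seq_len(n_genes), function(i) {
      L <- sample(len_range[1]:len_range[2], 1L)
      paste(c("ATG", sample(sense, L - 1L, replace = TRUE)), collapse = "")
    }, character(1))
    names(out) <- sprintf("gene%05d", seq_len(n_genes))
    out
  })
}

#' Generate a clade-structured homolog hit table
#'
#' Species are built from a clade census (defaults to 32 pennate, 56
#' centric, 18 raphid, 14 araphid, 8 benthic, 73 planktonic); raphid and
#' araphid species are subsets of the pennates, benthic/planktonic labels
#' are assigned across all species with any remainder left unlabeled. Each
#' gene belongs to a group, and its hit probability for a species is the
#' mean of the group's probabilities over the clade labels that species
#' carries (or `default_prob` when none match).
#'
#' @param n_genes number of query genes.
#' @param presence_probs named list (one entry per gene group) of named
#'   probability vectors over clade labels, e.g.
#'   `list(benthic_group = c(benthic = 1, planktonic = 0.1))`.
#' @param gene_groups optional character vector (recycled) assigning each
#'   gene to a group name; defaults to an even split over the groups.
#' @param clade_census named integer vector with entries `pennate`,
#'   `centric`, `raphid`, `araphid`, `benthic`, `planktonic`.
#' @param default_prob hit probability for species carrying no label named
#'   in the group's vector.
#' @param seed integer seed.
#' @return object of class `homolog_hits`: list with binary `hits`
#'   (genes x species), `species` data.frame (`species`, `major`, `raphe`,
#'   `habit`), `census`, and `gene_groups`.
#' @export
generate_hit_table <- function(n_genes, presence_probs,
                               gene_groups = NULL,
                               clade_census = c(pennate = 32, centric = 56,
                                                raphid = 18, araphid = 14,
                                                benthic = 8, planktonic = 73),
                               default_prob = 0.5, seed = 1) {
  n_genes <- check_count(n_genes, "n_genes")
  for (grp in names(presence_probs)) {
    pv <- presence_probs[[grp]]
    if (any(pv < 0 | pv > 1))
      stop_arg("presence probability outside [0, 1] in group ", grp)
  }
  cc <- clade_census
  need <- c("pennate", "centric", "raphid", "araphid", "benthic", "planktonic")
  if (!all(need %in% names(cc))) stop_arg("clade_census needs: ",
                                          paste(need, collapse = ", "))
  if (cc["raphid"] + cc["araphid"] > cc["pennate"])
    stop_arg("raphid + araphid exceed pennate census")
  n_sp <- cc["pennate"] + cc["centric"]
  if (cc["benthic"] + cc["planktonic"] > n_sp)
    stop_arg("benthic + planktonic exceed species count")
  with_seed(seed, {
    species <- sprintf("mmetsp%03d", seq_len(n_sp))
    major <- rep(c("pennate", "centric"), c(cc["pennate"], cc["centric"]))
    raphe <- rep("unlabeled", n_sp)
    raphe[seq_len(cc["raphid"])] <- "raphid"
    raphe[cc["raphid"] + seq_len(cc["araphid"])] <- "araphid"
    habit <- rep("unlabeled", n_sp)
    habit[sample.int(n_sp, cc["benthic"] + cc["planktonic"])] <-
      rep(c("benthic", "planktonic"), c(cc["benthic"], cc["planktonic"]))
    sp <- data.frame(species = species, major = major, raphe = raphe,
                     habit = habit, stringsAsFactors = FALSE)
    groups <- names(presence_probs)
    gene_groups <- if (is.null(gene_groups))
      rep_len(groups, n_genes) else rep_len(gene_groups, n_genes)
    genes <- sprintf("query%05d", seq_len(n_genes))
    names(gene_groups) <- genes
    hits <- matrix(0L, nrow = n_genes, ncol = n_sp,
                   dimnames = list(genes, species))
    sp_labels <- lapply(seq_len(n_sp), function(j)
      setdiff(c(major[j], raphe[j], habit[j]), "unlabeled"))
    for (i in seq_len(n_genes)) {
      pv <- presence_probs[[gene_groups[i]]]
      pr <- vapply(sp_labels, function(lab) {
        m <- intersect(lab, names(pv))
        if (length(m) == 0) default_prob else mean(pv[m])
      }, numeric(1))
      hits[i, ] <- as.integer(stats::runif(n_sp) < pr)
    }
    structure(list(hits = hits, species = sp, census = cc[need],
                   gene_groups = gene_groups),
              class = "homolog_hits")
  })
}

#' Generate a condition-structured expression atlas with planted
#' upregulation
#'
#' Counts follow a negative-binomial model (per-gene log-normal baseline,
#' fixed dispersion); genes of a planted (family, condition) pair have
#' their mean multiplied by `2^log2fc` in that condition's samples. TPM is
#' computed from counts and gene lengths. The differential-expression call
#' table is produced by thresholding the planted true effects at
#' `|log2 fold change| > 1` (no model fitting).
#'
#' @param n_genes number of genes.
#' @param condition_design named integer vector: condition -> replicate
#'   count (all >= 1).
#' @param planted_up data.frame with columns `family`, `condition`,
#'   `log2fc` (may have zero rows).
#' @param seed integer seed.
#' @param family_size genes per family for the automatic family assignment.
#' @param dispersion negative-binomial dispersion (1/size).
#' @return list with `expr` (class `expression_matrix`: `counts`, `tpm`,
#'   `samples`, `gene_length`, `gene_family`), `de_calls` (gene, condition,
#'   direction, log2fc, padj) and `truth` (`de_truth`).
#' @export
generate_expression <- function(n_genes, condition_design, planted_up, seed,
                                family_size = 4L, dispersion = 0.1) {
  n_genes <- check_count(n_genes, "n_genes")
  if (length(condition_design) == 0 || is.null(names(condition_design)))
    stop_arg("condition_design must be a named vector of replicate counts")
  if (any(condition_design < 1))
    stop_arg("every condition needs at least one replicate")
  with_seed(seed, {
    genes <- sprintf("gene%05d", seq_len(n_genes))
    fams <- sprintf("F%04d", ceiling(seq_len(n_genes) / family_size))
    names(fams) <- genes
    conds <- rep(names(condition_design), condition_design)
    samples <- data.frame(
      sample = sprintf("%s_rep%d", conds,
                       unlist(lapply(condition_design, seq_len))),
      condition = conds, stringsAsFactors = FALSE)
    len <- 3L * sample(100:1000, n_genes, replace = TRUE)
    base_mu <- exp(stats::rnorm(n_genes, log(100), 1))
    lfc <- matrix(0, nrow = n_genes, ncol = length(condition_design),
                  dimnames = list(genes, names(condition_design)))
    if (nrow(planted_up) > 0) {
      for (i in seq_len(nrow(planted_up))) {
        f <- planted_up$family[i]; cn <- planted_up$condition[i]
        if (!cn %in% colnames(lfc))
          stop_arg("planted condition not in design: ", cn)
        lfc[fams == f, cn] <- planted_up$log2fc[i]
      }
    }
    counts <- matrix(0L, nrow = n_genes, ncol = nrow(samples),
                     dimnames = list(genes, samples$sample))
    for (j in seq_len(nrow(samples))) {
      mu <- base_mu * 2^lfc[, samples$condition[j]]
      counts[, j] <- stats::rnbinom(n_genes, mu = mu, size = 1 / dispersion)
    }
    rate <- counts / len
    tpm <- sweep(rate, 2, colSums(rate), "/") * 1e6
    de_rows <- list()
    de_truth <- matrix("null", nrow = n_genes, ncol = length(condition_design),
                       dimnames = list(genes, names(condition_design)))
    if (nrow(planted_up) > 0) {
      for (i in seq_len(nrow(planted_up))) {
        l2 <- planted_up$log2fc[i]
        if (abs(l2) <= 1) next
        f <- planted_up$family[i]; cn <- planted_up$condition[i]
        members <- genes[fams == f]
        dir <- if (l2 > 0) "up" else "down"
        de_truth[members, cn] <- dir
        de_rows[[length(de_rows) + 1L]] <- data.frame(
          gene = members, condition = cn, direction = dir, log2fc = l2,
          padj = 1e-4, stringsAsFactors = FALSE)
      }
    }
    de_calls <- if (length(de_rows) == 0)
      data.frame(gene = character(), condition = character(),
                 direction = character(), log2fc = numeric(),
                 padj = numeric(), stringsAsFactors = FALSE)
    else do.call(rbind, de_rows)
    expr <- structure(list(counts = counts, tpm = tpm, samples = samples,
                           gene_length = stats::setNames(len, genes),
                           gene_family = fams),
                      class = "expression_matrix")
    list(expr = expr, de_calls = de_calls,
         truth = new_truth(de_truth = de_truth))
  })
}
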