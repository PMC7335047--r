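# Independent oracles: brute-force / enumeration re-implementations used
# to cross-check the package's detectors on small inputs. These stay
# deliberately naive and share no code with the implementation.

# Leave-one-out standard score and population variance by direct summation.
oracle_zscore <- function(counts, focal_idx, sd_floor = 1) {
  others <- counts[-focal_idx]
  mu <- sum(others) / length(others)
  sd_o <- sqrt(sum((others - mu)^2) / length(others))
  mu_all <- sum(counts) / length(counts)
  list(z = (counts[focal_idx] - mu) / max(sd_o, sd_floor),
       variance = sum((counts - mu_all)^2) / length(counts))
}

# Tandem arrays by exhaustive pairing + transitive closure.
oracle_tandem <- function(catalog, tandem_gap = 15) {
  g <- catalog$genes[!is.na(catalog$genes$family), ]
  n <- nrow(g)
  linked <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && g$scaffold[i] == g$scaffold[j] &&
        g$family[i] == g$family[j] &&
        abs(g$rank[i] - g$rank[j]) <= tandem_gap)
      linked[i, j] <- TRUE
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (linked[i, j] && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- list()
  for (cc in unique(comp)) {
    members <- g$gene[comp == cc]
    if (length(members) >= 2) out[[length(out) + 1L]] <- sort(members)
  }
  out
}

# All-chains DFS search for the best anchor chain (longest, then smallest
# rank span, then lexicographically smallest anchor sequence).
oracle_best_chain <- function(anc, gap_size) {
  n <- nrow(anc)
  best <- NULL
  score <- function(path) {
    span <- (anc$a[path[length(path)]] - anc$a[path[1]]) +
      abs(anc$b[path[length(path)]] - anc$b[path[1]])
    lex <- paste(paste(anc$gene_a[path], anc$gene_b[path], sep = "|"),
                 collapse = " ")
    list(len = length(path), span = span, lex = lex)
  }
  better <- function(p, q) {
    if (is.null(q)) return(TRUE)
    sp <- score(p); sq <- score(q)
    if (sp$len != sq$len) return(sp$len > sq$len)
    if (sp$span != sq$span) return(sp$span < sq$span)
    sp$lex < sq$lex
  }
  extend <- function(path, orient) {
    last <- path[length(path)]
    if (length(path) >= 2 && better(path, best)) best <<- path
    for (nx in seq_len(n)) {
      da <- anc$a[nx] - anc$a[last]
      db <- orient * (anc$b[nx] - anc$b[last])
      if (da >= 1 && da <= gap_size && db >= 1 && db <= gap_size)
        extend(c(path, nx), orient)
    }
  }
  for (start in seq_len(n)) for (orient in c(1, -1))
    extend(start, orient)
  if (is.null(best)) NULL else anc[best, ]
}

# Full block pipeline with the DFS chain search: collapse tandem arrays,
# enumerate anchors by double loop, extract chains best-first, merge close
# same-orientation chains, filter by min_anchors. Returns a set of
# canonical anchor-key strings, one per block.
oracle_blocks <- function(catalog, min_anchors = 3, gap_size = 15,
                          cluster_gap = 15, tandem_gap = 15) {
  g <- catalog$genes[!is.na(catalog$genes$family), ]
  for (arr in oracle_tandem(catalog, tandem_gap)) {
    ranks <- g$rank[match(arr, g$gene)]
    drop <- arr[-which.min(ranks)]
    g <- g[!g$gene %in% drop, ]
  }
  anchors <- NULL
  n <- nrow(g)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    if (g$family[i] != g$family[j]) next
    ii <- i; jj <- j
    if (g$scaffold[ii] > g$scaffold[jj] ||
        (g$scaffold[ii] == g$scaffold[jj] && g$rank[ii] > g$rank[jj])) {
      tmp <- ii; ii <- jj; jj <- tmp
    }
    anchors <- rbind(anchors, data.frame(
      pair = paste(g$scaffold[ii], g$scaffold[jj]),
      gene_a = g$gene[ii], gene_b = g$gene[jj],
      a = g$rank[ii], b = g$rank[jj], stringsAsFactors = FALSE))
  }
  chains <- list()
  if (!is.null(anchors)) {
    for (pr in unique(anchors$pair)) {
      pool <- anchors[anchors$pair == pr, , drop = FALSE]
      repeat {
        ch <- oracle_best_chain(pool, gap_size)
        if (is.null(ch)) break
        chains[[length(chains) + 1L]] <-
          list(pair = pr, anchors = ch,
               orient = if (ch$b[nrow(ch)] >= ch$b[1]) "same" else "inverted")
        pool <- pool[!paste(pool$gene_a, pool$gene_b) %in%
                       paste(ch$gene_a, ch$gene_b), , drop = FALSE]
        if (nrow(pool) < 2) break
      }
    }
  }
  # single-linkage merge of close same-pair same-orientation chains
  repeat {
    merged <- FALSE
    if (length(chains) >= 2) {
      for (i in seq_len(length(chains) - 1)) {
        for (j in seq((i + 1), length(chains))) {
          ci <- chains[[i]]; cj <- chains[[j]]
          if (ci$pair != cj$pair || ci$orient != cj$orient) next
          gapd <- function(x, y)
            max(0, max(min(x), min(y)) - min(max(x), max(y)))
          if (gapd(ci$anchors$a, cj$anchors$a) < cluster_gap &&
              gapd(ci$anchors$b, cj$anchors$b) < cluster_gap) {
            ci$anchors <- rbind(ci$anchors, cj$anchors)
            chains[[i]] <- ci
            chains[[j]] <- NULL
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
    }
    if (!merged) break
  }
  keys <- character(0)
  for (ch in chains) {
    if (nrow(ch$anchors) < min_anchors) next
    keys <- c(keys, paste(sort(paste(ch$anchors$gene_a, ch$anchors$gene_b,
                                     sep = "|")), collapse = " "))
  }
  sort(keys)
}

# canonical anchor-key strings for the package's block list
block_keys <- function(blocks) {
  blocks <- unname(blocks)
  sort(vapply(blocks, function(b)
    paste(sort(paste(b$anchors$gene_a, b$anchors$gene_b, sep = "|")),
          collapse = " "), character(1)))
}

# Upper-tail hypergeometric probability by summing combinatorial terms.
oracle_hypergeom <- function(k, set_size, universe, target_size) {
  i <- k:min(set_size, target_size)
  if (k > min(set_size, target_size)) return(0)
  sum(choose(set_size, i) * choose(universe - set_size, target_size - i)) /
    choose(universe, target_size)
}

# Pi from explicit haplotypes: average pairwise difference count over all
# C(n,2) chromosome pairs, divided by the class site total.
oracle_pi_pairwise <- function(hap, site_class, L_S, L_N) {
  n <- nrow(hap)
  pairs <- utils::combn(n, 2)
  diff_s <- 0; diff_n <- 0
  for (k in seq_len(ncol(pairs))) {
    d <- hap[pairs[1, k], ] != hap[pairs[2, k], ]
    diff_s <- diff_s + sum(d & site_class == "synonymous")
    diff_n <- diff_n + sum(d & site_class == "nonsynonymous")
  }
  list(pi_S = diff_s / ncol(pairs) / L_S,
       pi_N = diff_n / ncol(pairs) / L_N)
}

# Nei-Gojobori site counts by brute-force enumeration of all 9 single-base
# changes per codon.
oracle_ng_sites <- function(seq) {
  seq <- toupper(seq)
  code <- Biostrings::GENETIC_CODE
  L_S <- 0
  for (c0 in seq(1, nchar(seq), 3)) {
    cod <- substr(seq, c0, c0 + 2)
    aa <- code[[cod]]
    for (w in 1:3) for (b in c("A", "C", "G", "T")) {
      if (b == substr(cod, w, w)) next
      mut <- cod
      substr(mut, w, w) <- b
      if (code[[mut]] == aa) L_S <- L_S + 1 / 3
    }
  }
  list(L_S = L_S, L_N = nchar(seq) - L_S)
}

# Random small catalog for oracle-equivalence runs: 2 scaffolds, mixed
# multi-copy and singleton families.
random_small_catalog <- function(seed, genes_per_scaffold = 20,
                                 n_multi_families = 7) {
  set.seed(seed)
  rows <- list()
  for (s in c("scA", "scB")) {
    for (r in seq_len(genes_per_scaffold)) {
      fam <- if (stats::runif(1) < 0.6)
        sprintf("M%02d", sample.int(n_multi_families, 1))
      else sprintf("U_%s_%02d", s, r)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = sprintf("%s_g%02d", s, r), scaffold = s, rank = r - 1L,
        strand = "+", family = fam, stringsAsFactors = FALSE)
    }
  }
  genes <- do.call(rbind, rows)
  exons <- data.frame(gene = genes$gene,
                      start = 1000 * seq_len(nrow(genes)),
                      end = 1000 * seq_len(nrow(genes)) + 299)
  gene_catalog(genes, exons)
}
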