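# Tandem / block (segmental) / dispersed duplicate typing from gene order
# and family membership.
#
# Collinear blocks follow the usual collinearity-detector practice: tandem
# arrays are collapsed to one representative before anchor enumeration,
# anchor pairs (same-family genes) are chained in rank space allowing same
# or inverted orientation with a maximum inter-anchor gap, chains on the
# same scaffold pair closer than the cluster gap are merged, and merged
# blocks with fewer than the minimum number of anchor pairs are discarded.

#' Find tandem gene arrays
#'
#' Maximal sets built by transitive chaining of same-family, same-scaffold
#' gene pairs whose gene-order ranks differ by at most `tandem_gap`.
#' Arrays have at least two members; a gene belongs to at most one array.
#'
#' @param catalog a [gene_catalog()].
#' @param tandem_gap maximum rank difference between successive array
#'   members (default 15: "within 15 genes").
#' @return named list of character vectors (gene ids), names `ta1`,
#'   `ta2`, ... in scaffold/rank order.
#' @export
find_tandem_arrays <- function(catalog, tandem_gap = 15) {
  g <- catalog$genes
  g <- g[!is.na(g$family), ]
  arrays <- list()
  for (key in split(seq_len(nrow(g)), paste(g$scaffold, g$family, sep = "\r"))) {
    if (length(key) < 2) next
    sub <- g[key, ][order(g$rank[key]), ]
    brk <- c(0L, which(diff(sub$rank) > tandem_gap), nrow(sub))
    for (i in seq_len(length(brk) - 1L)) {
      members <- sub$gene[(brk[i] + 1L):brk[i + 1L]]
      if (length(members) >= 2) arrays[[length(arrays) + 1L]] <- members
    }
  }
  if (length(arrays) == 0) return(stats::setNames(list(), character(0)))
  first <- vapply(arrays, `[`, character(1), 1)
  ord <- order(match(first, catalog$genes$gene))
  arrays <- arrays[ord]
  names(arrays) <- sprintf("ta%d", seq_along(arrays))
  arrays
}

# Anchor pairs per scaffold pair after tandem collapse. Returns a list of
# data.frames (gene_a, gene_b, a, b) keyed by "scafA\rscafB" with
# scafA <= scafB; for same-scaffold comparisons a < b and the self
# diagonal is excluded.
enumerate_anchors <- function(catalog, arrays) {
  g <- catalog$genes
  collapsed <- unlist(lapply(arrays, function(m) {
    r <- g$rank[match(m, g$gene)]
    m[-which.min(r)]  # keep lowest-rank member as representative
  }))
  g <- g[!is.na(g$family) & !g$gene %in% collapsed, ]
  out <- list()
  for (ix in split(seq_len(nrow(g)), g$family)) {
    if (length(ix) < 2) next
    pr <- utils::combn(ix, 2)
    for (k in seq_len(ncol(pr))) {
      i <- pr[1, k]; j <- pr[2, k]
      si <- g$scaffold[i]; sj <- g$scaffold[j]
      if (si > sj || (si == sj && g$rank[i] > g$rank[j])) {
        tmp <- i; i <- j; j <- tmp
        si <- g$scaffold[i]; sj <- g$scaffold[j]
      }
      key <- paste(si, sj, sep = "\r")
      out[[key]] <- rbind(out[[key]], data.frame(
        gene_a = g$gene[i], gene_b = g$gene[j],
        a = g$rank[i], b = g$rank[j], stringsAsFactors = FALSE))
    }
  }
  out
}

# Best valid chain among `anc` (data.frame a, b, gene_a, gene_b):
# strictly increasing a, strictly monotone b, consecutive gaps <= gap_size
# on both axes. Best = longest, ties broken by smaller total rank span,
# then lexicographically smallest anchor gene-id sequence. Dynamic
# programme storing the best path ending at each anchor (the ranking is
# prefix-consistent for equal-length paths, so per-node bests suffice).
best_chain <- function(anc, gap_size) {
  n <- nrow(anc)
  ord <- order(anc$a, anc$b)
  anc <- anc[ord, ]
  seq_str <- paste(anc$gene_a, anc$gene_b, sep = "|")
  best <- NULL
  better <- function(p, q) {
    # is path p better than q? paths are integer index vectors into anc
    if (is.null(q)) return(TRUE)
    if (length(p) != length(q)) return(length(p) > length(q))
    sp <- function(x) (anc$a[x[length(x)]] - anc$a[x[1]]) +
      abs(anc$b[x[length(x)]] - anc$b[x[1]])
    if (sp(p) != sp(q)) return(sp(p) < sp(q))
    paste(seq_str[p], collapse = " ") < paste(seq_str[q], collapse = " ")
  }
  for (orient in c(1, -1)) {
    paths <- vector("list", n)
    for (i in seq_len(n)) {
      paths[[i]] <- i
      for (j in seq_len(i - 1L)) {
        da <- anc$a[i] - anc$a[j]
        db <- orient * (anc$b[i] - anc$b[j])
        if (da >= 1 && da <= gap_size && db >= 1 && db <= gap_size) {
          cand <- c(paths[[j]], i)
          if (better(cand, paths[[i]])) paths[[i]] <- cand
        }
      }
      if (length(paths[[i]]) >= 2 && better(paths[[i]], best))
        best <- paths[[i]]
    }
  }
  if (is.null(best)) return(NULL)
  anc[best, ]
}

#' Find collinear (duplicated) blocks
#'
#' Anchor pairs are enumerated from family co-membership across and within
#' scaffolds after collapsing tandem arrays to their lowest-rank member
#' (so one array cannot fabricate enough anchors to satisfy
#' `min_anchors`). Within each scaffold pair, chains of anchors are
#' extracted greedily best-first (longest chain by dynamic programming,
#' ties by smaller rank span then lexicographic anchor ids; extracted
#' anchors are removed and the search repeats down to chains of two).
#' Chains on the same scaffold pair with the same orientation whose rank
#' intervals are closer than `cluster_gap` on both axes are merged, and
#' merged blocks with fewer than `min_anchors` anchor pairs are discarded.
#'
#' @param catalog a [gene_catalog()].
#' @param min_anchors minimum anchor pairs per retained block (default 3).
#' @param gap_size maximum rank gap between consecutive anchors on either
#'   axis (default 15).
#' @param cluster_gap merge distance between chains on one scaffold pair
#'   (default 15).
#' @param tandem_gap gap used to collapse tandem arrays before anchoring.
#' @return list of `collinear_block` objects: `scaffold_a`, `scaffold_b`,
#'   `orientation` ("same"/"inverted"), `anchors` (data.frame `gene_a`,
#'   `gene_b`, `a`, `b`).
#' @export
find_collinear_blocks <- function(catalog, min_anchors = 3, gap_size = 15,
                                  cluster_gap = 15, tandem_gap = 15) {
  arrays <- find_tandem_arrays(catalog, tandem_gap)
  pools <- enumerate_anchors(catalog, arrays)
  chains <- list()
  for (key in names(pools)) {
    pool <- pools[[key]]
    repeat {
      if (nrow(pool) < 2) break
      ch <- best_chain(pool, gap_size)
      if (is.null(ch)) break
      sc <- strsplit(key, "\r")[[1]]
      chains[[length(chains) + 1L]] <- structure(list(
        scaffold_a = sc[1], scaffold_b = sc[2],
        orientation = if (ch$b[nrow(ch)] >= ch$b[1]) "same" else "inverted",
        anchors = ch), class = "collinear_block")
      used <- paste(ch$gene_a, ch$gene_b)
      pool <- pool[!paste(pool$gene_a, pool$gene_b) %in% used, , drop = FALSE]
    }
  }
  blocks <- merge_chains(chains, cluster_gap)
  blocks <- Filter(function(b) nrow(b$anchors) >= min_anchors, blocks)
  if (length(blocks) > 0) {
    ord <- order(vapply(blocks, function(b)
      paste(b$scaffold_a, b$scaffold_b, sprintf("%06d", min(b$anchors$a))),
      character(1)))
    blocks <- blocks[ord]
    names(blocks) <- sprintf("blk%d", seq_along(blocks))
  }
  blocks
}

# Single-linkage merge of same-orientation chains on one scaffold pair
# whose rank intervals are closer than cluster_gap on both axes.
merge_chains <- function(chains, cluster_gap) {
  if (length(chains) < 2) return(chains)
  n <- length(chains)
  key <- vapply(chains, function(b)
    paste(b$scaffold_a, b$scaffold_b, b$orientation), character(1))
  iv <- function(b, ax) range(b$anchors[[ax]])
  gap <- function(r1, r2) max(0, max(r1[1], r2[1]) - min(r1[2], r2[2]))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    if (key[i] != key[j]) next
    if (gap(iv(chains[[i]], "a"), iv(chains[[j]], "a")) < cluster_gap &&
        gap(iv(chains[[i]], "b"), iv(chains[[j]], "b")) < cluster_gap)
      parent[find(j)] <- find(i)
  }
  comp <- vapply(seq_len(n), find, integer(1))
  lapply(unname(split(seq_len(n), comp)), function(ix) {
    b <- chains[[ix[1]]]
    anchors <- do.call(rbind, lapply(chains[ix], `[[`, "anchors"))
    anchors <- anchors[order(anchors$a), ]
    rownames(anchors) <- NULL
    b$anchors <- anchors
    b
  })
}

#' Classify duplicated genes as single, tandem, block or dispersed
#'
#' Family singletons are `single`; multi-copy genes are typed with the
#' precedence tandem > block > dispersed: members of a tandem array are
#' `tandem`; remaining genes participating in at least one anchor pair of
#' a retained collinear block are `block`; every other multi-copy gene is
#' `dispersed` (duplicated, but explained by neither mechanism).
#'
#' @param catalog a [gene_catalog()].
#' @param arrays output of [find_tandem_arrays()].
#' @param blocks output of [find_collinear_blocks()].
#' @return object of class `duplication_call`: data.frame (`gene`, `type`,
#'   `array_id`, `block_ids`) plus a `counts` attribute (type table).
#' @export
classify_duplicates <- function(catalog, arrays, blocks) {
  g <- catalog$genes
  fs <- family_sizes(catalog)
  array_of <- character(0)
  for (nm in names(arrays))
    array_of[arrays[[nm]]] <- nm
  block_of <- list()
  for (nm in names(blocks)) {
    b <- blocks[[nm]]
    for (gene in unique(c(b$anchors$gene_a, b$anchors$gene_b)))
      block_of[[gene]] <- c(block_of[[gene]], nm)
  }
  type <- character(nrow(g)); array_id <- NA_character_
  res <- data.frame(gene = g$gene, type = "single",
                    array_id = NA_character_, block_ids = NA_character_,
                    stringsAsFactors = FALSE)
  multi <- !is.na(g$family) & fs[g$family] >= 2
  res$type[multi] <- "dispersed"
  in_arr <- res$gene %in% names(array_of)
  res$type[in_arr] <- "tandem"
  res$array_id[in_arr] <- array_of[res$gene[in_arr]]
  in_blk <- res$gene %in% names(block_of) & !in_arr & multi
  res$type[in_blk] <- "block"
  has_blk <- res$gene %in% names(block_of)
  res$block_ids[has_blk] <- vapply(res$gene[has_blk], function(x)
    paste(block_of[[x]], collapse = ";"), character(1))
  structure(res, class = c("duplication_call", "data.frame"),
            counts = table(factor(res$type, levels = c("single", "tandem",
                                                       "block", "dispersed"))))
}

#' @export
print.duplication_call <- function(x, ...) {
  cat("duplication_call:", nrow(x), "genes\n")
  print(attr(x, "counts"))
  invisible(x)
}
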