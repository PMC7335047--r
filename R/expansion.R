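# Gene-family expansion detection from copy-number profiles, and family
# age classes by phylostratification.

#' Detect species-specific family expansions from a copy-number matrix
#'
#' A family is deemed expanded in the focal species when the population
#' variance of its copy counts across all included species is larger than
#' two AND the focal species' leave-one-out standard score is larger than
#' three. The leave-one-out score is
#' `z = (c_focal - mean(others)) / max(sd_pop(others), 1)`: mean and
#' population standard deviation are taken over the included species other
#' than the focal one, with the standard deviation floored at one copy so
#' that constant backgrounds (sd 0) still yield a finite score. (With the
#' focal species included in the mean/sd, a single-species outlier can
#' never reach a score of 3 for profiles of ~9 species, so the threshold
#' is only meaningful leave-one-out.)
#'
#' @param matrix integer matrix families x species (non-negative counts).
#' @param focal focal species (column name).
#' @param excluded character vector of species to drop before computing
#'   profiles (e.g. allodiploid genomes whose counts are inflated).
#' @param var_cutoff,z_cutoff expansion thresholds (defaults 2 and 3).
#' @param sd_floor floor for the leave-one-out standard deviation.
#' @return data.frame with one row per family: `family`, `z`, `variance`,
#'   `expanded`.
#' @export
detect_expansions <- function(matrix, focal = attr(matrix, "focal"),
                              excluded = character(0),
                              var_cutoff = 2, z_cutoff = 3, sd_floor = 1) {
  if (is.null(colnames(matrix)) || is.null(rownames(matrix)))
    stop_arg("copy matrix needs family rownames and species colnames")
  if (any(matrix < 0) || any(matrix != trunc(matrix)))
    stop_arg("copy counts must be non-negative integers")
  if (is.null(focal) || !focal %in% colnames(matrix))
    stop_arg("focal species absent from matrix")
  if (focal %in% excluded) stop_arg("focal species cannot be excluded")
  included <- setdiff(colnames(matrix), excluded)
  if (length(included) < 3)
    stop_arg("need >= 3 included species (Z-score undefined)")
  m <- matrix[, included, drop = FALSE]
  others <- m[, setdiff(included, focal), drop = FALSE]
  pop_var <- function(x) mean((x - mean(x))^2)
  variance <- apply(m, 1, pop_var)
  mu_o <- rowMeans(others)
  sd_o <- sqrt(apply(others, 1, pop_var))
  z <- (m[, focal] - mu_o) / pmax(sd_o, sd_floor)
  data.frame(family = rownames(m), z = unname(z),
             variance = unname(variance),
             expanded = unname(variance > var_cutoff & z > z_cutoff),
             stringsAsFactors = FALSE)
}

#' Assign family age classes by phylostratification
#'
#' The age class of a family is the deepest taxonomy stratum that contains
#' every species with at least one copy: a family present in a single
#' species is species-specific; a family spanning all lineages gets the
#' oldest stratum.
#'
#' @param matrix integer matrix families x species.
#' @param taxonomy named list or named character vector: species ->
#'   lineage, given root-to-leaf as a character vector or a
#'   semicolon-joined string (e.g.
#'   `"Eukaryota;Stramenopiles;Bacillariophyta;Pennales"`).
#' @return data.frame with `family`, `age_class` (the deepest shared
#'   stratum; the species name itself for single-species families) and
#'   `n_species`.
#' @export
assign_age_classes <- function(matrix, taxonomy) {
  if (is.character(taxonomy)) taxonomy <- as.list(taxonomy)
  lineages <- lapply(taxonomy, function(x)
    if (length(x) == 1 && grepl(";", x)) strsplit(x, ";")[[1]] else x)
  missing <- setdiff(colnames(matrix), names(lineages))
  if (length(missing) > 0)
    stop_arg("species without taxonomy mapping: ",
             paste(missing, collapse = ", "))
  rows <- lapply(rownames(matrix), function(f) {
    present <- colnames(matrix)[matrix[f, ] >= 1]
    if (length(present) == 0)
      return(data.frame(family = f, age_class = NA_character_,
                        n_species = 0L, stringsAsFactors = FALSE))
    if (length(present) == 1)
      return(data.frame(family = f, age_class = present,
                        n_species = 1L, stringsAsFactors = FALSE))
    paths <- lapply(present, function(s) c(lineages[[s]], s))
    depth <- min(lengths(paths))
    lca <- NA_character_
    for (d in seq_len(depth)) {
      level <- vapply(paths, `[`, character(1), d)
      if (length(unique(level)) == 1) lca <- level[1] else break
    }
    data.frame(family = f, age_class = lca, n_species = length(present),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
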