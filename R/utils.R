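# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' All stochastic operations in the package route their randomness through
#' this helper: the global `.Random.seed` is saved, the generator is seeded
#' with `seed`, and the previous state is restored on exit. No function in
#' the package leaks or depends on global random state.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

stop_arg <- function(...) stop(..., call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != trunc(x) || x < min)
    stop_arg(sprintf("`%s` must be a single integer >= %d", name, min))
  as.integer(x)
}

# named character vector of sequences from character input or DNAStringSet
as_cds_vector <- function(cds_set) {
  if (is.character(cds_set)) return(cds_set)
  stats::setNames(as.character(cds_set), names(cds_set))
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_arg(sprintf("`%s` must be a probability in [0, 1]", name))
  as.numeric(x)
}
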