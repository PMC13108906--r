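# Internal helpers shared across modules.

#' Evaluate an expression with a temporarily set RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded internals do not disturb
#' the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-operation seed from a global seed
#'
#' Deterministic, cheap mixing of a global seed with an operation name so
#' that independent operations in a pipeline receive distinct but
#' reproducible seeds. Result is kept inside the 32-bit signed range.
#'
#' @param seed global integer seed.
#' @param op character operation name.
#' @return integer seed.
#' @export
derive_seed <- function(seed, op) {
  stopifnot(is.character(op), length(op) == 1L)
  h <- sum(utf8ToInt(op) * seq_along(utf8ToInt(op)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587)
}

# Matrix of K random permutations of 1..n, one per column.
make_permutations <- function(n, K, seed) {
  with_seed(seed, {
    vapply(seq_len(K), function(k) sample.int(n), integer(n))
  })
}

# All distinct arrangements of a label multiset, as columns. Used by the
# exhaustive permutation mode (small n only).
multiset_permutations <- function(y) {
  rec <- function(rem) {
    if (length(rem) == 0L) return(list(integer(0)))
    out <- list()
    for (v in sort(unique(rem))) {
      idx <- match(v, rem)
      for (tail in rec(rem[-idx])) out[[length(out) + 1L]] <- c(v, tail)
    }
    out
  }
  do.call(cbind, rec(sort(y)))
}

# Format numbers for TSV output. 15 significant digits so that
# read(write(x)) round-trips within 1e-12 even for O(1) magnitudes.
fmt_num <- function(x) formatC(x, digits = 15, format = "g")

stop_fmds <- function(...) stop(..., call. = FALSE)
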