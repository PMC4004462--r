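#' Canonical key for an unordered pair of identifiers
#'
#' Symmetric interaction predicates (boundp, boundd, boundr) are stored over
#' unordered pairs; the canonical key is the lexicographically sorted pair
#' joined by `"|"`.
#'
#' @param a,b character vectors of identifiers (recycled to common length).
#' @return character vector of keys.
#' @export
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Canonicalize a two-column pair table
#'
#' Orders each row lexicographically (`id_a < id_b`), drops duplicates and
#' sorts rows by key, so that identical pair sets always produce identical
#' tables.
#'
#' @param pairs data.frame (or matrix) whose first two columns are ids.
#' @param dedup drop duplicate pairs after canonicalization.
#' @return data.frame with columns `id_a`, `id_b` (plus any extra columns).
#' @export
canonical_pairs <- function(pairs, dedup = TRUE) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (nrow(pairs) == 0L) {
    return(data.frame(id_a = character(), id_b = character(),
                      stringsAsFactors = FALSE))
  }
  a <- as.character(pairs[[1L]])
  b <- as.character(pairs[[2L]])
  out <- pairs
  out[[1L]] <- pmin(a, b)
  out[[2L]] <- pmax(a, b)
  names(out)[1:2] <- c("id_a", "id_b")
  key <- pair_key(a, b)
  ord <- order(key)
  out <- out[ord, , drop = FALSE]
  if (dedup) out <- out[!duplicated(pair_key(out$id_a, out$id_b)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so that deterministic operations do not
#' disturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

levels3 <- c("protein", "domain", "residue")

check_level <- function(level) {
  level <- match.arg(level, levels3)
  level
}

`%||%` <- function(x, y) if (is.null(x)) y else x
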