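# Per-object Gram matrices, additive combination, and the pairwise
# (tensor-product) kernel transformation used to lift object kernels to
# kernels over interaction pairs.

#' Linear Gram matrix from a feature table
#'
#' @param features numeric matrix with one row per object; rownames are the
#'   object ids.
#' @return symmetric positive semidefinite matrix with id dimnames.
#' @export
linear_gram <- function(features) {
  features <- as.matrix(features)
  if (is.null(rownames(features)))
    stop("features must have object ids as rownames")
  if (!is.numeric(features)) stop("features must be numeric")
  g <- tcrossprod(features)
  dimnames(g) <- list(rownames(features), rownames(features))
  g
}

#' Gaussian (RBF) Gram matrix from a feature table
#'
#' Bandwidth defaults to the median heuristic: the median of the nonzero
#' pairwise Euclidean distances.
#'
#' @param features numeric matrix, rownames = object ids.
#' @param bandwidth kernel width `s` in `exp(-d^2 / (2 s^2))`; `NULL` for the
#'   median heuristic.
#' @return symmetric PSD matrix with id dimnames.
#' @export
gaussian_gram <- function(features, bandwidth = NULL) {
  features <- as.matrix(features)
  if (is.null(rownames(features)))
    stop("features must have object ids as rownames")
  d2 <- as.matrix(stats::dist(features))^2
  if (is.null(bandwidth)) {
    pos <- d2[upper.tri(d2)]
    pos <- pos[pos > 0]
    bandwidth <- if (length(pos)) sqrt(stats::median(pos)) else 1
  }
  g <- exp(-d2 / (2 * bandwidth^2))
  dimnames(g) <- list(rownames(features), rownames(features))
  g
}

#' Additive combination of Gram matrices
#'
#' Kernels computed from individual feature sources are combined additively
#' into a single kernel per level; a sum of valid kernels is a valid kernel.
#'
#' @param grams list of matrices with identical id dimnames.
#' @return elementwise sum.
#' @export
sum_grams <- function(grams) {
  if (!length(grams)) stop("empty gram list")
  ids <- rownames(grams[[1L]])
  for (g in grams) {
    if (!identical(rownames(g), ids) || !identical(colnames(g), ids))
      stop("gram matrices must share an identical id list")
  }
  Reduce(`+`, grams)
}

#' Cosine-normalize a Gram matrix
#'
#' `K(i,j) / sqrt(K(i,i) K(j,j))`; rows/columns with zero self-similarity are
#' left at zero.
#'
#' @param g Gram matrix.
#' @return normalized matrix with unit diagonal (where defined).
#' @export
normalize_gram <- function(g) {
  d <- sqrt(diag(g))
  d[d == 0] <- Inf
  out <- g / outer(d, d)
  out[!is.finite(out)] <- 0
  out
}

#' Positive semidefiniteness check
#'
#' @param g square symmetric matrix.
#' @param tol nonnegative tolerance: true iff the smallest eigenvalue is
#'   at least `-tol`.
#' @return logical scalar.
#' @export
is_psd <- function(g, tol = 1e-8 * sum(diag(g)) / max(1L, nrow(g))) {
  g <- as.matrix(g)
  if (nrow(g) != ncol(g)) stop("non-square input")
  if (nrow(g) == 0L) return(TRUE)
  ev <- eigen((g + t(g)) / 2, symmetric = TRUE, only.values = TRUE)$values
  min(ev) >= -tol
}

#' Pairwise kernel between sets of object pairs
#'
#' Lifts an object-level kernel `K` to interaction pairs with the symmetric
#' tensor-product transformation
#' `Kp((i,j),(k,l)) = K(i,k) K(j,l) + K(i,l) K(j,k)`,
#' which preserves positive semidefiniteness and is invariant to swapping
#' the members inside either pair. The `"printed"` variant
#' `K(i,k) K(i,l) + K(j,k) K(j,l)` is kept for reference; it is not
#' symmetric under member swaps and is not used by default (see the methods
#' vignette).
#'
#' @param g object Gram matrix with id dimnames.
#' @param rows,cols data.frames of pairs (`id_a`, `id_b`); `cols` defaults
#'   to `rows`.
#' @param variant `"symmetric"` (default) or `"printed"`.
#' @return matrix of size `nrow(rows) x nrow(cols)` with pair-key dimnames.
#' @export
pairwise_gram <- function(g, rows, cols = rows,
                          variant = c("symmetric", "printed")) {
  variant <- match.arg(variant)
  ids <- rownames(g)
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  cols <- as.data.frame(cols, stringsAsFactors = FALSE)
  ri <- match(as.character(rows$id_a), ids)
  rj <- match(as.character(rows$id_b), ids)
  ck <- match(as.character(cols$id_a), ids)
  cl <- match(as.character(cols$id_b), ids)
  if (anyNA(c(ri, rj, ck, cl)))
    stop("unknown id in pair list (absent from the gram matrix)")
  out <- if (variant == "symmetric") {
    g[ri, ck, drop = FALSE] * g[rj, cl, drop = FALSE] +
      g[ri, cl, drop = FALSE] * g[rj, ck, drop = FALSE]
  } else {
    g[ri, ck, drop = FALSE] * g[ri, cl, drop = FALSE] +
      g[rj, ck, drop = FALSE] * g[rj, cl, drop = FALSE]
  }
  dimnames(out) <- list(pair_key(rows$id_a, rows$id_b),
                        pair_key(cols$id_a, cols$id_b))
  out
}

#' Read a feature table (object id + tab-separated reals)
#'
#' @param path file path; first column is the object id, remaining columns
#'   numeric features. `#` comments allowed, no header.
#' @return numeric matrix with id rownames.
#' @export
load_features <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           comment.char = "#",
                           stringsAsFactors = FALSE)
  ids <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  colnames(m) <- NULL
  m
}

#' Write a feature table
#' @param features numeric matrix with id rownames.
#' @param path output path.
#' @export
write_features <- function(features, path) {
  df <- data.frame(id = rownames(features), features,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a precomputed kernel matrix
#'
#' Dense whitespace-separated matrix with a header row of object ids.
#'
#' @param path file path.
#' @return symmetric matrix with id dimnames.
#' @export
load_gram <- function(path) {
  lines <- readLines(path)
  lines <- lines[trimws(lines) != ""]
  ids <- strsplit(trimws(lines[1L]), "[ \t]+")[[1L]]
  vals <- lapply(lines[-1L], function(l)
    as.numeric(strsplit(trimws(l), "[ \t]+")[[1L]]))
  m <- do.call(rbind, vals)
  if (nrow(m) != length(ids) || ncol(m) != length(ids))
    stop("kernel matrix dimensions do not match header ids")
  dimnames(m) <- list(ids, ids)
  m
}
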