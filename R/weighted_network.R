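#' Complete weighted network
#'
#' A complete graph on `p` nodes stored as the vector of its
#' `q = p(p-1)/2` edge weights in a canonical order: row-major over the
#' upper triangle, i.e. edges (1,2), (1,3), ..., (1,p), (2,3), ...,
#' (p-1,p).  The canonical ordering makes barcodes and edge ranks
#' reproducible across readers and writers.
#'
#' @param p integer node count, at least 2.
#' @param weights numeric vector of length `p*(p-1)/2` of finite edge
#'   weights in canonical order.
#' @param labels optional character vector of `p` node labels.
#' @return An object of class `weighted_network` with fields `p`, `q`,
#'   `weights` and `labels`.
#' @examples
#' net <- weighted_network(3, c(0.2, 0.5, 0.9))
#' net$q
#' @export
weighted_network <- function(p, weights, labels = NULL) {
  p <- as.integer(p)
  if (length(p) != 1L || is.na(p) || p < 2L)
    stop("'p' must be a single integer >= 2", call. = FALSE)
  q <- p * (p - 1L) / 2L
  weights <- as.numeric(weights)
  if (length(weights) != q)
    stop(sprintf("expected %d edge weights for p = %d, got %d",
                 q, p, length(weights)), call. = FALSE)
  if (!all(is.finite(weights)))
    stop("edge weights must be finite (no NA/NaN/Inf)", call. = FALSE)
  if (!is.null(labels) && length(labels) != p)
    stop("'labels' must have length p", call. = FALSE)
  structure(list(p = p, q = as.integer(q), weights = weights,
                 labels = labels),
            class = "weighted_network")
}

#' Canonical edge endpoints of a complete graph
#'
#' @param p node count.
#' @return A two-column integer matrix (`i`, `j`), 1-based node indices
#'   with `i < j`, one row per edge in canonical (row-major upper
#'   triangle) order.
#' @export
edge_endpoints <- function(p) {
  p <- as.integer(p)
  if (p < 2L) stop("'p' must be >= 2", call. = FALSE)
  i <- rep.int(seq_len(p - 1L), times = (p - 1L):1L)
  j <- sequence((p - 1L):1L) + i
  cbind(i = i, j = j)
}

#' Convert a symmetric adjacency matrix to a weighted network
#'
#' The diagonal is ignored.  Asymmetry up to `tol` is repaired by
#' averaging `(A + t(A))/2` with a warning; larger asymmetry is an error.
#'
#' @param a square numeric matrix.
#' @param tol maximum tolerated absolute asymmetry (default `1e-8`).
#' @return A [weighted_network()].
#' @export
as_weighted_network <- function(a, tol = 1e-8) {
  a <- as.matrix(a)
  if (nrow(a) != ncol(a))
    stop("adjacency matrix must be square", call. = FALSE)
  if (!is.numeric(a) || anyNA(a))
    stop("adjacency matrix must be numeric with no missing values",
         call. = FALSE)
  asym <- max(abs(a - t(a)))
  if (asym > tol)
    stop(sprintf("adjacency matrix asymmetry %.3g exceeds tolerance %.3g",
                 asym, tol), call. = FALSE)
  if (asym > 0) {
    warning("adjacency matrix slightly asymmetric; symmetrized by averaging")
    a <- (a + t(a)) / 2
  }
  labels <- rownames(a)
  if (is.null(labels)) labels <- colnames(a)
  # row-major upper triangle == column-major lower triangle of t(a)
  w <- t(a)[lower.tri(a)]
  weighted_network(nrow(a), w, labels = labels)
}

#' Adjacency matrix of a weighted network
#'
#' @param net a [weighted_network()].
#' @param diag value placed on the diagonal (default 0).
#' @return A symmetric `p x p` numeric matrix.
#' @export
adjacency_matrix <- function(net, diag = 0) {
  stopifnot(inherits(net, "weighted_network"))
  p <- net$p
  a <- matrix(diag, p, p)
  ends <- edge_endpoints(p)
  a[cbind(ends[, 1L], ends[, 2L])] <- net$weights
  a[cbind(ends[, 2L], ends[, 1L])] <- net$weights
  if (!is.null(net$labels)) dimnames(a) <- list(net$labels, net$labels)
  a
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf("Complete weighted network: p = %d nodes, q = %d edges\n",
              x$p, x$q))
  cat(sprintf("  weight range [%.4g, %.4g]\n",
              min(x$weights), max(x$weights)))
  invisible(x)
}
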