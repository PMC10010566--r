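#' Birth-death decomposition of a weighted complete network
#'
#' Sweeping a threshold eps upward through the edge weights and keeping
#' edges with weight strictly greater than eps defines a graph
#' filtration.  Each of the `q` edge weights is then exactly one of
#' two things: the birth value of a connected component (the weights of
#' the maximum spanning tree, `m0 = p - 1` of them) or the death value
#' of an independent cycle (all remaining weights,
#' `m1 = (p-1)(p-2)/2`).  The two sets partition the weight vector.
#'
#' The maximum spanning tree is found by Kruskal's algorithm on weights
#' sorted in decreasing order; exact ties are broken by canonical edge
#' index, which keeps floating-point inputs reproducible.  Tied weights
#' are flagged with a warning because the underlying model assumes
#' continuous weights where ties have probability zero.
#'
#' @param net a [weighted_network()].
#' @return An object of class `barcode`: a list with `p`, sorted numeric
#'   `births` (length `p - 1`) and `deaths` (length `(p-1)(p-2)/2`), and
#'   integer `birth_ranks` / `death_ranks`, the 1-based positions of the
#'   birth and death values among all `q` weights sorted increasingly.
#' @examples
#' net <- weighted_network(4, c(0.2, 0.3, 0.1, 0.5, 0.4, 0.6))
#' bd <- birth_death_decomposition(net)
#' bd$births  # maximum spanning tree weights
#' @export
birth_death_decomposition <- function(net) {
  if (!inherits(net, "weighted_network"))
    stop("'net' must be a weighted_network", call. = FALSE)
  p <- net$p
  q <- net$q
  w <- net$weights
  if (anyDuplicated(w))
    warning("tied edge weights detected; ties broken by canonical edge index")

  ends <- edge_endpoints(p)
  ord_desc <- order(-w, seq_len(q))

  # Kruskal with union-find (path halving)
  parent <- seq_len(p)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  is_birth <- logical(q)
  n_tree <- 0L
  for (e in ord_desc) {
    ri <- find(ends[e, 1L])
    rj <- find(ends[e, 2L])
    if (ri != rj) {
      parent[ri] <- rj
      is_birth[e] <- TRUE
      n_tree <- n_tree + 1L
      if (n_tree == p - 1L) break
    }
  }

  rank_asc <- integer(q)
  rank_asc[order(w, seq_len(q))] <- seq_len(q)

  birth_ranks <- sort(rank_asc[is_birth])
  death_ranks <- sort(rank_asc[!is_birth])
  sorted_w <- sort(w)

  structure(list(p = p,
                 births = sorted_w[birth_ranks],
                 deaths = sorted_w[death_ranks],
                 birth_ranks = birth_ranks,
                 death_ranks = death_ranks),
            class = "barcode")
}

#' Construct a barcode from explicit components
#'
#' Mostly useful for tests and for reading barcodes back from disk.
#' Performs the cardinality checks (`m0 = p - 1`,
#' `m1 = (p-1)(p-2)/2`) but not the partition check against a weight
#' vector.
#'
#' @param p node count.
#' @param births,deaths sorted numeric vectors.
#' @param birth_ranks,death_ranks 1-based integer ranks among the sorted
#'   weights.
#' @return A `barcode` object.
#' @export
barcode <- function(p, births, deaths, birth_ranks = NULL,
                    death_ranks = NULL) {
  p <- as.integer(p)
  m0 <- p - 1L
  m1 <- (p - 1L) * (p - 2L) / 2L
  if (length(births) != m0)
    stop(sprintf("expected %d birth values, got %d", m0, length(births)),
         call. = FALSE)
  if (length(deaths) != m1)
    stop(sprintf("expected %d death values, got %d", m1, length(deaths)),
         call. = FALSE)
  if (is.unsorted(births) || is.unsorted(deaths))
    stop("births and deaths must be sorted increasingly", call. = FALSE)
  structure(list(p = p, births = as.numeric(births),
                 deaths = as.numeric(deaths),
                 birth_ranks = as.integer(birth_ranks),
                 death_ranks = as.integer(death_ranks)),
            class = "barcode")
}

#' @export
print.barcode <- function(x, ...) {
  cat(sprintf("Barcode: p = %d, m0 = %d births, m1 = %d deaths\n",
              x$p, length(x$births), length(x$deaths)))
  invisible(x)
}
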