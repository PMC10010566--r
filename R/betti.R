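#' Betti curves of a graph filtration
#'
#' The Betti-0 curve counts connected components of the thresholded graph
#' (edges with weight strictly greater than eps) and the Betti-1 curve
#' counts independent cycles.  Both are right-continuous step functions:
#' `beta0(eps) = 1 + #\{births <= eps\}` climbs from 1 (complete graph)
#' to `p`, and `beta1(eps) = m1 - #\{deaths <= eps\}` drops from
#' `m1 = (p-1)(p-2)/2` to 0.  Jumps occur at the birth/death values
#' themselves because an edge with weight exactly eps is already absent.
#'
#' @param bar a `barcode` (see [birth_death_decomposition()]).
#' @return A list with components `beta0` and `beta1`, each of class
#'   `betti_curve` with fields `knots` (sorted jump locations), `levels`
#'   (value on each of the `length(knots) + 1` intervals) and
#'   `dimension`.
#' @examples
#' net <- weighted_network(4, c(0.2, 0.3, 0.1, 0.5, 0.4, 0.6))
#' bc <- betti_curves(birth_death_decomposition(net))
#' betti_at(bc$beta0, 0.35)
#' @export
betti_curves <- function(bar) {
  if (!inherits(bar, "barcode"))
    stop("'bar' must be a barcode", call. = FALSE)
  m1 <- length(bar$deaths)
  beta0 <- new_betti_curve(bar$births, start = 1L, step = +1L, dimension = 0L)
  beta1 <- new_betti_curve(bar$deaths, start = m1, step = -1L, dimension = 1L)
  list(beta0 = beta0, beta1 = beta1)
}

# Collapse duplicate knots (tied weights) into single jumps of size > 1.
new_betti_curve <- function(values, start, step, dimension) {
  if (length(values) == 0L) {
    return(structure(list(knots = numeric(0), levels = as.integer(start),
                          dimension = dimension),
                     class = "betti_curve"))
  }
  r <- rle(sort(values))  # collapse exact ties without losing precision
  knots <- r$values
  jumps <- r$lengths * step
  levels <- as.integer(c(start, start + cumsum(jumps)))
  structure(list(knots = knots, levels = levels, dimension = dimension),
            class = "betti_curve")
}

#' Evaluate a Betti curve
#'
#' @param curve a `betti_curve`.
#' @param eps numeric vector of filtration values (may include `-Inf`,
#'   `Inf`).
#' @return Integer Betti numbers at each `eps`.
#' @export
betti_at <- function(curve, eps) {
  if (!inherits(curve, "betti_curve"))
    stop("'curve' must be a betti_curve", call. = FALSE)
  curve$levels[findInterval(eps, curve$knots) + 1L]
}

#' @export
print.betti_curve <- function(x, ...) {
  cat(sprintf("Betti-%d curve: %d knots, levels %d -> %d\n", x$dimension,
              length(x$knots), x$levels[1L], x$levels[length(x$levels)]))
  invisible(x)
}

#' @export
plot.betti_curve <- function(x, ...) {
  k <- x$knots
  if (length(k) == 0L) k <- c(0, 1)
  pad <- diff(range(k)) * 0.05 + 1e-3
  xs <- c(min(k) - pad, rep(x$knots, each = 2L), max(k) + pad)
  ys <- rep(x$levels, each = 2L)
  plot(xs, ys, type = "l", xlab = "filtration value",
       ylab = sprintf("Betti-%d", x$dimension), ...)
  invisible(x)
}

#' Euler characteristic self-check
#'
#' For a graph filtration of a complete network the Euler characteristic
#' identity `beta0(eps) - beta1(eps) = p - #\{w > eps\}` (nodes minus
#' surviving edges) must hold at every threshold.  This verifies it at
#' every distinct weight and at plus/minus infinity, and is used as a
#' consistency hook between a network and a barcode that claims to
#' decompose it.
#'
#' @param net a [weighted_network()].
#' @param bar a `barcode` for the same network.
#' @return `TRUE` if the identity holds everywhere, otherwise `FALSE`
#'   with attribute `"failures"` giving the offending thresholds.
#' @export
euler_check <- function(net, bar) {
  stopifnot(inherits(net, "weighted_network"), inherits(bar, "barcode"))
  if (net$p != bar$p) stop("node counts differ", call. = FALSE)
  bc <- betti_curves(bar)
  eps <- c(-Inf, sort(unique(net$weights)), Inf)
  lhs <- betti_at(bc$beta0, eps) - betti_at(bc$beta1, eps)
  n_edges <- vapply(eps, function(e) sum(net$weights > e), numeric(1))
  rhs <- net$p - n_edges
  ok <- lhs == rhs
  out <- all(ok)
  if (!out) attr(out, "failures") <- eps[!ok]
  out
}
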