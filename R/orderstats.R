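#' Expected order statistics via the quantile approximation
#'
#' For `q` iid draws from a continuous distribution with cdf `F`, the
#' k-th order statistic `W_(k)` is asymptotically normal around
#' `F^{-1}(k/(q+1))`; for the standard uniform this is exact
#' (`W_(k)` is Beta(k, q+1-k) with mean `k/(q+1)`).  This function
#' returns the approximation `F^{-1}(k/(q+1))`.
#'
#' @param dist a [dist_spec][dist_spec].
#' @param k rank(s), integers in `1..q` (vectorized).
#' @param q sample size (number of edges).
#' @return Numeric vector of expected order statistics.
#' @export
expected_order_stat <- function(dist, k, q) {
  check_dist(dist)
  q <- as.integer(q)
  if (q < 1L) stop("'q' must be >= 1", call. = FALSE)
  if (any(k < 1L | k > q))
    stop("ranks 'k' must lie in 1..q", call. = FALSE)
  dist$quantile(k / (q + 1))
}

#' Asymptotic variance of an order statistic
#'
#' Implements `var(W_(k)) ~ r(1-r) / ((q+1) f(F^{-1}(r))^2)` with
#' r = k/(q+1), the asymptotic-normal variance of the k-th of `q` iid
#' draws.  Requires a strictly positive density at the target quantile;
#' a zero or undefined density means the approximation breaks down at
#' that rank and is an error.  The approximation is weakest in the
#' extreme tails, so `k = 1` or `k = q` draws a warning.
#'
#' @inheritParams expected_order_stat
#' @return Numeric vector of variances.
#' @export
order_stat_variance <- function(dist, k, q) {
  check_dist(dist)
  if (is.null(dist$density))
    stop("distribution spec has no density; variance approximation unavailable",
         call. = FALSE)
  q <- as.integer(q)
  if (any(k < 1L | k > q))
    stop("ranks 'k' must lie in 1..q", call. = FALSE)
  if (any(k == 1L | k == q))
    warning("variance approximation is least accurate at extreme ranks ",
            "(k = 1 or k = q)")
  r <- k / (q + 1)
  fx <- dist$density(dist$quantile(r))
  if (any(!is.finite(fx) | fx <= 0))
    stop("density is zero or undefined at a requested quantile; ",
         "asymptotic variance is invalid there", call. = FALSE)
  r * (1 - r) / ((q + 1) * fx^2)
}

#' Expected persistent barcode of a random complete graph
#'
#' Maps each birth rank `i_k` and death rank `j_k` of a barcode to the
#' expected order statistic `F^{-1}(rank/(q+1))` of the edge-weight
#' distribution, yielding the expected birth and death values.  When the
#' spec has a density, per-value asymptotic variances are attached
#' (otherwise `NA`).
#'
#' @param dist a [dist_spec][dist_spec] for the edge weights.
#' @param ranks a `barcode` (its ranks are used) or a list with integer
#'   components `birth_ranks` and `death_ranks` forming a partition of
#'   `1..q`.
#' @param q total edge count `p(p-1)/2`.
#' @return An object of class `expected_barcode`: `expected_births`,
#'   `expected_deaths`, `birth_ranks`, `death_ranks`, `birth_vars`,
#'   `death_vars`, `q`.
#' @examples
#' net <- weighted_network(4, runif(6))
#' bd <- birth_death_decomposition(net)
#' expected_barcode(dist_uniform01(), bd, net$q)
#' @export
expected_barcode <- function(dist, ranks, q) {
  check_dist(dist)
  q <- as.integer(q)
  br <- as.integer(ranks$birth_ranks)
  dr <- as.integer(ranks$death_ranks)
  if (length(br) == 0L && length(dr) == 0L)
    stop("'ranks' must carry birth_ranks and death_ranks", call. = FALSE)
  all_ranks <- sort(c(br, dr))
  if (!identical(all_ranks, seq_len(q)))
    stop("birth and death ranks must partition 1..q", call. = FALSE)
  eb <- expected_order_stat(dist, br, q)
  ed <- if (length(dr)) expected_order_stat(dist, dr, q) else numeric(0)
  if (!is.null(dist$density)) {
    vb <- suppressWarnings(try(order_stat_variance(dist, br, q),
                               silent = TRUE))
    vd <- suppressWarnings(try(
      if (length(dr)) order_stat_variance(dist, dr, q) else numeric(0),
      silent = TRUE))
    if (inherits(vb, "try-error")) vb <- rep(NA_real_, length(br))
    if (inherits(vd, "try-error")) vd <- rep(NA_real_, length(dr))
  } else {
    vb <- rep(NA_real_, length(br))
    vd <- rep(NA_real_, length(dr))
  }
  structure(list(expected_births = eb, expected_deaths = ed,
                 birth_ranks = br, death_ranks = dr,
                 birth_vars = vb, death_vars = vd, q = q),
            class = "expected_barcode")
}

#' @export
print.expected_barcode <- function(x, ...) {
  cat(sprintf("Expected barcode: %d births, %d deaths (q = %d)\n",
              length(x$expected_births), length(x$expected_deaths), x$q))
  invisible(x)
}

#' Estimate the edge-weight distribution of a group of networks
#'
#' Averages the `n` networks element-wise into a single weight vector
#' `w_bar` of length `q` and returns its empirical distribution together
#' with a Gaussian kernel density estimate.  The empirical cdf and its
#' generalized inverse sum over the `q` entries of the averaged vector;
#' set `pool = TRUE` to instead use all `n * q` raw weights.
#'
#' @param nets list of [weighted_network()]s sharing the same `p`.
#' @param bandwidth KDE bandwidth (`"nrd0"` = Silverman's rule, or a
#'   positive number).
#' @param pool pool all weights rather than averaging (default `FALSE`).
#' @return A `dist_spec` of kind `"kde"` whose `sample` is `w_bar`.
#' @export
estimate_group_distribution <- function(nets, bandwidth = "nrd0",
                                        pool = FALSE) {
  wmat <- group_weight_matrix(nets)
  x <- if (pool) as.vector(wmat) else rowMeans(wmat)
  dist_kde(x, bandwidth = bandwidth)
}

#' Confidence bands on birth and death values
#'
#' For each rank `k` in `1..q`, estimates the expected order statistic
#' `mu_k = F^{-1}(k/(q+1))` from the group's averaged empirical
#' distribution and its asymptotic standard deviation `sigma_k` from the
#' kernel density estimate, then forms the normal interval
#' `mu_k +/- z * sigma_k` (`z = 1.96` at 95% coverage).  The ranks are
#' labelled birth or death according to the birth-death decomposition of
#' the averaged network, so the bands split into a birth band (length
#' `p - 1`) and a death band.
#'
#' Where the kernel density is numerically zero at a required quantile
#' the band is infinitely wide and a warning is issued (the
#' approximation, not the input, failed there).
#'
#' @param nets list of at least two [weighted_network()]s sharing `p`.
#' @param alpha_pct coverage percentage (default 95).
#' @param bandwidth KDE bandwidth passed to
#'   [estimate_group_distribution()].
#' @return A data frame with columns `rank`, `role` ("birth"/"death"),
#'   `mu_hat`, `sigma_hat`, `lo`, `hi`.
#' @export
confidence_bands <- function(nets, alpha_pct = 95, bandwidth = "nrd0") {
  if (length(nets) < 2L)
    stop("need at least 2 networks for confidence bands", call. = FALSE)
  wmat <- group_weight_matrix(nets)
  q <- nrow(wmat)
  p <- nets[[1L]]$p
  spec <- estimate_group_distribution(nets, bandwidth = bandwidth)
  z <- qnorm(1 - (1 - alpha_pct / 100) / 2)
  k <- seq_len(q)
  r <- k / (q + 1)
  mu <- spec$quantile(r)
  fx <- spec$density(mu)
  sigma <- sqrt(r * (1 - r) / ((q + 1) * fx^2))
  bad <- !is.finite(fx) | fx <= .Machine$double.eps
  if (any(bad)) {
    warning(sprintf(
      "kernel density ~ 0 at %d rank(s); intervals there are infinite",
      sum(bad)))
    sigma[bad] <- Inf
  }
  avg_net <- weighted_network(p, rowMeans(wmat))
  bd <- suppressWarnings(birth_death_decomposition(avg_net))
  role <- rep("death", q)
  role[bd$birth_ranks] <- "birth"
  data.frame(rank = k, role = role, mu_hat = mu, sigma_hat = sigma,
             lo = mu - z * sigma, hi = mu + z * sigma)
}

# shared validation: stack group weights as a q x n matrix
group_weight_matrix <- function(nets) {
  if (!length(nets)) stop("empty network list", call. = FALSE)
  ok <- vapply(nets, inherits, logical(1), what = "weighted_network")
  if (!all(ok)) stop("all elements must be weighted_network objects",
                     call. = FALSE)
  p <- vapply(nets, function(x) x$p, integer(1))
  if (length(unique(p)) != 1L)
    stop("all networks must share the same node count p", call. = FALSE)
  q <- nets[[1L]]$q
  wmat <- vapply(nets, function(x) x$weights, numeric(q))
  if (is.null(dim(wmat))) wmat <- matrix(wmat, nrow = q)  # q = 1 edge case
  wmat
}

check_dist <- function(dist) {
  if (!inherits(dist, "dist_spec"))
    stop("'dist' must be a dist_spec (see ?dist_spec)", call. = FALSE)
  invisible(dist)
}
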