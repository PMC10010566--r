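#' Random complete networks with iid edge weights
#'
#' Draws `q = p(p-1)/2` independent edge weights from the given
#' distribution and places them in canonical edge order, emulating the
#' random complete-graph model of dense correlation networks (for a
#' 116-region parcellation, `q = 6670`).
#'
#' @param p node count.
#' @param dist a [dist_spec][dist_spec] with a sampler (all built-in
#'   kinds have one; empirical specs sample by inverse transform).
#' @param seed optional integer seed; the draw is bit-for-bit
#'   reproducible given the seed.
#' @return A [weighted_network()].
#' @export
generate_iid_network <- function(p, dist, seed = NULL) {
  check_dist(dist)
  if (is.null(dist$rng))
    stop("distribution spec has no sampler", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  q <- p * (p - 1) / 2
  weighted_network(p, dist$rng(q))
}

#' Gaussian-noise-perturbed copies of a fixed network
#'
#' Produces `n` networks `G(p, w + e_i)` with `e_i ~ N_q(0, sigma^2 I)`,
#' the observation model used to validate expected-barcode estimation
#' (a stated world of `n = 15` copies at `sigma = 0.02`).  Weights are
#' deliberately not clipped to the base support: the filtration is
#' defined for any real weights.
#'
#' @param base a [weighted_network()] serving as ground truth.
#' @param n number of noisy copies (>= 1).
#' @param sigma noise standard deviation (>= 0); 0 gives exact copies.
#' @param seed optional integer seed.
#' @return A list of `n` [weighted_network()]s.
#' @export
generate_noisy_group <- function(base, n, sigma, seed = NULL) {
  stopifnot(inherits(base, "weighted_network"))
  if (n < 1) stop("'n' must be >= 1", call. = FALSE)
  if (sigma < 0) stop("'sigma' must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n), function(i)
    weighted_network(base$p, base$weights + rnorm(base$q, 0, sigma)))
}

#' Derive a reproducible sub-seed
#'
#' Small integer hash used to give each repeat/group/network of a
#' simulation its own stream from one master seed; results stay below
#' 2^31 so they are valid R integer seeds.
#'
#' @param master integer master seed.
#' @param ... further small integers identifying the stream.
#' @return A single integer seed.
#' @export
derive_seed <- function(master, ...) {
  ids <- c(as.numeric(master), as.numeric(c(...)))
  h <- 0
  for (x in ids) h <- (h * 69069 + x + 1) %% 2147483629
  as.integer(h)
}

#' Simulation driver for group-difference power/size tables
#'
#' For each distribution pair and each per-group size, generates two
#' groups of iid random networks, applies the requested test (ETL or
#' maximum-gap permutation test, or the Wilcoxon test on Betti-0 areas)
#' and averages the p-value over `n_repeats` independent repeats.  Each
#' repeat, group and network draws from its own sub-stream derived from
#' the master seed, so any cell of the table can be reproduced in
#' isolation.
#'
#' @param cfg a list (e.g. read from YAML) with fields:
#'   `p` (node count), `n_networks` (vector of per-group sizes),
#'   `pairs` (list of two-element character vectors naming the two
#'   edge-weight distributions, see [parse_dist()]),
#'   `stat` (`"etl"`, `"maxgap"` or `"auc"`), `n_perm` (permutations per
#'   test, default 10000), `n_repeats` (default 10), `seed`.
#' @return A data frame with columns `dist_a`, `dist_b`, `n_per_group`,
#'   `stat`, `mean_p`, `sd_p` and one row per (pair, size) cell.
#' @examples
#' cfg <- list(p = 10, n_networks = 4,
#'             pairs = list(c("beta(5,2)", "beta(1,5)")),
#'             stat = "etl", n_perm = 200, n_repeats = 2, seed = 7)
#' run_table_experiment(cfg)
#' @export
run_table_experiment <- function(cfg) {
  stopifnot(is.list(cfg), !is.null(cfg$p), !is.null(cfg$pairs))
  p <- as.integer(cfg$p)
  sizes <- as.integer(cfg$n_networks %||% 6L)
  stat <- match.arg(cfg$stat %||% "etl", c("etl", "maxgap", "auc"))
  n_perm <- as.integer(cfg$n_perm %||% 10000L)
  n_repeats <- as.integer(cfg$n_repeats %||% 10L)
  master <- as.integer(cfg$seed %||% 1L)

  rows <- list()
  for (pi in seq_along(cfg$pairs)) {
    pair <- cfg$pairs[[pi]]
    dist_a <- parse_dist(pair[[1]])
    dist_b <- parse_dist(pair[[2]])
    for (n_per in sizes) {
      pvals <- vapply(seq_len(n_repeats), function(rep) {
        netsA <- lapply(seq_len(n_per), function(i)
          generate_iid_network(p, dist_a,
                               seed = derive_seed(master, pi, n_per, rep, 1, i)))
        netsB <- lapply(seq_len(n_per), function(i)
          generate_iid_network(p, dist_b,
                               seed = derive_seed(master, pi, n_per, rep, 2, i)))
        if (stat == "auc") {
          wilcoxon_auc_test(netsA, netsB)$p_value
        } else {
          permutation_test(netsA, netsB, statistic = stat, n_perm = n_perm,
                           seed = derive_seed(master, pi, n_per, rep, 3)
          )$p_value
        }
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        dist_a = pair[[1]], dist_b = pair[[2]], n_per_group = n_per,
        stat = stat, mean_p = mean(pvals), sd_p = sd(pvals))
    }
  }
  do.call(rbind, rows)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
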