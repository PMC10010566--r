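# Shared fixtures and independent oracles, built in code.

# 4-node worked example: six sorted values W1 < ... < W6 placed on edges
# (1,2)=W2, (1,3)=W3, (1,4)=W1, (2,3)=W5, (2,4)=W4, (3,4)=W6.
# Maximum spanning tree is {W6, W5, W3}, so births are ranks {3,5,6} and
# deaths ranks {1,2,4}.
fig_w <- c(0.12, 0.25, 0.37, 0.51, 0.68, 0.83)
fig_network <- function(w = fig_w) {
  weighted_network(4, w[c(2, 3, 1, 5, 4, 6)])
}

rand_net <- function(p, seed) {
  set.seed(seed)
  weighted_network(p, runif(p * (p - 1) / 2))
}

# Independent filtration-replay oracle: walk the thresholds upward, count
# connected components of the surviving graph with igraph, and record
# every threshold at which beta0 increments.
oracle_births <- function(net) {
  w <- net$weights
  ends <- edge_endpoints(net$p)
  eps <- sort(unique(w))
  prev <- 1L
  births <- numeric(0)
  for (e in eps) {
    keep <- w > e
    g <- igraph::make_empty_graph(net$p, directed = FALSE)
    g <- igraph::add_edges(g, t(ends[keep, , drop = FALSE]))
    b0 <- igraph::components(g)$no
    if (b0 > prev) births <- c(births, rep(e, b0 - prev))
    prev <- b0
  }
  births
}

# All permutations of 1..n (n small), for brute-force bijection matching.
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (sub in all_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos - 1L)
    }
  }
  out
}

# Brute-force 2-Wasserstein: minimum L2 cost over every bijection.
brute_wasserstein <- function(b1, b2) {
  costs <- vapply(all_perms(length(b1)), function(pm)
    sqrt(sum((b1 - b2[pm])^2)), numeric(1))
  min(costs)
}

# Exact two-sided Wilcoxon rank-sum p-value by enumerating every
# assignment of pooled ranks to group A.
enum_wilcoxon_p <- function(x, y) {
  n <- length(x)
  ranks <- rank(c(x, y))
  w_obs <- sum(ranks[seq_len(n)]) - n * (n + 1) / 2
  splits <- utils::combn(length(ranks), n)
  w_null <- apply(splits, 2, function(idx)
    sum(ranks[idx]) - n * (n + 1) / 2)
  min(1, 2 * min(mean(w_null >= w_obs), mean(w_null <= w_obs)))
}

beta_nets <- function(n, p, a, b, seed0) {
  lapply(seq_len(n), function(i)
    generate_iid_network(p, dist_beta(a, b), seed = seed0 + i))
}
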