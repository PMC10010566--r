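# Expected order statistics, expected barcodes, confidence bands.

test_that("uniform expected order statistics are exactly k/(q+1)", {
  for (q in c(6L, 45L, 100L)) {
    k <- seq_len(q)
    expect_identical(expected_order_stat(dist_uniform01(), k, q), k / (q + 1))
  }
  expect_equal(expected_order_stat(dist_uniform01(), 3, 6), 3 / 7)
})

test_that("median rank of a symmetric distribution maps to 1/2", {
  for (d in list(dist_uniform01(), dist_beta(2, 2), dist_beta(5, 5))) {
    expect_equal(expected_order_stat(d, 50, 99), 0.5)
  }
})

test_that("ranks outside 1..q are rejected", {
  expect_error(expected_order_stat(dist_uniform01(), 0, 5), "1..q")
  expect_error(expected_order_stat(dist_uniform01(), 6, 5), "1..q")
  expect_error(order_stat_variance(dist_uniform01(), 100, 99), "1..q")
  expect_error(expected_order_stat(list(), 1, 5), "dist_spec")
})

test_that("order-statistic variance matches the closed form for uniform", {
  expect_equal(order_stat_variance(dist_uniform01(), 50, 99), 0.0025)
  expect_warning(v1 <- order_stat_variance(dist_uniform01(), 1, 99),
                 "extreme ranks")
  expect_equal(v1, 0.01 * 0.99 / 100)
})

test_that("variance requires a usable density", {
  expect_error(order_stat_variance(dist_empirical(1:5), 2, 4), "no density")
  flat <- dist_beta(2, 2)
  flat$density <- function(x) rep(0, length(x))  # simulate a degenerate fit
  expect_error(order_stat_variance(flat, 2, 4), "zero or undefined")
})

test_that("Monte-Carlo oracle validates the quantile approximation", {
  # E(W_(k)) ~ Q(r), r = k/(q+1), with second-order bias
  # r(1-r) Q''(r) / (2(q+2)); the MC mean at 1e5 replicates resolves that
  # bias, so compare against the bias-corrected value.
  set.seed(91)
  a <- 2; b <- 5; q <- 99L; k <- 50L; R <- 1e5
  m <- matrix(rbeta(R * q, a, b), R, q)
  w_k <- apply(m, 1, function(x) sort(x, partial = k)[k])
  r <- k / (q + 1)
  approx <- expected_order_stat(dist_beta(a, b), k, q)
  expect_equal(approx, qbeta(r, a, b))
  f <- function(x) dbeta(x, a, b)
  eps <- 1e-6
  Qpp <- (qbeta(r + eps, a, b) - 2 * qbeta(r, a, b) + qbeta(r - eps, a, b)) /
    eps^2
  bias <- r * (1 - r) * Qpp / (2 * (q + 2))
  se <- sd(w_k) / sqrt(R)
  expect_lt(abs(mean(w_k) - (approx + bias)), 3 * se)

  # variance approximation within 10% relative error
  set.seed(92)
  q2 <- 199L; k2 <- 100L
  m2 <- matrix(rbeta(R * q2, 2, 2), R, q2)
  w2 <- apply(m2, 1, function(x) sort(x, partial = k2)[k2])
  v_hat <- order_stat_variance(dist_beta(2, 2), k2, q2)
  expect_lt(abs(var(w2) - v_hat) / var(w2), 0.10)
})

test_that("quantile approximation error shrinks like 1/q", {
  set.seed(93)
  R <- 2e4
  for (q in c(19L, 99L, 499L)) {
    k <- (q + 1L) %/% 2L
    m <- matrix(rbeta(R * q, 2, 5), R, q)
    w_k <- apply(m, 1, function(x) sort(x, partial = k)[k])
    err <- abs(mean(w_k) - expected_order_stat(dist_beta(2, 5), k, q))
    expect_lt(err, 1 / q)
  }
})

test_that("expected barcode maps ranks through the quantile function", {
  bd <- birth_death_decomposition(fig_network())
  eb <- expected_barcode(dist_uniform01(), bd, 6)
  expect_equal(eb$expected_births, c(3, 5, 6) / 7)
  expect_equal(eb$expected_deaths, c(1, 2, 4) / 7)
  # uniform density is 1, so variances are r(1-r)/(q+1)
  r <- c(3, 5, 6) / 7
  expect_equal(eb$birth_vars, r * (1 - r) / 7)
})

test_that("empirical plug-in expected barcode equals the observed barcode", {
  net <- rand_net(10, seed = 31)
  bd <- birth_death_decomposition(net)
  eb <- expected_barcode(dist_empirical(net$weights), bd, net$q)
  # F_hat^{-1}(k/(q+1)) is exactly the k-th sorted weight
  expect_equal(eb$expected_births, bd$births)
  expect_equal(eb$expected_deaths, bd$deaths)
})

test_that("degenerate distribution collapses the expected barcode", {
  bd <- birth_death_decomposition(fig_network())
  eb <- expected_barcode(dist_empirical(0.4), bd, 6)
  expect_equal(eb$expected_births, rep(0.4, 3))
  expect_equal(eb$expected_deaths, rep(0.4, 3))
})

test_that("invalid rank partitions are rejected", {
  expect_error(
    expected_barcode(dist_uniform01(),
                     list(birth_ranks = c(1, 2), death_ranks = c(2, 3)), 4),
    "partition")
  expect_error(
    expected_barcode(dist_uniform01(),
                     list(birth_ranks = c(1, 2), death_ranks = 4), 4),
    "partition")
})

test_that("generalized inverse cdf honours its contract", {
  set.seed(41)
  x <- runif(37)
  spec <- dist_empirical(x)
  for (u in seq(0.01, 0.999, length.out = 25)) {
    expect_gte(spec$cdf(spec$quantile(u)), u)
  }
  for (t in sample(x, 10)) {
    expect_lte(spec$quantile(spec$cdf(t)), t)
  }
  # beyond the last jump the inverse returns the sample maximum
  expect_equal(spec$quantile(1), max(x))
  expect_equal(spec$quantile(1.2), max(x))
})

test_that("group distribution estimate averages the weight vectors", {
  net <- rand_net(6, seed = 51)
  spec1 <- estimate_group_distribution(list(net))
  expect_equal(spec1$sample, sort(net$weights))
  spec2 <- estimate_group_distribution(list(net, net))
  expect_equal(spec2$sample, spec1$sample)
  expect_error(estimate_group_distribution(list(net, rand_net(5, 1))),
               "same node count")
  # pooling option uses all n*q raw weights
  net2 <- rand_net(6, seed = 52)
  pooled <- estimate_group_distribution(list(net, net2), pool = TRUE)
  expect_length(pooled$sample, 2 * net$q)
})

test_that("group quantiles track the base graph under small noise", {
  base <- rand_net(10, seed = 61)
  nets <- generate_noisy_group(base, n = 15, sigma = 0.02, seed = 62)
  spec <- estimate_group_distribution(nets)
  got <- spec$quantile(seq_len(base$q) / (base$q + 1))
  expect_lt(max(abs(got - sort(base$weights))), 3 * 0.02)
})

test_that("confidence bands use the normal multiplier and both roles", {
  base <- rand_net(10, seed = 71)
  nets <- generate_noisy_group(base, n = 15, sigma = 0.02, seed = 72)
  bands <- confidence_bands(nets, alpha_pct = 95)
  expect_equal(nrow(bands), base$q)
  expect_equal(sum(bands$role == "birth"), base$p - 1)
  # half-width equals z * sigma with z = 1.96 at 95%
  z <- (bands$hi - bands$lo) / (2 * bands$sigma_hat)
  expect_equal(z, rep(qnorm(0.975), base$q), tolerance = 1e-12)
  expect_true(all(is.finite(bands$sigma_hat)))
  b90 <- confidence_bands(nets, alpha_pct = 90)
  expect_true(all(b90$hi - b90$lo < bands$hi - bands$lo))
})

test_that("two identical noise-free copies still yield finite bands", {
  net <- rand_net(8, seed = 81)
  bands <- confidence_bands(list(net, net))
  expect_true(all(is.finite(bands$sigma_hat)))
  expect_equal(bands$mu_hat, sort(net$weights))
  expect_error(confidence_bands(list(net)), "at least 2")
})
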