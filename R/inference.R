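#' Wasserstein distances between barcodes of graph filtrations
#'
#' For graph filtrations the barcodes are one-dimensional point sets, so
#' the 2-Wasserstein distance reduces to the L2 distance between the
#' sorted values: the sorted (rank) matching attains the infimum over
#' all bijections.  `wasserstein_0d` compares birth sets (lengths must
#' agree, i.e. same node count), `wasserstein_1d` compares death sets.
#'
#' @param b1,b2 numeric vectors of birth (or death) values; sorted
#'   internally.
#' @return The distance, a non-negative number.
#' @examples
#' wasserstein_0d(c(0.1, 0.4), c(0.2, 0.6))  # sqrt(0.01 + 0.04)
#' @export
wasserstein_0d <- function(b1, b2) {
  if (length(b1) != length(b2))
    stop("barcodes must have equal length (same node count)", call. = FALSE)
  sqrt(sum((sort(b1) - sort(b2))^2))
}

#' @rdname wasserstein_0d
#' @param d1,d2 numeric vectors of death values.
#' @export
wasserstein_1d <- function(d1, d2) wasserstein_0d(d1, d2)

#' Expected topological loss (ETL) between two expected barcodes
#'
#' The ETL between two random graphs with the same node count is the sum
#' of squared differences of their rank-matched expected birth values
#' plus the same for expected death values.  As defined it is a sum of
#' squares, i.e. the squared 2-Wasserstein distance between expected
#' barcodes; set `sqrt = TRUE` for the distance-scale variant.
#'
#' @param eb1,eb2 [expected_barcode()] objects with matching `m0`, `m1`.
#' @param sqrt return the square root of the loss (default `FALSE`,
#'   the literal sum of squares).
#' @return Non-negative number.
#' @export
etl <- function(eb1, eb2, sqrt = FALSE) {
  stopifnot(inherits(eb1, "expected_barcode"),
            inherits(eb2, "expected_barcode"))
  if (length(eb1$expected_births) != length(eb2$expected_births) ||
      length(eb1$expected_deaths) != length(eb2$expected_deaths))
    stop("expected barcodes must come from networks with the same p",
         call. = FALSE)
  val <- sum((eb1$expected_births - eb2$expected_births)^2) +
    sum((eb1$expected_deaths - eb2$expected_deaths)^2)
  if (sqrt) base::sqrt(val) else val
}

#' Per-network and group-mean expected barcodes
#'
#' For each network the empirical distribution of its own `q` edge
#' weights is plugged into the order-statistic quantile map at the ranks
#' of its own birth-death decomposition, giving per-network expected
#' birth values `u_{k,i}` and death values `v_{k,i}`.  Group summaries
#' are the element-wise means `u_bar`, `v_bar` across networks.
#'
#' With the empirical plug-in, `F_hat^{-1}(k/(q+1))` lands exactly on
#' the k-th sorted weight, so the per-network expected barcode coincides
#' with the observed barcode; the construction still goes through the
#' quantile map so that other distribution estimates can be swapped in.
#'
#' @param nets list of [weighted_network()]s sharing `p`.
#' @return An object of class `group_expected_barcodes` with fields `u`
#'   (`m0 x n` matrix), `v` (`m1 x n`), `u_bar`, `v_bar`, `p`, `n`.
#' @export
group_expected_barcodes <- function(nets) {
  wmat <- group_weight_matrix(nets)
  p <- nets[[1L]]$p
  q <- nets[[1L]]$q
  n <- length(nets)
  m0 <- p - 1L
  m1 <- q - m0
  u <- matrix(NA_real_, m0, n)
  v <- matrix(NA_real_, m1, n)
  for (i in seq_len(n)) {
    bd <- birth_death_decomposition(nets[[i]])
    eb <- expected_barcode(dist_empirical(nets[[i]]$weights), bd, q)
    u[, i] <- eb$expected_births
    v[, i] <- eb$expected_deaths
  }
  structure(list(u = u, v = v,
                 u_bar = rowMeans(u), v_bar = rowMeans(v),
                 p = p, n = n),
            class = "group_expected_barcodes")
}

#' Group-difference statistics on expected barcodes
#'
#' `group_statistic` is the ETL-type statistic
#' `L = sum_j (u_bar_j^A - u_bar_j^B)^2 + sum_j (v_bar_j^A - v_bar_j^B)^2`
#' on group-mean expected births `u_bar` and deaths `v_bar`.
#' `max_gap_statistic` is
#' `L1 = max_j |u_bar_j^A - u_bar_j^B| + max_j |v_bar_j^A - v_bar_j^B|`.
#' Both are non-negative, zero iff the group means coincide, and
#' symmetric in the two groups.
#'
#' @param groupA,groupB [group_expected_barcodes()] objects with the
#'   same `p`.
#' @return A non-negative number.
#' @export
group_statistic <- function(groupA, groupB) {
  check_groups(groupA, groupB)
  sum((groupA$u_bar - groupB$u_bar)^2) +
    sum((groupA$v_bar - groupB$v_bar)^2)
}

#' @rdname group_statistic
#' @export
max_gap_statistic <- function(groupA, groupB) {
  check_groups(groupA, groupB)
  dv <- if (length(groupA$v_bar)) max(abs(groupA$v_bar - groupB$v_bar)) else 0
  max(abs(groupA$u_bar - groupB$u_bar)) + dv
}

check_groups <- function(groupA, groupB) {
  stopifnot(inherits(groupA, "group_expected_barcodes"),
            inherits(groupB, "group_expected_barcodes"))
  if (groupA$p != groupB$p)
    stop("groups must share the same node count p", call. = FALSE)
  invisible(TRUE)
}

#' Area under the Betti-0 curve
#'
#' Summarises the Betti-0 step function over its birth values as the sum
#' of rectangular blocks, `AUC = sum_{k=2}^{m0} k (u_k - u_{k-1})`, where
#' `u_1 < ... < u_m0` are the (expected) birth values.  Invariant under
#' a constant shift of the births.
#'
#' @param births increasing numeric vector of (expected) birth values.
#' @return The area, a single number (0 with a warning when fewer than
#'   two births exist).
#' @export
auc_betti0 <- function(births) {
  m0 <- length(births)
  if (m0 < 2L) {
    warning("need at least two birth values for an area; returning 0")
    return(0)
  }
  sum((2:m0) * diff(births))
}

#' Permutation test for a topological group difference
#'
#' Computes the observed ETL (`"etl"`) or maximum-gap (`"maxgap"`)
#' statistic between two groups of networks, then builds a null
#' distribution by randomly relabeling the pooled networks into groups
#' of the original sizes.  The p-value uses the add-one estimator
#' `(1 + #\{null >= observed\}) / (n_perm + 1)`, which cannot be zero.
#' When `exhaustive = TRUE` (or `"auto"` with a feasible count) all
#' distinct relabelings are enumerated instead and the plain proportion
#' `#\{null >= observed\} / n_splits` is reported (the identity
#' relabeling is included, so the p-value is at least `1/n_splits`).
#'
#' Per-network expected barcodes are computed once; relabeling then only
#' re-averages them, so the test scales to dense networks.
#'
#' @param netsA,netsB lists of [weighted_network()]s sharing `p`.
#' @param statistic `"etl"` or `"maxgap"`.
#' @param n_perm number of random relabelings (default 10000).
#' @param seed optional integer seed for reproducibility.
#' @param exhaustive `FALSE`, `TRUE`, or `"auto"` (enumerate when the
#'   number of splits is at most `1e5`).
#' @return An object of class `nb_test`: `statistic`, `observed`,
#'   `null_samples`, `p_value`, `n_perm`, `seed`, `exhaustive`.
#' @examples
#' a <- lapply(1:4, function(i) generate_iid_network(6, dist_beta(5, 2)))
#' b <- lapply(1:4, function(i) generate_iid_network(6, dist_beta(1, 5)))
#' permutation_test(a, b, "etl", n_perm = 200, seed = 1)
#' @export
permutation_test <- function(netsA, netsB, statistic = c("etl", "maxgap"),
                             n_perm = 10000, seed = NULL,
                             exhaustive = FALSE) {
  statistic <- match.arg(statistic)
  if (!length(netsA) || !length(netsB))
    stop("both groups must be non-empty", call. = FALSE)
  if (n_perm < 1) stop("'n_perm' must be >= 1", call. = FALSE)
  ga <- group_expected_barcodes(netsA)
  gb <- group_expected_barcodes(netsB)
  if (ga$p != gb$p)
    stop("groups must share the same node count p", call. = FALSE)
  nA <- ga$n
  nB <- gb$n
  n <- nA + nB
  m0 <- nrow(ga$u)
  # rows = networks, cols = expected births then deaths
  E <- cbind(t(cbind(ga$u, gb$u)), t(cbind(ga$v, gb$v)))
  tot <- colSums(E)

  death_idx <- if (m0 < ncol(E)) (m0 + 1L):ncol(E) else integer(0)
  stat_fun <- function(sA) {
    d <- sA / nA - (tot - sA) / nB
    if (statistic == "etl") sum(d * d)
    else max(abs(d[seq_len(m0)])) +
      (if (length(death_idx)) max(abs(d[death_idx])) else 0)
  }
  observed <- stat_fun(colSums(E[seq_len(nA), , drop = FALSE]))

  do_exhaustive <- isTRUE(exhaustive) ||
    (identical(exhaustive, "auto") && choose(n, nA) <= 1e5)
  if (do_exhaustive) {
    splits <- utils::combn(n, nA)
    null_samples <- apply(splits, 2L, function(idx)
      stat_fun(colSums(E[idx, , drop = FALSE])))
    p_value <- mean(null_samples >= observed)
    n_used <- ncol(splits)
  } else {
    if (!is.null(seed)) set.seed(seed)
    null_samples <- numeric(n_perm)
    # chunked: indicator matrix times E uses BLAS, cheap even for p = 100
    chunk <- max(1L, min(n_perm, as.integer(2e6 / max(ncol(E), 1L))))
    done <- 0L
    while (done < n_perm) {
      b <- min(chunk, n_perm - done)
      P <- matrix(0, b, n)
      for (r in seq_len(b)) P[r, sample.int(n, nA)] <- 1
      S <- P %*% E
      D <- S / nA - (matrix(tot, b, ncol(E), byrow = TRUE) - S) / nB
      null_samples[done + seq_len(b)] <-
        if (statistic == "etl") rowSums(D * D)
        else apply(abs(D[, seq_len(m0), drop = FALSE]), 1L, max) +
          (if (length(death_idx))
             apply(abs(D[, death_idx, drop = FALSE]), 1L, max) else 0)
      done <- done + b
    }
    p_value <- (1 + sum(null_samples >= observed)) / (n_perm + 1)
    n_used <- n_perm
  }
  structure(list(statistic = statistic, observed = observed,
                 null_samples = null_samples, p_value = p_value,
                 n_perm = n_used, seed = seed,
                 exhaustive = do_exhaustive),
            class = "nb_test")
}

#' Wilcoxon rank-sum test on areas under Betti-0 curves
#'
#' Computes each network's area under its Betti-0 curve from its
#' expected birth values ([auc_betti0()]) and compares the two groups of
#' areas with the two-sided Wilcoxon rank-sum test.  The exact null
#' distribution is used when both groups have at most 12 networks and
#' there are no tied areas (complete separation of two groups of 6 then
#' gives the minimal two-sided p-value 2/choose(12, 6) ~ 0.0022);
#' otherwise the normal approximation with tie correction applies.
#'
#' @param netsA,netsB lists of [weighted_network()]s sharing `p`.
#' @return An `nb_test` with fields `statistic = "auc_wilcoxon"`,
#'   `observed` (the rank-sum W), `p_value`, `auc_a`, `auc_b`, `exact`.
#' @export
wilcoxon_auc_test <- function(netsA, netsB) {
  if (!length(netsA) || !length(netsB))
    stop("both groups must be non-empty", call. = FALSE)
  ga <- group_expected_barcodes(netsA)
  gb <- group_expected_barcodes(netsB)
  if (ga$p != gb$p)
    stop("groups must share the same node count p", call. = FALSE)
  auc_a <- apply(ga$u, 2L, auc_betti0)
  auc_b <- apply(gb$u, 2L, auc_betti0)
  exact <- length(auc_a) <= 12L && length(auc_b) <= 12L &&
    !anyDuplicated(c(auc_a, auc_b))
  wt <- wilcox.test(auc_a, auc_b, alternative = "two.sided",
                    exact = exact, correct = TRUE)
  structure(list(statistic = "auc_wilcoxon",
                 observed = unname(wt$statistic),
                 null_samples = NULL,
                 p_value = wt$p.value,
                 auc_a = auc_a, auc_b = auc_b,
                 exact = exact,
                 n_perm = NA_integer_, seed = NULL),
            class = "nb_test")
}

#' @export
print.nb_test <- function(x, ...) {
  cat(sprintf("Topological group-difference test (%s)\n", x$statistic))
  cat(sprintf("  observed statistic: %.6g\n", x$observed))
  cat(sprintf("  p-value: %.6g", x$p_value))
  if (!is.null(x$null_samples))
    cat(sprintf("  (%s%d relabelings)",
                if (isTRUE(x$exhaustive)) "exhaustive, " else "", x$n_perm))
  cat("\n")
  invisible(x)
}
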