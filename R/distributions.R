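#' Edge-weight distribution specifications
#'
#' A `dist_spec` bundles the cumulative distribution function, the
#' generalized inverse cdf `F^{-1}(x) = inf\{t : F(t) >= x\}`, a density
#' (where one exists) and a sampler, for use in expected-barcode and
#' confidence-band computations.  Constructors are provided for the
#' standard uniform, Beta(a, b), the empirical distribution of a sample,
#' and the empirical distribution augmented with a Gaussian kernel
#' density estimate.
#'
#' @param a,b Beta shape parameters (positive).
#' @return An object of class `dist_spec` with fields `kind`, `cdf`,
#'   `quantile`, `density` (may be `NULL`), `rng` (may be `NULL`),
#'   `sample` (data vector for empirical kinds) and `params`.
#' @name dist_spec
NULL

new_dist_spec <- function(kind, cdf, quantile, density = NULL, rng = NULL,
                          sample = NULL, params = list()) {
  structure(list(kind = kind, cdf = cdf, quantile = quantile,
                 density = density, rng = rng, sample = sample,
                 params = params),
            class = "dist_spec")
}

#' @rdname dist_spec
#' @export
dist_uniform01 <- function() {
  new_dist_spec("uniform01",
                cdf = function(x) punif(x),
                quantile = function(u) qunif(u),
                density = function(x) dunif(x),
                rng = function(n) runif(n))
}

#' @rdname dist_spec
#' @export
dist_beta <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), a > 0, b > 0)
  new_dist_spec(sprintf("beta(%g,%g)", a, b),
                cdf = function(x) pbeta(x, a, b),
                quantile = function(u) qbeta(u, a, b),
                density = function(x) dbeta(x, a, b),
                rng = function(n) rbeta(n, a, b),
                params = list(a = a, b = b))
}

#' @rdname dist_spec
#' @param x numeric sample defining an empirical distribution.
#' @details The empirical cdf is `F(t) = mean(x <= t)`, a right-continuous
#'   step function with `F(max(x)) = 1`.  Its generalized inverse maps
#'   `u` in `(0, 1]` to the `ceiling(u * n)`-th order statistic;
#'   `u <= 0` maps to the sample minimum and `u > 1` to the maximum
#'   (the infimum over an empty set is otherwise undefined).  Inverse
#'   sampling through the generalized inverse provides the sampler.
#' @export
dist_empirical <- function(x) {
  x <- as.numeric(x)
  if (length(x) == 0L || anyNA(x))
    stop("empirical sample must be non-empty with no NA", call. = FALSE)
  xs <- sort(x)
  n <- length(xs)
  qfun <- function(u) {
    k <- ceiling(u * n)
    xs[pmin(pmax(k, 1L), n)]
  }
  new_dist_spec("empirical",
                cdf = function(t) findInterval(t, xs) / n,
                quantile = qfun,
                density = NULL,
                rng = function(m) qfun(runif(m)),
                sample = xs)
}

#' @rdname dist_spec
#' @param bandwidth Gaussian kernel bandwidth: a positive number or
#'   `"nrd0"` for Silverman's rule of thumb.
#' @details `dist_kde` keeps the empirical cdf and generalized inverse of
#'   the sample but adds the kernel density
#'   `f(t) = (1/(n h)) sum K((t - x_i)/h)` with Gaussian kernel `K`, as
#'   needed by the order-statistic variance formula.
#' @export
dist_kde <- function(x, bandwidth = "nrd0") {
  spec <- dist_empirical(x)
  xs <- spec$sample
  h <- if (identical(bandwidth, "nrd0")) bw.nrd0(xs) else as.numeric(bandwidth)
  if (!is.finite(h) || h <= 0)
    stop("kernel bandwidth must be a positive number", call. = FALSE)
  dens <- function(t) {
    vapply(t, function(ti) mean(dnorm((ti - xs) / h)) / h, numeric(1))
  }
  spec$kind <- "kde"
  spec$density <- dens
  spec$params <- list(bandwidth = h)
  spec
}

#' Parse a distribution name
#'
#' Accepts `"uniform01"`, `"uniform(0,1)"` and `"beta(a,b)"` (case
#' insensitive, spaces ignored), as used in simulation configurations.
#'
#' @param name character scalar.
#' @return A `dist_spec`.
#' @export
parse_dist <- function(name) {
  s <- tolower(gsub("[[:space:]]", "", name))
  if (s %in% c("uniform01", "uniform(0,1)"))
    return(dist_uniform01())
  m <- regmatches(s, regexec("^beta\\(([0-9.]+),([0-9.]+)\\)$", s))[[1]]
  if (length(m) == 3L)
    return(dist_beta(as.numeric(m[2]), as.numeric(m[3])))
  stop(sprintf("unrecognized distribution name '%s'", name), call. = FALSE)
}

#' @export
print.dist_spec <- function(x, ...) {
  cat(sprintf("Distribution spec: %s", x$kind))
  if (!is.null(x$sample)) cat(sprintf(" (n = %d sample points)",
                                      length(x$sample)))
  cat("\n")
  invisible(x)
}
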