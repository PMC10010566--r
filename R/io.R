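#' Read a dense adjacency matrix as a weighted network
#'
#' Expects a square numeric CSV (no header, no row names; a header line
#' of non-numeric labels is auto-detected and used as node labels).
#' The matrix must be symmetric up to `1e-8`; the diagonal is ignored.
#'
#' @param path file path.
#' @return A [weighted_network()].
#' @export
read_adjacency <- function(path) {
  first <- readLines(path, n = 1L)
  fields <- strsplit(first, ",", fixed = TRUE)[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(fields)))
  a <- as.matrix(read.csv(path, header = has_header))
  if (has_header) rownames(a) <- colnames(a)
  storage.mode(a) <- "numeric"
  if (anyNA(a))
    stop(sprintf("non-numeric or missing entries in '%s'", path),
         call. = FALSE)
  as_weighted_network(a)
}

#' Write a weighted network as a dense adjacency CSV
#'
#' @param net a [weighted_network()].
#' @param path file path.
#' @return `path`, invisibly.  `read_adjacency(write_adjacency(net))`
#'   preserves the weights to full precision.
#' @export
write_adjacency <- function(net, path) {
  a <- adjacency_matrix(net)
  # 17 significant digits: lossless double round trip
  lines <- apply(a, 1L, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read an edge-list TSV as a weighted network
#'
#' Columns: `node_i`, `node_j`, `weight`; 0-based node indices; one row
#' per unordered pair.  Row order is irrelevant -- weights are placed in
#' the canonical edge ordering.  All `p(p-1)/2` edges must be present
#' (the model is a complete graph).
#'
#' @param path file path.
#' @return A [weighted_network()].
#' @export
read_edge_list <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("i", "j", "w"))
  p <- max(df$i, df$j) + 1L
  q <- p * (p - 1L) / 2L
  if (nrow(df) != q)
    stop(sprintf("edge list has %d rows; a complete graph on %d nodes needs %d",
                 nrow(df), p, q), call. = FALSE)
  i <- pmin(df$i, df$j)
  j <- pmax(df$i, df$j)
  if (any(i == j)) stop("self-loops are not allowed", call. = FALSE)
  # canonical index of 0-based pair (i, j), i < j
  idx <- i * p - i * (i + 1L) / 2L + (j - i)
  if (anyDuplicated(idx)) stop("duplicate edges in edge list", call. = FALSE)
  w <- numeric(q)
  w[idx] <- df$w
  weighted_network(p, w)
}

#' Read all adjacency CSVs in a directory as a group of networks
#'
#' Files are taken in lexicographic order; all networks must share the
#' same node count.
#'
#' @param dir directory containing `.csv` adjacency files.
#' @return A named list of [weighted_network()]s.
#' @export
read_group <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (!length(files))
    stop(sprintf("no .csv files found in '%s'", dir), call. = FALSE)
  nets <- lapply(files, read_adjacency)
  ps <- vapply(nets, function(x) x$p, integer(1))
  if (length(unique(ps)) != 1L)
    stop(sprintf("inconsistent node counts in '%s': %s", dir,
                 paste(unique(ps), collapse = ", ")), call. = FALSE)
  names(nets) <- basename(files)
  nets
}

#' Barcode JSON round trip
#'
#' @param bar a `barcode`.
#' @param path file path.
#' @return `write_barcode` returns `path` invisibly; `read_barcode`
#'   returns the `barcode`.
#' @export
write_barcode <- function(bar, path) {
  stopifnot(inherits(bar, "barcode"))
  jsonlite::write_json(
    list(p = bar$p, births = bar$births, deaths = bar$deaths,
         birth_ranks = bar$birth_ranks, death_ranks = bar$death_ranks),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_barcode
#' @export
read_barcode <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  barcode(x$p, x$births, x$deaths, x$birth_ranks, x$death_ranks)
}

#' Read a region time-series CSV
#'
#' One row per time point, one column per region; a header row carries
#' region labels.  Used to build Pearson correlation networks.
#'
#' @param path file path.
#' @return A `T x p` numeric matrix with region labels as column names.
#' @export
read_time_series <- function(path) {
  ts <- as.matrix(read.csv(path, header = TRUE, check.names = FALSE))
  storage.mode(ts) <- "numeric"
  if (anyNA(ts))
    stop(sprintf("non-numeric or missing entries in '%s'", path),
         call. = FALSE)
  ts
}

#' Pearson correlation network from region time series
#'
#' Correlates the columns (regions) of a time-series matrix pairwise and
#' returns the correlations as a complete weighted network -- the
#' standard construction of functional connectivity from per-region
#' signals (116 regions give `q = 6670` edges).
#'
#' @param ts numeric `T x p` matrix, `T >= 2` time points; columns may
#'   carry region labels.
#' @param zscore standardize each column first (does not change Pearson
#'   correlations; provided for pipelines that expect explicit
#'   normalisation). Default `FALSE`.
#' @return A [weighted_network()] of pairwise correlations.
#' @export
correlation_network <- function(ts, zscore = FALSE) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 2L)
    stop("need at least 2 time points", call. = FALSE)
  if (ncol(ts) < 2L)
    stop("need at least 2 regions", call. = FALSE)
  sds <- apply(ts, 2L, sd)
  if (any(sds == 0)) {
    bad <- colnames(ts)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop(sprintf("constant column(s): %s (correlation undefined)",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (zscore) ts <- scale(ts)
  as_weighted_network(cor(ts))
}

#' Write confidence bands as CSV
#'
#' @param bands data frame from [confidence_bands()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_bands <- function(bands, path) {
  write.csv(bands, path, row.names = FALSE)
  invisible(path)
}
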