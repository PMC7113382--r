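#' Pearson correlation matrix across regions
#'
#' Correlates every pair of columns (regions) of a coefficient or
#' time-series matrix. This is applied per subject to the level-of-interest
#' wavelet coefficients to build the functional connectivity matrix.
#'
#' @param coeff_matrix `T x R` numeric matrix; column names label regions.
#' @return Symmetric `R x R` correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(coeff_matrix) {
  x <- .as_signal_matrix(coeff_matrix)
  if (nrow(x) < 3) stop("need at least 3 timepoints for a correlation")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    nm <- colnames(x) %||% as.character(seq_len(ncol(x)))
    stop("constant time series (correlation undefined) for region(s): ",
         paste(nm[sds == 0], collapse = ", "))
  }
  r <- stats::cor(x)
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  r
}

#' Edge count implied by a connection density
#'
#' Number of edges retained when thresholding an `n`-region graph at the
#' given density, using round-half-up on `density * n * (n - 1) / 2`. At
#' the conventional 5% density a 264-region graph keeps 1736 edges.
#'
#' @param n_regions Number of nodes.
#' @param density Fraction of possible edges to keep, in (0, 1].
#' @return Integer edge count.
#' @export
#' @examples
#' edge_count_for_density(264, 0.05) # 1736
edge_count_for_density <- function(n_regions, density) {
  if (n_regions < 2) stop("`n_regions` must be at least 2")
  if (density <= 0 || density > 1) stop("`density` must be in (0, 1]")
  k <- floor(density * n_regions * (n_regions - 1) / 2 + 0.5)
  if (k < 1) {
    stop(sprintf("density %g on %d nodes implies 0 edges", density, n_regions))
  }
  as.integer(k)
}

#' Binarize a correlation matrix at fixed connection density
#'
#' Keeps exactly [edge_count_for_density()] edges — the top-ranked
#' region pairs by correlation — so every subject's graph has an identical
#' edge count regardless of their correlation distribution (the
#' connectivity-conservation criterion: the numeric threshold attained
#' varies per subject, the edge count does not). Ties at the cutoff are
#' broken by lexicographic `(i, j)` order, making the result deterministic.
#'
#' @param corr Correlation matrix from [correlation_matrix()].
#' @param density Connection density in (0, 1].
#' @param mode `"signed"` ranks by `r` (strongest positive correlations
#'   win, the default); `"absolute"` ranks by `|r|`.
#' @return An object of class `waveconn_adjacency`: list with `edges`
#'   (symmetric 0/1 matrix, zero diagonal), `edge_count`, `density`
#'   (realized), `threshold` (smallest retained ranking value), `mode`.
#' @export
threshold_to_density <- function(corr, density,
                                 mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  if (!is.matrix(corr) || nrow(corr) != ncol(corr)) {
    stop("`corr` must be a square matrix")
  }
  if (max(abs(corr - t(corr))) > 1e-8) stop("`corr` must be symmetric")
  n <- nrow(corr)
  k <- edge_count_for_density(n, density)
  ut <- which(upper.tri(corr), arr.ind = TRUE)
  r <- corr[ut]
  key <- if (mode == "signed") r else abs(r)
  ord <- order(-key, ut[, 1L], ut[, 2L])
  take <- ord[seq_len(k)]
  adj <- matrix(0L, n, n, dimnames = dimnames(corr))
  adj[ut[take, , drop = FALSE]] <- 1L
  adj <- adj + t(adj)
  structure(
    list(edges = adj, edge_count = k,
         density = k / (n * (n - 1) / 2),
         threshold = min(key[take]), mode = mode),
    class = "waveconn_adjacency"
  )
}

#' @export
print.waveconn_adjacency <- function(x, ...) {
  cat(sprintf(
    "Binary adjacency: %d nodes, %d edges (density %.4f), threshold %.4f (%s)\n",
    nrow(x$edges), x$edge_count, x$density, x$threshold, x$mode))
  invisible(x)
}

# Accept either a waveconn_adjacency or a bare symmetric 0/1 matrix.
.adjacency_matrix <- function(adjacency) {
  if (inherits(adjacency, "waveconn_adjacency")) return(adjacency$edges)
  if (is.matrix(adjacency) && nrow(adjacency) == ncol(adjacency) &&
      all(adjacency %in% c(0, 1)) && all(diag(adjacency) == 0) &&
      max(abs(adjacency - t(adjacency))) == 0) {
    return(adjacency)
  }
  stop("`adjacency` must be a waveconn_adjacency or a symmetric 0/1 matrix ",
       "with zero diagonal")
}

#' Write an adjacency as an edge-list TSV
#'
#' One row per retained edge: region indices `i < j` plus the correlation
#' value if the source matrix is supplied.
#'
#' @param adjacency A `waveconn_adjacency`.
#' @param path Output file.
#' @param corr Optional correlation matrix to annotate edges with `r`.
#' @export
write_edge_list <- function(adjacency, path, corr = NULL) {
  adj <- .adjacency_matrix(adjacency)
  ut <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  el <- data.frame(i = ut[, 1L] - 1L, j = ut[, 2L] - 1L)
  if (!is.null(corr)) el$r <- corr[ut]
  write_tsv(el, path)
}
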