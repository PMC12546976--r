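#' Standardize an expression matrix to per-gene z-scores
#'
#' Each gene's row is centered and scaled by its sample standard deviation
#' (m-1 denominator) across the chosen samples. Constant rows (sd = 0) are
#' set to zero so they can never be flagged as extreme.
#'
#' @param expr An \code{expression_matrix}.
#' @param columns Which samples the mean and sd are computed over:
#'   \code{"all"} (default) or \code{"tumor"}.
#' @return Numeric matrix of z-scores, same dimensions and dimnames as the
#'   selected columns of the input.
#' @export
zscore_expression <- function(expr, columns = c("all", "tumor")) {
  columns <- match.arg(columns)
  L <- expr$values
  if (columns == "tumor") L <- L[, expr$conditions == "tumor", drop = FALSE]
  if (ncol(L) < 2L) stop("need at least two samples to standardize")
  mu <- rowMeans(L)
  sigma <- apply(L, 1L, stats::sd)
  z <- (L - mu) / ifelse(sigma > 0, sigma, 1)
  z[sigma == 0, ] <- 0
  z
}

#' Binarize a z-score matrix at an extremeness threshold
#'
#' Flags the cells whose z-score strictly exceeds \code{tau}; the flag
#' matrix feeds the differential-expression rule.
#'
#' @param z Numeric z-score matrix.
#' @param tau Positive threshold, default 2.5.
#' @return Integer 0/1 matrix of the same shape.
#' @export
binarize <- function(z, tau = 2.5) {
  stopifnot(tau > 0)
  flags <- (z > tau) + 0L
  dimnames(flags) <- dimnames(z)
  flags
}

#' Call differentially expressed genes from a binary flag matrix
#'
#' A gene is differentially expressed when its fraction of flagged samples
#' strictly exceeds the matrix-wide mean flag rate.
#'
#' @param flags 0/1 matrix (genes x samples), typically the tumor columns
#'   of \code{\link{binarize}} output.
#' @return Character vector of DE gene identifiers (possibly empty), with
#'   the global mean flag rate as attribute \code{"global_mean"}.
#' @export
call_de_genes <- function(flags) {
  stopifnot(is.matrix(flags), all(flags %in% c(0L, 1L)))
  rate <- rowMeans(flags)
  global <- mean(flags)
  de <- rownames(flags)[rate > global]
  structure(de, global_mean = global)
}

#' Per-edge Pearson co-expression of a PPI network
#'
#' Correlates the expression profiles of each interacting gene pair over
#' the chosen samples. Edges with an endpoint missing from the matrix, or
#' with a zero-variance endpoint, get coefficient 0.
#'
#' @param expr An \code{expression_matrix}.
#' @param network A \code{ppi_network}.
#' @param columns Samples to correlate over: \code{"tumor"} (default) or
#'   \code{"all"}.
#' @return Numeric vector of correlations aligned with
#'   \code{network$edges} rows.
#' @export
edge_correlations <- function(expr, network, columns = c("tumor", "all")) {
  columns <- match.arg(columns)
  L <- expr$values
  if (columns == "tumor") L <- L[, expr$conditions == "tumor", drop = FALSE]
  edges <- network$edges
  present <- rownames(L)
  rho <- numeric(nrow(edges))
  both <- edges$from %in% present & edges$to %in% present
  if (any(both)) {
    genes <- unique(c(edges$from[both], edges$to[both]))
    cm <- suppressWarnings(stats::cor(t(L[genes, , drop = FALSE])))
    rho[both] <- cm[cbind(edges$from[both], edges$to[both])]
  }
  rho[is.na(rho)] <- 0  # zero-variance endpoints
  rho
}
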