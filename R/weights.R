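#' Seed-proximal topology score
#'
#' For each differentially expressed gene, the fraction of its first-order
#' neighbors that are seeds plus the fraction of its second-order neighbors
#' (shortest-path distance exactly 2) that are seeds; a term with an empty
#' neighborhood contributes 0. All other genes score 0.
#'
#' @param network A \code{ppi_network}.
#' @param seeds Character vector of seed genes.
#' @param de Character vector of differentially expressed genes (subset of
#'   the network nodes).
#' @return Named numeric vector over the network nodes, values in \[0, 2\].
#' @export
compute_phi <- function(network, seeds, de) {
  stopifnot(all(de %in% network$nodes))
  seeds <- intersect(seeds, network$nodes)
  phi <- stats::setNames(numeric(length(network$nodes)), network$nodes)
  for (g in de) {
    n1 <- ppi_neighbors(network, g)
    n2 <- ppi_neighbors2(network, g)
    t1 <- if (length(n1) > 0L) length(intersect(n1, seeds)) / length(n1) else 0
    t2 <- if (length(n2) > 0L) length(intersect(n2, seeds)) / length(n2) else 0
    phi[g] <- t1 + t2
  }
  phi
}

#' Build the personalization (teleport) vector
#'
#' The annotation score theta and the topology score phi are each
#' normalized to sum 1 and mixed convexly:
#' \deqn{q = \alpha \hat\theta + (1 - \alpha) \hat\phi}
#' An all-zero phi (no DE genes, or none near seeds) is replaced by the
#' uniform vector so q remains a proper distribution.
#'
#' @param theta Named numeric annotation scores (from
#'   \code{\link{compute_theta}}); must not be all zero.
#' @param phi Named numeric topology scores over the same genes.
#' @param alpha Mixing weight in \[0, 1\]; 1 uses annotations only.
#' @return Named numeric vector summing to 1.
#' @export
build_personalization <- function(theta, phi, alpha = 0.5) {
  stopifnot(alpha >= 0, alpha <= 1, length(theta) == length(phi))
  if (!identical(names(theta), names(phi))) {
    phi <- phi[names(theta)]
    stopifnot(!anyNA(phi))
  }
  if (all(theta == 0)) stop("theta is all zero: no seeds or annotations scored")
  if (any(theta < 0) || any(phi < 0)) stop("scores must be non-negative")
  theta_hat <- theta / sum(theta)
  if (all(phi == 0)) {
    message("phi is all zero; using the uniform vector for the topology term")
    phi_hat <- rep(1 / length(phi), length(phi))
  } else {
    phi_hat <- phi / sum(phi)
  }
  q <- alpha * theta_hat + (1 - alpha) * phi_hat
  stats::setNames(as.numeric(q), names(theta))
}

#' Count of significant annotations shared by two genes
#'
#' The number of (source, term) pairs annotating both genes that survived
#' the enrichment filter; the edge-level evidence of disease-specific
#' functional similarity.
#'
#' @param i,j Gene identifiers (distinct).
#' @param catalog An \code{annotation_catalog}.
#' @param F Character vector of retained term ids (from
#'   \code{\link{select_significant_terms}}).
#' @return Non-negative integer count.
#' @export
dsi <- function(i, j, catalog, F) {
  stopifnot(i != j)
  if (length(F) == 0L) return(0L)
  ai <- gene_annotations(catalog, i)
  aj <- gene_annotations(catalog, j)
  length(intersect(intersect(ai, aj), F))
}

directed_support <- function(network) {
  # each undirected edge as both arcs, as (row, col) node-name pairs
  e <- network$edges
  list(from = c(e$from, e$to), to = c(e$to, e$from))
}

edge_matrix <- function(network, values) {
  # symmetric sparse matrix with `values` (aligned to network$edges) on
  # both arcs of every edge
  nodes <- network$nodes
  sup <- directed_support(network)
  Matrix::sparseMatrix(
    i = match(sup$from, nodes), j = match(sup$to, nodes),
    x = rep(values, 2L), dims = c(length(nodes), length(nodes)),
    dimnames = list(nodes, nodes))
}

#' Annotation-based edge weights
#'
#' Each interacting pair gets weight \code{c + DSI(i, j)}; the positive
#' floor \code{c} keeps every interaction traversable when no shared
#' significant annotation exists. Non-adjacent pairs have weight 0.
#'
#' @param network A \code{ppi_network}.
#' @param catalog An \code{annotation_catalog}.
#' @param F Retained significant term ids.
#' @param c Positive floor constant, default 0.1.
#' @return Sparse symmetric matrix (nodes x nodes) supported on the PPI
#'   edge set.
#' @export
compute_w1 <- function(network, catalog, F, c = 0.1) {
  stopifnot(c > 0)
  e <- network$edges
  counts <- vapply(seq_len(nrow(e)),
                   function(r) dsi(e$from[r], e$to[r], catalog, F),
                   integer(1))
  edge_matrix(network, c + counts)
}

#' Co-expression edge weights
#'
#' Pearson coefficients are clipped at zero (or folded by absolute value)
#' and each row is normalized over the gene's neighbors; a row whose
#' clipped sum is zero falls back to the uniform distribution over its
#' neighbors, so no interaction is silently deleted.
#'
#' @param P Numeric vector of per-edge Pearson coefficients aligned with
#'   \code{network$edges} (see \code{\link{edge_correlations}}).
#' @param network A \code{ppi_network}.
#' @param negative_corr How to make negative correlations usable as
#'   transition mass: \code{"clip"} (default) or \code{"abs"}.
#' @return Sparse row-stochastic matrix supported on the PPI edge set.
#' @export
compute_w2 <- function(P, network, negative_corr = c("clip", "abs")) {
  negative_corr <- match.arg(negative_corr)
  stopifnot(length(P) == nrow(network$edges))
  Ppos <- if (negative_corr == "abs") abs(P) else pmax(P, 0)
  M <- edge_matrix(network, Ppos)
  A <- edge_matrix(network, rep(1, nrow(network$edges)))  # adjacency
  rs <- Matrix::rowSums(M)
  zero <- rs == 0
  if (any(zero)) {
    # uniform fallback over neighbors for rows with no positive mass
    M[zero, ] <- A[zero, , drop = FALSE]
    rs <- Matrix::rowSums(M)
  }
  row_normalize(M, rs)
}

row_normalize <- function(M, rs = Matrix::rowSums(M)) {
  scale <- ifelse(rs > 0, 1 / rs, 0)
  out <- Matrix::Diagonal(x = scale) %*% M
  dimnames(out) <- dimnames(M)
  methods::as(out, "CsparseMatrix")
}

#' Combine annotation and co-expression edge weights
#'
#' The annotation matrix is row-normalized so both kernels are
#' row-stochastic, then mixed convexly:
#' \deqn{W = \beta \hat W_1 + (1 - \beta) W_2}
#'
#' @param W1 Annotation-based weights (\code{\link{compute_w1}}).
#' @param W2 Row-stochastic co-expression weights
#'   (\code{\link{compute_w2}}).
#' @param beta Mixing weight in \[0, 1\]; 1 uses annotations only.
#' @return Sparse matrix whose every row with outgoing edges sums to 1.
#' @export
combine_edge_weights <- function(W1, W2, beta = 0.5) {
  stopifnot(beta >= 0, beta <= 1, all(dim(W1) == dim(W2)))
  beta * row_normalize(W1) + (1 - beta) * W2
}

#' Uniform row-stochastic transition matrix of a PPI network
#'
#' Adjacency with each row divided by the node degree; the kernel of the
#' classic PageRank baseline.
#' @param network A \code{ppi_network}.
#' @return Sparse row-stochastic matrix.
#' @export
uniform_edge_weights <- function(network) {
  row_normalize(edge_matrix(network, rep(1, nrow(network$edges))))
}
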