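#' Personalized PageRank by power iteration
#'
#' Finds the fixed point of
#' \deqn{PR(v) = (1 - d)\, q(v) + d \sum_{u \to v} PR(u)\, w(u, v) / \sum_k w(u, k)}
#' over a row-stochastic transition matrix. Mass on dangling rows (no
#' outgoing weight) is redistributed through the teleport vector q, so the
#' score vector sums to 1 at every iteration. Iteration stops when the L1
#' change drops below \code{tol}.
#'
#' @param W Row-stochastic transition matrix (rows sum to 1, or to 0 for
#'   dangling rows), with node names as dimnames.
#' @param q Teleport distribution (named, non-negative, sums to 1) aligned
#'   with \code{W}'s rows.
#' @param d Damping factor in \[0, 1); probability of following an edge
#'   rather than teleporting. Default 0.85. With d = 0 the result is q.
#' @param tol L1 convergence tolerance, default 1e-10.
#' @param max_iter Iteration cap, default 1000; non-convergence is an
#'   error carrying the final residual.
#' @return Named numeric score vector summing to 1, with attributes
#'   \code{iterations} and \code{residual}.
#' @export
personalized_pagerank <- function(W, q, d = 0.85, tol = 1e-10,
                                  max_iter = 1000L) {
  stopifnot(d >= 0, d < 1, tol > 0, max_iter >= 1L)
  n <- nrow(W)
  stopifnot(ncol(W) == n, length(q) == n)
  if (!is.null(names(q)) && !is.null(rownames(W))) {
    stopifnot(identical(names(q), rownames(W)))
  }
  if (any(q < 0)) stop("q must be non-negative")
  if (abs(sum(q) - 1) > 1e-8) stop("q must sum to 1")
  q <- q / sum(q)
  rs <- Matrix::rowSums(W)
  if (any(rs > 0 & abs(rs - 1) > 1e-8)) {
    stop("W rows must sum to 1 (or 0 for dangling rows)")
  }
  dangling <- rs == 0
  Wt <- Matrix::t(W)
  pr <- q
  iter <- 0L
  res <- Inf
  while (iter < max_iter) {
    iter <- iter + 1L
    pr_new <- (1 - d) * q + d * as.numeric(Wt %*% pr) +
      d * sum(pr[dangling]) * q
    s <- sum(pr_new)
    if (abs(s - 1) > 1e-9) {
      stop("score mass not conserved at iteration ", iter, " (sum = ", s, ")")
    }
    pr_new <- pr_new / s
    res <- sum(abs(pr_new - pr))
    pr <- pr_new
    if (res < tol) break
  }
  if (res >= tol) {
    stop("PageRank did not converge in ", max_iter,
         " iterations (final L1 residual ", format(res), ")")
  }
  structure(stats::setNames(as.numeric(pr), rownames(W)),
            iterations = iter, residual = res)
}

#' Classic PageRank on the unweighted PPI graph
#'
#' Uniform teleport (1/N) and uniform out-edge weights (1/degree); the
#' topology-only baseline, equal by construction to
#' \code{personalized_pagerank} with uniform q and uniform W.
#'
#' @param network A \code{ppi_network}.
#' @inheritParams personalized_pagerank
#' @return Named numeric score vector summing to 1.
#' @export
classic_pagerank <- function(network, d = 0.85, tol = 1e-10,
                             max_iter = 1000L) {
  n <- length(network$nodes)
  q <- stats::setNames(rep(1 / n, n), network$nodes)
  personalized_pagerank(uniform_edge_weights(network), q,
                        d = d, tol = tol, max_iter = max_iter)
}

#' Order genes by score into a deterministic ranking
#'
#' Descending by score with ties broken by ascending gene identifier, so
#' rankings are bit-reproducible across runs and platforms. Seeds can be
#' filtered out before ranking when evaluating recovery of non-seed genes.
#'
#' @param scores Named numeric score vector.
#' @param seeds Seed genes, used only when \code{include_seeds = FALSE}.
#' @param include_seeds Keep seed genes in the ranking (default TRUE).
#' @return A \code{biorank_ranking} data frame with columns \code{rank},
#'   \code{gene}, \code{score} and provenance carried in attributes.
#' @export
rank_genes <- function(scores, seeds = character(0), include_seeds = TRUE) {
  stopifnot(!is.null(names(scores)), all(is.finite(scores)))
  genes <- names(scores)
  if (!include_seeds) {
    keep <- !(genes %in% seeds)
    genes <- genes[keep]
    scores <- scores[keep]
  }
  ord <- order(-scores, genes, method = "radix")
  structure(
    data.frame(rank = seq_along(ord), gene = genes[ord],
               score = as.numeric(scores[ord]), stringsAsFactors = FALSE),
    class = c("biorank_ranking", "data.frame"),
    include_seeds = include_seeds)
}

#' @export
print.biorank_ranking <- function(x, n = 10L, ...) {
  cat("Gene ranking over", nrow(x), "genes; top", min(n, nrow(x)), ":\n")
  print.data.frame(utils::head(as.data.frame(x), n), row.names = FALSE)
  invisible(x)
}
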