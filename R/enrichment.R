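#' One-sided Fisher exact test for over-representation
#'
#' Upper tail of the hypergeometric distribution: the probability of
#' observing \code{k} or more seed genes in a term, given \code{K} seeds,
#' a term of size \code{n} and a universe of \code{N} genes.
#'
#' @param k Observed overlap, \code{|term genes ∩ seeds|}.
#' @param K Number of seed genes in the universe.
#' @param n Number of the term's genes in the universe.
#' @param N Universe size.
#' @return P(X >= k) for X ~ hypergeometric(N, n, K), in (0, 1].
#' @export
fisher_one_sided <- function(k, K, n, N) {
  stopifnot(length(k) == 1L, length(K) == 1L, length(n) == 1L, length(N) == 1L)
  if (k < 0 || K < 0 || n < 0 || N < 0) stop("counts must be non-negative")
  if (k > n || k > K) stop("inconsistent counts: k exceeds n or K")
  if (K > N || n > N) stop("inconsistent counts: K or n exceeds N")
  if (k == 0) return(1)
  # P(X >= k) = upper tail at k-1; white balls = term genes, draws = seeds
  stats::phyper(k - 1, n, N - n, K, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, order-preserving with the input.
#' @param pvalues Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  stats::p.adjust(pvalues, method = "BH")
}

#' Select annotation terms significantly enriched in the seed set
#'
#' Every term of every source is tested for over-representation among the
#' seed genes against the network universe with a one-sided Fisher exact
#' test; p-values are BH-adjusted within each source's term family (or
#' pooled across sources) and terms with adjusted value strictly below
#' \code{level} are retained. The retained per-source sets Fj and their
#' union F drive the annotation node score and the shared-annotation edge
#' weights.
#'
#' @param catalog An \code{annotation_catalog}.
#' @param seeds Character vector of seed genes.
#' @param universe Character vector of universe genes (the PPI node set).
#' @param level Significance level applied to the adjusted value
#'   (default 1e-5, strict inequality).
#' @param adjust_scope \code{"per_source"} (default) applies BH within each
#'   source's term family; \code{"pooled"} adjusts all terms together.
#' @return A \code{significant_terms} object: the per-term test table
#'   (source, term, k, K, n, N, p, adjusted, retained), the per-source
#'   retained term-id sets \code{F_by_source}, and their union \code{F}.
#' @export
select_significant_terms <- function(catalog, seeds, universe, level = 1e-5,
                                     adjust_scope = c("per_source", "pooled")) {
  adjust_scope <- match.arg(adjust_scope)
  stopifnot(level >= 0)
  universe <- unique(universe)
  seeds <- intersect(unique(seeds), universe)
  if (length(seeds) == 0L) stop("no seed genes present in the universe")
  K <- length(seeds)
  N <- length(universe)
  rows <- list()
  for (src in catalog$sources) {
    tm <- catalog$terms[[src]]
    if (length(tm) == 0L) next
    k <- n <- integer(length(tm))
    for (i in seq_along(tm)) {
      genes <- intersect(tm[[i]], universe)
      n[i] <- length(genes)
      k[i] <- length(intersect(genes, seeds))
    }
    p <- vapply(seq_along(tm),
                function(i) fisher_one_sided(k[i], K, n[i], N), numeric(1))
    rows[[src]] <- data.frame(source = src, term = names(tm),
                              k = k, K = K, n = n, N = N, p = p,
                              stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (adjust_scope == "per_source") {
    tab$adjusted <- stats::ave(tab$p, tab$source, FUN = bh_adjust)
  } else {
    tab$adjusted <- bh_adjust(tab$p)
  }
  tab$retained <- tab$adjusted < level
  F_by_source <- lapply(stats::setNames(catalog$sources, catalog$sources),
                        function(src) {
    sel <- tab$source == src & tab$retained
    term_id(src, tab$term[sel])
  })
  structure(list(table = tab, F_by_source = F_by_source,
                 F = unname(unlist(F_by_source)), level = level,
                 adjust_scope = adjust_scope),
            class = "significant_terms")
}

#' @export
print.significant_terms <- function(x, ...) {
  cat("Significant annotation terms: ", length(x$F), " retained of ",
      nrow(x$table), " tested (adjusted < ", format(x$level), ", ",
      x$adjust_scope, ")\n", sep = "")
  invisible(x)
}

#' Annotation-based node score
#'
#' Seed genes receive the large constant \code{ell} so that known disease
#' genes carry the highest possible teleport priority; every other gene
#' scores the overlap of its annotation set with each source's retained
#' terms, normalized by that source's retained-set size:
#' \deqn{\theta_i = \sum_j |A(i) \cap F_j| / |F_j|}
#' Sources with an empty retained set contribute 0.
#'
#' @param catalog An \code{annotation_catalog}.
#' @param sig A \code{significant_terms} object.
#' @param seeds Character vector of seed genes.
#' @param universe Character vector of genes to score (the PPI node set).
#' @param ell Seed constant; must strictly exceed the number of sources,
#'   the maximum score a non-seed can attain. Default 1000.
#' @return Named numeric vector of scores over \code{universe}, with
#'   attributes \code{ell} and \code{seeds}.
#' @export
compute_theta <- function(catalog, sig, seeds, universe, ell = 1000) {
  l <- length(catalog$sources)
  if (ell <= l) {
    stop("ell (", ell, ") must exceed the number of sources (", l,
         ") to guarantee seed priority")
  }
  theta <- stats::setNames(numeric(length(universe)), universe)
  for (src in catalog$sources) {
    Fj <- sig$F_by_source[[src]]
    if (length(Fj) == 0L) next
    counts <- stats::setNames(numeric(length(universe)), universe)
    tm <- catalog$terms[[src]]
    for (id in Fj) {
      tname <- sub("^[^\t]*\t", "", id)
      members <- intersect(tm[[tname]], universe)
      counts[members] <- counts[members] + 1
    }
    theta <- theta + counts / length(Fj)
  }
  theta[intersect(seeds, universe)] <- ell
  attr(theta, "ell") <- ell
  attr(theta, "seeds") <- intersect(seeds, universe)
  theta
}
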