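# Independent oracles and small fixture builders shared across tests.

# Hypergeometric upper tail P(X >= k) by explicit enumeration on the
# log-choose scale (independent of stats::phyper).
hyper_tail_oracle <- function(k, K, n, N) {
  if (k == 0) return(1)
  xs <- k:min(K, n)
  terms <- lchoose(n, xs) + lchoose(N - n, K - xs) - lchoose(N, K)
  sum(exp(terms))
}

# Textbook BH step-up: adjusted_(i) = min_{j >= i} p_(j) * m / j.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, p[ord[i]] * m / i)
    adj[ord[i]] <- min(running, 1)
  }
  adj
}

# Seed-proximity score by breadth-first distances (independent of the
# igraph neighborhood queries used in compute_phi).
phi_bfs_oracle <- function(network, seeds, de) {
  d <- igraph::distances(network$graph)
  phi <- stats::setNames(numeric(length(network$nodes)), network$nodes)
  for (g in de) {
    n1 <- network$nodes[d[g, ] == 1]
    n2 <- network$nodes[d[g, ] == 2]
    t1 <- if (length(n1)) mean(n1 %in% seeds) else 0
    t2 <- if (length(n2)) mean(n2 %in% seeds) else 0
    phi[g] <- t1 + t2
  }
  phi
}

# Exact stationary scores by direct linear solve, dangling mass routed
# through q: x = (I - d(W' + q 1_dangling'))^-1 (1-d) q.
pagerank_solve_oracle <- function(W, q, d) {
  n <- nrow(W)
  M <- t(as.matrix(W))
  dangling <- Matrix::rowSums(W) == 0
  if (any(dangling)) M <- M + as.numeric(q) %*% t(as.numeric(dangling))
  x <- solve(diag(n) - d * M, (1 - d) * as.numeric(q))
  stats::setNames(as.numeric(x), rownames(W))
}

# --- fixture builders -------------------------------------------------

write_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# PPI network from an edge data frame without touching disk.
make_network <- function(from, to, confidence = 0.9) {
  edges <- data.frame(from = pmin(from, to), to = pmax(from, to),
                      confidence = rep_len(confidence, length(from)),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  biorankr:::new_ppi_network(edges)
}

# Erdos-Renyi-ish connected-enough random network on n nodes.
random_network <- function(n, p = 0.25) {
  pairs <- utils::combn(sprintf("n%02d", seq_len(n)), 2L)
  keep <- stats::runif(ncol(pairs)) < p
  # guarantee no isolated node so every node appears as an endpoint
  nodes <- sprintf("n%02d", seq_len(n))
  from <- pairs[1L, keep]; to <- pairs[2L, keep]
  for (g in setdiff(nodes, c(from, to))) {
    partner <- sample(setdiff(nodes, g), 1L)
    from <- c(from, min(g, partner)); to <- c(to, max(g, partner))
  }
  make_network(from, to)
}

# Annotation catalog from a nested list source -> term -> genes, routed
# through the GMT reader so the file surface stays exercised.
make_catalog <- function(sources) {
  paths <- vapply(names(sources), function(src) {
    write_tmp(vapply(names(sources[[src]]), function(t)
      paste(c(t, "desc", sources[[src]][[t]]), collapse = "\t"),
      character(1)), ext = ".gmt")
  }, character(1))
  read_gmt(unname(paths), sources = names(sources))
}

# Significance container built directly (bypasses the Fisher filter) for
# unit tests of downstream scores.
make_sig <- function(F_by_source) {
  structure(list(F_by_source = F_by_source,
                 F = unname(unlist(F_by_source)),
                 level = NA_real_, adjust_scope = "per_source"),
            class = "significant_terms")
}

tid <- function(source, term) paste(source, term, sep = "\t")

# Random row-stochastic weights on a network's directed edge support.
random_edge_weights <- function(network) {
  raw <- biorankr:::edge_matrix(network,
                                stats::runif(nrow(network$edges), 0.1, 1))
  biorankr:::row_normalize(raw)
}

random_simplex <- function(nodes) {
  x <- stats::runif(length(nodes), 0.01, 1)
  stats::setNames(x / sum(x), nodes)
}

# Ranking object from scores given as a named vector.
make_ranking <- function(...) {
  rank_genes(c(...))
}
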