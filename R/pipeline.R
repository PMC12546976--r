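#' Pipeline parameters
#'
#' All tunable knobs of the evidence-propagation pipeline with their
#' defaults: the teleport mix \code{alpha}, the edge mix \code{beta}, the
#' annotation edge floor \code{c}, the seed constant \code{ell}, the
#' z-score extremeness threshold \code{tau}, the enrichment significance
#' level, the damping factor and the power-iteration controls.
#'
#' @param alpha Teleport mix between annotation (\code{theta}) and
#'   topology (\code{phi}) scores, in \[0, 1\].
#' @param beta Edge mix between annotation (\code{W1}) and co-expression
#'   (\code{W2}) kernels, in \[0, 1\].
#' @param c Positive floor for annotation edge weights.
#' @param ell Seed constant for theta (must exceed the number of
#'   annotation sources).
#' @param tau Z-score threshold for the extremeness flags.
#' @param level Significance level for the BH-adjusted enrichment values.
#' @param damping Damping factor d in \[0, 1).
#' @param tol,max_iter Power-iteration convergence controls.
#' @param zscore_columns Samples used for per-gene standardization
#'   (\code{"all"} or \code{"tumor"}).
#' @param de_columns Samples whose flags feed the DE rule
#'   (\code{"tumor"} or \code{"all"}).
#' @param coexpr_columns Samples used for edge correlations
#'   (\code{"tumor"} or \code{"all"}).
#' @param negative_corr Treatment of negative correlations
#'   (\code{"clip"} or \code{"abs"}).
#' @param adjust_scope BH family per \code{"per_source"} or
#'   \code{"pooled"}.
#' @param include_seeds Keep seeds in the final ranking.
#' @param topk Cutoffs reported by the evaluation step.
#' @return Named list of parameters.
#' @export
biorank_params <- function(alpha = 0.5, beta = 0.5, c = 0.1, ell = 1000,
                           tau = 2.5, level = 1e-5, damping = 0.85,
                           tol = 1e-10, max_iter = 1000L,
                           zscore_columns = "all", de_columns = "tumor",
                           coexpr_columns = "tumor",
                           negative_corr = "clip",
                           adjust_scope = "per_source",
                           include_seeds = TRUE, topk = c(10L, 15L)) {
  list(alpha = alpha, beta = beta, c = c, ell = ell, tau = tau,
       level = level, damping = damping, tol = tol,
       max_iter = as.integer(max_iter), zscore_columns = zscore_columns,
       de_columns = de_columns, coexpr_columns = coexpr_columns,
       negative_corr = negative_corr, adjust_scope = adjust_scope,
       include_seeds = include_seeds, topk = as.integer(topk))
}

#' Run the full evidence-propagation pipeline on loaded objects
#'
#' Composes the stages: seed enrichment of annotation terms, annotation
#' node score theta, z-score/flag/DE calling, seed-proximal topology score
#' phi, the teleport vector q, per-edge correlations, the two edge kernels
#' and their convex mix W, the personalized PageRank propagation, and the
#' deterministic ranking — plus an evaluation report when a truth list is
#' supplied.
#'
#' @param network A \code{ppi_network}.
#' @param catalog An \code{annotation_catalog}.
#' @param seeds Character vector of seed genes (restricted to the network;
#'   an error if none survive).
#' @param expr An \code{expression_matrix}.
#' @param params See \code{\link{biorank_params}}.
#' @param truth Optional character vector of ground-truth genes.
#' @return List: \code{ranking}, \code{scores}, \code{q}, \code{theta},
#'   \code{phi}, \code{de}, \code{sig}, \code{W}, \code{evaluation} (NULL
#'   without truth), \code{params}.
#' @export
biorank_pipeline <- function(network, catalog, seeds, expr,
                             params = biorank_params(), truth = NULL) {
  universe <- network$nodes
  seeds <- restrict_to_network(unique(seeds), network, "seed genes",
                               error_if_empty = TRUE)
  sig <- select_significant_terms(catalog, seeds, universe,
                                  level = params$level,
                                  adjust_scope = params$adjust_scope)
  theta <- compute_theta(catalog, sig, seeds, universe, ell = params$ell)

  z <- zscore_expression(expr, columns = params$zscore_columns)
  flags <- binarize(z, tau = params$tau)
  de_cols <- if (params$de_columns == "tumor") {
    colnames(flags) %in% names(expr$conditions)[expr$conditions == "tumor"]
  } else rep(TRUE, ncol(flags))
  de <- call_de_genes(flags[, de_cols, drop = FALSE])
  de_net <- restrict_to_network(de, network, "DE genes")

  phi <- compute_phi(network, seeds, de_net)
  q <- build_personalization(theta, phi, alpha = params$alpha)

  P <- edge_correlations(expr, network, columns = params$coexpr_columns)
  W1 <- compute_w1(network, catalog, sig$F, c = params$c)
  W2 <- compute_w2(P, network, negative_corr = params$negative_corr)
  W <- combine_edge_weights(W1, W2, beta = params$beta)

  scores <- personalized_pagerank(W, q, d = params$damping,
                                  tol = params$tol,
                                  max_iter = params$max_iter)
  ranking <- rank_genes(scores, seeds = seeds,
                        include_seeds = params$include_seeds)
  evaluation <- NULL
  if (!is.null(truth)) {
    evaluation <- do.call(rbind, lapply(params$topk, function(k)
      evaluate_ranking(ranking, truth, k = k)))
  }
  list(ranking = ranking, scores = scores, q = q, theta = theta, phi = phi,
       de = de_net, sig = sig, W = W, evaluation = evaluation,
       params = params)
}

#' Assemble a run configuration
#'
#' Merges (in increasing precedence) the package defaults, a YAML config
#' file and explicit overrides. The YAML keys mirror the function
#' arguments: input paths (\code{ppi}, \code{gmt}, \code{expr},
#'   \code{conditions}, \code{seeds}, \code{truth}), \code{min_confidence},
#'   \code{out}, and every \code{\link{biorank_params}} key.
#'
#' @param config_file Optional YAML file path.
#' @param ... Overrides (flags win over the file).
#' @return Named configuration list.
#' @export
biorank_config <- function(config_file = NULL, ...) {
  cfg <- c(list(ppi = NULL, gmt = NULL, expr = NULL, conditions = NULL,
                seeds = NULL, truth = NULL, out = NULL,
                min_confidence = 0.7),
           biorank_params())
  if (!is.null(config_file)) {
    from_file <- yaml::read_yaml(config_file)
    cfg[names(from_file)] <- from_file
  }
  overrides <- list(...)
  overrides <- overrides[!vapply(overrides, is.null, logical(1))]
  cfg[names(overrides)] <- overrides
  cfg
}

config_params <- function(cfg) {
  do.call(biorank_params, cfg[intersect(names(cfg),
                                        names(formals(biorank_params)))])
}

load_inputs <- function(cfg, need_expr = TRUE) {
  for (key in c("ppi", if (need_expr) c("gmt", "expr", "conditions", "seeds"))) {
    if (is.null(cfg[[key]])) stop("missing required input: --", key)
  }
  network <- read_ppi(cfg$ppi, min_confidence = cfg$min_confidence)
  out <- list(network = network)
  if (need_expr) {
    out$catalog <- read_gmt(cfg$gmt)
    out$expr <- read_expression(cfg$expr, cfg$conditions)
    out$seeds <- read_gene_list(cfg$seeds)
  }
  if (!is.null(cfg$truth)) out$truth <- read_gene_list(cfg$truth)
  out
}

write_run_outputs <- function(dir, cfg, ranking, evaluation = NULL) {
  if (is.null(dir)) return(invisible(NULL))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_ranking(ranking, file.path(dir, "ranking.tsv"))
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  if (!is.null(evaluation)) {
    utils::write.table(evaluation, file.path(dir, "evaluation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Run the pipeline end-to-end from files
#'
#' Reads the five inputs named in the configuration, executes
#' \code{\link{biorank_pipeline}} and, when an output directory is
#' configured, writes \code{ranking.tsv}, a verbatim \code{config.yaml}
#' snapshot and (with a truth list) \code{evaluation.tsv}.
#'
#' @param cfg Configuration list from \code{\link{biorank_config}}.
#' @return The \code{\link{biorank_pipeline}} result, invisibly.
#' @export
run_biorank <- function(cfg) {
  inputs <- load_inputs(cfg, need_expr = TRUE)
  fit <- biorank_pipeline(inputs$network, inputs$catalog, inputs$seeds,
                          inputs$expr, params = config_params(cfg),
                          truth = inputs$truth)
  write_run_outputs(cfg$out, cfg, fit$ranking, fit$evaluation)
  invisible(fit)
}

#' Run the classic PageRank baseline from files
#'
#' Needs only the PPI input; produces a ranking in the same format as the
#' full pipeline (and an evaluation report when a truth list is given).
#'
#' @inheritParams run_biorank
#' @return List with \code{ranking}, \code{scores} and \code{evaluation},
#'   invisibly.
#' @export
run_baseline <- function(cfg) {
  inputs <- load_inputs(cfg, need_expr = FALSE)
  params <- config_params(cfg)
  scores <- classic_pagerank(inputs$network, d = params$damping,
                             tol = params$tol, max_iter = params$max_iter)
  ranking <- rank_genes(scores)
  evaluation <- NULL
  if (!is.null(inputs$truth)) {
    evaluation <- do.call(rbind, lapply(params$topk, function(k)
      evaluate_ranking(ranking, inputs$truth, k = k)))
  }
  write_run_outputs(cfg$out, cfg, ranking, evaluation)
  invisible(list(ranking = ranking, scores = scores,
                 evaluation = evaluation))
}
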