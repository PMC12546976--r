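#' Top-K genes of a ranking
#' @param ranking A \code{biorank_ranking}.
#' @param k Cutoff rank.
#' @return Character vector of the first k genes (fewer if the ranking is
#'   shorter).
#' @export
top_k <- function(ranking, k) {
  stopifnot(inherits(ranking, "biorank_ranking"), k >= 1)
  ranking$gene[seq_len(min(k, nrow(ranking)))]
}

#' Recall at K
#'
#' Fraction of all ground-truth genes recovered within the top K ranks:
#' \code{|top-K ∩ R| / |R|}. The truth list is used as given (its full
#' size is the denominator); set \code{restrict = TRUE} to first intersect
#' it with the ranked universe.
#'
#' @param ranking A \code{biorank_ranking}.
#' @param truth Character vector of relevant genes (R).
#' @param k Cutoff rank, >= 1.
#' @param restrict Restrict the truth set to the ranked genes first
#'   (default FALSE; the restriction is reported when it drops genes).
#' @return Recall in \[0, 1\].
#' @export
recall_at_k <- function(ranking, truth, k, restrict = FALSE) {
  truth <- unique(truth)
  if (restrict) {
    inside <- truth %in% ranking$gene
    if (any(!inside)) {
      message(sum(!inside), " truth genes outside the ranked universe dropped")
    }
    truth <- truth[inside]
  }
  if (length(truth) == 0L) stop("empty truth set")
  length(intersect(top_k(ranking, k), truth)) / length(truth)
}

#' Normalized discounted cumulative gain at K
#'
#' Binary relevance (gene in the truth set) with the standard
#' \code{1/log2(p + 1)} position discount, normalized by the ideal ordering
#' that places relevant genes in the first \code{min(k, |R|)} positions.
#'
#' @inheritParams recall_at_k
#' @return nDCG in \[0, 1\].
#' @export
ndcg_at_k <- function(ranking, truth, k, restrict = FALSE) {
  truth <- unique(truth)
  if (restrict) truth <- intersect(truth, ranking$gene)
  if (length(truth) == 0L) stop("empty truth set")
  top <- top_k(ranking, k)
  rel <- as.numeric(top %in% truth)
  dcg <- sum(rel / log2(seq_along(rel) + 1))
  ideal <- min(k, length(truth))
  idcg <- sum(1 / log2(seq_len(ideal) + 1))
  dcg / idcg
}

#' Top-K validation rate
#'
#' Percentage of the top K predictions found in the truth set,
#' \code{100 * |top-K ∩ R| / k}, truncated (not rounded) to one decimal
#' place: 14/15 prints as 93.3, 13/15 as 86.6.
#'
#' @inheritParams recall_at_k
#' @return Percentage in \[0, 100\] with one decimal.
#' @export
validation_rate <- function(ranking, truth, k) {
  hits <- length(intersect(top_k(ranking, k), unique(truth)))
  trunc(100 * hits / k * 10) / 10
}

#' Full evaluation report for a ranking
#'
#' @inheritParams recall_at_k
#' @return A one-row data frame: k, match count, recall, ndcg,
#'   validation rate and the truth-set size used as denominator.
#' @export
evaluate_ranking <- function(ranking, truth, k = 15, restrict = FALSE) {
  truth <- unique(truth)
  data.frame(
    k = k,
    match = length(intersect(top_k(ranking, k), truth)),
    recall = recall_at_k(ranking, truth, k, restrict = restrict),
    ndcg = ndcg_at_k(ranking, truth, k, restrict = restrict),
    validation_rate = validation_rate(ranking, truth, k),
    n_truth = length(truth))
}

#' Shared and unique genes among top-K sets of several rankings
#'
#' For each method the number of top-K genes found by no other method, and
#' for every pair (and triple, when three or more rankings are given) the
#' size of the top-K intersection.
#'
#' @param rankings Named list of \code{biorank_ranking} objects over the
#'   same gene universe.
#' @param k Cutoff rank.
#' @return List with elements \code{unique} (named integer vector),
#'   \code{pairs} (data frame a, b, shared) and, for >= 3 rankings,
#'   \code{triples}.
#' @export
overlap_report <- function(rankings, k = 100) {
  stopifnot(is.list(rankings), length(rankings) >= 2L,
            !is.null(names(rankings)))
  universes <- lapply(rankings, function(r) sort(r$gene))
  for (i in seq_along(universes)[-1L]) {
    if (!identical(universes[[i]], universes[[1L]])) {
      stop("rankings '", names(rankings)[1L], "' and '", names(rankings)[i],
           "' cover different gene universes")
    }
  }
  tops <- lapply(rankings, top_k, k = k)
  nm <- names(rankings)
  uniq <- vapply(seq_along(tops), function(i) {
    others <- unique(unlist(tops[-i]))
    sum(!(tops[[i]] %in% others))
  }, integer(1))
  names(uniq) <- nm
  pairs <- utils::combn(seq_along(tops), 2L)
  pair_df <- data.frame(
    a = nm[pairs[1L, ]], b = nm[pairs[2L, ]],
    shared = apply(pairs, 2L, function(ij)
      length(intersect(tops[[ij[1L]]], tops[[ij[2L]]]))),
    stringsAsFactors = FALSE)
  out <- list(unique = uniq, pairs = pair_df)
  if (length(tops) >= 3L) {
    triples <- utils::combn(seq_along(tops), 3L)
    out$triples <- data.frame(
      a = nm[triples[1L, ]], b = nm[triples[2L, ]], c = nm[triples[3L, ]],
      shared = apply(triples, 2L, function(ijk)
        length(Reduce(intersect, tops[ijk]))),
      stringsAsFactors = FALSE)
  }
  out
}
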