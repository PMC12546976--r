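#' Read a protein-protein interaction network from a HIPPIE-style edge list
#'
#' Parses a tab-separated edge list (gene A, gene B, confidence, further
#' columns ignored) and keeps only interactions whose confidence score
#' strictly exceeds \code{min_confidence}. Self-loops are dropped and
#' duplicate unordered pairs are collapsed keeping the maximum confidence.
#' A first line whose third field is not numeric is treated as a header and
#' skipped.
#'
#' @param path Path to the tab-separated edge list.
#' @param min_confidence Confidence threshold in \[0, 1\]; edges with
#'   confidence \code{> min_confidence} are retained (strict inequality).
#' @return A \code{ppi_network} object: the node set (sorted gene
#'   identifiers), the canonical undirected edge table (\code{from},
#'   \code{to}, \code{confidence}) and an \pkg{igraph} graph used for
#'   neighborhood queries.
#' @export
read_ppi <- function(path, min_confidence = 0.7) {
  stopifnot(is.numeric(min_confidence), length(min_confidence) == 1L,
            min_confidence >= 0, min_confidence <= 1)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("PPI file '", path, "' is empty")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  first <- fields[[1L]]
  start <- 1L
  if (length(first) >= 3L && is.na(suppressWarnings(as.numeric(first[3L])))) {
    start <- 2L  # header row
  }
  if (start > length(fields)) stop("PPI file '", path, "' has no data rows")
  a <- b <- character(0); conf <- numeric(0)
  for (ln in seq(start, length(fields))) {
    f <- fields[[ln]]
    if (length(f) < 3L) {
      stop("PPI file '", path, "', line ", ln, ": expected at least 3 tab-separated fields")
    }
    cv <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(cv)) {
      stop("PPI file '", path, "', line ", ln, ": confidence '", f[3L], "' is not numeric")
    }
    a <- c(a, trimws(f[1L])); b <- c(b, trimws(f[2L])); conf <- c(conf, cv)
  }
  keep <- conf > min_confidence & a != b & nzchar(a) & nzchar(b)
  a <- a[keep]; b <- b[keep]; conf <- conf[keep]
  if (length(a) == 0L) {
    stop("no edges retained from '", path, "' at min_confidence = ", min_confidence)
  }
  # canonical unordered pair, collapse duplicates keeping max confidence
  from <- pmin(a, b); to <- pmax(a, b)
  key <- paste(from, to, sep = "\t")
  best <- tapply(conf, key, max)
  keys <- strsplit(names(best), "\t", fixed = TRUE)
  edges <- data.frame(
    from = vapply(keys, `[`, character(1), 1L),
    to = vapply(keys, `[`, character(1), 2L),
    confidence = as.numeric(best),
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  new_ppi_network(edges)
}

new_ppi_network <- function(edges) {
  nodes <- sort(unique(c(edges$from, edges$to)))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  structure(list(nodes = nodes, edges = edges, graph = g),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("PPI network:", length(x$nodes), "genes,", nrow(x$edges), "interactions\n")
  invisible(x)
}

#' First-order neighbors of a gene in a PPI network
#' @param network A \code{ppi_network}.
#' @param gene A gene identifier present in the network.
#' @return Character vector of neighboring gene identifiers.
#' @export
ppi_neighbors <- function(network, gene) {
  names(igraph::neighbors(network$graph, gene))
}

#' Genes at shortest-path distance exactly two
#' @inheritParams ppi_neighbors
#' @return Character vector of second-order neighbors (distance exactly 2;
#'   disjoint from the first-order neighborhood and from the gene itself).
#' @export
ppi_neighbors2 <- function(network, gene) {
  ring <- igraph::ego(network$graph, order = 2, nodes = gene, mindist = 2)[[1L]]
  names(ring)
}

#' Read gene annotation sets from GMT files
#'
#' Each file is one annotation source (GO/KEGG/Reactome-style). Lines are
#' tab-separated: term, description, then member genes. Genes are
#' deduplicated within a term; terms with no genes are dropped with a
#' warning.
#'
#' @param paths Character vector of GMT file paths, one source per file.
#' @param sources Optional source labels (default: file base names, made
#'   unique).
#' @return An \code{annotation_catalog}: source labels in argument order,
#'   per-source term-to-gene-set maps, and the inverse per-gene annotation
#'   map used for the annotation scores.
#' @export
read_gmt <- function(paths, sources = NULL) {
  stopifnot(length(paths) >= 1L)
  if (is.null(sources)) {
    sources <- make.unique(sub("\\.gmt$", "", basename(paths)))
  }
  stopifnot(length(sources) == length(paths), !anyDuplicated(sources))
  if (any(grepl("\t", sources, fixed = TRUE))) stop("source labels must not contain tabs")
  terms <- vector("list", length(paths))
  names(terms) <- sources
  for (i in seq_along(paths)) {
    lines <- readLines(paths[i], warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    tmap <- list()
    for (ln in seq_along(lines)) {
      f <- trimws(strsplit(lines[ln], "\t", fixed = TRUE)[[1L]])
      if (length(f) < 2L) {
        stop("GMT file '", paths[i], "', line ", ln,
             ": expected at least term and description fields")
      }
      genes <- unique(f[-(1:2)])
      genes <- genes[nzchar(genes)]
      if (length(genes) == 0L) {
        warning("GMT file '", paths[i], "', line ", ln, ": term '", f[1L],
                "' has no genes; dropped")
        next
      }
      if (!is.null(tmap[[f[1L]]])) {
        tmap[[f[1L]]] <- unique(c(tmap[[f[1L]]], genes))
      } else {
        tmap[[f[1L]]] <- genes
      }
    }
    terms[[i]] <- tmap
  }
  if (sum(lengths(terms)) == 0L) stop("no annotation terms found in any GMT file")
  new_annotation_catalog(sources, terms)
}

new_annotation_catalog <- function(sources, terms) {
  # inverse map: gene -> character vector of term ids "source<TAB>term"
  gene_terms <- new.env(parent = emptyenv())
  pairs_g <- character(0); pairs_t <- character(0)
  for (src in sources) {
    tm <- terms[[src]]
    for (tname in names(tm)) {
      id <- term_id(src, tname)
      pairs_g <- c(pairs_g, tm[[tname]])
      pairs_t <- c(pairs_t, rep(id, length(tm[[tname]])))
    }
  }
  inv <- split(pairs_t, pairs_g)
  structure(list(sources = sources, terms = terms, gene_terms = inv),
            class = "annotation_catalog")
}

#' @export
print.annotation_catalog <- function(x, ...) {
  cat("Annotation catalog:", length(x$sources), "source(s);",
      paste(sprintf("%s (%d terms)", x$sources, lengths(x$terms)), collapse = ", "),
      "\n")
  invisible(x)
}

term_id <- function(source, term) {
  if (length(term) == 0L) return(character(0))  # paste would recycle to ""
  paste(source, term, sep = "\t")
}

#' Per-gene annotation set A(i)
#'
#' All (source, term) pairs containing the gene, encoded as term ids; empty
#' for unannotated genes.
#' @param catalog An \code{annotation_catalog}.
#' @param gene Gene identifier.
#' @return Character vector of term ids.
#' @export
gene_annotations <- function(catalog, gene) {
  a <- catalog$gene_terms[[gene]]
  if (is.null(a)) character(0) else a
}

#' Read a gene expression matrix with condition labels
#'
#' TSV with a header row of sample identifiers and gene identifiers in the
#' first column. Every sample must be labelled \code{"tumor"} or
#' \code{"control"} in \code{condition_map}; missing cells and duplicated
#' gene rows are errors (no silent aggregation).
#'
#' @param path Path to the TSV file.
#' @param condition_map Named character vector mapping sample identifiers to
#'   \code{"tumor"}/\code{"control"}, or a path to a two-column TSV
#'   (sample, condition).
#' @return An \code{expression_matrix}: numeric genes-by-samples matrix plus
#'   the per-sample condition labels.
#' @export
read_expression <- function(path, condition_map) {
  if (is.character(condition_map) && is.null(names(condition_map)) &&
      length(condition_map) == 1L && file.exists(condition_map)) {
    condition_map <- read_condition_map(condition_map)
  }
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("expression file '", path, "' needs >= 2 sample columns")
  genes <- trimws(as.character(tab[[1L]]))
  if (anyDuplicated(genes)) {
    stop("duplicated gene rows in '", path, "': ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  values <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- genes
  if (anyNA(values)) stop("missing values in expression matrix '", path, "'")
  samples <- colnames(values)
  missing <- setdiff(samples, names(condition_map))
  if (length(missing) > 0L) {
    stop("samples without condition label: ", paste(missing, collapse = ", "))
  }
  new_expression_matrix(values, condition_map[samples])
}

new_expression_matrix <- function(values, conditions) {
  stopifnot(is.matrix(values), nrow(values) >= 2L, ncol(values) >= 2L)
  conditions <- as.character(conditions)
  names(conditions) <- colnames(values)
  bad <- setdiff(unique(conditions), c("tumor", "control"))
  if (length(bad) > 0L) {
    stop("unknown condition label(s): ", paste(bad, collapse = ", "),
         " (expected 'tumor' or 'control')")
  }
  structure(list(values = values, conditions = conditions),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("Expression matrix:", nrow(x$values), "genes x", ncol(x$values), "samples (",
      sum(x$conditions == "tumor"), "tumor,", sum(x$conditions == "control"),
      "control )\n")
  invisible(x)
}

#' Read a sample-to-condition map from a two-column TSV
#' @param path Path to a headerless two-column TSV (sample, condition).
#' @return Named character vector of condition labels.
#' @export
read_condition_map <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("condition map '", path, "' needs two columns")
  stats::setNames(trimws(tab[[2L]]), trimws(tab[[1L]]))
}

#' Read a plain-text gene list
#'
#' One identifier per line; blank lines and lines starting with '#' are
#' ignored; identifiers are whitespace-trimmed.
#' @param path File path.
#' @return Character vector of unique gene identifiers.
#' @export
read_gene_list <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  genes <- unique(lines)
  if (length(genes) == 0L) stop("gene list '", path, "' is empty")
  genes
}

#' Write a gene ranking to TSV
#'
#' Columns rank, gene, score; scores printed at 15 significant digits so a
#' read-back reproduces the ordering exactly.
#' @param ranking A \code{biorank_ranking} (see \code{\link{rank_genes}}).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  stopifnot(inherits(ranking, "biorank_ranking"))
  out <- data.frame(rank = ranking$rank, gene = ranking$gene,
                    score = formatC(ranking$score, digits = 15, format = "g"))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ranking written by \code{write_ranking}
#' @param path Path to a ranking TSV (rank, gene, score).
#' @return A \code{biorank_ranking} data frame.
#' @export
read_ranking <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("rank", "gene", "score") %in% names(tab)))
  structure(
    data.frame(rank = as.integer(tab$rank), gene = as.character(tab$gene),
               score = as.numeric(tab$score), stringsAsFactors = FALSE),
    class = c("biorank_ranking", "data.frame"))
}

#' Restrict genes to the network's node universe
#'
#' Downstream stages operate only on genes present in the PPI network; this
#' performs the restriction once and reports the number of dropped
#' identifiers.
#' @param genes Character vector of gene identifiers.
#' @param network A \code{ppi_network}.
#' @param what Label used in the log message.
#' @param error_if_empty Error (rather than return empty) when nothing
#'   survives.
#' @return The genes present in the network, original order preserved.
#' @export
restrict_to_network <- function(genes, network, what = "genes",
                                error_if_empty = FALSE) {
  keep <- genes %in% network$nodes
  if (any(!keep)) {
    message(sum(!keep), " ", what, " not in the PPI network dropped (",
            sum(keep), " retained)")
  }
  out <- genes[keep]
  if (error_if_empty && length(out) == 0L) {
    stop("no ", what, " remain after restriction to the PPI network")
  }
  out
}
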