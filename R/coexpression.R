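#' @importFrom stats cor sd
NULL

#' Log-transform an atlas and flag unrankable genes
#'
#' Prepares a TPM atlas for correlation: values become
#' `log2(TPM + log_offset)`. Genes that cannot be ranked — zero variance
#' across samples (including all-zero genes), or below an optional
#' minimum-expression filter — are flagged and carried through as excluded
#' rather than being given arbitrary correlations.
#'
#' @param atlas an [expression_atlas()].
#' @param log_offset positive pseudo-count added before log2 (default 1).
#' @param min_expression optional filter: genes whose maximum TPM across all
#'   samples is below this value are flagged unrankable. `NULL` (default)
#'   disables the filter.
#' @return list of class `atlas_transform`: `mat` (log2 matrix, all genes),
#'   `unrankable` (character), `log_offset`, `min_expression`.
#' @export
preprocess_atlas <- function(atlas, log_offset = 1, min_expression = NULL) {
  if (!inherits(atlas, "expression_atlas"))
    stop("`atlas` must be an expression_atlas")
  if (!is.numeric(log_offset) || length(log_offset) != 1 || log_offset <= 0)
    stop("`log_offset` must be a single positive number")
  mat <- log2(atlas$values + log_offset)
  v <- apply(mat, 1, function(r) max(r) - min(r))
  unrankable <- rownames(mat)[v == 0]
  if (!is.null(min_expression)) {
    low <- rownames(atlas$values)[apply(atlas$values, 1, max) < min_expression]
    unrankable <- union(unrankable, low)
  }
  if (length(unrankable))
    message(sprintf("preprocess_atlas: %d gene(s) flagged unrankable (zero variance or below min_expression)",
                    length(unrankable)))
  structure(list(mat = mat, unrankable = unrankable,
                 log_offset = log_offset, min_expression = min_expression),
            class = "atlas_transform")
}

#' Full co-expression similarity ranking
#'
#' For every rankable gene, orders all other rankable genes by descending
#' similarity (Pearson correlation of the log2 matrix by default, Spearman
#' as option), breaking ties by ascending gene id so rankings are
#' deterministic and independent of input row order. The resulting rank
#' `r(A -> B)` (position of B in A's ordered neighbor list, 1-based) is the
#' primitive used for mutual ranks, KNN networks and bait-neighborhood
#' candidate search.
#'
#' @param transformed an `atlas_transform` from [preprocess_atlas()], or an
#'   [expression_atlas()] (preprocessed with defaults).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return list of class `similarity_ranking`: `genes` (rankable ids,
#'   sorted), `sim` (similarity matrix), `rank` (rank matrix, `rank[A, B]`
#'   = r(A -> B), NA on the diagonal), `excluded` (unrankable ids),
#'   `method`.
#' @export
compute_similarity <- function(transformed, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (inherits(transformed, "expression_atlas"))
    transformed <- preprocess_atlas(transformed)
  if (!inherits(transformed, "atlas_transform"))
    stop("`transformed` must come from preprocess_atlas()")
  mat <- transformed$mat
  if (ncol(mat) < 3)
    stop("at least 3 samples are required for a stable correlation ranking")
  genes <- sort(setdiff(rownames(mat), transformed$unrankable))
  if (length(genes) < 2)
    stop("fewer than 2 rankable genes")
  sim <- cor(t(mat[genes, , drop = FALSE]), method = method)
  rk <- matrix(NA_integer_, nrow = length(genes), ncol = length(genes),
               dimnames = list(genes, genes))
  for (i in seq_along(genes)) {
    others <- setdiff(seq_along(genes), i)
    # descending similarity, ties by ascending gene id (genes is sorted,
    # so index order is id order)
    ord <- others[order(-sim[i, others], others)]
    rk[i, ord] <- seq_along(ord)
  }
  structure(list(genes = genes, sim = sim, rank = rk,
                 excluded = transformed$unrankable, method = method),
            class = "similarity_ranking")
}

#' @export
print.similarity_ranking <- function(x, ...) {
  cat(sprintf("similarity_ranking (%s): %d rankable genes, %d excluded\n",
              x$method, length(x$genes), length(x$excluded)))
  invisible(x)
}

check_rankable <- function(ranking, gene) {
  if (!gene %in% ranking$genes) {
    if (gene %in% ranking$excluded)
      stop(sprintf("gene '%s' is unrankable (zero variance or filtered)", gene))
    stop(sprintf("gene '%s' is not in the ranking", gene))
  }
}

#' Neighborhood rank r(A -> B)
#'
#' @param ranking a `similarity_ranking`.
#' @param a,b gene ids, `a != b`, both rankable.
#' @return integer rank of `b` in `a`'s ordered neighbor list (1 = most
#'   co-expressed).
#' @export
rank_of <- function(ranking, a, b) {
  stopifnot(inherits(ranking, "similarity_ranking"))
  check_rankable(ranking, a); check_rankable(ranking, b)
  if (a == b) stop("a gene has no rank with respect to itself")
  ranking$rank[a, b]
}

#' Top co-expression neighbors of a gene
#'
#' @param ranking a `similarity_ranking`.
#' @param gene gene id.
#' @param n how many neighbors (default: all).
#' @return character vector of gene ids in rank order.
#' @export
top_neighbors <- function(ranking, gene, n = Inf) {
  stopifnot(inherits(ranking, "similarity_ranking"))
  check_rankable(ranking, gene)
  r <- ranking$rank[gene, ]
  ord <- names(sort(r[!is.na(r)]))
  utils::head(ord, n)
}

#' Mutual rank of co-expression
#'
#' The symmetric co-expression strength of a gene pair: the geometric mean
#' `sqrt(r(A -> B) * r(B -> A))` of the two directed neighborhood ranks,
#' computed from the full rankings (not truncated at k). Lower is stronger;
#' the minimum, 1, occurs exactly for reciprocal rank-1 pairs.
#'
#' @param ranking a `similarity_ranking`.
#' @param a,b gene ids (vectorized in parallel), `a != b`, both rankable.
#' @return numeric mutual rank(s), >= 1.
#' @export
mutual_rank <- function(ranking, a, b) {
  stopifnot(inherits(ranking, "similarity_ranking"), length(a) == length(b))
  vapply(seq_along(a), function(i) {
    check_rankable(ranking, a[i]); check_rankable(ranking, b[i])
    if (a[i] == b[i]) stop("mutual rank is undefined for a gene with itself")
    sqrt(as.numeric(ranking$rank[a[i], b[i]]) *
         as.numeric(ranking$rank[b[i], a[i]]))
  }, numeric(1))
}

#' Build a k-nearest-neighbor co-expression network
#'
#' Connects each gene to its top-k most co-expressing genes (the study
#' default is k = 500). The directed adjacency is the first k entries of
#' each gene's ordered neighbor list; the undirected edge set is the union
#' symmetrization (an edge exists if either gene lists the other in its
#' top-k), annotated with both directed ranks and the mutual rank.
#'
#' @param ranking a `similarity_ranking`.
#' @param k neighborhood size, `1 <= k <= n - 1` rankable genes.
#' @return list of class `knn_network`: `k`, `genes`, `neighbors` (named
#'   list of top-k id vectors in rank order), `edges` (data.frame `gene_a`,
#'   `gene_b`, `rank_ab`, `rank_ba`, `mutual_rank`, `gene_a < gene_b`,
#'   sorted lexicographically), and the `ranking` it was built from.
#' @export
build_knn <- function(ranking, k) {
  stopifnot(inherits(ranking, "similarity_ranking"))
  n <- length(ranking$genes)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > n - 1)
    stop(sprintf("`k` must be between 1 and %d (rankable genes - 1)", n - 1))
  k <- as.integer(k)
  rk <- ranking$rank
  neighbors <- lapply(ranking$genes, function(g) {
    r <- rk[g, ]
    names(sort(r[!is.na(r) & r <= k]))
  })
  names(neighbors) <- ranking$genes
  idx <- which(rk <= k | t(rk) <= k, arr.ind = TRUE)
  idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  ga <- ranking$genes[idx[, 1]]
  gb <- ranking$genes[idx[, 2]]
  rab <- rk[idx]
  rba <- t(rk)[idx]
  edges <- data.frame(gene_a = ga, gene_b = gb,
                      rank_ab = as.integer(rab), rank_ba = as.integer(rba),
                      mutual_rank = sqrt(as.numeric(rab) * as.numeric(rba)),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(k = k, genes = ranking$genes, neighbors = neighbors,
                 edges = edges, ranking = ranking),
            class = "knn_network")
}

#' @export
print.knn_network <- function(x, ...) {
  cat(sprintf("knn_network: k = %d, %d genes, %d undirected edges\n",
              x$k, length(x$genes), nrow(x$edges)))
  invisible(x)
}

#' Export network edges as TSV
#'
#' Writes the undirected mutual-rank annotated edge list with columns
#' `gene_a`, `gene_b`, `rank_ab`, `rank_ba`, `mutual_rank` in deterministic
#' lexicographic row order (header-only file for an empty network).
#'
#' @param network a `knn_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_edges <- function(network, path) {
  stopifnot(inherits(network, "knn_network"))
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an edge-list TSV written by [export_edges()]
#'
#' @param path file path.
#' @return data.frame with the edge columns.
#' @export
read_edges <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Export the KNN network as GraphML
#'
#' Writes an undirected igraph GraphML file with `mutual_rank` (and both
#' directed ranks) as edge attributes, suitable for network visualization
#' where edge opacity is scaled by mutual rank.
#'
#' @param network a `knn_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(network, path) {
  stopifnot(inherits(network, "knn_network"))
  g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                     vertices = network$genes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
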