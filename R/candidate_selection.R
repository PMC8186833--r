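#' Select candidate regulators from bait-gene neighborhoods
#'
#' For each bait (known pathway gene), its top-k most co-expressing genes
#' are searched for members of the annotated regulator set; matches are
#' ordered by neighborhood rank and truncated to the top `cap` per bait
#' (study defaults: k = 500, cap = 10, i.e. at most `length(baits) * cap`
#' candidates before the union collapses overlaps). A bait is never its own
#' candidate, but a bait that is itself annotated as a regulator may be
#' selected as a candidate of other baits.
#'
#' @param x a `similarity_ranking` or a `knn_network` (its ranking is used;
#'   `k` must not exceed the network's k).
#' @param baits character vector of bait gene ids, all rankable in the
#'   atlas; optionally named by pathway branch.
#' @param regulators character vector of annotated regulator gene ids
#'   (e.g. a "regulation of gene expression" GO annotation set).
#' @param k neighborhood size searched per bait (default 500, truncated to
#'   the number of rankable genes minus 1).
#' @param cap maximum candidates kept per bait (default 10); `k >= cap >= 1`.
#' @return object of class `candidate_table`: data.frame `associations`
#'   with columns `candidate`, `bait`, `rank` (one row per surviving
#'   (candidate, bait) pair), plus `candidates` (unique ids, sorted),
#'   `baits`, `k`, `cap`.
#' @export
select_candidates <- function(x, baits, regulators, k = 500, cap = 10) {
  ranking <- if (inherits(x, "knn_network")) {
    if (k > x$k)
      stop(sprintf("k = %d exceeds the network's k = %d; build a larger network or pass the ranking", k, x$k))
    x$ranking
  } else if (inherits(x, "similarity_ranking")) {
    x
  } else stop("`x` must be a similarity_ranking or knn_network")
  baits <- as.character(baits)
  if (!length(baits)) stop("`baits` must be non-empty")
  if (anyDuplicated(baits))
    stop("duplicate bait ids: ", paste(unique(baits[duplicated(baits)]), collapse = ", "))
  absent <- setdiff(baits, ranking$genes)
  if (length(absent))
    stop("bait gene(s) absent from the atlas or unrankable: ",
         paste(absent, collapse = ", "))
  regulators <- unique(as.character(regulators))
  if (!length(regulators)) stop("`regulators` must be non-empty")
  if (!is.numeric(k) || !is.numeric(cap) || cap < 1 || k < cap)
    stop("require k >= cap >= 1")
  k <- min(as.integer(k), length(ranking$genes) - 1L)
  rows <- lapply(baits, function(b) {
    r <- ranking$rank[b, ]
    hits <- r[names(r) %in% setdiff(regulators, b) & !is.na(r) & r <= k]
    if (!length(hits)) return(NULL)
    hits <- sort(hits)[seq_len(min(cap, length(hits)))]
    data.frame(candidate = names(hits), bait = b, rank = as.integer(hits),
               stringsAsFactors = FALSE)
  })
  assoc <- do.call(rbind, rows)
  if (is.null(assoc))
    assoc <- data.frame(candidate = character(0), bait = character(0),
                        rank = integer(0), stringsAsFactors = FALSE)
  assoc <- assoc[order(assoc$candidate, assoc$bait), , drop = FALSE]
  rownames(assoc) <- NULL
  structure(list(associations = assoc,
                 candidates = sort(unique(assoc$candidate)),
                 baits = baits, k = k, cap = as.integer(cap)),
            class = "candidate_table")
}

#' @export
print.candidate_table <- function(x, ...) {
  cat(sprintf("candidate_table: %d candidates from %d baits (k = %d, cap = %d), %d associations\n",
              length(x$candidates), length(x$baits), x$k, x$cap,
              nrow(x$associations)))
  invisible(x)
}

#' Relative-rank matrix of candidates vs baits
#'
#' The heatmap behind candidate prioritization: entry (bait, candidate) is
#' the neighborhood rank divided by k — a value in (0, 1] where small means
#' strongly co-expressed — and NA where the candidate was not recorded for
#' that bait (absence is not rank 0).
#'
#' @param table a `candidate_table`.
#' @param path optional TSV output path (baits as rows, candidates as
#'   columns; empty cells for absent pairs).
#' @return numeric matrix, baits x candidates, with NA for absent pairs.
#' @export
relative_rank_matrix <- function(table, path = NULL) {
  stopifnot(inherits(table, "candidate_table"))
  m <- matrix(NA_real_, nrow = length(table$baits),
              ncol = length(table$candidates),
              dimnames = list(table$baits, table$candidates))
  a <- table$associations
  if (nrow(a))
    m[cbind(a$bait, a$candidate)] <- a$rank / table$k
  if (!is.null(path)) {
    out <- data.frame(bait = rownames(m), m, check.names = FALSE,
                      stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  m
}

#' Assemble combinatorial screening groups
#'
#' Partitions candidates into co-overexpression groups of at most
#' `max_size` (default 4), combining candidates that are co-expressed with
#' the same or overlapping subsets of bait genes. The assignment is a
#' deterministic greedy clustering: candidates are represented by their
#' bait-association sets and ordered by descending association count (ties
#' by id); each group is seeded with the first unassigned candidate and
#' filled with the unassigned candidates most similar to the seed by
#' Jaccard similarity of bait sets (only similarities > 0 merge; ties by
#' id) until `max_size` is reached.
#'
#' @param table a non-empty `candidate_table`.
#' @param max_size maximum group size, >= 1 (default 4).
#' @return object of class `screening_groups`: data.frame `assignments`
#'   (`group`, `candidate`) plus `groups`, a named list of member id
#'   vectors. Group labels are `G1`, `G2`, ... in creation order.
#' @export
assign_groups <- function(table, max_size = 4) {
  stopifnot(inherits(table, "candidate_table"))
  if (!nrow(table$associations)) stop("`table` has no candidates to group")
  if (!is.numeric(max_size) || max_size < 1)
    stop("`max_size` must be >= 1")
  bait_sets <- split(table$associations$bait, table$associations$candidate)
  cands <- names(bait_sets)
  sizes <- lengths(bait_sets)
  ord <- cands[order(-sizes, cands)]
  jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  unassigned <- ord
  groups <- list()
  while (length(unassigned)) {
    seed <- unassigned[1]
    unassigned <- unassigned[-1]
    members <- seed
    if (length(unassigned) && max_size > 1) {
      js <- vapply(unassigned, function(c2) jaccard(bait_sets[[seed]],
                                                    bait_sets[[c2]]),
                   numeric(1))
      pool <- unassigned[js > 0]
      pool <- pool[order(-js[js > 0], pool)]
      take <- utils::head(pool, max_size - 1)
      members <- c(members, take)
      unassigned <- setdiff(unassigned, take)
    }
    groups[[length(groups) + 1L]] <- members
  }
  names(groups) <- sprintf("G%d", seq_along(groups))
  assignments <- data.frame(
    group = rep(names(groups), lengths(groups)),
    candidate = unlist(groups, use.names = FALSE),
    stringsAsFactors = FALSE)
  structure(list(assignments = assignments, groups = groups,
                 max_size = as.integer(max_size)),
            class = "screening_groups")
}

#' @export
print.screening_groups <- function(x, ...) {
  cat(sprintf("screening_groups: %d candidates in %d groups (max size %d)\n",
              nrow(x$assignments), length(x$groups), x$max_size))
  invisible(x)
}
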