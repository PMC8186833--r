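# Independent brute-force oracle for co-expression rankings, mutual ranks,
# KNN adjacency and capped candidate selection. Correlations are computed
# from textbook sum formulas with explicit loops; nothing here shares code
# with the package implementation.

oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

oracle_rankvec <- function(x) {
  # midranks computed by explicit comparison counting
  vapply(seq_along(x), function(i) {
    less <- sum(x < x[i])
    equal <- sum(x == x[i])
    less + (equal + 1) / 2
  }, numeric(1))
}

oracle_similarity <- function(mat, method = "pearson") {
  genes <- rownames(mat)
  n <- length(genes)
  s <- matrix(NA_real_, n, n, dimnames = list(genes, genes))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    xi <- mat[i, ]; xj <- mat[j, ]
    if (method == "spearman") { xi <- oracle_rankvec(xi); xj <- oracle_rankvec(xj) }
    s[i, j] <- oracle_pearson(xi, xj)
  }
  s
}

# rank of every other gene in `gene`'s list: descending similarity, ties by
# ascending gene id
oracle_ranks_for <- function(sim, gene) {
  others <- setdiff(sort(rownames(sim)), gene)
  ord <- others[order(-sim[gene, others], others)]
  stats::setNames(seq_along(ord), ord)
}

oracle_rank_matrix <- function(sim) {
  genes <- sort(rownames(sim))
  rk <- matrix(NA_integer_, length(genes), length(genes),
               dimnames = list(genes, genes))
  for (g in genes) {
    r <- oracle_ranks_for(sim, g)
    rk[g, names(r)] <- r
  }
  rk
}

oracle_mutual_rank <- function(rk, a, b) sqrt(rk[a, b] * rk[b, a])

# undirected union-symmetrized KNN edge set as a sorted "a|b" key vector
oracle_knn_edges <- function(rk, k) {
  genes <- rownames(rk)
  keys <- character(0)
  for (a in genes) for (b in genes) {
    if (a >= b) next
    if (rk[a, b] <= k || rk[b, a] <= k)
      keys <- c(keys, paste(a, b, sep = "|"))
  }
  sort(keys)
}

oracle_select <- function(rk, baits, regulators, k, cap) {
  out <- list()
  for (bait in baits) {
    r <- rk[bait, ]
    hits <- r[names(r) %in% setdiff(regulators, bait) & !is.na(r) & r <= k]
    hits <- sort(hits)
    hits <- hits[seq_len(min(cap, length(hits)))]
    for (nm in names(hits))
      out[[length(out) + 1L]] <- data.frame(candidate = nm, bait = bait,
                                            rank = as.integer(hits[[nm]]))
  }
  if (!length(out))
    return(data.frame(candidate = character(0), bait = character(0),
                      rank = integer(0)))
  df <- do.call(rbind, out)
  df <- df[order(df$candidate, df$bait), ]
  rownames(df) <- NULL
  df
}

# random small atlas for oracle-equivalence sweeps; values strictly positive
# with per-gene variation so every gene is rankable
random_atlas <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  m <- matrix(2 ^ runif(n_genes * n_samples, 0, 10), nrow = n_genes,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  expression_atlas(m)
}
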