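# candidate_table with given associations, for grouping tests
mock_table <- function(assoc, baits = unique(assoc$bait), k = 100, cap = 10) {
  structure(list(associations = assoc[order(assoc$candidate, assoc$bait), ],
                 candidates = sort(unique(assoc$candidate)),
                 baits = baits, k = k, cap = cap),
            class = "candidate_table")
}

test_that("candidate selection matches the brute-force oracle on random atlases", {
  for (seed in c(1, 2, 3)) {
    atlas <- random_atlas(18, 7, seed = seed)
    rk <- compute_similarity(preprocess_atlas(atlas))
    set.seed(seed + 100)
    baits <- sample(rk$genes, 4)
    regulators <- sample(setdiff(rk$genes, baits), 8)
    for (cap in c(2, 5)) {
      ct <- select_candidates(rk, baits, regulators, k = 10, cap = cap)
      oc <- oracle_select(rk$rank, baits, regulators, k = 10, cap = cap)
      expect_equal(ct$associations, oc)
      expect_true(all(ct$candidates %in% regulators))
      expect_true(all(table(ct$associations$bait) <= cap))
    }
  }
})

test_that("planted regulators are recovered for baits of their own module", {
  sim <- simulate_atlas(recovery_config(seed = 1, noise_sd = 0.05))
  rk <- compute_similarity(preprocess_atlas(sim$atlas))
  k <- length(rk$genes) - 1
  ct <- select_candidates(rk, pathway_list(sim$truth),
                          regulator_list(sim$truth), k = k, cap = 10)
  for (m in names(sim$truth$modules)) {
    own_baits <- sim$truth$modules[[m]]$pathway
    for (reg in sim$truth$modules[[m]]$regulators) {
      hits <- ct$associations$bait[ct$associations$candidate == reg]
      expect_true(length(intersect(hits, own_baits)) >= 1,
                  label = sprintf("regulator %s recovered by own module", reg))
    }
  }
  # background genes never become candidates when absent from the regulator set
  expect_length(intersect(ct$candidates, sim$truth$background), 0)
  # agreement with exhaustive brute-force selection on the same instance
  oc <- oracle_select(rk$rank, pathway_list(sim$truth),
                      regulator_list(sim$truth), k = k, cap = 10)
  expect_equal(ct$associations, oc)
})

test_that("selection enforces its preconditions and membership rules", {
  atlas <- random_atlas(10, 6, seed = 4)
  rk <- compute_similarity(preprocess_atlas(atlas))
  expect_error(select_candidates(rk, "nope", rk$genes[1], k = 5, cap = 2),
               "nope")
  expect_error(select_candidates(rk, rk$genes[1], character(0), k = 5, cap = 2),
               "regulators")
  expect_error(select_candidates(rk, rk$genes[1], rk$genes[2], k = 2, cap = 5),
               "k >= cap")
  # a bait is never its own candidate, even when annotated as a regulator
  ct <- select_candidates(rk, rk$genes[1:2], regulators = rk$genes,
                          k = 9, cap = 9)
  a <- ct$associations
  expect_false(any(a$candidate == a$bait))
  # ...but baits can be candidates for other baits
  expect_true(rk$genes[1] %in% a$candidate[a$bait == rk$genes[2]])
  # disjoint regulator set gives an empty table
  ct0 <- select_candidates(rk, rk$genes[1], regulators = "absent_gene",
                           k = 5, cap = 2)
  expect_length(ct0$candidates, 0)
})

test_that("raising the cap never loses a candidate", {
  atlas <- random_atlas(20, 8, seed = 6)
  rk <- compute_similarity(preprocess_atlas(atlas))
  baits <- rk$genes[1:3]
  regulators <- rk$genes[10:20]
  prev <- character(0)
  for (cap in c(1, 2, 4, 8)) {
    ct <- select_candidates(rk, baits, regulators, k = 15, cap = cap)
    expect_true(all(prev %in% ct$candidates))
    expect_lte(length(ct$candidates), length(baits) * cap)
    prev <- ct$candidates
  }
})

test_that("relative ranks divide by k and mask absences", {
  assoc <- data.frame(candidate = c("c1", "c1", "c2"),
                      bait = c("b1", "b2", "b1"),
                      rank = c(1L, 500L, 250L))
  ct <- mock_table(assoc, baits = c("b1", "b2"), k = 500)
  m <- relative_rank_matrix(ct)
  expect_equal(m["b1", "c1"], 0.002)
  expect_equal(m["b2", "c1"], 1.0)
  expect_equal(m["b1", "c2"], 0.5)
  expect_true(is.na(m["b2", "c2"]))  # absence is masked, never 0
  path <- withr::local_tempfile(fileext = ".tsv")
  relative_rank_matrix(ct, path)
  back <- utils::read.delim(path, check.names = FALSE)
  expect_equal(back$c1, c(0.002, 1.0))
})

test_that("grouping merges shared-bait candidates and separates disjoint ones", {
  # four candidates with identical bait sets form one group of four
  same <- do.call(rbind, lapply(sprintf("c%d", 1:4), function(cand)
    data.frame(candidate = cand, bait = c("b1", "b2"), rank = 1L)))
  g1 <- assign_groups(mock_table(same), max_size = 4)
  expect_length(g1$groups, 1)
  expect_setequal(g1$groups[[1]], sprintf("c%d", 1:4))
  # pairwise-disjoint bait sets stay singletons
  disj <- data.frame(candidate = sprintf("c%d", 1:3),
                     bait = sprintf("b%d", 1:3), rank = 1L)
  g2 <- assign_groups(mock_table(disj), max_size = 4)
  expect_length(g2$groups, 3)
  expect_true(all(lengths(g2$groups) == 1))
})

test_that("greedy grouping never mixes two planted candidate blocks", {
  # two blocks of five candidates; bait sets identical within a block and
  # disjoint across blocks. Hand-enumerated greedy outcome: seed A1 fills
  # {A1..A4}; next seed A5 finds no Jaccard > 0 partner left and stays a
  # singleton; then {B1..B4} and {B5}.
  blockA <- do.call(rbind, lapply(sprintf("A%d", 1:5), function(cand)
    data.frame(candidate = cand, bait = c("bA1", "bA2"), rank = 1L)))
  blockB <- do.call(rbind, lapply(sprintf("B%d", 1:5), function(cand)
    data.frame(candidate = cand, bait = c("bB1", "bB2"), rank = 1L)))
  g <- assign_groups(mock_table(rbind(blockA, blockB)), max_size = 4)
  expect_equal(unname(lengths(g$groups)), c(4, 1, 4, 1))
  expect_equal(g$groups[[1]], sprintf("A%d", 1:4))
  expect_equal(g$groups[[2]], "A5")
  expect_equal(g$groups[[3]], sprintf("B%d", 1:4))
  expect_equal(g$groups[[4]], "B5")
  # partition: nobody assigned twice
  expect_false(anyDuplicated(g$assignments$candidate) > 0)
})
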