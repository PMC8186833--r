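# build a qpcr_dataset from explicit per-condition Cq shifts (cycles below
# the control baseline), flat references
shift_dataset <- function(target_shift, n = 3, base = 25,
                          refs = c("N2227", "SAND"), eff = NULL) {
  conds <- c("GUS", "OE")
  recs <- do.call(rbind, lapply(conds, function(cond) {
    do.call(rbind, lapply(seq_len(n), function(r) {
      genes <- c(refs, names(target_shift))
      shift <- c(rep(0, length(refs)),
                 if (cond == "OE") target_shift else rep(0, length(target_shift)))
      data.frame(sample = sprintf("%s_%d", cond, r), condition = cond,
                 gene = genes, cq = base - shift)
    }))
  }))
  qpcr_dataset(recs, reference_genes = refs, control = "GUS",
               efficiencies = eff)
}

test_that("NRQ normalization is calibrated to the control and follows the Cq arithmetic", {
  # identical Cq everywhere: every NRQ is 1
  d0 <- shift_dataset(c(tgt = 0))
  nrq0 <- normalize_qpcr(d0)
  expect_true(all(abs(nrq0$values$nrq - 1) < 1e-12))
  # target 2 cycles lower in treatment, flat references, E = 2: treatment
  # NRQ mean is exactly 4
  d2 <- shift_dataset(c(tgt = 2))
  nrq2 <- normalize_qpcr(d2)
  v <- nrq2$values
  expect_equal(mean(v$nrq[v$gene == "tgt" & v$condition == "OE"]), 4,
               tolerance = 1e-12)
  # per-gene control means are 1 within 1e-9
  ctrl <- v[v$condition == "GUS", ]
  expect_true(all(abs(tapply(ctrl$nrq, ctrl$gene, mean) - 1) < 1e-9))
})

test_that("NRQ is invariant to uniform Cq shifts of a reference gene", {
  d <- simulate_qpcr(list(OE = c(tgt = 3)), c("N2227", "SAND"),
                     control = "GUS", cq_sd = 0.2, seed = 4)
  nrq <- normalize_qpcr(d)
  shifted <- d
  idx <- shifted$records$gene == "SAND"
  shifted$records$cq[idx] <- shifted$records$cq[idx] + 3.7
  nrq_s <- normalize_qpcr(shifted)
  expect_equal(nrq$values$nrq, nrq_s$values$nrq, tolerance = 1e-12)
  # uniform shift of a target gene's Cq across all samples leaves FC alone
  shifted2 <- d
  idx2 <- shifted2$records$gene == "tgt"
  shifted2$records$cq[idx2] <- shifted2$records$cq[idx2] - 1.3
  expect_equal(fold_changes(normalize_qpcr(shifted2), "OE")$fc,
               fold_changes(nrq, "OE")$fc, tolerance = 1e-12)
})

test_that("dataset validation names the offending sample or efficiency", {
  recs <- data.frame(sample = c("a1", "a2", "b1", "b2"),
                     condition = c("GUS", "GUS", "OE", "OE"),
                     gene = "ref", cq = 25)
  expect_error(qpcr_dataset(rbind(recs,
                                  data.frame(sample = "a1", condition = "GUS",
                                             gene = "tgt", cq = 24)),
                            reference_genes = "missing_ref", control = "GUS"),
               "missing_ref")
  expect_error(qpcr_dataset(recs, "ref", control = "GUS",
                            efficiencies = c(ref = 0.9)),
               "> 1")
  one_rep <- data.frame(sample = c("a1", "b1", "b2"),
                        condition = c("GUS", "OE", "OE"),
                        gene = "ref", cq = 25)
  expect_error(qpcr_dataset(one_rep, "ref", control = "GUS"), "replicates")
})

test_that("fold changes are geometric-mean ratios with equal-variance t-tests", {
  # exact log2 shift of 2 with nonzero within-group variance: FC = 4
  v <- data.frame(
    sample = sprintf("s%d", 1:8),
    condition = rep(c("GUS", "OE"), each = 4),
    gene = "tgt",
    nrq = 2 ^ c(c(-0.3, 0.1, 0.2, 0) , c(-0.3, 0.1, 0.2, 0) + 2))
  v$nrq[v$condition == "GUS"] <-
    v$nrq[v$condition == "GUS"] / mean(v$nrq[v$condition == "GUS"])
  v$nrq[v$condition == "OE"] <-
    v$nrq[v$condition == "OE"] / mean(2 ^ c(-0.3, 0.1, 0.2, 0))
  nrq <- structure(list(values = v, control = "GUS",
                        reference_genes = character(0)),
                   class = "nrq_table")
  res <- fold_changes(nrq, "OE", "GUS")
  expect_equal(res$fc, 4, tolerance = 1e-12)
  # equal-variance Student form: matches t.test(var.equal = TRUE)
  ref <- t.test(log2(v$nrq[v$condition == "OE"]),
                log2(v$nrq[v$condition == "GUS"]), var.equal = TRUE)$p.value
  expect_equal(res$p, ref)
  expect_error(fold_changes(nrq, "nope"), "nope")
})

test_that("simulated 4-fold targets are estimated accurately and pass the gate", {
  inside <- 0; passed <- 0; reps <- 200
  for (i in seq_len(reps)) {
    d <- simulate_qpcr(list(OE = c(TF = 40, tgt = 4)), c("N2227", "SAND"),
                       control = "GUS", n_replicates = 4, cq_sd = 0.1,
                       seed = 3000 + i)
    res <- fold_changes(normalize_qpcr(d), "OE")
    fc <- res$fc[res$gene == "tgt"]
    inside <- inside + (fc >= 3 && fc <= 5.3)
    gate <- apply_gate(res, "TF", target_genes = "tgt")
    passed <- passed + gate$advance
  }
  expect_gte(inside / reps, 0.95)
  expect_gte(passed / reps, 0.95)
})

test_that("the advancement gate applies strict thresholds and logs triggers", {
  res <- data.frame(gene = c("TF", "t1", "t2", "t3"),
                    fc = c(5.0, 3, 3, 10), p = c(1e-6, 0.01, 0.2, 0.04))
  # OE fold change of exactly 5 fails the strict > 5 rule
  g <- apply_gate(res, "TF")
  expect_false(g$oe_ok)
  expect_false(g$advance)
  # raise OE: t1 (FC 3, p 0.01) and t3 trigger; t2 fails on p
  res$fc[1] <- 100
  g2 <- apply_gate(res, "TF")
  expect_true(g2$oe_ok)
  expect_true(g2$advance)
  expect_setequal(g2$triggered_by, c("t1", "t3"))
  # boundary cases are strict
  g3 <- apply_gate(data.frame(gene = c("TF", "t"), fc = c(100, 2.0),
                              p = c(1e-9, 0.01)), "TF")
  expect_false(g3$advance)
  g4 <- apply_gate(data.frame(gene = c("TF", "t"), fc = c(100, 3),
                              p = c(1e-9, 0.05)), "TF")
  expect_false(g4$advance)
  # missing targets are listed and treated as non-hits
  g5 <- apply_gate(res, "TF", target_genes = c("t1", "ghost"))
  expect_equal(g5$missing_targets, "ghost")
  expect_true(g5$advance)
  # missing OE measurement is an error
  expect_error(apply_gate(res, c("TF", "TF2")), "TF2")
  # gate monotonicity: with p fixed, larger target FC never loses advancement
  fcs <- seq(2.1, 50, length.out = 20)
  adv <- vapply(fcs, function(f)
    apply_gate(data.frame(gene = c("TF", "t"), fc = c(100, f),
                          p = c(1e-9, 0.01)), "TF")$advance, logical(1))
  expect_true(all(adv))
})

test_that("follow-up list unions members of advancing groups deterministically", {
  assoc <- data.frame(candidate = c("c1", "c2", "c3", "c4", "c5"),
                      bait = c("b1", "b1", "b2", "b2", "b3"), rank = 1L)
  tab <- structure(list(associations = assoc, candidates = sort(assoc$candidate),
                        baits = unique(assoc$bait), k = 10L, cap = 10L),
                   class = "candidate_table")
  groups <- assign_groups(tab, max_size = 4)
  mk <- function(adv) structure(list(advance = adv), class = "gate_decision")
  labs <- names(groups$groups)
  none <- followup_list(stats::setNames(lapply(labs, function(x) mk(FALSE)), labs),
                        groups)
  expect_length(none, 0)
  all_d <- stats::setNames(lapply(labs, function(x) mk(TRUE)), labs)
  expect_equal(followup_list(all_d, groups), sort(unlist(groups$groups,
                                                         use.names = FALSE)))
  expect_equal(length(followup_list(all_d, groups)),
               sum(lengths(groups$groups)))
  one <- stats::setNames(lapply(labs, function(x) mk(x == labs[1])), labs)
  expect_setequal(followup_list(one, groups), groups$groups[[1]])
  expect_error(followup_list(list(ZZ = mk(TRUE)), groups), "ZZ")
})

test_that("null simulations hit at the nominal two-sided rate", {
  reps <- 1000
  hits <- 0
  for (i in seq_len(reps)) {
    d <- simulate_qpcr(list(OE = c(null1 = 1)), c("N2227", "SAND"),
                       control = "GUS", n_replicates = 4, cq_sd = 0.15,
                       seed = 7000 + i)
    res <- fold_changes(normalize_qpcr(d), "OE")
    hits <- hits + (res$p[res$gene == "null1"] < 0.05)
  }
  bounds <- qbinom(c(0.005, 0.995), reps, 0.05) / reps
  rate <- hits / reps
  expect_gte(rate, bounds[1])
  expect_lte(rate, bounds[2])
})
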