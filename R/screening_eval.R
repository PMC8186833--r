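#' @importFrom stats t.test
NULL

#' Reference-gene normalized relative quantities (NRQ)
#'
#' Efficiency-corrected relative quantification in the qBase style: per gene
#' the relative quantity is `RQ(g, s) = E_g^(meanCq_g - Cq(g, s))` with the
#' gene's mean Cq over all samples as calibrator; the per-sample
#' normalization factor `NF(s)` is the geometric mean of the reference
#' genes' RQs; `NRQ = RQ / NF`, finally rescaled per gene so the
#' control-condition mean equals 1. Uniform Cq shifts of a reference gene
#' cancel, so NRQs are invariant to reference-gene loading.
#'
#' @param dataset a [qpcr_dataset()].
#' @return object of class `nrq_table`: data.frame `values` with columns
#'   `sample`, `condition`, `gene`, `nrq`, plus `control` and
#'   `reference_genes`.
#' @export
normalize_qpcr <- function(dataset) {
  stopifnot(inherits(dataset, "qpcr_dataset"))
  rec <- dataset$records
  eff <- dataset$efficiencies
  mean_cq <- tapply(rec$cq, rec$gene, mean)
  rq <- eff[rec$gene] ^ (mean_cq[rec$gene] - rec$cq)
  # geometric-mean normalization factor over reference genes, per sample
  is_ref <- rec$gene %in% dataset$reference_genes
  log_nf <- tapply(log(rq[is_ref]), rec$sample[is_ref], mean)
  nrq <- rq / exp(log_nf[rec$sample])
  values <- data.frame(sample = rec$sample, condition = rec$condition,
                       gene = rec$gene, nrq = as.numeric(nrq),
                       stringsAsFactors = FALSE)
  ctrl <- values$condition == dataset$control
  ctrl_mean <- tapply(values$nrq[ctrl], values$gene[ctrl], mean)
  no_ctrl <- setdiff(values$gene, names(ctrl_mean))
  if (length(no_ctrl))
    stop("gene(s) not measured in the control condition: ",
         paste(no_ctrl, collapse = ", "))
  values$nrq <- values$nrq / as.numeric(ctrl_mean[values$gene])
  rownames(values) <- NULL
  structure(list(values = values, control = dataset$control,
                 reference_genes = dataset$reference_genes),
            class = "nrq_table")
}

#' @export
print.nrq_table <- function(x, ...) {
  cat(sprintf("nrq_table: %d values, %d genes, control condition '%s'\n",
              nrow(x$values), length(unique(x$values$gene)), x$control))
  invisible(x)
}

#' Per-gene fold changes and t-test p-values
#'
#' Compares a treatment condition against the control on log2 NRQs: the
#' fold change is the geometric-mean ratio `2^(mean log2 treatment - mean
#' log2 control)` and the p-value a two-sided, equal-variance (classic
#' Student) two-sample t-test on the log2 values.
#'
#' @param nrq an `nrq_table` from [normalize_qpcr()].
#' @param treatment treatment condition label.
#' @param control control condition label (default: the table's control).
#' @return data.frame with columns `gene`, `fc`, `p`, `n_treatment`,
#'   `n_control`, ordered by gene id.
#' @export
fold_changes <- function(nrq, treatment, control = NULL) {
  stopifnot(inherits(nrq, "nrq_table"))
  if (is.null(control)) control <- nrq$control
  v <- nrq$values
  for (cond in c(treatment, control))
    if (!cond %in% v$condition)
      stop(sprintf("condition '%s' not present in NRQ table", cond))
  if (any(v$nrq <= 0))
    stop("non-positive NRQ encountered; normalization is corrupt")
  genes <- sort(intersect(unique(v$gene[v$condition == treatment]),
                          unique(v$gene[v$condition == control])))
  res <- lapply(genes, function(g) {
    xt <- log2(v$nrq[v$gene == g & v$condition == treatment])
    xc <- log2(v$nrq[v$gene == g & v$condition == control])
    if (length(xt) < 2 || length(xc) < 2)
      stop(sprintf("gene '%s': need >= 2 replicates per condition", g))
    d <- mean(xt) - mean(xc)
    p <- if (sd(c(xt - mean(xt), xc - mean(xc))) == 0) {
      if (d == 0) 1 else 0
    } else {
      t.test(xt, xc, var.equal = TRUE)$p.value
    }
    data.frame(gene = g, fc = 2 ^ d, p = p,
               n_treatment = length(xt), n_control = length(xc),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Apply the screening advancement gate
#'
#' The pass/fail rule for advancing a (group of) overexpressed TF
#' candidate(s) to individual testing: overexpression is successful when
#' every introduced TF exceeds `oe_threshold`-fold (default > 5), a target
#' gene is a hit when its fold change exceeds `target_threshold` (default
#' > 2) with `p < alpha` (default 0.05), and the unit advances when
#' overexpression succeeded and at least one target is a hit. All
#' inequalities are strict.
#'
#' @param results data.frame from [fold_changes()] covering the introduced
#'   TFs and target genes.
#' @param oe_genes ids of the introduced (overexpressed) TFs; each must be
#'   present in `results`.
#' @param target_genes ids of the pathway target genes; defaults to all
#'   non-OE genes in `results`. Targets missing from `results` are listed
#'   and treated as non-hits.
#' @param oe_threshold,target_threshold,alpha gate thresholds (defaults 5,
#'   2, 0.05).
#' @return object of class `gate_decision`: `oe` (per-TF fold changes with
#'   `ok` flag), `targets` (per-target `fc`, `p`, `hit`), `missing_targets`,
#'   `oe_ok`, `advance`, `triggered_by` (hit target ids), `thresholds`.
#' @export
apply_gate <- function(results, oe_genes, target_genes = NULL,
                       oe_threshold = 5, target_threshold = 2, alpha = 0.05) {
  stopifnot(is.data.frame(results), all(c("gene", "fc", "p") %in% names(results)))
  oe_genes <- as.character(oe_genes)
  miss_oe <- setdiff(oe_genes, results$gene)
  if (length(miss_oe))
    stop("overexpression fold change missing for introduced TF(s): ",
         paste(miss_oe, collapse = ", "))
  if (is.null(target_genes))
    target_genes <- setdiff(results$gene, oe_genes)
  target_genes <- as.character(target_genes)
  oe <- results[match(oe_genes, results$gene), c("gene", "fc", "p")]
  oe$ok <- oe$fc > oe_threshold
  present <- intersect(target_genes, results$gene)
  missing_targets <- setdiff(target_genes, results$gene)
  targets <- results[match(present, results$gene), c("gene", "fc", "p")]
  targets$hit <- targets$fc > target_threshold & targets$p < alpha
  rownames(oe) <- rownames(targets) <- NULL
  oe_ok <- all(oe$ok)
  triggered <- targets$gene[targets$hit]
  structure(list(oe = oe, targets = targets,
                 missing_targets = missing_targets,
                 oe_ok = oe_ok, advance = oe_ok && length(triggered) > 0,
                 triggered_by = triggered,
                 thresholds = c(oe = oe_threshold, target = target_threshold,
                                alpha = alpha)),
            class = "gate_decision")
}

#' @export
print.gate_decision <- function(x, ...) {
  cat(sprintf("gate_decision: oe_ok = %s, advance = %s\n",
              x$oe_ok, x$advance))
  if (length(x$triggered_by))
    cat("triggered by target(s):", paste(x$triggered_by, collapse = ", "), "\n")
  if (length(x$missing_targets))
    cat("missing targets (treated as non-hits):",
        paste(x$missing_targets, collapse = ", "), "\n")
  invisible(x)
}

#' Candidates to carry forward to individual overexpression
#'
#' Union of the members of every advancing screening group, deduplicated,
#' in deterministic (sorted) order.
#'
#' @param decisions named list of `gate_decision` objects, one per group
#'   label in `groups`.
#' @param groups a `screening_groups` object.
#' @return character vector of candidate ids (possibly empty).
#' @export
followup_list <- function(decisions, groups) {
  stopifnot(inherits(groups, "screening_groups"), is.list(decisions))
  unknown <- setdiff(names(decisions), names(groups$groups))
  if (length(unknown))
    stop("decisions for unknown group(s): ", paste(unknown, collapse = ", "))
  advancing <- names(decisions)[vapply(decisions, function(d) {
    stopifnot(inherits(d, "gate_decision")); isTRUE(d$advance)
  }, logical(1))]
  sort(unique(unlist(groups$groups[advancing], use.names = FALSE)))
}
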