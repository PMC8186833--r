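#' qPCR dataset container
#'
#' Holds quantification-cycle (Cq) measurements (one averaged Cq per gene per
#' biological replicate) plus the metadata needed for relative
#' quantification: reference gene ids, per-gene amplification efficiencies
#' and the control condition label.
#'
#' @param records data.frame with columns `sample`, `condition`, `gene`,
#'   `cq`. Cq values must be finite.
#' @param reference_genes character, >= 1 reference gene id; each must be
#'   measured in every sample.
#' @param control label of the control condition; must occur in `records`.
#' @param efficiencies named numeric amplification efficiencies (fold per
#'   cycle, > 1); genes without an entry default to 2.
#' @return list of class `qpcr_dataset` with elements `records`,
#'   `reference_genes`, `control`, `efficiencies`.
#' @export
qpcr_dataset <- function(records, reference_genes, control,
                         efficiencies = NULL) {
  records <- as.data.frame(records)
  need <- c("sample", "condition", "gene", "cq")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("`records` is missing columns: ", paste(miss, collapse = ", "))
  if (!is.numeric(records$cq) || any(!is.finite(records$cq)))
    stop("Cq values must be finite numbers")
  if (anyDuplicated(records[c("sample", "gene")]))
    stop("duplicate (sample, gene) measurements; average technical replicates first")
  if (!control %in% records$condition)
    stop(sprintf("control condition '%s' not present in records", control))
  reps <- table(unique(records[c("sample", "condition")])$condition)
  few <- names(reps)[reps < 2]
  if (length(few))
    stop("conditions with fewer than 2 biological replicates: ",
         paste(few, collapse = ", "))
  samples <- unique(records$sample)
  for (ref in reference_genes) {
    missing_in <- setdiff(samples, records$sample[records$gene == ref])
    if (length(missing_in))
      stop(sprintf("reference gene '%s' not measured in sample(s): %s",
                   ref, paste(missing_in, collapse = ", ")))
  }
  genes <- unique(records$gene)
  eff <- rep(2, length(genes)); names(eff) <- genes
  if (!is.null(efficiencies)) {
    unknown <- setdiff(names(efficiencies), genes)
    eff[intersect(names(efficiencies), genes)] <-
      efficiencies[intersect(names(efficiencies), genes)]
  }
  if (any(eff <= 1))
    stop("amplification efficiencies must be > 1 (fold per cycle): ",
         paste(names(eff)[eff <= 1], collapse = ", "))
  rownames(records) <- NULL
  structure(list(records = records, reference_genes = reference_genes,
                 control = control, efficiencies = eff),
            class = "qpcr_dataset")
}

#' @export
print.qpcr_dataset <- function(x, ...) {
  cat(sprintf("qpcr_dataset: %d measurements, %d genes, %d samples\n",
              nrow(x$records), length(unique(x$records$gene)),
              length(unique(x$records$sample))))
  cat("conditions:", paste(unique(x$records$condition), collapse = ", "),
      sprintf("(control: %s)\n", x$control))
  cat("reference genes:", paste(x$reference_genes, collapse = ", "), "\n")
  invisible(x)
}
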