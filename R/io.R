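#' Read an expression atlas from TSV
#'
#' Expects a genes x samples table: header row of sample ids, first column
#' gene ids, tab-separated numeric TPM values. Gene ids are treated as
#' opaque strings and pass through unmodified.
#'
#' @param path TSV file path.
#' @param meta_path optional sample-metadata TSV (columns `sample`,
#'   `organ`, `treatment`).
#' @return an [expression_atlas()].
#' @export
read_expression_tsv <- function(path, meta_path = NULL) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 2)
    stop("expression file is empty or has no data rows: ", path)
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2)
    stop("expression file needs a gene-id column plus >= 1 sample column: ", path)
  gene_ids <- df[[1]]
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup))
    stop("duplicate gene id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(gene_ids, colnames(vals))))
  bad <- which(is.na(num) & !is.na(vals))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(num))
    stop(sprintf("non-numeric cell at line %d (gene '%s', sample '%s') in %s",
                 i[1] + 1L, gene_ids[i[1]], colnames(num)[i[2]], path))
  }
  meta <- if (!is.null(meta_path))
    utils::read.delim(meta_path, stringsAsFactors = FALSE) else NULL
  expression_atlas(num, meta)
}

#' Write an expression atlas as TSV
#'
#' @param atlas an [expression_atlas()].
#' @param path output TSV path (gene ids in the first column, `gene_id`).
#' @param meta_path optional path for the sample-metadata TSV.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(atlas, path, meta_path = NULL) {
  stopifnot(inherits(atlas, "expression_atlas"))
  df <- data.frame(gene_id = rownames(atlas$values), atlas$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path) && !is.null(atlas$sample_meta))
    utils::write.table(atlas$sample_meta, meta_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-id list
#'
#' One id per line; blank lines and `#` comments are skipped; duplicates
#' are removed with a warning. An optional second tab-separated column
#' (e.g. a pathway-branch tag for baits) is returned as names.
#'
#' @param path file path.
#' @return character vector of ids (named by tag when a second column is
#'   present).
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("gene list file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t")
  ids <- vapply(parts, `[[`, character(1), 1)
  tags <- vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_,
                 character(1))
  if (anyDuplicated(ids)) {
    warning("duplicate gene id(s) in ", path, ": ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "),
            " (deduplicated)")
    keep <- !duplicated(ids)
    ids <- ids[keep]; tags <- tags[keep]
  }
  if (any(!is.na(tags))) names(ids) <- tags
  ids
}

#' Write a gene-id list
#'
#' @param ids character vector (names, if present, written as a second
#'   tab-separated tag column).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(ids, path) {
  lines <- if (is.null(names(ids))) as.character(ids)
           else paste(ids, names(ids), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a qPCR Cq table from CSV
#'
#' Expects columns `sample`, `condition`, `gene`, `cq`.
#'
#' @param path CSV path.
#' @param reference_genes,control passed to [qpcr_dataset()].
#' @param efficiency_path optional CSV with columns `gene`, `E`.
#' @return a [qpcr_dataset()].
#' @export
read_qpcr_csv <- function(path, reference_genes, control,
                          efficiency_path = NULL) {
  if (!file.exists(path)) stop("qPCR file not found: ", path)
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  eff <- NULL
  if (!is.null(efficiency_path)) {
    e <- utils::read.csv(efficiency_path, stringsAsFactors = FALSE)
    eff <- stats::setNames(e$E, e$gene)
  }
  qpcr_dataset(rec, reference_genes = reference_genes, control = control,
               efficiencies = eff)
}

#' Write a qPCR dataset as CSV
#'
#' @param dataset a [qpcr_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_qpcr_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "qpcr_dataset"))
  utils::write.csv(dataset$records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write planted truth as structured text
#'
#' Three-column TSV (`gene`, `role`, `module`) where role is `pathway`,
#' `regulator` or `background`.
#'
#' @param truth a `planted_truth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_planted_truth <- function(truth, path) {
  stopifnot(inherits(truth, "planted_truth"))
  rows <- lapply(names(truth$modules), function(m) {
    tm <- truth$modules[[m]]
    rbind(
      if (length(tm$pathway))
        data.frame(gene = tm$pathway, role = "pathway", module = m),
      if (length(tm$regulators))
        data.frame(gene = tm$regulators, role = "regulator", module = m))
  })
  if (length(truth$background))
    rows <- c(rows, list(data.frame(gene = truth$background,
                                    role = "background", module = NA)))
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Write a candidate table as TSV
#'
#' Columns: `candidate`, `bait`, `rank`, `relative_rank`.
#'
#' @param table a `candidate_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(table, path) {
  stopifnot(inherits(table, "candidate_table"))
  a <- table$associations
  a$relative_rank <- a$rank / table$k
  utils::write.table(a, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write screening groups as TSV
#'
#' Columns: `group_id`, `candidate`.
#'
#' @param groups a `screening_groups`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_groups <- function(groups, path) {
  stopifnot(inherits(groups, "screening_groups"))
  out <- groups$assignments
  names(out) <- c("group_id", "candidate")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
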