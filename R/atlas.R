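#' Expression atlas container
#'
#' An `expression_atlas` holds a genes x samples matrix of TPM
#' (transcripts per million) values together with optional per-sample
#' metadata (organ, treatment). It is the substrate for all co-expression
#' computation.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   unique rownames (gene ids) and colnames (sample ids). Values must be
#'   finite and non-negative.
#' @param sample_meta optional data.frame with one row per sample; must
#'   contain a `sample` column matching `colnames(values)`.
#' @return an object of class `expression_atlas`: a list with elements
#'   `values` and `sample_meta`.
#' @examples
#' m <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' atlas <- expression_atlas(m)
#' dim(atlas$values)
#' @export
expression_atlas <- function(values, sample_meta = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (genes x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  bad <- which(!is.finite(values))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(values))
    stop(sprintf("non-finite expression value for gene '%s' in sample '%s'",
                 rownames(values)[i[1]], colnames(values)[i[2]]))
  }
  if (any(values < 0)) {
    i <- arrayInd(which(values < 0)[1], dim(values))
    stop(sprintf("negative expression value for gene '%s' in sample '%s'",
                 rownames(values)[i[1]], colnames(values)[i[2]]))
  }
  if (!is.null(sample_meta)) {
    sample_meta <- as.data.frame(sample_meta)
    if (!"sample" %in% names(sample_meta))
      stop("`sample_meta` must have a 'sample' column")
    if (!setequal(sample_meta$sample, colnames(values)))
      stop("`sample_meta` samples do not match atlas sample ids")
    sample_meta <- sample_meta[match(colnames(values), sample_meta$sample), ,
                               drop = FALSE]
    rownames(sample_meta) <- NULL
  }
  structure(list(values = values, sample_meta = sample_meta),
            class = "expression_atlas")
}

#' @export
print.expression_atlas <- function(x, ...) {
  cat(sprintf("expression_atlas: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$sample_meta))
    cat("sample metadata columns:",
        paste(setdiff(names(x$sample_meta), "sample"), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_atlas <- function(x) dim(x$values)
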