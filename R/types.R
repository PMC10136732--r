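#' Count matrix with per-sample metadata
#'
#' Bundles a nonnegative integer splice-variant-by-sample count matrix with
#' the per-sample metadata the downstream analyses need: a binary class
#' label (`cancer` / `control`), a cohort tag, and a collection site.
#'
#' @param counts integer matrix, variants in rows, samples in columns; both
#'   dimensions must carry unique names.
#' @param meta data.frame with columns `sample_id`, `label`, `cohort`,
#'   `site`; one row per column of `counts`, matched by `sample_id`.
#' @return An object of class `tep_counts`: a list with elements `counts`
#'   and `meta` (meta rows ordered as the count columns).
#' @export
tep_counts <- function(counts, meta) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop_field("counts", "must be a numeric matrix")
  if (any(counts < 0) || any(counts != round(counts)))
    stop_field("counts", "must contain nonnegative integers")
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop_field("counts", "rownames (variant ids) must be present and unique")
  if (is.null(colnames(counts)) || anyDuplicated(colnames(counts)))
    stop_field("counts", "colnames (sample ids) must be present and unique")
  req <- c("sample_id", "label", "cohort", "site")
  if (!is.data.frame(meta) || !all(req %in% names(meta)))
    stop_field("meta", paste("must be a data.frame with columns",
                             paste(req, collapse = ", ")))
  if (!setequal(meta$sample_id, colnames(counts)))
    stop_field("meta", "sample_id set must equal count matrix columns")
  if (!all(meta$label %in% c("cancer", "control")))
    stop_field("meta", "label must be 'cancer' or 'control'")
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(counts = counts, meta = meta), class = "tep_counts")
}

#' @export
print.tep_counts <- function(x, ...) {
  cat(sprintf("<tep_counts> %d variants x %d samples (%d cancer / %d control; %d sites)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$meta$label == "cancer"), sum(x$meta$label == "control"),
              length(unique(x$meta$site))))
  invisible(x)
}

#' @export
dim.tep_counts <- function(x) dim(x$counts)

#' Normalized expression matrix with per-sample metadata
#'
#' Real-valued feature-by-sample expression (typically the output of
#' [vst_transform()]), carrying the same metadata as [tep_counts()].
#'
#' @param values real matrix, features in rows, samples in columns, with
#'   unique row and column names.
#' @param meta per-sample metadata as for [tep_counts()].
#' @return An object of class `tep_expr`.
#' @export
tep_expr <- function(values, meta) {
  if (!is.matrix(values) || !is.numeric(values) || any(!is.finite(values)))
    stop_field("values", "must be a finite numeric matrix")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop_field("values", "rownames (feature ids) must be present and unique")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop_field("values", "colnames (sample ids) must be present and unique")
  if (!setequal(meta$sample_id, colnames(values)))
    stop_field("meta", "sample_id set must equal expression columns")
  meta <- meta[match(colnames(values), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(values = values, meta = meta), class = "tep_expr")
}

#' @export
print.tep_expr <- function(x, ...) {
  cat(sprintf("<tep_expr> %d features x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.tep_expr <- function(x) dim(x$values)

#' Subset a count or expression object by sample id
#'
#' @param x a [tep_counts()] or [tep_expr()].
#' @param ids sample ids to keep, in the requested order.
#' @return object of the same class restricted to `ids`.
#' @export
subset_samples <- function(x, ids) {
  slot <- if (inherits(x, "tep_counts")) "counts" else "values"
  miss <- setdiff(ids, colnames(x[[slot]]))
  if (length(miss))
    stop("unknown sample ids: ", paste(head(miss, 5), collapse = ", "),
         call. = FALSE)
  x[[slot]] <- x[[slot]][, ids, drop = FALSE]
  x$meta <- x$meta[match(ids, x$meta$sample_id), , drop = FALSE]
  rownames(x$meta) <- NULL
  x
}

#' Named label vector of a count or expression object
#'
#' @param x a [tep_counts()] or [tep_expr()].
#' @return character vector (`cancer`/`control`) named by sample id.
#' @export
sample_labels <- function(x) setNames(x$meta$label, x$meta$sample_id)
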