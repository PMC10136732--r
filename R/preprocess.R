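#' Quality-control filter on total reads per sample
#'
#' Excludes samples whose total read count falls below a threshold. The
#' comparison is strict: a sample with exactly `min_total` reads is
#' retained. Variant set and relative sample order are unchanged.
#'
#' @param x a [tep_counts()].
#' @param min_total minimum total reads; default 100,000.
#' @return filtered [tep_counts()].
#' @export
qc_filter <- function(x, min_total = 100000) {
  stopifnot(inherits(x, "tep_counts"))
  totals <- colSums(x$counts)
  keep <- colnames(x$counts)[totals >= min_total]
  if (length(keep) == 0L)
    stop("qc_filter removed every sample (max total = ",
         max(totals), " < ", min_total, ")", call. = FALSE)
  subset_samples(x, keep)
}

#' Keep only variants annotated with status "known"
#'
#' Variants absent from the annotation table are dropped along with
#' variants whose status is not `known`.
#'
#' @param x a [tep_counts()].
#' @param annot annotation data.frame (`variant_id`, `gene_name`,
#'   `status`, `level`).
#' @return filtered [tep_counts()].
#' @export
filter_known <- function(x, annot) {
  stopifnot(inherits(x, "tep_counts"))
  known <- annot$variant_id[annot$status == "known"]
  keep <- rownames(x$counts) %in% known
  x$counts <- x$counts[keep, , drop = FALSE]
  x
}

#' Deduplicate variants mapping to one gene name
#'
#' When several variant ids share a gene name, the id with the smallest
#' annotation level is kept (Level 1 wins over Level 2). Among equal
#' levels the id with the larger total count is kept; a tie on totals
#' falls to the lexicographically smaller id. Surviving features are
#' relabeled from variant id to gene name.
#'
#' @param x a [tep_counts()] whose variants are all present in `annot`.
#' @param annot annotation data.frame.
#' @return [tep_counts()] with at most one feature per gene, rownames =
#'   gene names.
#' @export
dedup_by_level <- function(x, annot) {
  stopifnot(inherits(x, "tep_counts"))
  ids <- rownames(x$counts)
  hit <- match(ids, annot$variant_id)
  if (anyNA(hit))
    stop("variants missing from annotation: ",
         paste(head(ids[is.na(hit)], 5), collapse = ", "), call. = FALSE)
  df <- data.frame(variant_id = ids, gene = annot$gene_name[hit],
                   level = annot$level[hit], total = rowSums(x$counts),
                   stringsAsFactors = FALSE)
  # order so that the preferred id per gene comes first, then take firsts
  ord <- order(df$gene, df$level, -df$total, df$variant_id)
  df <- df[ord, , drop = FALSE]
  keep <- df[!duplicated(df$gene), , drop = FALSE]
  keep <- keep[match(ids[ids %in% keep$variant_id], keep$variant_id), ]
  x$counts <- x$counts[keep$variant_id, , drop = FALSE]
  rownames(x$counts) <- keep$gene
  x
}

#' Median-of-ratios size factors
#'
#' The per-sample normalization constants of the standard RNA-seq
#' median-of-ratios method: for each variant with a strictly positive
#' geometric mean across samples, form the ratio of the sample's count to
#' that geometric mean; the sample's size factor is the median of those
#' ratios. If no variant is positive in every sample, a fallback reference
#' is computed from variants with at least 90% nonzero samples, using the
#' geometric mean of their positive counts and medians over positive
#' ratios only.
#'
#' @param x a [tep_counts()] or a count matrix (variants x samples).
#' @return named positive numeric vector of per-sample size factors.
#' @export
size_factors <- function(x) {
  k <- if (inherits(x, "tep_counts")) x$counts else x
  stopifnot(is.matrix(k))
  all_pos <- rowSums(k == 0) == 0L
  if (any(all_pos)) {
    ref <- apply(k[all_pos, , drop = FALSE], 1L, geomean)
    s <- apply(k[all_pos, , drop = FALSE] / ref, 2L, median)
  } else {
    frac_pos <- rowMeans(k > 0)
    use <- frac_pos >= 0.9
    if (!any(use))
      stop("no variant expressed in >= 90% of samples; cannot form a ",
           "pseudo-reference for size factors", call. = FALSE)
    kk <- k[use, , drop = FALSE]
    ref <- apply(kk, 1L, function(v) geomean(v[v > 0]))
    s <- vapply(seq_len(ncol(kk)), function(j) {
      r <- kk[, j] / ref
      r <- r[kk[, j] > 0]
      if (!length(r))
        stop("sample ", colnames(kk)[j], " has no positive count among ",
             "reference variants", call. = FALSE)
      median(r)
    }, numeric(1))
    names(s) <- colnames(kk)
  }
  if (any(s <= 0)) stop("non-positive size factor computed", call. = FALSE)
  s
}

#' Pooled method-of-moments dispersion estimate
#'
#' For size-factor-normalized counts, the per-variant moment estimate of
#' the negative-binomial dispersion is `(var - mean) / mean^2`, floored at
#' zero; the pooled estimate is the median over variants, floored at 1e-4.
#'
#' @param x a [tep_counts()] or count matrix.
#' @param s size factors from [size_factors()].
#' @return single positive dispersion estimate.
#' @export
estimate_dispersion <- function(x, s) {
  k <- if (inherits(x, "tep_counts")) x$counts else x
  stopifnot(ncol(k) >= 2L, length(s) == ncol(k))
  q <- sweep(k, 2L, s, "/")
  m <- rowMeans(q)
  v <- apply(q, 1L, var)
  ok <- m > 0
  a <- pmax(0, (v[ok] - m[ok]) / m[ok]^2)
  max(median(a), 1e-4)
}

#' Variance-stabilizing transform for negative-binomial counts
#'
#' Applies the closed-form common-dispersion VST
#' `(2 * asinh(sqrt(alpha * q)) - log(4 * alpha)) / log(2)` to size-factor
#' normalized counts `q = k / s`. The transform is monotone increasing,
#' converges to `log2(q)` for large `q`, and takes its finite minimum
#' `-log2(4 * alpha)` at `q = 0`.
#'
#' @param x a [tep_counts()] or count matrix.
#' @param s size factors.
#' @param alpha common dispersion, > 0 (see [estimate_dispersion()]).
#' @return a [tep_expr()] (or plain matrix when `x` is a matrix).
#' @export
vst_transform <- function(x, s, alpha) {
  alpha <- check_real(alpha, "alpha", min = .Machine$double.eps)
  k <- if (inherits(x, "tep_counts")) x$counts else x
  stopifnot(length(s) == ncol(k), all(s > 0))
  q <- sweep(k, 2L, s, "/")
  v <- (2 * asinh(sqrt(alpha * q)) - log(4 * alpha)) / log(2)
  if (inherits(x, "tep_counts")) tep_expr(v, x$meta) else v
}

#' Full preprocessing pipeline
#'
#' Composes the fixed preprocessing order: total-read QC, known-status
#' filter, level-based deduplication, size factors, pooled dispersion,
#' and the variance-stabilizing transform.
#'
#' @param x a [tep_counts()].
#' @param annot annotation data.frame.
#' @param min_total QC threshold (default 100,000 reads).
#' @return list with `expr` ([tep_expr()], features = gene names),
#'   `size_factors`, `dispersion`, and `counts` (the filtered counts).
#' @export
preprocess_counts <- function(x, annot, min_total = 100000) {
  x <- qc_filter(x, min_total)
  x <- filter_known(x, annot)
  x <- dedup_by_level(x, annot)
  s <- size_factors(x)
  alpha <- estimate_dispersion(x, s)
  expr <- vst_transform(x, s, alpha)
  list(expr = expr, size_factors = s, dispersion = alpha, counts = x)
}
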