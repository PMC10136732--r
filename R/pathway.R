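#' The eight KEGG-style pathway group names
#'
#' Fixed vocabulary of pathway groups, in canonical order: metabolism,
#' genetic information processing, environmental information processing,
#' cellular processes, immune system, other organismal systems, cancer,
#' other human diseases.
#'
#' @return character vector of length 8.
#' @export
kegg_groups <- function() {
  c("metabolism", "genetic_information_processing",
    "environmental_information_processing", "cellular_processes",
    "immune_system", "other_organismal_systems", "cancer",
    "other_human_diseases")
}

#' Pathway database
#'
#' An ordered collection of pathways, each with a unique id, one of the
#' eight group tags, and an ordered non-empty member gene list (duplicate
#' members collapsed to first occurrence).
#'
#' @param pathway_id character vector of unique pathway ids.
#' @param group character vector of group tags (see [kegg_groups()]).
#' @param members list of character vectors of member gene names.
#' @return object of class `pathway_db`.
#' @export
pathway_db <- function(pathway_id, group, members) {
  if (anyDuplicated(pathway_id))
    stop_field("pathway_id", "must be unique")
  if (!all(group %in% kegg_groups()))
    stop_field("group", paste("unknown group tag:",
                              paste(setdiff(group, kegg_groups()), collapse = ", ")))
  if (length(pathway_id) != length(group) || length(group) != length(members))
    stop_field("members", "pathway_id, group, members must have equal length")
  members <- lapply(members, function(m) m[!duplicated(m)])
  if (any(lengths(members) == 0L))
    stop_field("members", "member lists must be non-empty")
  structure(list(pathway_id = as.character(pathway_id),
                 group = as.character(group),
                 members = members),
            class = "pathway_db")
}

#' @export
print.pathway_db <- function(x, ...) {
  cat(sprintf("<pathway_db> %d pathways, %d groups, %d member entries (%d distinct genes)\n",
              length(x$pathway_id), length(unique(x$group)),
              sum(lengths(x$members)), length(unique(unlist(x$members)))))
  invisible(x)
}

#' @export
length.pathway_db <- function(x) length(x$pathway_id)

#' Read a pathway database from a GMT file
#'
#' One pathway per line: field 1 = pathway id, field 2 = group tag,
#' fields 3+ = member genes, tab-separated. Malformed lines (fewer than 3
#' fields), unknown group tags and duplicate pathway ids raise a parse
#' error naming the line.
#'
#' @param path GMT file path.
#' @return a [pathway_db()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("GMT file has no records: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(fields)) {
    if (length(fields[[i]]) < 3L)
      stop(sprintf("GMT parse error at line %d: fewer than 3 fields", i),
           call. = FALSE)
    if (!fields[[i]][2] %in% kegg_groups())
      stop(sprintf("GMT parse error at line %d: unknown group tag '%s'",
                   i, fields[[i]][2]), call. = FALSE)
  }
  ids <- vapply(fields, `[`, "", 1L)
  if (anyDuplicated(ids))
    stop(sprintf("GMT parse error at line %d: duplicate pathway id '%s'",
                 which(duplicated(ids))[1], ids[duplicated(ids)][1]),
         call. = FALSE)
  pathway_db(ids,
             vapply(fields, `[`, "", 2L),
             lapply(fields, function(f) f[-(1:2)]))
}

#' Write a pathway database to a GMT file
#'
#' @param db a [pathway_db()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(db, path) {
  stopifnot(inherits(db, "pathway_db"))
  lines <- vapply(seq_along(db$pathway_id), function(i) {
    paste(c(db$pathway_id[i], db$group[i], db$members[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Subset a pathway database to one group
#'
#' @param db a [pathway_db()].
#' @param group one of [kegg_groups()].
#' @return a [pathway_db()] with only that group's pathways, order
#'   preserved.
#' @export
subset_group <- function(db, group) {
  stopifnot(inherits(db, "pathway_db"))
  if (!group %in% kegg_groups())
    stop_field("group", paste("unknown group tag:", group))
  keep <- db$group == group
  if (!any(keep))
    stop("group '", group, "' absent from pathway database", call. = FALSE)
  pathway_db(db$pathway_id[keep], db$group[keep], db$members[keep])
}

#' Pathway-based feature preselection
#'
#' Returns the union of pathway member genes that are measured in the
#' expression matrix, ordered by first occurrence across pathways.
#' Measured genes belonging to no pathway are excluded; pathway members
#' absent from the expression data (unmapped ids) are dropped.
#'
#' @param db a [pathway_db()].
#' @param expr a [tep_expr()] (features = gene names).
#' @return character vector of preselected feature names.
#' @export
preselect_features <- function(db, expr) {
  stopifnot(inherits(db, "pathway_db"), inherits(expr, "tep_expr"))
  all_members <- unlist(db$members, use.names = FALSE)
  sel <- all_members[!duplicated(all_members)]
  sel <- sel[sel %in% rownames(expr$values)]
  if (!length(sel))
    stop("no pathway member gene is present in the expression matrix",
         call. = FALSE)
  sel
}

# Canonical row order: group-major in kegg_groups() order, file order
# within group.
db_row_order <- function(db) {
  order(match(db$group, kegg_groups()), seq_along(db$pathway_id))
}

#' Build per-sample pathway-grid images
#'
#' Encodes each sample's expression profile as a 2D array with one row
#' per pathway (rows grouped by pathway group in canonical order) and one
#' column per member-gene slot. Cell (p, k) holds the scaled expression
#' of the k-th member gene of pathway p; rows are right-padded with 0 to
#' the maximum pathway width. Pixel scaling is global min-max over the
#' training samples mapped to \[0, 1\] (non-training values are clipped
#' into the range); a gene in m pathways appears in m cells with equal
#' value.
#'
#' @param expr a [tep_expr()].
#' @param db a [pathway_db()]; members absent from `expr` are dropped
#'   (unmapped-ID removal) before layout.
#' @param train_ids sample ids on which the min-max scaling constants are
#'   computed; defaults to all samples.
#' @return object of class `tep_images`: list with `values` (array
#'   n_pathways x width x n_samples), `cell_gene` (character matrix, NA =
#'   padding), `pathway_id`, `group`, `scale` (min, max), `sample_ids`,
#'   `meta`.
#' @export
build_images <- function(expr, db, train_ids = NULL) {
  stopifnot(inherits(expr, "tep_expr"), inherits(db, "pathway_db"))
  measured <- rownames(expr$values)
  members <- lapply(db$members, function(m) m[m %in% measured])
  keep <- lengths(members) > 0L
  if (!any(keep))
    stop("no pathway retains a measured member gene", call. = FALSE)
  sub <- pathway_db(db$pathway_id[keep], db$group[keep], members[keep])
  ord <- db_row_order(sub)
  ids <- sub$pathway_id[ord]
  grp <- sub$group[ord]
  mem <- sub$members[ord]
  width <- max(lengths(mem))
  np <- length(ids)
  cell_gene <- matrix(NA_character_, np, width,
                      dimnames = list(ids, NULL))
  for (i in seq_len(np)) cell_gene[i, seq_along(mem[[i]])] <- mem[[i]]

  train_ids <- train_ids %||% colnames(expr$values)
  genes <- unique(unlist(mem, use.names = FALSE))
  tr <- expr$values[genes, train_ids, drop = FALSE]
  mn <- min(tr); mx <- max(tr)
  if (mx <= mn) mx <- mn + 1     # constant training expression: map to 0
  scaled <- (expr$values[genes, , drop = FALSE] - mn) / (mx - mn)
  scaled[scaled < 0] <- 0
  scaled[scaled > 1] <- 1

  n <- ncol(expr$values)
  vals <- array(0, dim = c(np, width, n),
                dimnames = list(ids, NULL, colnames(expr$values)))
  flat_idx <- which(!is.na(cell_gene))
  gene_idx <- match(cell_gene[flat_idx], genes)
  for (j in seq_len(n))
    vals[, , j][flat_idx] <- scaled[gene_idx, j]

  structure(list(values = vals, cell_gene = cell_gene, pathway_id = ids,
                 group = grp, scale = c(min = mn, max = mx),
                 sample_ids = colnames(expr$values), meta = expr$meta),
            class = "tep_images")
}

#' @export
print.tep_images <- function(x, ...) {
  cat(sprintf("<tep_images> %d samples of %d x %d (pathways x slots), %d mapped cells\n",
              dim(x$values)[3], dim(x$values)[1], dim(x$values)[2],
              sum(!is.na(x$cell_gene))))
  invisible(x)
}

#' Apply one random row or column permutation to all images
#'
#' Draws a single seed-determined permutation and applies it to every
#' sample's image (and to the cell-to-gene map), preserving the value
#' multiset of each image.
#'
#' @param imgs a `tep_images` object from [build_images()].
#' @param axis `"rows"` or `"columns"`.
#' @param seed integer seed for the permutation draw.
#' @return permuted `tep_images`.
#' @export
permute_images <- function(imgs, axis = c("rows", "columns"), seed) {
  stopifnot(inherits(imgs, "tep_images"))
  axis <- match.arg(axis)
  n <- if (axis == "rows") dim(imgs$values)[1] else dim(imgs$values)[2]
  perm <- with_seed(seed, sample.int(n))
  if (axis == "rows") {
    imgs$values <- imgs$values[perm, , , drop = FALSE]
    imgs$cell_gene <- imgs$cell_gene[perm, , drop = FALSE]
    imgs$pathway_id <- imgs$pathway_id[perm]
    imgs$group <- imgs$group[perm]
  } else {
    imgs$values <- imgs$values[, perm, , drop = FALSE]
    imgs$cell_gene <- imgs$cell_gene[, perm, drop = FALSE]
  }
  imgs
}

#' Canonical flat feature matrix from pathway-grid images
#'
#' Deduplicates the cell-to-gene map (a gene in several pathways appears
#' once) and returns a samples x genes matrix with columns in
#' lexicographic gene order — a canonical form invariant to any row or
#' column permutation of the images.
#'
#' @param imgs a `tep_images` object.
#' @return numeric matrix, samples in rows, genes in columns.
#' @export
images_to_features <- function(imgs) {
  stopifnot(inherits(imgs, "tep_images"))
  cells <- which(!is.na(imgs$cell_gene))
  genes <- imgs$cell_gene[cells]
  first <- cells[!duplicated(genes)]
  gname <- genes[!duplicated(genes)]
  ord <- order(gname)
  first <- first[ord]; gname <- gname[ord]
  n <- dim(imgs$values)[3]
  out <- vapply(seq_len(n), function(j) imgs$values[, , j][first],
                numeric(length(first)))
  out <- t(out)
  dimnames(out) <- list(imgs$sample_ids, gname)
  out
}

#' Samples-by-features matrix from an expression object
#'
#' Transposes the expression matrix restricted to `features` (all
#' features if omitted), columns sorted lexicographically — the canonical
#' input for the boosting classifier.
#'
#' @param expr a [tep_expr()].
#' @param features feature names to keep.
#' @return numeric matrix, samples in rows.
#' @export
feature_matrix <- function(expr, features = NULL) {
  stopifnot(inherits(expr, "tep_expr"))
  features <- features %||% rownames(expr$values)
  miss <- setdiff(features, rownames(expr$values))
  if (length(miss))
    stop("features absent from expression matrix: ",
         paste(head(miss, 5), collapse = ", "), call. = FALSE)
  t(expr$values[sort(features), , drop = FALSE])
}
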