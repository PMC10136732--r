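# Small in-code fixtures shared across test files.

toy_counts <- function(m, sample_prefix = "S", variant_prefix = "V",
                       labels = NULL, site = NULL) {
  m <- as.matrix(m)
  rownames(m) <- paste0(variant_prefix, seq_len(nrow(m)))
  colnames(m) <- paste0(sample_prefix, seq_len(ncol(m)))
  n <- ncol(m)
  labels <- labels %||% rep(c("cancer", "control"), length.out = n)
  meta <- data.frame(sample_id = colnames(m), label = labels,
                     cohort = "cohort1",
                     site = site %||% rep("site1", n),
                     stringsAsFactors = FALSE)
  tep_counts(m, meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# An all-"known", duplicate-free annotation covering a count object.
full_annotation <- function(x) {
  ids <- rownames(x$counts)
  data.frame(variant_id = ids, gene_name = sub("^V", "G", ids),
             status = "known", level = 2L, stringsAsFactors = FALSE)
}

# A small expression object built directly from a matrix.
toy_expr <- function(m, labels = NULL) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("S", seq_len(ncol(m)))
  n <- ncol(m)
  meta <- data.frame(sample_id = colnames(m),
                     label = labels %||% rep(c("cancer", "control"),
                                             length.out = n),
                     cohort = "cohort1", site = "site1",
                     stringsAsFactors = FALSE)
  tep_expr(m, meta)
}

# Small pathway DB over genes g1..gk.
toy_db <- function(members, groups = NULL) {
  n <- length(members)
  pathway_db(paste0("P", seq_len(n)),
             groups %||% rep_len(kegg_groups(), n),
             members)
}

# Quick small synthetic study for experiment tests.
small_study <- function(seed = 11, ...) {
  cfg <- synthetic_config(n_cancer = 120, n_control = 80, n_variants = 400,
                          n_informative = 40, n_pathways = 16,
                          pathway_size_range = c(4, 8),
                          library_size_log_sd = 0.1, seed = seed, ...)
  st <- simulate_study(cfg, fraction_duplicates = 0,
                       fraction_non_known = 0)
  st$prep <- preprocess_counts(st$counts, st$annot, min_total = 0)
  st$split <- stratified_split(sample_labels(st$prep$expr), seed = seed)
  st
}

fast_search <- function(seed = 1, n = 4)
  search_config(n_settings = n, repeats_per_setting = 1,
                n_estimators = c(30L, 120L), seed = seed)

# O(n^2) pair-counting AUC oracle (ties count one half).
auc_pairs <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}
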