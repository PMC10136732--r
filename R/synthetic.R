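#' Configuration for the synthetic TEP count generator
#'
#' Describes a synthetic study: cohort sizes, a planted set of informative
#' splice variants with class-dependent fold changes, negative-binomial
#' noise, log-normal library sizes, multi-site collection with optional
#' per-site effects, and a pathway database layered on top. The defaults
#' emulate the structure of a multi-center platelet RNA-seq case/control
#' study at a scale convenient for testing: 800 samples with roughly the
#' 63/37 class imbalance of the real cohorts, 2,000 splice variants of
#' which 100 carry a 2-3x class fold change, and dispersion 0.2.
#'
#' @param n_cancer,n_control samples per class.
#' @param n_variants total splice variants.
#' @param n_informative variants carrying a class-dependent fold change.
#' @param fold_change_range (low, high) multiplicative fold-change
#'   magnitudes, low >= 1; the direction (up/down in cancer) is drawn per
#'   variant with equal probability.
#' @param dispersion negative-binomial dispersion alpha (variance
#'   mu + alpha * mu^2); 0 gives Poisson counts.
#' @param library_size_log_mean,library_size_log_sd log-normal parameters
#'   of the per-sample library-size factor.
#' @param n_sites number of collection sites.
#' @param site_effect_sd log-scale SD of the per-site multiplicative effect
#'   on the site-affected variant subset; 0 disables site effects.
#' @param frac_site_affected fraction of variants subject to site effects.
#' @param confound_site_with_label if `TRUE`, site membership is skewed by
#'   class (cancer samples predominantly drawn from the first half of the
#'   sites), planting a label-site confounder that transfer experiments
#'   should detect.
#' @param n_pathways,pathway_size_range pathway database shape.
#' @param frac_informative_in_pathways fraction of informative variants
#'   whose genes are guaranteed pathway members; the remainder are
#'   guaranteed absent from every pathway.
#' @param seed integer seed governing all draws.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cancer = 500L, n_control = 300L,
                             n_variants = 2000L, n_informative = 100L,
                             fold_change_range = c(2, 3), dispersion = 0.2,
                             library_size_log_mean = 0.25,
                             library_size_log_sd = 0.3,
                             n_sites = 4L, site_effect_sd = 0,
                             frac_site_affected = 0.1,
                             confound_site_with_label = FALSE,
                             n_pathways = 40L,
                             pathway_size_range = c(5L, 15L),
                             frac_informative_in_pathways = 0.8,
                             seed = 1L) {
  cfg <- list(
    n_cancer = check_count(n_cancer, "n_cancer"),
    n_control = check_count(n_control, "n_control"),
    n_variants = check_count(n_variants, "n_variants"),
    n_informative = check_count(n_informative, "n_informative", min = 0L),
    fold_change_range = check_pair(fold_change_range, "fold_change_range", min = 1),
    dispersion = check_real(dispersion, "dispersion", min = 0),
    library_size_log_mean = check_real(library_size_log_mean, "library_size_log_mean"),
    library_size_log_sd = check_real(library_size_log_sd, "library_size_log_sd", min = 0),
    n_sites = check_count(n_sites, "n_sites"),
    site_effect_sd = check_real(site_effect_sd, "site_effect_sd", min = 0),
    frac_site_affected = check_real(frac_site_affected, "frac_site_affected", 0, 1),
    confound_site_with_label = isTRUE(confound_site_with_label),
    n_pathways = check_count(n_pathways, "n_pathways"),
    pathway_size_range = check_pair(pathway_size_range, "pathway_size_range", min = 1),
    frac_informative_in_pathways =
      check_real(frac_informative_in_pathways, "frac_informative_in_pathways", 0, 1),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (cfg$n_informative > cfg$n_variants)
    stop_field("n_informative", "cannot exceed n_variants")
  if (cfg$pathway_size_range[2] > cfg$n_variants)
    stop_field("pathway_size_range", "cannot exceed n_variants")
  structure(cfg, class = "synthetic_config")
}

# Base-expression log-normal shape: fixed internal constants chosen so that
# with 2,000 variants the typical library lands around the 100,000-read QC
# scale (meanlog log(20), sdlog 1.5 => mean count ~ 62 per variant).
.base_expr_meanlog <- log(20)
.base_expr_sdlog <- 1.5

variant_ids <- function(n) sprintf("VAR%05d", seq_len(n))

#' Simulate a splice-variant count matrix with planted class signal
#'
#' Draws counts for variant i, sample j as negative binomial with mean
#' `s_j * q_i * f_i^z_j * b_site(j),i`: `s_j` a log-normal library-size
#' factor, `q_i` a log-normal base expression level, `f_i` the planted
#' fold change (1 for non-informative variants, direction random), `z_j`
#' the binary cancer label, and `b` a per-site multiplicative effect on
#' the site-affected variant subset. Fully reproducible from
#' `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return A list with `counts` (a [tep_counts()]) and `truth`, the ground
#'   truth: `informative_variants`, `fold_change` (the applied multiplier
#'   per informative variant), `fold_change_magnitude`, `direction`,
#'   `site_assignment`, `site_affected_variants`, and the per-site effect
#'   matrix `site_effects` (sites x affected variants).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    nv <- config$n_variants
    n <- config$n_cancer + config$n_control
    vids <- variant_ids(nv)
    sids <- sprintf("S%04d", seq_len(n))
    label <- c(rep("cancer", config$n_cancer), rep("control", config$n_control))

    q <- rlnorm(nv, .base_expr_meanlog, .base_expr_sdlog)
    s <- rlnorm(n, config$library_size_log_mean, config$library_size_log_sd)

    info <- sort(sample(nv, config$n_informative))
    fc_mag <- runif(config$n_informative, config$fold_change_range[1],
                    config$fold_change_range[2])
    dir <- sample(c(1, -1), config$n_informative, replace = TRUE)
    f <- rep(1, nv)
    f[info] <- fc_mag^dir

    site <- assign_sites(label, config)
    affected <- sort(sample(nv, round(config$frac_site_affected * nv)))
    b <- matrix(1, nrow = config$n_sites, ncol = length(affected))
    if (config$site_effect_sd > 0 && length(affected))
      b[] <- exp(rnorm(length(b), 0, config$site_effect_sd))

    mu <- outer(q, s)                      # nv x n
    z <- as.integer(label == "cancer")
    mu <- mu * (f %o% rep(1, n))^rep(z, each = nv)
    if (length(affected))
      mu[affected, ] <- mu[affected, ] * t(b[site, , drop = FALSE])

    counts <- matrix(0L, nv, n, dimnames = list(vids, sids))
    draw <- if (config$dispersion == 0) {
      rpois(length(mu), lambda = mu)
    } else {
      rnbinom(length(mu), size = 1 / config$dispersion, mu = mu)
    }
    stopifnot(max(draw) < .Machine$integer.max)
    counts[] <- as.integer(draw)

    meta <- data.frame(
      sample_id = sids, label = label,
      cohort = paste0("cohort", 1L + (site - 1L) %/% 2L),
      site = paste0("site", site),
      stringsAsFactors = FALSE
    )
    truth <- list(
      informative_variants = vids[info],
      fold_change = setNames(f[info], vids[info]),
      fold_change_magnitude = setNames(fc_mag, vids[info]),
      direction = setNames(dir, vids[info]),
      site_assignment = setNames(paste0("site", site), sids),
      site_affected_variants = vids[affected],
      site_effects = `dimnames<-`(b, list(paste0("site", seq_len(config$n_sites)),
                                          vids[affected])),
      base_expression = setNames(q, vids),
      library_size = setNames(s, sids)
    )
    list(counts = tep_counts(counts, meta), truth = truth)
  })
}

# Site assignment: uniform and label-independent unless the confound flag is
# set, in which case cancer samples come 90% from the first half of the
# sites and controls 90% from the second half.
assign_sites <- function(label, config) {
  k <- config$n_sites
  n <- length(label)
  if (!config$confound_site_with_label || k < 2L)
    return(sample.int(k, n, replace = TRUE))
  first <- seq_len(max(1L, k %/% 2L))
  second <- setdiff(seq_len(k), first)
  p_cancer <- rep(0.1 / length(second), k)
  p_cancer[first] <- 0.9 / length(first)
  p_control <- rep(0.1 / length(first), k)
  p_control[second] <- 0.9 / length(second)
  site <- integer(n)
  site[label == "cancer"] <- sample.int(k, sum(label == "cancer"),
                                        replace = TRUE, prob = p_cancer)
  site[label == "control"] <- sample.int(k, sum(label == "control"),
                                         replace = TRUE, prob = p_control)
  site
}

#' Generate a synthetic Gencode-style annotation table
#'
#' Every variant id of the configured matrix receives a gene name, a status
#' and a level. A configurable fraction of gene names is shared by two
#' variant ids at (usually) different levels, and a configurable fraction
#' of variants carries a status other than `known`, so both the
#' known-status filter and the level-based deduplication are exercised.
#'
#' @param config a [synthetic_config()].
#' @param fraction_duplicates fraction of `n_variants` that becomes
#'   duplicated gene names (each such gene carries exactly two variant ids).
#' @param fraction_non_known fraction of variants with status `novel` or
#'   `putative`.
#' @param fraction_equal_level among duplicated genes, fraction whose two
#'   ids share the same level (exercising the total-count tie-break).
#' @return data.frame with columns `variant_id`, `gene_name`, `status`,
#'   `level`.
#' @export
generate_annotation <- function(config, fraction_duplicates = 0.1,
                                fraction_non_known = 0.1,
                                fraction_equal_level = 0.2) {
  stopifnot(inherits(config, "synthetic_config"))
  fraction_duplicates <- check_real(fraction_duplicates, "fraction_duplicates", 0, 0.5)
  fraction_non_known <- check_real(fraction_non_known, "fraction_non_known", 0, 1)
  with_seed(config$seed + 1L, {
    nv <- config$n_variants
    vids <- variant_ids(nv)
    n_dup <- round(fraction_duplicates * nv)
    n_genes <- nv - n_dup
    genes <- sprintf("GENE%05d", seq_len(n_genes))
    # first 2*n_dup variants pair up on the first n_dup genes
    gene_of <- c(rep(genes[seq_len(n_dup)], each = 2),
                 genes[seq.int(n_dup + 1L, length.out = nv - 2L * n_dup)])
    level <- rep(2L, nv)
    if (n_dup > 0) {
      eq <- runif(n_dup) < fraction_equal_level
      first <- seq(1L, 2L * n_dup, by = 2L)
      level[first] <- ifelse(eq, 2L, 1L)
      level[first + 1L] <- 2L
    }
    status <- rep("known", nv)
    n_nk <- round(fraction_non_known * nv)
    if (n_nk > 0) {
      idx <- sample(nv, n_nk)
      status[idx] <- sample(c("novel", "putative"), n_nk, replace = TRUE)
    }
    data.frame(variant_id = vids, gene_name = gene_of, status = status,
               level = level, stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic pathway database
#'
#' Builds `n_pathways` gene sets tagged with the eight KEGG-style group
#' names (cycled in order). A fraction `frac_informative_in_pathways` of
#' the planted informative genes is guaranteed pathway membership; the
#' remaining informative genes are guaranteed absent from every pathway,
#' so the benefit of pathway preselection is controllable. A small
#' fraction of unmapped member ids (absent from any expression data) is
#' injected to exercise unmapped-ID removal.
#'
#' @param config a [synthetic_config()].
#' @param annot annotation table from [generate_annotation()].
#' @param truth ground truth from [simulate_counts()].
#' @param frac_unmapped fraction of pathways receiving one synthetic
#'   unmapped member id.
#' @return A [pathway_db()].
#' @export
generate_pathway_db <- function(config, annot, truth, frac_unmapped = 0.1) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed + 2L, {
    info_genes <- unique(annot$gene_name[match(truth$informative_variants,
                                               annot$variant_id)])
    n_in <- round(config$frac_informative_in_pathways * length(info_genes))
    in_genes <- sample(info_genes, n_in)
    out_genes <- setdiff(info_genes, in_genes)
    pool <- setdiff(unique(annot$gene_name), out_genes)
    np <- config$n_pathways
    sizes <- sample(seq(config$pathway_size_range[1], config$pathway_size_range[2]),
                    np, replace = TRUE)
    members <- lapply(sizes, function(k) sample(pool, min(k, length(pool))))
    # guarantee membership of the selected informative genes
    if (length(in_genes)) {
      home <- sample.int(np, length(in_genes), replace = TRUE)
      for (i in seq_along(in_genes)) {
        p <- home[i]
        members[[p]] <- unique(c(members[[p]], in_genes[i]))
      }
    }
    if (frac_unmapped > 0) {
      n_un <- round(frac_unmapped * np)
      if (n_un > 0) {
        idx <- sample.int(np, n_un)
        for (j in seq_along(idx))
          members[[idx[j]]] <- c(members[[idx[j]]], sprintf("UNMAPPED%03d", j))
      }
    }
    pathway_db(pathway_id = sprintf("PATH%03d", seq_len(np)),
               group = rep_len(kegg_groups(), np),
               members = members)
  })
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper running [simulate_counts()], [generate_annotation()]
#' and [generate_pathway_db()] with one config, returning everything the
#' downstream pipeline needs.
#'
#' @param config a [synthetic_config()].
#' @param ... passed to [generate_annotation()].
#' @return list with `counts`, `truth`, `annot`, `db`, `config`.
#' @export
simulate_study <- function(config, ...) {
  sim <- simulate_counts(config)
  annot <- generate_annotation(config, ...)
  db <- generate_pathway_db(config, annot, sim$truth)
  list(counts = sim$counts, truth = sim$truth, annot = annot, db = db,
       config = config)
}

#' Map planted informative variants to gene names
#'
#' After level-based deduplication, features are gene names; recovery
#' checks against the planted truth therefore need the variant-to-gene
#' map.
#'
#' @param truth ground truth from [simulate_counts()].
#' @param annot annotation table.
#' @return character vector of informative gene names.
#' @export
informative_genes <- function(truth, annot) {
  unique(annot$gene_name[match(truth$informative_variants, annot$variant_id)])
}
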