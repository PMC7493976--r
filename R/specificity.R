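#' Reads-per-kilobase-per-million normalization
#'
#' `RPKM = count / (site length in kb x library size in millions)`.
#'
#' @param counts Site x dataset tibble of read counts (first column
#'   `site_id`) or a numeric matrix with site ids as rownames.
#' @param site_lengths Site lengths in bp, in row order.
#' @param library_sizes Per-dataset total mapped reads, in column order.
#' @return A tibble of the same shape as `counts` holding RPKM values.
#' @export
compute_rpkm <- function(counts, site_lengths, library_sizes) {
  m <- if (is.data.frame(counts)) signal_as_matrix(counts) else counts
  stopifnot(length(site_lengths) == nrow(m),
            length(library_sizes) == ncol(m))
  if (any(site_lengths <= 0)) stop("site lengths must be positive", call. = FALSE)
  if (any(library_sizes <= 0)) stop("library sizes must be positive", call. = FALSE)
  rpkm <- m / (site_lengths / 1e3)
  rpkm <- sweep(rpkm, 2, library_sizes / 1e6, "/")
  matrix_as_signal(rpkm)
}

#' Quantile normalization of a signal matrix
#'
#' Every column is rank-transformed to the common reference distribution (the
#' row means of the column-sorted matrix); ties within a column receive the
#' mean of the reference values at the tied ranks. After normalization the
#' sorted values of every column are identical. Delegates to
#' [limma::normalizeQuantiles()].
#'
#' @param mat Site x dataset tibble (first column `site_id`) or numeric
#'   matrix.
#' @return Normalized data in the same representation as the input.
#' @export
quantile_normalize <- function(mat) {
  tab <- is.data.frame(mat)
  m <- if (tab) signal_as_matrix(mat) else mat
  if (ncol(m) < 2L) stop("quantile normalization needs at least 2 columns",
                         call. = FALSE)
  qn <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(qn) <- dimnames(m)
  if (tab) matrix_as_signal(qn) else qn
}

#' Differential binding between two dataset groups
#'
#' Unpaired two-tailed Student's t test with pooled variance per site,
#' Cohen's d (mean difference over pooled SD), log2 fold change of group
#' means (with a 0.01 pseudocount), and Benjamini-Hochberg adjustment across
#' all sites of the run. Zero pooled variance with equal means gives
#' `t = 0, p = 1`; zero pooled variance with unequal means is flagged
#' `degenerate` with `p = 0`.
#'
#' @param mat Normalized site x dataset tibble or matrix.
#' @param group_a,group_b Character vectors of dataset (column) ids; each
#'   needs at least 2 datasets.
#' @param sites Optional subset of site ids to test (BH is applied within the
#'   tested set).
#' @return Tibble `site_id, mean_a, mean_b, t_statistic, df, p_value, fdr,
#'   effect_size, log2_fold_change, degenerate`. The sign of `t` is the sign
#'   of `mean_a - mean_b`.
#' @export
differential_binding <- function(mat, group_a, group_b, sites = NULL) {
  m <- if (is.data.frame(mat)) signal_as_matrix(mat) else mat
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 datasets", call. = FALSE)
  }
  miss <- setdiff(c(group_a, group_b), colnames(m))
  if (length(miss)) stop("dataset id(s) not in matrix: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!is.null(sites)) m <- m[rownames(m) %in% sites, , drop = FALSE]
  a <- m[, group_a, drop = FALSE]
  b <- m[, group_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  mean_a <- rowMeans(a)
  mean_b <- rowMeans(b)
  var_a <- apply(a, 1, stats::var)
  var_b <- apply(b, 1, stats::var)
  df <- na + nb - 2L
  sp2 <- ((na - 1) * var_a + (nb - 1) * var_b) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t_stat <- (mean_a - mean_b) / se
  degenerate <- sp2 == 0 & mean_a != mean_b
  t_stat[sp2 == 0 & mean_a == mean_b] <- 0
  p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  p[sp2 == 0 & mean_a == mean_b] <- 1
  p[degenerate] <- 0
  t_stat[degenerate] <- sign(mean_a - mean_b)[degenerate] * Inf
  d <- (mean_a - mean_b) / sqrt(sp2)
  d[sp2 == 0] <- ifelse(mean_a[sp2 == 0] == mean_b[sp2 == 0], 0,
                        sign(mean_a - mean_b)[sp2 == 0] * Inf)
  tibble::tibble(
    site_id = rownames(m),
    mean_a = unname(mean_a), mean_b = unname(mean_b),
    t_statistic = unname(t_stat), df = df,
    p_value = unname(p),
    fdr = unname(stats::p.adjust(p, method = "BH")),
    effect_size = unname(d),
    log2_fold_change = unname(log2((mean_a + 0.01) / (mean_b + 0.01))),
    degenerate = unname(degenerate)
  )
}

#' Call cancer-specific lost and gained CTCF sites
#'
#' Applies the two conjunctive criteria lists to every high-confidence atlas
#' site for one cancer type.
#'
#' A site is **lost** iff all of: occupancy frequency <= 0.2 in the cancer
#' datasets; frequency >= 0.7 over all datasets; frequency >= 0.5 with score
#' >= 2 in the matched normal datasets; binding level lower in cancer than in
#' all other datasets (t statistic < 0); lower than in matched normal
#' (t < 0); and mean cancer RPKM < 5.
#'
#' A site is **gained** iff all of: cancer frequency >= 0.5 with score >= 2;
#' overall frequency <= 0.2; occupancy score exactly 0 in matched normal;
#' binding significantly higher than all other datasets (BH FDR <= 0.01);
#' significantly higher than matched normal (FDR <= 0.01); and mean cancer
#' RPKM > 2.
#'
#' BH adjustment is applied per comparison family: all tested sites of this
#' cancer type, separately for the vs-others and vs-matched-normal
#' comparisons. The full criterion-by-criterion ledger is returned so every
#' call is auditable.
#'
#' @param atlas Atlas tibble with overall occupancy (`occupancy_score`,
#'   `occupancy_frequency`, `high_confidence`) computed over all datasets.
#' @param peak_datasets The per-dataset peak tibbles used to compute
#'   stratum-level occupancy.
#' @param mat Quantile-normalized RPKM site x dataset tibble or matrix.
#' @param design Tibble `dataset_id, cohort, cancer_type, matched_normal`
#'   where `cancer_type` labels cancer datasets by type and `matched_normal`
#'   carries the cancer type a normal dataset matches (`NA` otherwise).
#' @param cancer_type The cancer type to call.
#' @param cfg A [pipeline_config()].
#' @return Tibble with one row per tested site: `site_id, call` (`"lost"`,
#'   `"gained"` or `"none"`), the stratum occupancy columns, both t
#'   statistics and FDRs, mean cancer RPKM, and logical ledger columns
#'   `lost_c1 ... lost_c6, gained_c1 ... gained_c6`.
#' @export
call_cancer_specific_sites <- function(atlas, peak_datasets, mat, design,
                                       cancer_type, cfg = NULL) {
  cfg <- as_config(cfg)
  cancer_ids <- design$dataset_id[!is.na(design$cancer_type) &
                                    design$cancer_type == cancer_type]
  normal_ids <- design$dataset_id[!is.na(design$matched_normal) &
                                    design$matched_normal == cancer_type]
  other_ids <- setdiff(design$dataset_id, cancer_ids)
  if (length(cancer_ids) < 2L) {
    stop("cancer type '", cancer_type, "' has fewer than 2 datasets",
         call. = FALSE)
  }
  if (!length(normal_ids)) {
    stop("no matched normal datasets for cancer type '", cancer_type,
         "'; calls are disabled without a matched-normal stratum",
         call. = FALSE)
  }
  peaks <- bind_peak_datasets(peak_datasets)
  strat_occ <- function(ids) {
    sub <- dplyr::filter(peaks, .data$dataset_id %in% ids)
    compute_occupancy(atlas, sub, cfg, n_datasets = length(ids))
  }
  occ_cancer <- strat_occ(cancer_ids)
  occ_normal <- strat_occ(normal_ids)

  sites <- atlas$site_id[atlas$high_confidence]
  db_others <- differential_binding(mat, cancer_ids, other_ids, sites = sites)
  db_normal <- differential_binding(mat, cancer_ids, normal_ids, sites = sites)

  m <- if (is.data.frame(mat)) signal_as_matrix(mat) else mat
  mean_cancer_rpkm <- rowMeans(m[sites, cancer_ids, drop = FALSE])

  idx <- match(sites, atlas$site_id)
  led <- tibble::tibble(
    site_id = sites,
    cancer_score = occ_cancer$occupancy_score[idx],
    cancer_freq = occ_cancer$occupancy_frequency[idx],
    overall_freq = atlas$occupancy_frequency[idx],
    normal_score = occ_normal$occupancy_score[idx],
    normal_freq = occ_normal$occupancy_frequency[idx],
    t_vs_others = db_others$t_statistic[match(sites, db_others$site_id)],
    fdr_vs_others = db_others$fdr[match(sites, db_others$site_id)],
    t_vs_normal = db_normal$t_statistic[match(sites, db_normal$site_id)],
    fdr_vs_normal = db_normal$fdr[match(sites, db_normal$site_id)],
    effect_size = db_others$effect_size[match(sites, db_others$site_id)],
    mean_cancer_rpkm = mean_cancer_rpkm
  )
  led <- dplyr::mutate(
    led,
    lost_c1 = .data$cancer_freq <= cfg$lost_cancer_max_freq,
    lost_c2 = .data$overall_freq >= cfg$lost_overall_min_freq,
    lost_c3 = .data$normal_freq >= cfg$lost_normal_min_freq &
      .data$normal_score >= cfg$matched_normal_min_score,
    lost_c4 = .data$t_vs_others < 0,
    lost_c5 = .data$t_vs_normal < 0,
    lost_c6 = .data$mean_cancer_rpkm < cfg$lost_max_rpkm,
    gained_c1 = .data$cancer_freq >= cfg$gained_cancer_min_freq &
      .data$cancer_score >= cfg$cancer_min_score,
    gained_c2 = .data$overall_freq <= cfg$gained_overall_max_freq,
    gained_c3 = .data$normal_score == 0L,
    gained_c4 = .data$t_vs_others > 0 & .data$fdr_vs_others <= cfg$specificity_fdr,
    gained_c5 = .data$t_vs_normal > 0 & .data$fdr_vs_normal <= cfg$specificity_fdr,
    gained_c6 = .data$mean_cancer_rpkm > cfg$gained_min_rpkm,
    call = dplyr::case_when(
      lost_c1 & lost_c2 & lost_c3 & lost_c4 & lost_c5 & lost_c6 ~ "lost",
      gained_c1 & gained_c2 & gained_c3 & gained_c4 & gained_c5 & gained_c6 ~ "gained",
      TRUE ~ "none"
    )
  )
  dplyr::relocate(led, "call", .after = "site_id")
}

#' Differential chromatin-accessibility score
#'
#' The per-site accessibility score is the fold change of the mean
#' log2-scaled (pseudocount 5), quantile-normalized insertion counts in the
#' cancer-type samples versus all other samples.
#'
#' @param atac Site x sample tibble or matrix of raw insertion counts (set
#'   `prepared = TRUE` if already log2(x+5)-scaled and quantile normalized).
#' @param cancer_samples,other_samples Column ids of the two strata.
#' @param prepared Skip the log2/quantile preparation.
#' @return Tibble `site_id, mean_cancer, mean_other, accessibility_score`.
#' @export
differential_accessibility_score <- function(atac, cancer_samples,
                                             other_samples, prepared = FALSE) {
  m <- if (is.data.frame(atac)) signal_as_matrix(atac) else atac
  if (!length(cancer_samples) || !length(other_samples)) {
    stop("both strata must be non-empty", call. = FALSE)
  }
  if (!prepared) {
    m <- log2(m + 5)
    if (ncol(m) >= 2L) m <- quantile_normalize(m)
  }
  mean_cancer <- rowMeans(m[, cancer_samples, drop = FALSE])
  mean_other <- rowMeans(m[, other_samples, drop = FALSE])
  tibble::tibble(site_id = rownames(m),
                 mean_cancer = unname(mean_cancer),
                 mean_other = unname(mean_other),
                 accessibility_score = unname(mean_cancer / mean_other))
}
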