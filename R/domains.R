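#' Build a constitutive-CTCF-bounded chromatin domain around an anchor site
#'
#' The domain around an anchor is delimited, on each side, by the nearest
#' constitutive site whose distance from the anchor center lies within
#' `[domain_min_side, domain_max_side]` and whose motif strand satisfies the
#' orientation rule. The default rule is `"divergent"` (left boundary on the
#' minus strand, right boundary on plus); `"convergent"` is the mirror image
#' and `"opposite_any"` accepts any left/right pair with opposite strands,
#' choosing the pair with the smallest total span (ties to the nearer left
#' boundary). Constitutive sites failing the orientation or the per-side
#' distance bounds are skipped, not treated as blockers. The domain is absent
#' (`NULL`-like row of `NA`s) when either side has no qualifying boundary.
#'
#' @param anchor One-row tibble (or list) with `chrom, start, end`; the
#'   anchor center is `floor((start + end) / 2)`.
#' @param constitutive Tibble of constitutive sites with `site_id, chrom,
#'   start, end, motif_strand` (`"+"`/`"-"`; sites with `NA` strand are
#'   ignored).
#' @param cfg A [pipeline_config()].
#' @return One-row tibble `left_site_id, left_boundary, right_site_id,
#'   right_boundary, domain_start, domain_end, found` where the boundaries
#'   are the constitutive sites' centers and the domain interval is
#'   half-open `[domain_start, domain_end)`.
#' @export
build_domain <- function(anchor, constitutive, cfg = NULL) {
  cfg <- as_config(cfg)
  center <- site_center(anchor$start, anchor$end)
  cand <- constitutive[constitutive$chrom == anchor$chrom &
                         !is.na(constitutive$motif_strand), , drop = FALSE]
  ccent <- site_center(cand$start, cand$end)
  dist_left <- center - ccent
  dist_right <- ccent - center
  ok_left <- dist_left >= cfg$domain_min_side & dist_left <= cfg$domain_max_side
  ok_right <- dist_right >= cfg$domain_min_side & dist_right <= cfg$domain_max_side
  mode <- cfg$domain_orientation
  absent <- tibble::tibble(left_site_id = NA_character_,
                           left_boundary = NA_integer_,
                           right_site_id = NA_character_,
                           right_boundary = NA_integer_,
                           domain_start = NA_integer_,
                           domain_end = NA_integer_,
                           found = FALSE)
  pick_nearest <- function(ok, dist) {
    idx <- which(ok)
    if (!length(idx)) return(NA_integer_)
    idx[which.min(dist[idx])]
  }
  if (mode %in% c("divergent", "convergent")) {
    ls <- if (mode == "divergent") "-" else "+"
    rs <- if (mode == "divergent") "+" else "-"
    li <- pick_nearest(ok_left & cand$motif_strand == ls, dist_left)
    ri <- pick_nearest(ok_right & cand$motif_strand == rs, dist_right)
    if (is.na(li) || is.na(ri)) return(absent)
  } else {
    lidx <- which(ok_left)
    ridx <- which(ok_right)
    if (!length(lidx) || !length(ridx)) return(absent)
    combos <- expand.grid(li = lidx, ri = ridx)
    combos <- combos[cand$motif_strand[combos$li] != cand$motif_strand[combos$ri], ,
                     drop = FALSE]
    if (!nrow(combos)) return(absent)
    span <- dist_left[combos$li] + dist_right[combos$ri]
    combos <- combos[order(span, dist_left[combos$li]), , drop = FALSE]
    li <- combos$li[1]
    ri <- combos$ri[1]
  }
  tibble::tibble(left_site_id = cand$site_id[li],
                 left_boundary = as.integer(ccent[li]),
                 right_site_id = cand$site_id[ri],
                 right_boundary = as.integer(ccent[ri]),
                 domain_start = as.integer(ccent[li]),
                 domain_end = as.integer(ccent[ri]),
                 found = TRUE)
}

site_center <- function(start, end) (start + end) %/% 2L

#' @rdname build_domain
#' @param anchors Tibble of anchor sites (`site_id, chrom, start, end`).
#' @return `build_domains()`: one row per anchor with `site_id` prepended.
#' @export
build_domains <- function(anchors, constitutive, cfg = NULL) {
  cfg <- as_config(cfg)
  rows <- purrr::map(seq_len(nrow(anchors)), function(k) {
    build_domain(anchors[k, ], constitutive, cfg)
  })
  dplyr::bind_cols(tibble::tibble(site_id = anchors$site_id),
                   dplyr::bind_rows(rows))
}

#' Correlate CTCF binding with gene expression across cell types
#'
#' Pearson correlation between the prepared site signal (square-root RPKM,
#' quantile normalized across cell types) and gene expression (square-root
#' TPM) over the shared cell types. A pair is highly correlated iff
#' R-squared strictly exceeds `r2_threshold` (0.25). Zero variance in either
#' vector flags the pair undefined; such pairs never count as highly
#' correlated.
#'
#' @param site_signal Named numeric vector of prepared CTCF signal per cell
#'   type.
#' @param gene_expression Named numeric vector of sqrt-TPM per cell type.
#' @param cfg A [pipeline_config()].
#' @return One-row tibble `r, r_squared, highly_correlated, undefined,
#'   n_cell_types`.
#' @export
correlate_ctcf_gene <- function(site_signal, gene_expression, cfg = NULL) {
  cfg <- as_config(cfg)
  shared <- intersect(names(site_signal), names(gene_expression))
  if (length(shared) < 3L) {
    stop("need at least 3 shared cell types", call. = FALSE)
  }
  x <- site_signal[shared]
  y <- gene_expression[shared]
  undefined <- stats::sd(x) == 0 || stats::sd(y) == 0
  r <- if (undefined) NA_real_ else stats::cor(x, y)
  tibble::tibble(r = r,
                 r_squared = r^2,
                 highly_correlated = !undefined && r^2 > cfg$r2_threshold,
                 undefined = undefined,
                 n_cell_types = length(shared))
}

#' Assign candidate target genes to a site
#'
#' If the site overlaps a promoter (TSS +/- `promoter_halfwidth`), those
#' genes are its promoter targets and take precedence. Otherwise all genes
#' whose TSS lies inside the site's chromatin domain are intra-domain
#' targets. Remaining same-chromosome genes are categorized inter-domain for
#' pair classification; the three categories partition all site-gene pairs
#' with precedence promoter > intra-domain > inter-domain.
#'
#' @param site One-row tibble with `chrom, start, end`.
#' @param genes Gene-model tibble (`gene_id, chrom, strand, tss`).
#' @param domain One-row tibble from [build_domain()] (may have
#'   `found = FALSE`).
#' @param cfg A [pipeline_config()].
#' @return Tibble `gene_id, category` for every same-chromosome gene, with
#'   `category` in `promoter, intra_domain, inter_domain`.
#' @export
assign_candidate_targets <- function(site, genes, domain, cfg = NULL) {
  cfg <- as_config(cfg)
  g <- genes[genes$chrom == site$chrom, , drop = FALSE]
  if (!nrow(g)) return(tibble::tibble(gene_id = character(),
                                      category = character()))
  hw <- cfg$promoter_halfwidth
  promoter <- site$start < g$tss + hw + 1L & site$end > g$tss - hw
  in_domain <- if (isTRUE(domain$found)) {
    g$tss >= domain$domain_start & g$tss < domain$domain_end
  } else rep(FALSE, nrow(g))
  category <- if (any(promoter)) {
    ifelse(promoter, "promoter", "inter_domain")
  } else {
    ifelse(in_domain, "intra_domain", "inter_domain")
  }
  tibble::tibble(gene_id = g$gene_id, category = category)
}

#' Differential-expression enrichment of a target gene set
#'
#' Tests whether a site's candidate target genes are enriched for
#' differentially expressed genes (|log2FC| > `de_log2fc`, FDR < `de_fdr`)
#' with a two-tailed Fisher's exact test on the 2x2 table
#' {in target set} x {DE}. The odds ratio is computed from the table; 0.5 is
#' added to every cell only when a margin cell is zero (flagged).
#'
#' @param target_genes Character vector of candidate target gene ids.
#' @param de_table Tibble `gene_id, log2fc, fdr`.
#' @param universe Character vector of all genes considered (must contain the
#'   target set).
#' @param cfg A [pipeline_config()].
#' @param direction `"both"` (|log2FC|), `"up"` or `"down"` for directional
#'   DE definitions.
#' @return One-row tibble `n_target, n_de, n_overlap, odds_ratio, p_value,
#'   continuity`.
#' @export
de_enrichment <- function(target_genes, de_table, universe, cfg = NULL,
                          direction = c("both", "up", "down")) {
  cfg <- as_config(cfg)
  direction <- match.arg(direction)
  if (!length(universe)) stop("empty universe", call. = FALSE)
  if (length(setdiff(target_genes, universe))) {
    stop("target set contains genes outside the universe", call. = FALSE)
  }
  de <- de_table[de_table$gene_id %in% universe, , drop = FALSE]
  is_de <- switch(direction,
                  both = abs(de$log2fc) > cfg$de_log2fc,
                  up = de$log2fc > cfg$de_log2fc,
                  down = de$log2fc < -cfg$de_log2fc) & de$fdr < cfg$de_fdr
  de_genes <- de$gene_id[is_de]
  a <- length(intersect(target_genes, de_genes))
  b <- length(setdiff(target_genes, de_genes))
  c_ <- length(setdiff(de_genes, target_genes))
  d <- length(universe) - a - b - c_
  p <- fisher_two_tailed(a, b, c_, d)
  tab <- c(a, b, c_, d)
  continuity <- any(c(a + b, c_ + d, a + c_, b + d) == 0)
  if (continuity) tab <- tab + 0.5
  or <- (tab[1] * tab[4]) / (tab[2] * tab[3])
  tibble::tibble(n_target = length(target_genes), n_de = length(de_genes),
                 n_overlap = a, odds_ratio = or, p_value = p,
                 continuity = continuity)
}

# Two-tailed Fisher exact p for the 2x2 table [[a, b], [c, d]]: the sum of
# hypergeometric probabilities of all tables (with the same margins) no more
# likely than the observed one. Cross-checked against stats::fisher.test.
fisher_two_tailed <- function(a, b, c, d) {
  m <- a + b          # row 1 margin
  n <- c + d          # row 2 margin
  k <- a + c          # column 1 margin
  if (m == 0 || n == 0 || k == 0 || b + d == 0) return(1)
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}
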