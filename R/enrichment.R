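#' Overlap query regions with a regulatory-element repertoire
#'
#' Marks each repertoire element (a candidate cis-regulatory element, e.g. a
#' union DNase I hypersensitive site) selected iff it overlaps any query
#' region by at least 1 bp.
#'
#' @param regions Tibble of query intervals (`chrom, start, end`, 0-based
#'   half-open).
#' @param repertoire Tibble of non-overlapping sorted elements (`chrom,
#'   start, end`).
#' @return Logical vector over the repertoire rows.
#' @export
overlap_repertoire <- function(regions, repertoire) {
  sel <- rep(FALSE, nrow(repertoire))
  if (!nrow(regions) || !nrow(repertoire)) return(sel)
  rep_gr <- GenomicRanges::GRanges(
    repertoire$chrom,
    IRanges::IRanges(start = repertoire$start + 1L, end = repertoire$end))
  qry_gr <- GenomicRanges::GRanges(
    regions$chrom,
    IRanges::IRanges(start = regions$start + 1L, end = regions$end))
  hits <- GenomicRanges::findOverlaps(rep_gr, qry_gr)
  sel[unique(S4Vectors::queryHits(hits))] <- TRUE
  sel
}

#' Rank transcription factors by binding enrichment in selected elements
#'
#' For each TF's binary occupancy profile over the repertoire, builds the
#' 2x2 table {bound, unbound} x {selected, unselected} and computes a
#' two-tailed Fisher's exact p-value plus the table odds ratio. TFs are
#' ranked by ascending p, ties broken by descending odds ratio then name.
#' A TF bound nowhere gets `p = 1` and odds ratio 0.
#'
#' @param selection Logical vector over the repertoire (from
#'   [overlap_repertoire()]); must select at least one element.
#' @param profiles Tibble or data frame of 0/1 profiles, one column per TF,
#'   rows aligned to the repertoire (a logical/numeric matrix also works).
#' @return Tibble `tf, n_bound, n_bound_selected, odds_ratio, p_value, rank`.
#' @export
tf_rank_enrichment <- function(selection, profiles) {
  if (!any(selection)) stop("selection is empty", call. = FALSE)
  m <- as.matrix(profiles)
  if (nrow(m) != length(selection)) {
    stop("profiles rows (", nrow(m), ") must match repertoire size (",
         length(selection), ")", call. = FALSE)
  }
  storage.mode(m) <- "integer"
  n_sel <- sum(selection)
  n_tot <- length(selection)
  res <- purrr::map(colnames(m), function(tf) {
    bound <- m[, tf] > 0L
    a <- sum(bound & selection)
    b <- sum(bound & !selection)
    c_ <- n_sel - a
    d <- n_tot - n_sel - b
    if (!any(bound)) {
      return(tibble::tibble(tf = tf, n_bound = 0L, n_bound_selected = 0L,
                            odds_ratio = 0, p_value = 1))
    }
    or <- if (b == 0 || c_ == 0) Inf else (a * d) / (b * c_)
    if (a == 0) or <- 0
    tibble::tibble(tf = tf, n_bound = sum(bound), n_bound_selected = a,
                   odds_ratio = or,
                   p_value = fisher_two_tailed(a, b, c_, d))
  }) |> dplyr::bind_rows()
  res <- res[order(res$p_value, -res$odds_ratio, res$tf), , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  res
}
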