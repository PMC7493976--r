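#' Differential methylation of the window around one site
#'
#' The window is the `meth_window` (300 bp) region centered at the site
#' (`[center - 150, center + 150)`). A CpG is used only if it is covered by
#' at least `meth_min_coverage` (5) reads at the same position in **both**
#' conditions; at least `meth_min_cpgs` (3) such CpGs are required, otherwise
#' the status is `insufficient`. The mean per-CpG difference
#' (cancer - normal, percentage points) is called `hyper` when strictly above
#' `meth_delta_threshold` (20), `hypo` when strictly below its negative, and
#' `unchanged` otherwise.
#'
#' @param site One-row tibble with `site_id, chrom, start, end`.
#' @param cpgs_cancer,cpgs_normal CpG tibbles from [read_cpg_table()].
#' @param cfg A [pipeline_config()].
#' @return One-row tibble `site_id, n_cpgs_used, mean_delta, status`.
#' @export
region_differential_methylation <- function(site, cpgs_cancer, cpgs_normal,
                                            cfg = NULL) {
  cfg <- as_config(cfg)
  hw <- cfg$meth_window %/% 2L
  center <- site_center(site$start, site$end)
  lo <- center - hw
  hi <- center + hw
  pick <- function(cpgs) {
    cpgs[cpgs$chrom == site$chrom & cpgs$pos >= lo & cpgs$pos < hi &
           cpgs$coverage >= cfg$meth_min_coverage, c("pos", "meth_level")]
  }
  ca <- pick(cpgs_cancer)
  no <- pick(cpgs_normal)
  shared <- intersect(ca$pos, no$pos)
  sid <- if ("site_id" %in% names(site)) site$site_id else NA_character_
  if (length(shared) < cfg$meth_min_cpgs) {
    return(tibble::tibble(site_id = sid, n_cpgs_used = length(shared),
                          mean_delta = NA_real_, status = "insufficient"))
  }
  delta <- ca$meth_level[match(shared, ca$pos)] -
    no$meth_level[match(shared, no$pos)]
  md <- mean(delta)
  status <- if (md > cfg$meth_delta_threshold) "hyper"
    else if (md < -cfg$meth_delta_threshold) "hypo"
    else "unchanged"
  tibble::tibble(site_id = sid, n_cpgs_used = length(shared),
                 mean_delta = md, status = status)
}

#' @rdname region_differential_methylation
#' @param sites Tibble of sites.
#' @return `region_differential_methylation_all()`: one row per site.
#' @export
region_differential_methylation_all <- function(sites, cpgs_cancer,
                                                cpgs_normal, cfg = NULL) {
  cfg <- as_config(cfg)
  purrr::map(seq_len(nrow(sites)), function(k) {
    region_differential_methylation(sites[k, ], cpgs_cancer, cpgs_normal, cfg)
  }) |> dplyr::bind_rows()
}

#' Genome-wide binding-change versus methylation-change profile
#'
#' Sites with a methylation status (insufficient ones dropped) are ranked by
#' their differential-binding t statistic and split into `n_bins` equal-count
#' bins (any remainder goes to the first bins). Per bin the fractions of
#' hypo / unchanged / hyper sites (summing to 1) and the median t statistic
#' are reported; a negative association between median t and the hyper
#' fraction is the signature of methylation gain accompanying binding loss.
#'
#' @param site_stats Tibble with `site_id, t_statistic, status` (status from
#'   [region_differential_methylation()]).
#' @param n_bins Number of equal-count bins (default 100); reduced with a
#'   warning when fewer sites than bins are available.
#' @return Tibble `bin, n_sites, median_t, frac_hypo, frac_unchanged,
#'   frac_hyper`.
#' @export
binding_methylation_association <- function(site_stats, n_bins = 100L) {
  ok <- site_stats[site_stats$status != "insufficient" &
                     !is.na(site_stats$t_statistic), , drop = FALSE]
  n <- nrow(ok)
  if (n == 0L) stop("no sites with methylation status", call. = FALSE)
  if (n < n_bins) {
    warning("only ", n, " usable sites; reducing bin count from ", n_bins,
            call. = FALSE)
    n_bins <- n
  }
  ok <- ok[order(ok$t_statistic), , drop = FALSE]
  base <- n %/% n_bins
  rem <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, rem), rep(0L, n_bins - rem))
  ok$bin <- rep(seq_len(n_bins), times = sizes)
  ok |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      n_sites = dplyr::n(),
      median_t = stats::median(.data$t_statistic),
      frac_hypo = mean(.data$status == "hypo"),
      frac_unchanged = mean(.data$status == "unchanged"),
      frac_hyper = mean(.data$status == "hyper"),
      .groups = "drop"
    )
}
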