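#' Occupancy-score distribution with the fitted power law
#'
#' Log-log plot of observed site counts per occupancy score with the fitted
#' expectation overlaid; the vertical line marks the constitutive cutoff
#' when supplied.
#'
#' @param dist Tibble from [occupancy_distribution()].
#' @param fit Optional `"ctcf_powerlaw"` fit.
#' @param A Optional cutoff from [determine_cutoff()].
#' @return A ggplot object.
#' @export
plot_occupancy_distribution <- function(dist, fit = NULL, A = NULL) {
  obs <- dist[dist$n_sites > 0, , drop = FALSE]
  p <- ggplot2::ggplot(obs, ggplot2::aes(x = .data$score, y = .data$n_sites)) +
    ggplot2::geom_point(size = 0.8, colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "occupancy score", y = "number of sites") +
    ggplot2::theme_bw()
  if (!is.null(fit)) {
    curve <- tibble::tibble(score = obs$score,
                            expected = power_law_expected(fit, obs$score))
    p <- p + ggplot2::geom_line(data = curve,
                                ggplot2::aes(y = .data$expected),
                                colour = "darkgreen")
  }
  if (!is.null(A) && !is.na(A)) {
    p <- p + ggplot2::geom_vline(xintercept = A, linetype = "dashed")
  }
  p
}

#' Volcano-style view of differential binding
#'
#' @param calls Tibble from [call_cancer_specific_sites()].
#' @return A ggplot object of the vs-all-others t statistic against the BH
#'   FDR, coloured by call.
#' @export
plot_specificity_calls <- function(calls) {
  ggplot2::ggplot(calls,
                  ggplot2::aes(x = .data$t_vs_others,
                               y = -log10(pmax(.data$fdr_vs_others, 1e-300)),
                               colour = .data$call)) +
    ggplot2::geom_point(size = 0.7, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(lost = "#3366cc",
                                            gained = "#cc3333",
                                            none = "grey70")) +
    ggplot2::labs(x = "t statistic (cancer vs all others)",
                  y = "-log10 FDR", colour = NULL) +
    ggplot2::theme_bw()
}

#' Stacked binding-vs-methylation association profile
#'
#' @param profile Tibble from [binding_methylation_association()].
#' @return A ggplot object: per-bin stacked fractions of hypo / unchanged /
#'   hyper methylation along the binding-change ranking.
#' @export
plot_methylation_association <- function(profile) {
  long <- tidyr::pivot_longer(profile,
                              cols = c("frac_hypo", "frac_unchanged",
                                       "frac_hyper"),
                              names_to = "status", names_prefix = "frac_",
                              values_to = "fraction")
  long$status <- factor(long$status, levels = c("hypo", "unchanged", "hyper"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$bin, y = .data$fraction,
                                     fill = .data$status)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::scale_fill_manual(values = c(hypo = "#2e8b57",
                                          unchanged = "grey80",
                                          hyper = "#7b2d8b")) +
    ggplot2::labs(x = "sites ranked by differential binding (t statistic)",
                  y = "fraction of sites", fill = NULL) +
    ggplot2::theme_bw()
}

#' Mutation-rate profile around site groups
#'
#' @param profile Tibble from [mutation_rate_profile()], optionally with a
#'   `group` column for faceting.
#' @return A ggplot object of mean mutation count per site per bp by offset.
#' @export
plot_mutation_profile <- function(profile) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$offset, y = .data$rate)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::labs(x = "offset from site center (bp)",
                  y = "mutations per site per bp") +
    ggplot2::theme_bw()
  if ("group" %in% names(profile)) {
    p <- p + ggplot2::facet_wrap(~group, scales = "free_y")
  }
  p
}

#' Distance-decay profile of a contact map
#'
#' @param map A [contact_map()] (raw).
#' @return A ggplot object of mean interaction against genomic distance on
#'   log-log axes.
#' @export
plot_distance_decay <- function(map) {
  prof <- distance_profile(map)
  prof <- prof[prof$mean_count > 0, , drop = FALSE]
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$distance, y = .data$mean_count)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "genomic distance (bp)", y = "mean contact count") +
    ggplot2::theme_bw()
}
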