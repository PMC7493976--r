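#' Occupancy-score distribution of an atlas
#'
#' Tallies how many sites carry each occupancy score `i` in `1..n_datasets`
#' (`O_i`), the raw material for the power-law model behind the constitutive
#' cutoff.
#'
#' @param atlas Atlas tibble with an `occupancy_score` column.
#' @param n_datasets Total number of datasets; defaults to the atlas
#'   `n_datasets` attribute or the maximum observed score.
#' @return A tibble `score, n_sites` covering every score `1..n_datasets`.
#' @export
occupancy_distribution <- function(atlas, n_datasets = NULL) {
  if (is.null(n_datasets)) {
    n_datasets <- attr(atlas, "n_datasets")
    if (is.null(n_datasets)) n_datasets <- max(atlas$occupancy_score, 1L)
  }
  tab <- table(factor(atlas$occupancy_score, levels = seq_len(n_datasets)))
  tibble::tibble(score = seq_len(n_datasets), n_sites = as.integer(tab))
}

#' Fit a shifted power law to the occupancy-score distribution
#'
#' Models the expected number of sites at occupancy score `i` as
#' `E_i = a * (i - b)^(-c)`. The offset `b` is found by bounded 1-D search on
#' `[0, min(fit_range) - 0.01]`; for each candidate `b` the scale and
#' exponent come from least squares of `log(O_i)` on `log(i - b)` over the
#' scores in `fit_range` with `O_i > 0`. Log-space least squares is used for
#' robustness on heavy-tailed counts. The fit is deterministic.
#'
#' @param dist Tibble `score, n_sites` from [occupancy_distribution()] (a
#'   named or dense numeric vector of counts is also accepted).
#' @param fit_range Integer range of scores used for fitting; defaults to all
#'   scores with positive counts.
#' @return An object of class `"ctcf_powerlaw"`: list with `a, b, c`,
#'   `fit_range`, `residual` (sum of squared log residuals) and `n_points`.
#'   Supports [generics::tidy()] and [generics::glance()].
#' @export
fit_power_law <- function(dist, fit_range = NULL) {
  dist <- as_occupancy_dist(dist)
  if (is.null(fit_range)) fit_range <- dist$score[dist$n_sites > 0]
  pts <- dist[dist$score %in% fit_range & dist$n_sites > 0, , drop = FALSE]
  if (nrow(pts) < 5L) {
    stop("need at least 5 nonzero counts in fit_range to fit the power law",
         call. = FALSE)
  }
  i <- pts$score
  logO <- log(pts$n_sites)
  b_hi <- min(i) - 0.01
  sse_for_b <- function(b) {
    x <- log(i - b)
    fit <- stats::lm.fit(cbind(1, x), logO)
    sum(fit$residuals^2)
  }
  b <- if (b_hi <= 0) 0 else stats::optimize(sse_for_b, c(0, b_hi))$minimum
  # a pole just below min(i) can edge out a flat optimum; prefer b = 0 when equal
  if (b_hi > 0 && sse_for_b(0) <= sse_for_b(b) + 1e-12) b <- 0
  x <- log(i - b)
  fit <- stats::lm.fit(cbind(1, x), logO)
  structure(list(a = exp(fit$coefficients[[1]]),
                 b = b,
                 c = -fit$coefficients[[2]],
                 fit_range = range(i),
                 residual = sum(fit$residuals^2),
                 n_points = nrow(pts)),
            class = "ctcf_powerlaw")
}

as_occupancy_dist <- function(dist) {
  if (is.data.frame(dist)) return(dist)
  if (is.numeric(dist)) {
    score <- if (!is.null(names(dist))) as.integer(names(dist)) else
      seq_along(dist)
    return(tibble::tibble(score = score, n_sites = as.numeric(dist)))
  }
  stop("dist must be a score/n_sites tibble or a numeric count vector",
       call. = FALSE)
}

#' Expected counts under a fitted power law
#'
#' @param fit A `"ctcf_powerlaw"` object.
#' @param scores Occupancy scores at which to evaluate `E_i`.
#' @return Numeric vector of expected site counts.
#' @export
power_law_expected <- function(fit, scores) {
  fit$a * (scores - fit$b)^(-fit$c)
}

#' @export
print.ctcf_powerlaw <- function(x, ...) {
  cat(sprintf("<ctcf_powerlaw> E_i = %.4g * (i - %.4g)^(-%.4g)  [fit on %d points]\n",
              x$a, x$b, x$c, x$n_points))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.ctcf_powerlaw <- function(x, ...) {
  tibble::tibble(term = c("a", "b", "c"),
                 estimate = c(x$a, x$b, x$c))
}

#' @export
glance.ctcf_powerlaw <- function(x, ...) {
  tibble::tibble(residual = x$residual, n_points = x$n_points,
                 fit_min = x$fit_range[1], fit_max = x$fit_range[2])
}

#' Constitutive-site cutoff from tail excess over the power law
#'
#' Returns the smallest occupancy score `A` such that the observed tail
#' beyond `A` exceeds the model expectation by more than `excess_factor`:
#' `sum_{j >= A}(O_j - E_j) / sum_{j >= A} E_j > excess_factor`, i.e. the
#' observed tail is more than `excess_factor + 1` times the expected tail.
#' `NA` (absent) is a valid outcome when no score qualifies. The cutoff is
#' monotone: raising `excess_factor` can only raise (or remove) `A`.
#'
#' @param dist Occupancy distribution (`score, n_sites` tibble or vector).
#' @param fit A `"ctcf_powerlaw"` from [fit_power_law()], or a numeric vector
#'   of expected counts aligned to the distribution's scores.
#' @param excess_factor Required tail excess ratio (default 5).
#' @return Integer cutoff `A`, or `NA_integer_` if no score qualifies.
#' @export
determine_cutoff <- function(dist, fit, excess_factor = 5) {
  dist <- as_occupancy_dist(dist)
  dist <- dist[order(dist$score), , drop = FALSE]
  O <- dist$n_sites
  E <- if (is.numeric(fit)) {
    stopifnot(length(fit) == nrow(dist))
    fit
  } else {
    power_law_expected(fit, dist$score)
  }
  tail_O <- rev(cumsum(rev(O)))
  tail_E <- rev(cumsum(rev(E)))
  ratio <- (tail_O - tail_E) / tail_E
  ok <- which(ratio > excess_factor)
  if (!length(ok)) return(NA_integer_)
  as.integer(dist$score[ok[1]])
}

#' Select constitutive sites
#'
#' Constitutive sites are those with occupancy score at least `A + 1` (the
#' observed tail strictly beyond the cutoff). When `A` is absent the fallback
#' is the occupancy-frequency rule: score at least
#' `ceiling(constitutive_frequency * n_datasets)`. The rule that fired is
#' recorded in the `rule` attribute.
#'
#' @param atlas Atlas tibble with `occupancy_score`.
#' @param A Cutoff from [determine_cutoff()] (may be `NA`).
#' @param cfg A [pipeline_config()].
#' @param n_datasets Total dataset count for the fallback rule; defaults to
#'   the atlas `n_datasets` attribute.
#' @return The subset of `atlas` that is constitutive, with attribute `rule`
#'   (`"excess_tail"` or `"frequency"`) and `min_score`.
#' @export
select_constitutive <- function(atlas, A, cfg = NULL, n_datasets = NULL) {
  cfg <- as_config(cfg)
  if (is.null(n_datasets)) {
    n_datasets <- attr(atlas, "n_datasets")
    if (is.null(n_datasets)) n_datasets <- max(atlas$occupancy_score, 1L)
  }
  if (!is.na(A)) {
    min_score <- A + 1L
    rule <- "excess_tail"
  } else {
    min_score <- as.integer(ceiling(cfg$constitutive_frequency * n_datasets))
    rule <- "frequency"
  }
  out <- dplyr::filter(atlas, .data$occupancy_score >= min_score)
  attr(out, "rule") <- rule
  attr(out, "min_score") <- min_score
  out
}
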