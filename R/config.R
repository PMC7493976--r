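#' Pipeline configuration
#'
#' All tunable thresholds of the pipeline live in a single flat, validated
#' list so every stage receives the same auditable set of parameters.
#' Defaults are the values used throughout the analysis: peaks are extended
#' +/- 75 bp around their summit and merged with an effective 150-bp cutoff,
#' datasets need at least 2000 peaks at fold enrichment >= 4, sites with
#' occupancy score >= 3 are high-confidence, the constitutive cutoff uses a
#' 5x excess over the power-law expectation (falling back to 80% occupancy
#' frequency), and so on through the Hi-C, methylation, mutation and motif
#' stages.
#'
#' @param ... Named overrides of any default (see Details).
#'
#' @details Fields (units, default):
#' \describe{
#'   \item{merge_halfwidth}{bp half-width around each summit (75)}
#'   \item{merge_gap_cutoff}{bp merge cutoff, normally 2 x halfwidth (150)}
#'   \item{min_peaks_per_dataset}{minimum surviving peaks to include a dataset (2000)}
#'   \item{min_fold_enrichment}{peak fold-enrichment filter (4)}
#'   \item{high_confidence_min_occupancy}{occupancy score for high-confidence sites (3)}
#'   \item{excess_factor}{observed-over-expected tail excess for the constitutive cutoff (5)}
#'   \item{constitutive_frequency}{fallback occupancy-frequency cutoff (0.8)}
#'   \item{lost_cancer_max_freq, lost_overall_min_freq, lost_normal_min_freq}{lost-site
#'     occupancy-frequency bounds (0.2, 0.7, 0.5)}
#'   \item{gained_cancer_min_freq, gained_overall_max_freq}{gained-site bounds (0.5, 0.2)}
#'   \item{matched_normal_min_score, cancer_min_score}{minimum occupancy scores backing the
#'     frequency criteria (2, 2)}
#'   \item{lost_max_rpkm, gained_min_rpkm}{mean cancer RPKM bounds (5, 2)}
#'   \item{specificity_fdr}{BH FDR cutoff for gained calls (0.01)}
#'   \item{promoter_halfwidth}{bp around a TSS counting as promoter (2000)}
#'   \item{domain_min_side, domain_max_side}{per-side domain size bounds in bp (1e5, 1e6)}
#'   \item{domain_orientation}{boundary motif rule: "divergent", "convergent" or
#'     "opposite_any" ("divergent")}
#'   \item{r2_threshold}{R-squared above which a CTCF-gene pair is highly correlated (0.25)}
#'   \item{hic_bin_size, hic_flank_L}{contact-map bin size and flank span in bp (5000, 5e5)}
#'   \item{hic_pseudocount}{epsilon added to normalized contacts before log2 (0.01)}
#'   \item{meth_window, meth_min_cpgs, meth_min_coverage, meth_delta_threshold}{CpG window
#'     bp, minimum qualifying CpGs, per-CpG coverage, and percentage-point call
#'     threshold (300, 3, 5, 20)}
#'   \item{mutation_window, motif_window}{bp windows for mutation profiles and motif
#'     scoring (400, 19)}
#'   \item{pwm_background}{A,C,G,T background frequencies
#'     (0.275, 0.225, 0.225, 0.275)}
#'   \item{pwm_pseudocount}{pseudocount added per PFM cell (0.5)}
#'   \item{pwm_pvalue_threshold}{motif-hit p-value cutoff (1e-4)}
#'   \item{de_log2fc, de_fdr}{differential-expression thresholds (1, 1e-5)}
#'   \item{random_seed}{integer seed recorded in run metadata (1)}
#' }
#'
#' @return A validated list of class `"ctcf_config"`.
#' @examples
#' cfg <- pipeline_config(hic_bin_size = 10000)
#' cfg$merge_gap_cutoff
#' @export
pipeline_config <- function(...) {
  cfg <- config_defaults()
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad)) {
      stop("unknown configuration field(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    cfg[names(overrides)] <- overrides
  }
  validate_config(cfg)
}

config_defaults <- function() {
  list(
    merge_halfwidth = 75L,
    merge_gap_cutoff = 150L,
    min_peaks_per_dataset = 2000L,
    min_fold_enrichment = 4,
    high_confidence_min_occupancy = 3L,
    excess_factor = 5,
    constitutive_frequency = 0.8,
    lost_cancer_max_freq = 0.2,
    lost_overall_min_freq = 0.7,
    lost_normal_min_freq = 0.5,
    gained_cancer_min_freq = 0.5,
    gained_overall_max_freq = 0.2,
    matched_normal_min_score = 2L,
    cancer_min_score = 2L,
    lost_max_rpkm = 5,
    gained_min_rpkm = 2,
    specificity_fdr = 0.01,
    promoter_halfwidth = 2000L,
    domain_min_side = 100000L,
    domain_max_side = 1000000L,
    domain_orientation = "divergent",
    r2_threshold = 0.25,
    hic_bin_size = 5000L,
    hic_flank_L = 500000L,
    hic_pseudocount = 0.01,
    meth_window = 300L,
    meth_min_cpgs = 3L,
    meth_min_coverage = 5L,
    meth_delta_threshold = 20,
    mutation_window = 400L,
    motif_window = 19L,
    pwm_background = c(A = 0.275, C = 0.225, G = 0.225, T = 0.275),
    pwm_pseudocount = 0.5,
    pwm_pvalue_threshold = 1e-4,
    de_log2fc = 1,
    de_fdr = 1e-5,
    random_seed = 1L
  )
}

validate_config <- function(cfg) {
  bp_fields <- c("merge_halfwidth", "merge_gap_cutoff", "promoter_halfwidth",
                 "domain_min_side", "domain_max_side", "hic_bin_size",
                 "hic_flank_L", "meth_window", "mutation_window", "motif_window")
  for (f in bp_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0 || v != round(v)) {
      stop("configuration field '", f, "' must be a positive integer (bp)",
           call. = FALSE)
    }
    cfg[[f]] <- as.integer(v)
  }
  frac_fields <- c("constitutive_frequency", "lost_cancer_max_freq",
                   "lost_overall_min_freq", "lost_normal_min_freq",
                   "gained_cancer_min_freq", "gained_overall_max_freq",
                   "specificity_fdr", "r2_threshold", "pwm_pvalue_threshold",
                   "de_fdr")
  for (f in frac_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("configuration field '", f, "' must be a fraction in [0, 1]",
           call. = FALSE)
    }
  }
  bg <- cfg$pwm_background
  if (!is.numeric(bg) || length(bg) != 4L || any(bg < 0)) {
    stop("pwm_background must be 4 non-negative frequencies (A,C,G,T)",
         call. = FALSE)
  }
  if (abs(sum(bg) - 1) > 1e-12) {
    stop("pwm_background must sum to 1 (within 1e-12); got ", sum(bg),
         call. = FALSE)
  }
  names(cfg$pwm_background) <- c("A", "C", "G", "T")
  if (!cfg$domain_orientation %in% c("divergent", "convergent", "opposite_any")) {
    stop("domain_orientation must be one of 'divergent', 'convergent', 'opposite_any'",
         call. = FALSE)
  }
  if (cfg$domain_min_side > cfg$domain_max_side) {
    stop("domain_min_side exceeds domain_max_side", call. = FALSE)
  }
  if (cfg$merge_gap_cutoff != 2L * cfg$merge_halfwidth) {
    warning("merge_gap_cutoff (", cfg$merge_gap_cutoff,
            ") is not 2 x merge_halfwidth (", cfg$merge_halfwidth, ")",
            call. = FALSE)
  }
  cfg$random_seed <- as.integer(cfg$random_seed)
  structure(cfg, class = "ctcf_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Unspecified keys take their defaults; an empty file yields the full
#' default configuration.
#'
#' @param path Path to a YAML or JSON mapping of configuration fields.
#' @return A validated `"ctcf_config"` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  vals <- if (!nzchar(trimws(txt))) {
    list()
  } else if (grepl("\\.json$", path, ignore.case = TRUE) ||
             grepl("^\\s*\\{", txt)) {
    tryCatch(jsonlite::fromJSON(txt, simplifyVector = TRUE),
             error = function(e) stop("failed to parse JSON config '", path,
                                      "': ", conditionMessage(e), call. = FALSE))
  } else {
    tryCatch(yaml::yaml.load(txt),
             error = function(e) stop("failed to parse YAML config '", path,
                                      "': ", conditionMessage(e), call. = FALSE))
  }
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) stop("config file must be a mapping of field: value",
                           call. = FALSE)
  do.call(pipeline_config, vals)
}

#' @export
print.ctcf_config <- function(x, ...) {
  cat("<ctcf_config> ", length(x), " fields\n", sep = "")
  for (nm in names(x)) {
    cat(sprintf("  %-32s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  }
  invisible(x)
}

as_config <- function(cfg) {
  if (is.null(cfg)) return(pipeline_config())
  if (inherits(cfg, "ctcf_config")) return(cfg)
  if (is.list(cfg)) return(do.call(pipeline_config, cfg))
  stop("cfg must be a ctcf_config or a list of overrides", call. = FALSE)
}
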