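#' Build the union CTCF binding-site atlas
#'
#' Every peak is represented by a fixed window centered at its summit
#' (+/- `merge_halfwidth`, 150 bp total by default) and overlapping windows
#' from all datasets are merged transitively per chromosome into
#' non-overlapping, sorted union sites. Because the windows are 150 bp wide,
#' two summits closer than the 150-bp merge cutoff always end up in the same
#' site; merged sites may exceed 150 bp. Site ids are stable
#' (`chrom:start-end`).
#'
#' @param peak_datasets A list of peak tibbles from [read_peak_dataset()] (or
#'   a single tibble holding several `dataset_id`s). Datasets flagged excluded
#'   are dropped unless `keep_excluded` is `TRUE`.
#' @param cfg A [pipeline_config()].
#' @param chrom_sizes Optional named vector of chromosome lengths used to clip
#'   windows (with a warning) when summits sit near an end.
#' @param keep_excluded Keep datasets that failed the minimum-peak filter.
#' @return A tibble `site_id, chrom, start, end` sorted by chromosome and
#'   start, with attribute `dataset_ids` recording the contributing datasets.
#' @export
build_union_atlas <- function(peak_datasets, cfg = NULL, chrom_sizes = NULL,
                              keep_excluded = FALSE) {
  cfg <- as_config(cfg)
  peaks <- bind_peak_datasets(peak_datasets, keep_excluded)
  dataset_ids <- sort(unique(peaks$dataset_id))
  if (nrow(peaks) == 0L) {
    out <- tibble::tibble(site_id = character(), chrom = character(),
                          start = integer(), end = integer())
    attr(out, "dataset_ids") <- dataset_ids
    return(out)
  }
  hw <- cfg$merge_halfwidth
  start <- peaks$summit - hw
  end <- peaks$summit + hw
  if (!is.null(chrom_sizes)) {
    size <- unname(chrom_sizes[peaks$chrom])
    clip <- which(start < 0L | end > size)
    if (length(clip)) {
      warning(length(clip), " summit window(s) clipped at chromosome ends",
              call. = FALSE)
      start <- pmax(start, 0L)
      end <- pmin(end, size)
    }
  } else {
    start <- pmax(start, 0L)
  }
  gr <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(start = start + 1L, end = end))
  merged <- GenomicRanges::reduce(GenomicRanges::sort(gr))
  out <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged) - 1L,
    end = GenomicRanges::end(merged)
  )
  out <- dplyr::arrange(out, .data$chrom, .data$start)
  out <- dplyr::mutate(out,
                       site_id = paste0(.data$chrom, ":", .data$start, "-", .data$end),
                       .before = 1L)
  attr(out, "dataset_ids") <- dataset_ids
  out
}

bind_peak_datasets <- function(peak_datasets, keep_excluded = FALSE) {
  if (is.data.frame(peak_datasets)) return(tibble::as_tibble(peak_datasets))
  if (!keep_excluded) {
    drop_flagged <- vapply(peak_datasets, function(p) {
      !is.null(attr(p, "included")) && !isTRUE(attr(p, "included"))
    }, logical(1))
    peak_datasets <- peak_datasets[!drop_flagged]
  }
  if (!length(peak_datasets)) {
    return(tibble::tibble(dataset_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          summit = integer(), fold_enrichment = numeric()))
  }
  dplyr::bind_rows(peak_datasets)
}

#' Assign occupancy scores and frequencies to atlas sites
#'
#' The occupancy score of a site is the tally of datasets exhibiting at least
#' one peak (summit) within the site: a dataset contributes at most 1 no
#' matter how many of its peaks fall inside. The occupancy frequency is the
#' score divided by the number of datasets considered. Sites reaching
#' `high_confidence_min_occupancy` (3 by default) are flagged
#' `high_confidence`.
#'
#' @inheritParams build_union_atlas
#' @param atlas Site tibble from [build_union_atlas()].
#' @param n_datasets Denominator for the frequency; defaults to the number of
#'   distinct datasets supplied (use this to score a stratum of a larger
#'   cohort against its own size).
#' @return The atlas tibble with `occupancy_score`, `occupancy_frequency` and
#'   `high_confidence` columns added.
#' @export
compute_occupancy <- function(atlas, peak_datasets, cfg = NULL,
                              n_datasets = NULL, keep_excluded = FALSE) {
  cfg <- as_config(cfg)
  peaks <- bind_peak_datasets(peak_datasets, keep_excluded)
  provenance <- attr(atlas, "dataset_ids")
  supplied <- unique(peaks$dataset_id)
  if (!is.null(provenance) && length(provenance) &&
      length(setdiff(supplied, provenance)) &&
      !is.null(n_datasets)) {
    # scoring a stratum against an unrelated atlas is almost certainly a bug
    stop("dataset id(s) not in atlas provenance: ",
         paste(utils::head(setdiff(supplied, provenance), 5L), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(n_datasets)) n_datasets <- length(supplied)
  score <- count_datasets_per_site(atlas, peaks)
  out <- dplyr::mutate(
    atlas,
    occupancy_score = score,
    occupancy_frequency = if (n_datasets > 0) score / n_datasets else 0,
    high_confidence = score >= cfg$high_confidence_min_occupancy
  )
  attr(out, "dataset_ids") <- provenance
  attr(out, "n_datasets") <- n_datasets
  out
}

count_datasets_per_site <- function(atlas, peaks) {
  if (nrow(atlas) == 0L) return(integer(0))
  if (nrow(peaks) == 0L) return(integer(nrow(atlas)))
  sites_gr <- GenomicRanges::GRanges(
    atlas$chrom, IRanges::IRanges(start = atlas$start + 1L, end = atlas$end))
  summit_gr <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(start = peaks$summit + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(summit_gr, sites_gr)
  inc <- tibble::tibble(site = S4Vectors::subjectHits(hits),
                        dataset = peaks$dataset_id[S4Vectors::queryHits(hits)])
  inc <- dplyr::distinct(inc)
  tab <- table(factor(inc$site, levels = seq_len(nrow(atlas))))
  as.integer(tab)
}

#' Histogram of gaps between adjacent pooled peak summits
#'
#' Summits from all datasets are pooled per chromosome, sorted, and gaps
#' between consecutive summits tallied in 1-bp bins. The inflection of this
#' distribution is the diagnostic behind the 150-bp merge cutoff.
#'
#' @inheritParams build_union_atlas
#' @return A tibble `gap, count` sorted by gap; empty when fewer than two
#'   summits share a chromosome.
#' @export
summit_interval_histogram <- function(peak_datasets) {
  peaks <- bind_peak_datasets(peak_datasets, keep_excluded = TRUE)
  gaps <- peaks |>
    dplyr::group_by(.data$chrom) |>
    dplyr::reframe(gap = diff(sort(.data$summit)))
  if (nrow(gaps) == 0L) {
    return(tibble::tibble(gap = integer(), count = integer()))
  }
  gaps |>
    dplyr::count(.data$gap, name = "count") |>
    dplyr::arrange(.data$gap)
}

# ---- position weight matrices -----------------------------------------------

#' Convert a position frequency matrix to a log-likelihood-ratio PWM
#'
#' Counts get a pseudocount per cell (0.5 by default) before conversion to
#' per-position probabilities; the PWM entry is log2(p_motif / p_background).
#' A column whose probabilities equal the background therefore scores 0 for
#' every base.
#'
#' @param pfm 4 x width count matrix with rows A, C, G, T.
#' @param background Length-4 background frequencies for A, C, G, T
#'   (default 0.275, 0.225, 0.225, 0.275).
#' @param pseudocount Added to every cell before normalization.
#' @return 4 x width matrix of log2 likelihood ratios.
#' @export
pwm_from_pfm <- function(pfm,
                         background = c(0.275, 0.225, 0.225, 0.275),
                         pseudocount = 0.5) {
  stopifnot(nrow(pfm) == 4L)
  probs <- sweep(pfm + pseudocount, 2, colSums(pfm + pseudocount), "/")
  lw <- log2(probs / background)
  rownames(lw) <- c("A", "C", "G", "T")
  lw
}

#' Exact null distribution of PWM scores and tail p-values
#'
#' `pwm_score_distribution()` computes the distribution of the total
#' log-likelihood-ratio score of a random background sequence by dynamic
#' programming over per-position score distributions. For matrices up to
#' width 11 the achievable sums are carried exactly (value-merged DP); wider
#' matrices use a discretized lattice with step `step` log-units.
#' `pwm_exact_pvalue()` returns `P(score >= s)` with a 1e-9 score tolerance,
#' so a score achieved by some sequence always includes that sequence's
#' probability mass.
#'
#' @param pwm Log-likelihood-ratio matrix from [pwm_from_pfm()].
#' @param background Length-4 background frequencies (A, C, G, T).
#' @param step Lattice discretization step for wide matrices.
#' @return `pwm_score_distribution()`: list with sorted `value`, `prob` and a
#'   tail cumulative `tail_prob`; `pwm_exact_pvalue()`: a probability.
#' @export
pwm_score_distribution <- function(pwm,
                                   background = c(0.275, 0.225, 0.225, 0.275),
                                   step = 1e-3) {
  w <- ncol(pwm)
  if (4^w <= 2^22) {
    value <- 0
    prob <- 1
    for (k in seq_len(w)) {
      v <- as.vector(outer(value, pwm[, k], "+"))
      p <- as.vector(outer(prob, background, "*"))
      o <- order(v)
      v <- v[o]; p <- p[o]
      grp <- cumsum(c(TRUE, diff(v) > 0))
      value <- v[!duplicated(grp)]
      prob <- as.vector(rowsum(p, grp))
    }
  } else {
    q <- round(pwm / step)
    dist <- 1
    off <- 0  # current vector covers lattice offsets off .. off+length-1
    for (k in seq_len(w)) {
      qk <- q[, k]
      newlo <- off + min(qk)
      newhi <- off + length(dist) - 1L + max(qk)
      nd <- numeric(newhi - newlo + 1L)
      for (b in 1:4) {
        sh <- off + qk[b] - newlo
        idx <- seq_along(dist) + sh
        nd[idx] <- nd[idx] + dist * background[b]
      }
      dist <- nd
      off <- newlo
    }
    keep <- dist > 0
    value <- (seq_along(dist) - 1L + off)[keep] * step
    prob <- dist[keep]
  }
  list(value = value, prob = prob,
       tail_prob = rev(cumsum(rev(prob))))
}

#' @rdname pwm_score_distribution
#' @param score Query log-likelihood-ratio score (may be `-Inf`).
#' @param dist Optional precomputed distribution to avoid recomputation.
#' @export
pwm_exact_pvalue <- function(score, pwm,
                             background = c(0.275, 0.225, 0.225, 0.275),
                             dist = NULL) {
  if (is.null(dist)) dist <- pwm_score_distribution(pwm, background)
  if (score == -Inf) return(1)
  idx <- findInterval(score - 1e-9, dist$value) + 1L
  if (idx > length(dist$value)) return(0)
  dist$tail_prob[idx]
}

# ---- motif scanning ---------------------------------------------------------

#' Scan atlas sites for their best motif hit
#'
#' Both strands of each site interval are scanned with the PWM; a window's
#' minus-strand score is the score of its reverse complement. Windows
#' containing a non-ACGT base are skipped. A hit is kept only if its exact
#' tail p-value is at or below `pwm_pvalue_threshold`; among passing windows
#' the smallest p-value wins, ties broken by smaller start then + strand.
#'
#' @param sites Atlas tibble (`site_id, chrom, start, end`).
#' @param genome Named `DNAStringSet` or named character vector of chromosome
#'   sequences.
#' @param pfm 4 x width count matrix (see [read_jaspar_pfm()]).
#' @param cfg A [pipeline_config()].
#' @return `sites` with columns `motif_start, motif_strand, motif_score,
#'   motif_p` (`NA` where no window passes).
#' @export
scan_best_motif <- function(sites, genome, pfm, cfg = NULL) {
  cfg <- as_config(cfg)
  bg <- unname(cfg$pwm_background)
  pwm <- pwm_from_pfm(pfm, bg, cfg$pwm_pseudocount)
  w <- ncol(pwm)
  dist <- pwm_score_distribution(pwm, bg)
  if (!is.character(genome)) genome <- as.character(genome)
  hits <- purrr::pmap(
    list(sites$chrom, sites$start, sites$end),
    function(chrom, start, end) {
      seq <- substr(genome[[chrom]], start + 1L, end)
      best_motif_in_sequence(seq, pwm, bg, dist, cfg$pwm_pvalue_threshold,
                             offset = start)
    })
  dplyr::bind_cols(sites, dplyr::bind_rows(hits))
}

no_hit <- tibble::tibble(motif_start = NA_integer_, motif_strand = NA_character_,
                         motif_score = NA_real_, motif_p = NA_real_)

best_motif_in_sequence <- function(seq, pwm, background, dist, p_threshold,
                                   offset = 0L) {
  codes <- seq_codes(seq)
  n <- length(codes)
  w <- ncol(pwm)
  if (n < w) return(no_hit)
  starts <- seq_len(n - w + 1L)
  # window starting at s is clean iff no NA in codes[s..s+w-1]
  na_run <- vapply(starts, function(s) anyNA(codes[s:(s + w - 1L)]), logical(1))
  fwd <- vapply(starts, function(s) {
    if (na_run[s]) return(NA_real_)
    sum(pwm[cbind(codes[s:(s + w - 1L)], seq_len(w))])
  }, numeric(1))
  rc_pwm <- pwm[4:1, w:1]
  rev_ <- vapply(starts, function(s) {
    if (na_run[s]) return(NA_real_)
    sum(rc_pwm[cbind(codes[s:(s + w - 1L)], seq_len(w))])
  }, numeric(1))
  if (anyNA(codes)) {
    warning(sum(na_run), " window(s) containing non-ACGT bases skipped",
            call. = FALSE)
  }
  cand <- tibble::tibble(
    start = rep(starts - 1L, 2L),
    strand = rep(c("+", "-"), each = length(starts)),
    score = c(fwd, rev_)
  )
  cand <- cand[!is.na(cand$score), , drop = FALSE]
  if (nrow(cand) == 0L) return(no_hit)
  cand$p <- vapply(cand$score, pwm_exact_pvalue, numeric(1),
                   pwm = pwm, background = background, dist = dist)
  cand <- cand[cand$p <= p_threshold, , drop = FALSE]
  if (nrow(cand) == 0L) return(no_hit)
  cand <- cand[order(cand$p, cand$start, cand$strand), , drop = FALSE]
  tibble::tibble(motif_start = as.integer(offset + cand$start[1]),
                 motif_strand = cand$strand[1],
                 motif_score = cand$score[1],
                 motif_p = cand$p[1])
}

seq_codes <- function(seq) {
  m <- match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T"))
  m
}

revcomp <- function(seq) {
  chartr("ACGTacgt", "TGCAtgca",
         paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}
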