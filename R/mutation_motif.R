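#' Per-base-pair mutation-rate profile around a site group
#'
#' Counts mutation events (per sample, per position) at each offset of the
#' `mutation_window` (400 bp) region centered at every site and divides by
#' the number of sites, giving the mean mutation count per site per bp at
#' offsets -200 .. +199.
#'
#' @param sites Tibble of sites (`chrom, start, end`).
#' @param mutations Tibble from [read_mutations()] (0-based `pos`).
#' @param cfg A [pipeline_config()].
#' @return Tibble `offset, rate` of length `mutation_window`.
#' @export
mutation_rate_profile <- function(sites, mutations, cfg = NULL) {
  cfg <- as_config(cfg)
  if (nrow(sites) == 0L) stop("empty site set", call. = FALSE)
  hw <- cfg$mutation_window %/% 2L
  offsets <- seq(-hw, hw - 1L)
  counts <- integer(length(offsets))
  if (nrow(mutations)) {
    centers <- site_center(sites$start, sites$end)
    site_gr <- GenomicRanges::GRanges(
      sites$chrom, IRanges::IRanges(start = centers - hw + 1L, width = 2L * hw))
    mut_gr <- GenomicRanges::GRanges(
      mutations$chrom, IRanges::IRanges(start = mutations$pos + 1L, width = 1L))
    hits <- GenomicRanges::findOverlaps(mut_gr, site_gr)
    off <- mutations$pos[S4Vectors::queryHits(hits)] -
      centers[S4Vectors::subjectHits(hits)]
    tab <- table(factor(off, levels = offsets))
    counts <- as.integer(tab)
  }
  tibble::tibble(offset = offsets, rate = counts / nrow(sites))
}

#' Log-likelihood-ratio motif score of a fixed-width sequence
#'
#' Sum over positions of `log2(p_pwm(base) / p_background(base))` for a
#' sequence whose length equals the PWM width. For minus-strand motifs the
#' reverse complement of the sequence is scored. Non-ACGT positions are
#' skipped with a warning.
#'
#' @param seq Character sequence of length equal to the PWM width.
#' @param pwm Log-likelihood-ratio matrix from [pwm_from_pfm()].
#' @param strand `"+"` or `"-"`.
#' @return Numeric score (log2 units).
#' @export
motif_llr_score <- function(seq, pwm, strand = "+") {
  if (strand == "-") seq <- revcomp(seq)
  codes <- seq_codes(seq)
  w <- ncol(pwm)
  if (length(codes) != w) {
    stop("sequence length ", length(codes), " does not match PWM width ", w,
         call. = FALSE)
  }
  bad <- is.na(codes)
  if (any(bad)) {
    warning(sum(bad), " non-ACGT position(s) skipped in motif scoring",
            call. = FALSE)
  }
  pos <- which(!bad)
  sum(pwm[cbind(codes[pos], pos)])
}

#' Differential motif score of a variant
#'
#' Scores the 19-bp (PWM-width) reference window centered on a site's motif
#' and the same window carrying the alternate allele; the delta
#' (`alt - ref`) is negative when the variant disrupts the motif. Variants
#' outside the window are reported with `delta = 0` and
#' `status = "out_of_window"`. Only single-nucleotide variants are scored.
#'
#' @param site One-row tibble with `chrom` and motif annotation
#'   (`motif_start`, `motif_strand`; the window is the PWM width anchored at
#'   `motif_start`).
#' @param variant One-row tibble `chrom, pos` (0-based), `ref, alt`.
#' @param genome Named character vector / `DNAStringSet` of chromosome
#'   sequences.
#' @param pwm Log-likelihood-ratio matrix.
#' @return One-row tibble `ref_score, alt_score, delta, status`.
#' @export
differential_motif_score <- function(site, variant, genome, pwm) {
  w <- ncol(pwm)
  if (!is.character(genome)) genome <- as.character(genome)
  if (is.na(site$motif_start)) {
    stop("site has no motif annotation", call. = FALSE)
  }
  if (nchar(variant$ref) != 1L || nchar(variant$alt) != 1L) {
    return(tibble::tibble(ref_score = NA_real_, alt_score = NA_real_,
                          delta = 0, status = "indel_not_scored"))
  }
  win_start <- site$motif_start
  win_end <- win_start + w  # half-open
  pos <- variant$pos
  ref_seq <- substr(genome[[site$chrom]], win_start + 1L, win_end)
  if (pos < win_start || pos >= win_end) {
    return(tibble::tibble(ref_score = NA_real_, alt_score = NA_real_,
                          delta = 0, status = "out_of_window"))
  }
  k <- pos - win_start + 1L
  if (toupper(substr(ref_seq, k, k)) != toupper(variant$ref)) {
    stop("variant ref allele '", variant$ref, "' disagrees with genome base '",
         substr(ref_seq, k, k), "' at ", site$chrom, ":", pos, call. = FALSE)
  }
  alt_seq <- ref_seq
  substr(alt_seq, k, k) <- toupper(variant$alt)
  strand <- if (is.na(site$motif_strand)) "+" else site$motif_strand
  ref_score <- motif_llr_score(ref_seq, pwm, strand)
  alt_score <- motif_llr_score(alt_seq, pwm, strand)
  tibble::tibble(ref_score = ref_score, alt_score = alt_score,
                 delta = alt_score - ref_score, status = "scored")
}
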