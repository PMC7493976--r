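#' Sparse symmetric contact map
#'
#' A per-chromosome binned Hi-C contact map stored sparsely. Entries are
#' folded into the canonical upper triangle (`i <= j`) with duplicates and
#' mirrored entries summed into one record, so the map is symmetric by
#' construction (`a_ij = a_ji`).
#'
#' @param entries Tibble `i, j, count` of 0-based bin indices.
#' @param chrom Chromosome name.
#' @param bin_size Bin size in bp.
#' @param n_bins Number of bins; inferred from the largest index if `NULL`.
#' @param normalized Whether the counts are already expected-at-distance
#'   normalized.
#' @return A list of class `"contact_map"` with fields `chrom, bin_size,
#'   n_bins, entries, normalized`.
#' @export
contact_map <- function(entries, chrom, bin_size = 5000L, n_bins = NULL,
                        normalized = FALSE) {
  stopifnot(all(c("i", "j", "count") %in% names(entries)))
  if (any(entries$count < 0)) stop("contact counts must be >= 0", call. = FALSE)
  i <- pmin(entries$i, entries$j)
  j <- pmax(entries$i, entries$j)
  ent <- tibble::tibble(i = as.integer(i), j = as.integer(j),
                        count = as.numeric(entries$count))
  ent <- ent |>
    dplyr::group_by(.data$i, .data$j) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::arrange(.data$i, .data$j)
  if (is.null(n_bins)) n_bins <- if (nrow(ent)) max(ent$j) + 1L else 0L
  if (nrow(ent) && max(ent$j) >= n_bins) {
    stop("bin index exceeds n_bins", call. = FALSE)
  }
  structure(list(chrom = as.character(chrom), bin_size = as.integer(bin_size),
                 n_bins = as.integer(n_bins), entries = ent,
                 normalized = normalized),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> %s: %d bins of %d bp, %d nonzero pairs%s\n",
              x$chrom, x$n_bins, x$bin_size, nrow(x$entries),
              if (x$normalized) " (distance-normalized)" else ""))
  invisible(x)
}

#' Mean interaction per genomic distance
#'
#' For each distance `d_k = k x bin_size` the mean count over **all**
#' `n_bins - k` bin pairs at that distance on the chromosome (zeros
#' included), the expected-at-distance profile used for normalization.
#'
#' @param map A [contact_map()].
#' @return Tibble `k, distance, mean_count, n_pairs` for `k` in
#'   `1 .. n_bins - 1`.
#' @export
distance_profile <- function(map) {
  k <- seq_len(max(map$n_bins - 1L, 0L))
  sums <- numeric(length(k))
  ent <- map$entries[map$entries$j > map$entries$i, , drop = FALSE]
  if (nrow(ent)) {
    agg <- rowsum(ent$count, ent$j - ent$i)
    sums[as.integer(rownames(agg))] <- agg[, 1]
  }
  n_pairs <- map$n_bins - k
  tibble::tibble(k = k, distance = k * map$bin_size,
                 mean_count = sums / n_pairs, n_pairs = n_pairs)
}

#' Expected-at-distance normalization of a contact map
#'
#' Because contact probability decays with genomic distance, every off-
#' diagonal entry is divided by the chromosome-wide mean count at its
#' distance (`a'_ij = a_ij / S_bar(d)`). Zero entries stay zero; distances
#' whose mean is zero are left at zero and recorded in the
#' `zero_distances` attribute. The diagonal (`k = 0`) is excluded from
#' normalization and dropped from the normalized map, as it takes no part in
#' downstream tests.
#'
#' @param map A raw [contact_map()].
#' @return A normalized `contact_map` (`normalized = TRUE`), carrying the
#'   distance profile in attribute `profile`.
#' @export
normalize_by_distance <- function(map) {
  prof <- distance_profile(map)
  ent <- map$entries[map$entries$j > map$entries$i, , drop = FALSE]
  k <- ent$j - ent$i
  sbar <- prof$mean_count[k]
  keep <- sbar > 0
  ent$count <- ifelse(keep, ent$count / ifelse(sbar > 0, sbar, 1), 0)
  out <- contact_map(ent, map$chrom, map$bin_size, map$n_bins,
                     normalized = TRUE)
  attr(out, "profile") <- prof
  attr(out, "zero_distances") <- prof$k[prof$mean_count == 0]
  out
}

# Dense lookup of normalized contacts between a fixed bin and a set of bins.
map_values_at <- function(map, anchor_bin, bins) {
  ent <- map$entries
  i <- pmin(anchor_bin, bins)
  j <- pmax(anchor_bin, bins)
  nb <- as.numeric(map$n_bins)
  hit <- match(i * nb + j, ent$i * nb + ent$j)
  vals <- ent$count[hit]
  vals[is.na(vals)] <- 0
  vals
}

#' Interaction vector between a site and its flanking bins
#'
#' The anchor bin is `floor(site_center / bin_size)`; the vector collects the
#' normalized interactions between the anchor bin and every non-overlapping
#' bin within `hic_flank_L` on **both** sides, ordered by signed offset, the
#' anchor bin itself excluded. Bins outside the chromosome are truncated;
#' distances whose chromosome-wide mean was zero are dropped (their
#' normalized value is undefined).
#'
#' @param site One-row tibble with `start, end` (on the map's chromosome).
#' @param map A normalized [contact_map()].
#' @param cfg A [pipeline_config()].
#' @param sides `"both"` (default) or `"right"` for the one-sided variant.
#' @return Tibble `bin, offset, value` ordered by `offset`.
#' @export
site_flank_vector <- function(site, map, cfg = NULL, sides = c("both", "right")) {
  cfg <- as_config(cfg)
  sides <- match.arg(sides)
  anchor <- site_center(site$start, site$end) %/% map$bin_size
  if (anchor < 0 || anchor >= map$n_bins) {
    stop("anchor bin ", anchor, " outside contact map", call. = FALSE)
  }
  span <- cfg$hic_flank_L %/% map$bin_size
  offsets <- if (sides == "both") c(-(span:1), seq_len(span)) else seq_len(span)
  bins <- anchor + offsets
  ok <- bins >= 0 & bins < map$n_bins
  zd <- attr(map, "zero_distances")
  if (!is.null(zd)) ok <- ok & !(abs(offsets) %in% zd)
  bins <- bins[ok]
  offsets <- offsets[ok]
  tibble::tibble(bin = bins, offset = offsets,
                 value = map_values_at(map, anchor, bins))
}

#' Differential chromatin interaction at a site
#'
#' Collects the flank interaction vectors of a site from the cancer and
#' normal normalized maps, pairs them bin-by-bin, and applies a paired
#' two-tailed Student's t test to the differences. The mean log2 fold change
#' uses a pseudocount (`hic_pseudocount`, 0.01) on the normalized values.
#' All-zero difference vectors give `t = 0, p = 1`.
#'
#' @param site One-row tibble with `site_id, start, end`.
#' @param map_cancer,map_normal Normalized [contact_map()]s sharing
#'   chromosome and bin size.
#' @param cfg A [pipeline_config()].
#' @param sides Flank sides, see [site_flank_vector()].
#' @return One-row tibble `site_id, n_flank_bins, mean_log2_fc, t_statistic,
#'   p_value, status` (`"ok"` or `"insufficient_data"`).
#' @export
differential_interaction <- function(site, map_cancer, map_normal, cfg = NULL,
                                     sides = "both") {
  cfg <- as_config(cfg)
  if (map_cancer$chrom != map_normal$chrom ||
      map_cancer$bin_size != map_normal$bin_size) {
    stop("cancer and normal maps must share chromosome and bin size",
         call. = FALSE)
  }
  vc <- site_flank_vector(site, map_cancer, cfg, sides)
  vn <- site_flank_vector(site, map_normal, cfg, sides)
  common <- intersect(vc$offset, vn$offset)
  ic <- vc$value[match(common, vc$offset)]
  in_ <- vn$value[match(common, vn$offset)]
  sid <- if ("site_id" %in% names(site)) site$site_id else NA_character_
  if (length(common) < 3L || all(ic == 0 & in_ == 0)) {
    return(tibble::tibble(site_id = sid, n_flank_bins = length(common),
                          mean_log2_fc = NA_real_, t_statistic = NA_real_,
                          p_value = NA_real_, status = "insufficient_data"))
  }
  eps <- cfg$hic_pseudocount
  lfc <- mean(log2((ic + eps) / (in_ + eps)))
  diffs <- ic - in_
  if (all(diffs == 0)) {
    t_stat <- 0; p <- 1
  } else if (stats::sd(diffs) == 0) {
    t_stat <- sign(mean(diffs)) * Inf; p <- 0
  } else {
    tt <- stats::t.test(ic, in_, paired = TRUE)
    t_stat <- unname(tt$statistic); p <- tt$p.value
  }
  tibble::tibble(site_id = sid, n_flank_bins = length(common),
                 mean_log2_fc = lfc, t_statistic = t_stat, p_value = p,
                 status = "ok")
}

#' Intra-domain differentially interacting regions
#'
#' For each site with a chromatin domain, reports the in-domain bins whose
#' normalized interaction with the site's anchor bin changed strongly between
#' conditions: increased (`log2 FC > 1`) for gained-direction queries,
#' decreased (`log2 FC < -1`) for lost-direction queries, always requiring
#' the mean of the two conditions' log2 interactions to be positive (so only
#' bins with appreciable interaction in at least one condition qualify).
#' Fold changes and means use the `hic_pseudocount` on normalized values.
#'
#' @param sites Tibble of sites (`site_id, chrom, start, end`).
#' @param map_cancer,map_normal Normalized [contact_map()]s.
#' @param domains Tibble from [build_domains()] (`site_id, domain_start,
#'   domain_end, found`).
#' @param cfg A [pipeline_config()].
#' @param direction `"increased"` or `"decreased"`.
#' @return Tibble `site_id, bin, bin_start, bin_end, log2_fc,
#'   mean_log2_interaction`; sites without a domain are skipped.
#' @export
find_differential_regions <- function(sites, map_cancer, map_normal, domains,
                                      cfg = NULL,
                                      direction = c("increased", "decreased")) {
  cfg <- as_config(cfg)
  direction <- match.arg(direction)
  eps <- cfg$hic_pseudocount
  bs <- map_cancer$bin_size
  out <- purrr::map(seq_len(nrow(sites)), function(k) {
    site <- sites[k, ]
    dom <- domains[domains$site_id == site$site_id, , drop = FALSE]
    if (!nrow(dom) || !isTRUE(dom$found[1])) return(NULL)
    anchor <- site_center(site$start, site$end) %/% bs
    bins <- (dom$domain_start[1] %/% bs):((dom$domain_end[1] - 1L) %/% bs)
    bins <- setdiff(bins, anchor)
    bins <- bins[bins >= 0 & bins < map_cancer$n_bins]
    if (!length(bins)) return(NULL)
    ic <- map_values_at(map_cancer, anchor, bins)
    in_ <- map_values_at(map_normal, anchor, bins)
    lfc <- log2((ic + eps) / (in_ + eps))
    mli <- (log2(ic + eps) + log2(in_ + eps)) / 2
    keep <- if (direction == "increased") lfc > 1 else lfc < -1
    keep <- keep & mli > 0
    if (!any(keep)) return(NULL)
    tibble::tibble(site_id = site$site_id, bin = bins[keep],
                   bin_start = bins[keep] * bs,
                   bin_end = (bins[keep] + 1L) * bs,
                   log2_fc = lfc[keep],
                   mean_log2_interaction = mli[keep])
  })
  res <- dplyr::bind_rows(out)
  if (!nrow(res)) {
    res <- tibble::tibble(site_id = character(), bin = integer(),
                          bin_start = integer(), bin_end = integer(),
                          log2_fc = numeric(),
                          mean_log2_interaction = numeric())
  }
  res
}
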