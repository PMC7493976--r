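#' Synthetic-scenario configuration
#'
#' Parameters of the planted-truth multi-omics generator. The defaults
#' describe the benchmark scenario used throughout the package: 2,000 sites
#' on two 2-Mb chromosomes observed by 8 cancer, 8 matched-normal and 24
#' other datasets, with 2.5% of sites planted as cancer-lost and 2.5% as
#' cancer-gained.
#'
#' Site classes and their per-cohort peak presence probabilities
#' (cancer / matched normal / other):
#' constitutive 0.95/0.95/0.95, common 0.85/0.85/0.85,
#' cancer_lost 0.02/0.95/0.95, cancer_gained 0.95/0/0,
#' sample_specific 0.05/0.05/0.05. With these defaults a lost site has
#' expected cancer occupancy frequency well below 0.2 and overall frequency
#' above 0.7, and a gained site is absent from matched normal by
#' construction, as the calling criteria require.
#'
#' @param ... Named overrides of the defaults.
#' @return A list of class `"ctcf_scenario_config"`.
#' @export
scenario_config <- function(...) {
  cfg <- list(
    n_chromosomes = 2L,
    chrom_length = 2000000L,
    n_sites = 2000L,
    n_datasets_cancer = 8L,
    n_datasets_normal_matched = 8L,
    n_datasets_other = 24L,
    class_fractions = c(constitutive = 0.10, common = 0.60,
                        cancer_lost = 0.025, cancer_gained = 0.025,
                        sample_specific = 0.25),
    presence = list(
      constitutive = c(cancer = 0.95, normal = 0.95, other = 0.95),
      common = c(cancer = 0.85, normal = 0.85, other = 0.85),
      cancer_lost = c(cancer = 0.02, normal = 0.95, other = 0.95),
      cancer_gained = c(cancer = 0.95, normal = 0, other = 0),
      sample_specific = c(cancer = 0.05, normal = 0.05, other = 0.05)
    ),
    signal_baseline_log2 = -1,
    signal_effect_log2 = 3.3,
    signal_noise_sd = 0.3,
    summit_jitter_sd = 10,
    site_halfwidth = 75L,
    min_spacing = 1000L,
    hic_decay_exponent = 1,
    hic_interaction_boost = 2,
    hic_scale = 100,
    meth_shift = 30,
    meth_baseline = 30,
    meth_coverage_mean = 50,
    meth_low_coverage_fraction = 0.1,
    mutation_background_rate = 1e-4,
    mutation_n_samples = 10L,
    n_genes = 200L,
    n_cell_types = 12L,
    expression_r = 0.8,
    n_planted_pairs = 100L,
    seed = 1L
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(cfg))
  if (length(bad)) stop("unknown scenario field(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  cfg[names(overrides)] <- overrides
  if (abs(sum(cfg$class_fractions) - 1) > 1e-9) {
    stop("class fractions must sum to 1 (within 1e-9)", call. = FALSE)
  }
  for (cls in names(cfg$presence)) {
    p <- cfg$presence[[cls]]
    if (any(p < 0 | p > 1)) stop("presence probabilities must be in [0, 1]",
                                 call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "ctcf_scenario_config")
}

# Keyed substreams: each modality draws from its own seed so adding one
# modality never perturbs the others.
substream_seed <- function(seed, key) {
  offsets <- c(sites = 101L, presence = 202L, peaks = 303L, signal = 404L,
               genome = 505L, genes = 606L, expression = 707L, hic = 808L,
               meth = 909L, mutation = 1010L)
  (as.integer(seed) * 1009L + offsets[[key]]) %% 2147483647L
}

#' Generate a planted-truth multi-omics scenario
#'
#' Emits peak datasets, a cohort design, an RPKM-like signal matrix, a
#' genome with the motif consensus planted at constitutive and gained sites,
#' gene models, a cell-type expression panel with planted CTCF-gene pairs,
#' and the ground truth. Fully deterministic given `cfg$seed`.
#'
#' Site positions are non-overlapping with at least `min_spacing` (1 kb)
#' between centers. Each dataset's peaks are summit jitters (normal,
#' sd `summit_jitter_sd` <= 20 bp, clamped to the site) of the sites drawn
#' present under the class/cohort presence model. Site-level signal is
#' log-normal: `RPKM = 2^(baseline + effect x present + noise)`, so bound
#' sites carry the planted log2 effect (3.3 by default, a roughly 10-fold
#' bound/unbound ratio consistent with the >= 4 fold-enrichment peak model)
#' over the unbound background of about 0.5 RPKM.
#'
#' @param cfg A [scenario_config()].
#' @param pfm Position frequency matrix whose consensus is planted
#'   (default [ctcf_demo_pfm()]).
#' @return A list with elements `peak_datasets` (named list of peak
#'   tibbles), `design`, `signal` (site x dataset RPKM tibble), `genome`
#'   (named character vector), `gene_models`, `expression` (list
#'   `site_signal`, `gene_expression` matrices over cell types),
#'   `sites` (planted site tibble) and `truth` (list `site_class`,
#'   `planted_pairs`, plus per-modality plants filled in by the other
#'   generators).
#' @export
generate_scenario <- function(cfg = scenario_config(), pfm = ctcf_demo_pfm()) {
  n <- cfg$n_sites
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  per_chrom <- diff(round(seq(0, n, length.out = cfg$n_chromosomes + 1L)))

  # --- site positions ---------------------------------------------------
  set.seed(substream_seed(cfg$seed, "sites"))
  margin <- 5000L
  sites <- purrr::map2(chroms, per_chrom, function(ch, k) {
    usable <- cfg$chrom_length - 2L * margin
    if (k * cfg$min_spacing > usable) {
      stop("cannot place ", k, " sites with ", cfg$min_spacing,
           " bp spacing on a ", cfg$chrom_length, " bp chromosome",
           call. = FALSE)
    }
    slack <- usable - k * cfg$min_spacing
    extra <- diff(c(0, sort(stats::runif(k, 0, slack))))
    centers <- margin + cumsum(cfg$min_spacing + extra)
    tibble::tibble(chrom = ch, center = as.integer(round(centers)))
  }) |> dplyr::bind_rows()
  hw <- cfg$site_halfwidth
  sites <- dplyr::mutate(sites,
                         start = .data$center - hw,
                         end = .data$center + hw,
                         site_id = paste0(.data$chrom, ":", .data$start, "-",
                                          .data$end))
  classes <- largest_remainder_counts(cfg$class_fractions, n)
  site_class <- sample(rep(names(classes), classes))
  sites$class <- site_class

  # --- cohort design ----------------------------------------------------
  design <- tibble::tibble(
    dataset_id = c(sprintf("cancer_%02d", seq_len(cfg$n_datasets_cancer)),
                   sprintf("normal_%02d", seq_len(cfg$n_datasets_normal_matched)),
                   sprintf("other_%02d", seq_len(cfg$n_datasets_other))),
    cohort = c(rep("cancer", cfg$n_datasets_cancer),
               rep("normal", cfg$n_datasets_normal_matched),
               rep("other", cfg$n_datasets_other)),
    cancer_type = c(rep("T-ALL", cfg$n_datasets_cancer),
                    rep(NA_character_,
                        cfg$n_datasets_normal_matched + cfg$n_datasets_other)),
    matched_normal = c(rep(NA_character_, cfg$n_datasets_cancer),
                       rep("T-ALL", cfg$n_datasets_normal_matched),
                       rep(NA_character_, cfg$n_datasets_other))
  )

  # --- presence ---------------------------------------------------------
  set.seed(substream_seed(cfg$seed, "presence"))
  pmat <- vapply(seq_len(nrow(design)), function(j) {
    p <- vapply(sites$class,
                function(cl) cfg$presence[[cl]][[design$cohort[j]]],
                numeric(1))
    stats::runif(n) < p
  }, logical(n))
  colnames(pmat) <- design$dataset_id
  rownames(pmat) <- sites$site_id

  # --- peaks ------------------------------------------------------------
  set.seed(substream_seed(cfg$seed, "peaks"))
  peak_datasets <- purrr::map(seq_len(nrow(design)), function(j) {
    idx <- which(pmat[, j])
    jitter <- round(stats::rnorm(length(idx), 0, cfg$summit_jitter_sd))
    jitter <- pmax(pmin(jitter, hw - 1L), -(hw - 1L))
    summit <- sites$center[idx] + as.integer(jitter)
    tibble::tibble(
      dataset_id = design$dataset_id[j],
      chrom = sites$chrom[idx],
      start = summit - 100L,
      end = summit + 100L,
      summit = summit,
      fold_enrichment = round(stats::rlnorm(length(idx), log(10), 0.3), 3)
    ) |> dplyr::arrange(.data$chrom, .data$start)
  })
  names(peak_datasets) <- design$dataset_id
  peak_datasets <- purrr::map(peak_datasets, function(p) {
    attr(p, "included") <- TRUE
    p
  })

  # --- signal -----------------------------------------------------------
  set.seed(substream_seed(cfg$seed, "signal"))
  log2sig <- cfg$signal_baseline_log2 + cfg$signal_effect_log2 * pmat +
    matrix(stats::rnorm(n * nrow(design), 0, cfg$signal_noise_sd),
           nrow = n)
  signal <- 2^log2sig
  dimnames(signal) <- dimnames(pmat)

  # --- genome -----------------------------------------------------------
  set.seed(substream_seed(cfg$seed, "genome"))
  bg <- c(A = 0.275, C = 0.225, G = 0.225, T = 0.275)
  genome <- stats::setNames(vapply(chroms, function(ch) {
    paste(sample(names(bg), cfg$chrom_length, replace = TRUE, prob = bg),
          collapse = "")
  }, character(1)), chroms)
  consensus <- pfm_consensus(pfm)
  w <- nchar(consensus)
  motif_sites <- sites$class %in% c("constitutive", "cancer_gained")
  strand <- rep(NA_character_, n)
  for (ch in chroms) {
    idx <- which(motif_sites & sites$chrom == ch)
    # alternate boundary orientation along the chromosome so divergently
    # oriented constitutive pairs exist
    strand[idx] <- rep(c("+", "-"), length.out = length(idx))
    for (k in seq_along(idx)) {
      i <- idx[k]
      at <- sites$center[i] - w %/% 2L
      planted <- if (strand[i] == "+") consensus else revcomp(consensus)
      substr(genome[[ch]], at + 1L, at + w) <- planted
    }
  }
  sites$planted_strand <- strand

  # --- gene models and expression panel --------------------------------
  set.seed(substream_seed(cfg$seed, "genes"))
  gene_models <- tibble::tibble(
    gene_id = sprintf("gene_%03d", seq_len(cfg$n_genes)),
    chrom = sample(chroms, cfg$n_genes, replace = TRUE),
    strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE),
    tss = as.integer(round(stats::runif(cfg$n_genes, margin,
                                        cfg$chrom_length - margin)))
  )
  set.seed(substream_seed(cfg$seed, "expression"))
  ct <- sprintf("celltype_%02d", seq_len(cfg$n_cell_types))
  site_ct <- matrix(2^stats::rnorm(n * cfg$n_cell_types, 3, 1),
                    nrow = n, dimnames = list(sites$site_id, ct))
  gene_ct <- matrix(2^stats::rnorm(cfg$n_genes * cfg$n_cell_types, 4, 1),
                    nrow = cfg$n_genes, dimnames = list(gene_models$gene_id, ct))
  n_pairs <- min(cfg$n_planted_pairs, n, cfg$n_genes)
  pair_sites <- sample(seq_len(n), n_pairs)
  pair_genes <- sample(seq_len(cfg$n_genes), n_pairs)
  r <- cfg$expression_r
  for (k in seq_len(n_pairs)) {
    x <- scale(sqrt(site_ct[pair_sites[k], ]))[, 1]
    y <- r * x + sqrt(1 - r^2) * stats::rnorm(cfg$n_cell_types)
    # map back to a non-negative TPM-like scale via the sqrt transform
    gene_ct[pair_genes[k], ] <- pmax(y + 3, 0.1)^2
  }
  planted_pairs <- tibble::tibble(site_id = sites$site_id[pair_sites],
                                  gene_id = gene_models$gene_id[pair_genes],
                                  r_target = r)

  truth <- list(
    site_class = stats::setNames(sites$class, sites$site_id),
    sites = sites,
    presence = pmat,
    planted_pairs = planted_pairs,
    planted_strand = stats::setNames(sites$planted_strand, sites$site_id)
  )
  list(peak_datasets = peak_datasets, design = design,
       signal = matrix_as_signal(signal), genome = genome,
       gene_models = gene_models,
       expression = list(site_signal = site_ct, gene_expression = gene_ct),
       sites = sites, truth = truth, config = cfg)
}

largest_remainder_counts <- function(fracs, n) {
  raw <- fracs * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    up <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[up] <- counts[up] + 1
  }
  stats::setNames(as.integer(counts), names(fracs))
}

pfm_consensus <- function(pfm) {
  paste(rownames(pfm)[apply(pfm, 2, which.max)], collapse = "")
}

#' Synthetic CTCF-like position frequency matrix
#'
#' A 19-column count matrix with the information profile of a CTCF core
#' motif (strongly constrained center, degenerate edges). This is a
#' synthetic stand-in constructed for demonstrations and testing, not a
#' database matrix.
#'
#' @return 4 x 19 count matrix with rows A, C, G, T.
#' @export
ctcf_demo_pfm <- function() {
  consensus <- strsplit("TGGCCACCAGGGGGCGCTA", "")[[1]]
  weight <- c(40, 55, 70, 85, 90, 95, 95, 95, 95, 95, 95, 90, 90, 85, 80,
              70, 60, 50, 40)
  total <- 100
  pfm <- matrix(0, 4, 19, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (k in 1:19) {
    rest <- (total - weight[k]) / 3
    pfm[, k] <- rest
    pfm[consensus[k], k] <- weight[k]
  }
  pfm
}

#' Generate a cancer/normal contact-map pair with planted boosts
#'
#' Counts at bin distance `k >= 1` are Poisson with mean
#' `hic_scale * k^(-hic_decay_exponent)`; in the cancer map, pairs between a
#' planted gained site's anchor bin and every bin within `hic_flank_L` have
#' their mean multiplied by `hic_interaction_boost`. With boost 1 the two
#' maps are exchangeable draws. Maps are symmetric by construction.
#'
#' @param cfg A [scenario_config()].
#' @param truth Ground truth from [generate_scenario()] (used for the gained
#'   anchors); pass `NULL` for a fully null pair.
#' @param chrom Chromosome to simulate (default `"chr1"`).
#' @param pipeline_cfg A [pipeline_config()] supplying `hic_bin_size` and
#'   `hic_flank_L`.
#' @param seed Optional override of the substream seed.
#' @return List `cancer, normal` of raw [contact_map()]s plus
#'   `boosted_anchor_bins`.
#' @export
generate_contact_map_pair <- function(cfg = scenario_config(), truth = NULL,
                                      chrom = "chr1", pipeline_cfg = NULL,
                                      seed = NULL) {
  pcfg <- as_config(pipeline_cfg)
  if (cfg$hic_decay_exponent <= 0) stop("decay exponent must be > 0",
                                        call. = FALSE)
  bs <- pcfg$hic_bin_size
  n_bins <- as.integer(cfg$chrom_length %/% bs)
  set.seed(if (is.null(seed)) substream_seed(cfg$seed, "hic") else seed)
  pairs <- which(upper.tri(matrix(0, n_bins, n_bins)), arr.ind = TRUE)
  i <- pairs[, 1] - 1L
  j <- pairs[, 2] - 1L
  k <- j - i
  lambda <- cfg$hic_scale * k^(-cfg$hic_decay_exponent)
  anchors <- integer(0)
  if (!is.null(truth)) {
    g <- truth$sites[truth$sites$class == "cancer_gained" &
                       truth$sites$chrom == chrom, , drop = FALSE]
    anchors <- unique(site_center(g$start, g$end) %/% bs)
  }
  lambda_c <- lambda
  if (length(anchors) && cfg$hic_interaction_boost != 1) {
    span <- pcfg$hic_flank_L %/% bs
    hit <- rep(FALSE, length(k))
    for (a in anchors) {
      hit <- hit | (i == a & (j - a) <= span) | (j == a & (a - i) <= span)
    }
    lambda_c[hit] <- lambda_c[hit] * cfg$hic_interaction_boost
  }
  mk <- function(lam) {
    cnt <- stats::rpois(length(lam), lam)
    keep <- cnt > 0
    contact_map(tibble::tibble(i = i[keep], j = j[keep], count = cnt[keep]),
                chrom = chrom, bin_size = bs, n_bins = n_bins)
  }
  cancer <- mk(lambda_c)
  normal <- mk(lambda)
  list(cancer = cancer, normal = normal, boosted_anchor_bins = anchors)
}

#' Generate cancer/normal CpG methylation tables
#'
#' CpG positions are placed every 20-60 bp within +/- 150 bp of each site
#' center; coverage is Poisson around `meth_coverage_mean` and methylated
#' counts are binomial at the site's methylation level: `meth_baseline`,
#' shifted up by `meth_shift` percentage points in the cancer table at
#' planted lost sites and down by the same amount at planted gained sites
#' (methylation change anti-correlated with the planted binding change). A
#' `meth_low_coverage_fraction` of sites is emitted with fewer than 3
#' adequately covered CpGs to exercise the insufficiency filter.
#'
#' @param cfg A [scenario_config()].
#' @param truth Ground truth from [generate_scenario()].
#' @param seed Optional substream-seed override.
#' @return List `cancer, normal` of CpG tibbles (see [read_cpg_table()]) and
#'   `low_coverage_sites` (site ids planted as insufficient).
#' @export
generate_methylation_tables <- function(cfg = scenario_config(), truth,
                                        seed = NULL) {
  set.seed(if (is.null(seed)) substream_seed(cfg$seed, "meth") else seed)
  sites <- truth$sites
  n <- nrow(sites)
  n_low <- round(cfg$meth_low_coverage_fraction * n)
  low <- sample(seq_len(n), n_low)
  low_flag <- seq_len(n) %in% low
  rows_c <- vector("list", n)
  rows_n <- vector("list", n)
  for (s in seq_len(n)) {
    center <- site_center(sites$start[s], sites$end[s])
    pos <- center - 150L + cumsum(sample(20:60, 20, replace = TRUE))
    pos <- pos[pos < center + 150L]
    m <- length(pos)
    cov_c <- stats::rpois(m, cfg$meth_coverage_mean)
    cov_n <- stats::rpois(m, cfg$meth_coverage_mean)
    if (low_flag[s]) {
      # at most 2 CpGs adequately covered in cancer -> insufficient
      cov_c <- c(stats::rpois(min(m, 2L), cfg$meth_coverage_mean),
                 sample(0:4, max(m - 2L, 0L), replace = TRUE))[seq_len(m)]
    }
    p_n <- cfg$meth_baseline / 100
    shift <- switch(sites$class[s],
                    cancer_lost = cfg$meth_shift / 100,
                    cancer_gained = -cfg$meth_shift / 100,
                    0)
    p_c <- min(max(p_n + shift, 0), 1)
    mc <- stats::rbinom(m, cov_c, p_c)
    mn <- stats::rbinom(m, cov_n, p_n)
    rows_c[[s]] <- tibble::tibble(chrom = sites$chrom[s], pos = pos,
                                  meth_count = mc, unmeth_count = cov_c - mc,
                                  coverage = cov_c,
                                  meth_level = ifelse(cov_c > 0,
                                                      100 * mc / cov_c, 0))
    rows_n[[s]] <- tibble::tibble(chrom = sites$chrom[s], pos = pos,
                                  meth_count = mn, unmeth_count = cov_n - mn,
                                  coverage = cov_n,
                                  meth_level = ifelse(cov_n > 0,
                                                      100 * mn / cov_n, 0))
  }
  col_order <- c("chrom", "pos", "meth_level", "meth_count", "unmeth_count",
                 "coverage")
  planted_delta <- dplyr::case_when(
    sites$class == "cancer_lost" ~ cfg$meth_shift,
    sites$class == "cancer_gained" ~ -cfg$meth_shift,
    TRUE ~ 0)
  list(cancer = dplyr::bind_rows(rows_c)[, col_order],
       normal = dplyr::bind_rows(rows_n)[, col_order],
       low_coverage_sites = sites$site_id[low],
       planted_delta = stats::setNames(planted_delta, sites$site_id))
}

#' Generate a mutation table over site windows
#'
#' Background mutations fall uniformly (per bp, per sample) in the 400-bp
#' window around every site; optional planted variants are appended as
#' given. Reference alleles are taken from the genome; alternates are drawn
#' uniformly from the other three bases.
#'
#' @param cfg A [scenario_config()].
#' @param truth Ground truth from [generate_scenario()].
#' @param genome Named character vector of chromosome sequences.
#' @param planted Optional tibble `chrom, pos, ref, alt, sample_id` appended
#'   verbatim.
#' @param pipeline_cfg A [pipeline_config()] supplying `mutation_window`.
#' @param seed Optional substream-seed override.
#' @return Mutation tibble (`chrom, pos, ref, alt, sample_id`, 0-based pos).
#' @export
generate_mutations <- function(cfg = scenario_config(), truth, genome,
                               planted = NULL, pipeline_cfg = NULL,
                               seed = NULL) {
  pcfg <- as_config(pipeline_cfg)
  set.seed(if (is.null(seed)) substream_seed(cfg$seed, "mutation") else seed)
  sites <- truth$sites
  hw <- pcfg$mutation_window %/% 2L
  samples <- sprintf("sample_%02d", seq_len(cfg$mutation_n_samples))
  lam <- cfg$mutation_background_rate * pcfg$mutation_window
  out <- list()
  bases <- c("A", "C", "G", "T")
  for (sm in samples) {
    n_events <- stats::rpois(nrow(sites), lam)
    idx <- rep(seq_len(nrow(sites)), n_events)
    if (!length(idx)) next
    centers <- site_center(sites$start[idx], sites$end[idx])
    pos <- centers - hw + floor(stats::runif(length(idx), 0,
                                             pcfg$mutation_window))
    ref <- toupper(substring(genome[sites$chrom[idx]], pos + 1L, pos + 1L))
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
    out[[sm]] <- tibble::tibble(chrom = sites$chrom[idx], pos = as.integer(pos),
                                ref = ref, alt = alt, sample_id = sm)
  }
  res <- dplyr::bind_rows(out)
  if (!nrow(res)) {
    res <- tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          sample_id = character())
  }
  if (!is.null(planted) && nrow(planted)) {
    res <- dplyr::bind_rows(res, planted)
  }
  dplyr::arrange(res, .data$chrom, .data$pos, .data$sample_id)
}

#' Match planted truth to atlas site ids
#'
#' Atlas sites are built from jittered summits, so their coordinates differ
#' slightly from the planted site windows; this matches each atlas site to
#' the planted site whose center it contains.
#'
#' @param truth Ground truth from [generate_scenario()].
#' @param atlas Atlas tibble.
#' @return `atlas` with `class` and `planted_site_id` columns (`NA` where an
#'   atlas site covers no planted center).
#' @export
match_truth_to_atlas <- function(truth, atlas) {
  sites <- truth$sites
  centers_gr <- GenomicRanges::GRanges(
    sites$chrom,
    IRanges::IRanges(start = site_center(sites$start, sites$end) + 1L,
                     width = 1L))
  atlas_gr <- GenomicRanges::GRanges(
    atlas$chrom, IRanges::IRanges(start = atlas$start + 1L, end = atlas$end))
  hits <- GenomicRanges::findOverlaps(centers_gr, atlas_gr)
  cls <- rep(NA_character_, nrow(atlas))
  pid <- rep(NA_character_, nrow(atlas))
  cls[S4Vectors::subjectHits(hits)] <- sites$class[S4Vectors::queryHits(hits)]
  pid[S4Vectors::subjectHits(hits)] <- sites$site_id[S4Vectors::queryHits(hits)]
  out <- dplyr::mutate(atlas, class = cls, planted_site_id = pid)
  for (a in c("dataset_ids", "n_datasets")) attr(out, a) <- attr(atlas, a)
  out
}

#' Re-key a planted signal matrix to atlas site ids
#'
#' The generator keys its signal matrix by planted site id
#' (`chrom:start-end` of the planted window); the pipeline tests on atlas
#' site ids. Rows are matched by planted-window center containment; rows
#' without an atlas site are dropped.
#'
#' @param mat Site x dataset tibble keyed by planted site id.
#' @param atlas Atlas tibble.
#' @return The matrix tibble re-keyed by atlas `site_id`.
#' @export
align_matrix_to_atlas <- function(mat, atlas) {
  ids <- mat[[1]]
  parts <- stringr::str_match(ids, "^(.+):(\\d+)-(\\d+)$")
  if (anyNA(parts[, 1])) {
    stop("matrix row ids must look like chrom:start-end", call. = FALSE)
  }
  start <- as.integer(parts[, 3])
  end <- as.integer(parts[, 4])
  centers_gr <- GenomicRanges::GRanges(
    parts[, 2], IRanges::IRanges(start = site_center(start, end) + 1L,
                                 width = 1L))
  atlas_gr <- GenomicRanges::GRanges(
    atlas$chrom, IRanges::IRanges(start = atlas$start + 1L, end = atlas$end))
  hits <- GenomicRanges::findOverlaps(centers_gr, atlas_gr)
  keep <- S4Vectors::queryHits(hits)
  out <- mat[keep, , drop = FALSE]
  out[[1]] <- atlas$site_id[S4Vectors::subjectHits(hits)]
  out
}
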