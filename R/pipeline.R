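#' Run the specificity stages of a scenario in memory
#'
#' Convenience end-to-end driver used by the demo, the benchmark metrics and
#' the vignette: builds the union atlas from the scenario's peak datasets,
#' computes occupancy, quantile-normalizes the RPKM matrix, and calls
#' cancer-specific lost/gained sites for one cancer type.
#'
#' @param scenario A list from [generate_scenario()] (or equivalent fields
#'   read from disk: `peak_datasets`, `signal`, `design`).
#' @param cancer_type Cancer type to call (default the first in the design).
#' @param cfg A [pipeline_config()].
#' @return List `atlas` (with occupancy), `matrix` (normalized, atlas-keyed)
#'   and `calls` (criteria ledger from [call_cancer_specific_sites()]).
#' @export
call_scenario <- function(scenario, cancer_type = NULL, cfg = NULL) {
  cfg <- as_config(cfg)
  if (is.null(cancer_type)) {
    cancer_type <- stats::na.omit(scenario$design$cancer_type)[1]
  }
  atlas <- build_union_atlas(scenario$peak_datasets, cfg)
  atlas <- compute_occupancy(atlas, scenario$peak_datasets, cfg)
  mat <- align_matrix_to_atlas(scenario$signal, atlas)
  mat <- quantile_normalize(mat)
  calls <- call_cancer_specific_sites(atlas, scenario$peak_datasets, mat,
                                      scenario$design, cancer_type, cfg)
  list(atlas = atlas, matrix = mat, calls = calls)
}

#' Planted-truth recovery metrics for a called scenario
#'
#' Compares lost/gained calls against the generator's ground truth:
#' sensitivity is the fraction of planted lost (gained) sites recovered with
#' the right label; the false-call rate is the fraction of unplanted
#' (neither lost nor gained) tested sites receiving any call.
#'
#' @param scenario Scenario from [generate_scenario()].
#' @param result Result of [call_scenario()] on that scenario.
#' @return One-row tibble `lost_sensitivity, gained_sensitivity,
#'   false_call_rate, n_lost_planted, n_gained_planted, n_unplanted_tested`.
#' @export
recovery_metrics <- function(scenario, result) {
  labeled <- match_truth_to_atlas(scenario$truth, result$atlas)
  calls <- dplyr::left_join(result$calls,
                            labeled[, c("site_id", "class")],
                            by = "site_id")
  truth_class <- scenario$truth$site_class
  recovered <- function(cls, lab) {
    planted <- names(truth_class)[truth_class == cls]
    hit <- calls$site_id[calls$call == lab & !is.na(calls$class) &
                           calls$class == cls]
    # sensitivity over all planted sites, whether or not they were tested
    c(n = length(planted), hits = length(unique(
      labeled$planted_site_id[labeled$site_id %in% hit])))
  }
  lost <- recovered("cancer_lost", "lost")
  gained <- recovered("cancer_gained", "gained")
  unplanted <- calls[is.na(calls$class) |
                       !calls$class %in% c("cancer_lost", "cancer_gained"), ]
  tibble::tibble(
    lost_sensitivity = lost["hits"] / lost["n"],
    gained_sensitivity = gained["hits"] / gained["n"],
    false_call_rate = mean(unplanted$call != "none"),
    n_lost_planted = lost[["n"]],
    n_gained_planted = gained[["n"]],
    n_unplanted_tested = nrow(unplanted)
  )
}

#' Write a scenario to disk in the pipeline's input formats
#'
#' Peaks become 10-column narrowPeak files, the design / signal / gene
#' models / mutations become TSV, the genome a FASTA, the PFM JASPAR text,
#' CpG tables Bismark-coverage TSV, contact maps sparse bin-pair TSV, and
#' `scenario.json` records the configuration and file manifest.
#'
#' @param scenario Scenario from [generate_scenario()].
#' @param dir Output directory (created if needed).
#' @param pfm The PFM planted in the genome.
#' @param with_hic,with_meth,with_mutations Emit the optional modalities.
#' @return Invisibly, the manifest list (also written as `scenario.json`).
#' @export
write_scenario <- function(scenario, dir, pfm = ctcf_demo_pfm(),
                           with_hic = TRUE, with_meth = TRUE,
                           with_mutations = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory ", dir, call. = FALSE)
  peaks_dir <- file.path(dir, "peaks")
  dir.create(peaks_dir, showWarnings = FALSE)
  manifest <- list(files = list())
  for (id in names(scenario$peak_datasets)) {
    p <- scenario$peak_datasets[[id]]
    path <- file.path(peaks_dir, paste0(id, ".narrowPeak"))
    df <- data.frame(p$chrom, p$start, p$end,
                     paste0(id, "_peak_", seq_len(nrow(p))), 0L, ".",
                     p$fold_enrichment, -1, -1, p$summit - p$start)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  manifest$files$peaks_dir <- "peaks"
  utils::write.table(scenario$design, file.path(dir, "design.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_signal_matrix(scenario$signal, file.path(dir, "signal_rpkm.tsv"))
  write_genome(scenario$genome, file.path(dir, "genome.fa"))
  write_jaspar_pfm(pfm, file.path(dir, "motif.pfm"), "CTCF_SYNTHETIC")
  write_gene_models(scenario$gene_models, file.path(dir, "genes.tsv"))
  write_sites_bed(scenario$sites, file.path(dir, "planted_sites.bed"))
  utils::write.table(
    data.frame(site_id = names(scenario$truth$site_class),
               class = unname(scenario$truth$site_class)),
    file.path(dir, "ground_truth.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  manifest$files <- c(manifest$files, list(
    design = "design.tsv", signal = "signal_rpkm.tsv", genome = "genome.fa",
    pfm = "motif.pfm", genes = "genes.tsv",
    planted_sites = "planted_sites.bed", ground_truth = "ground_truth.tsv"))
  if (with_hic) {
    maps <- generate_contact_map_pair(scenario$config, scenario$truth)
    write_contact_map(maps$cancer, file.path(dir, "hic_cancer.tsv"))
    write_contact_map(maps$normal, file.path(dir, "hic_normal.tsv"))
    manifest$files$hic_cancer <- "hic_cancer.tsv"
    manifest$files$hic_normal <- "hic_normal.tsv"
  }
  if (with_meth) {
    meth <- generate_methylation_tables(scenario$config, scenario$truth)
    write_cpg_table(meth$cancer, file.path(dir, "meth_cancer.cov"))
    write_cpg_table(meth$normal, file.path(dir, "meth_normal.cov"))
    manifest$files$meth_cancer <- "meth_cancer.cov"
    manifest$files$meth_normal <- "meth_normal.cov"
  }
  if (with_mutations) {
    muts <- generate_mutations(scenario$config, scenario$truth,
                               scenario$genome)
    write_mutations(muts, file.path(dir, "mutations.tsv"))
    manifest$files$mutations <- "mutations.tsv"
  }
  manifest$scenario_config <- unclass(scenario$config)
  # desk-scale scenarios carry far fewer peaks per dataset than a production
  # ChIP-seq compendium; scale the dataset-inclusion filter accordingly
  manifest$pipeline_config <- list(
    min_peaks_per_dataset = max(1L, round(0.05 * scenario$config$n_sites)))
  manifest$cancer_type <- stats::na.omit(scenario$design$cancer_type)[1]
  jsonlite::write_json(manifest, file.path(dir, "scenario.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Write a ready-to-run demo scenario
#'
#' Generates the default synthetic scenario under `out` and returns the path
#' of its `scenario.json` manifest, which [run_pipeline()] accepts directly.
#'
#' @param seed Integer seed for the scenario.
#' @param out Output directory.
#' @return Path to the written `scenario.json`.
#' @export
make_demo <- function(seed = 1L, out = tempfile("ctcf_demo_")) {
  scn <- generate_scenario(scenario_config(seed = seed))
  write_scenario(scn, out)
  file.path(out, "scenario.json")
}

#' Run the pipeline end-to-end from a scenario manifest
#'
#' Reads the inputs named in a `scenario.json` manifest (as written by
#' [write_scenario()] / [make_demo()]) and executes the stages in dependency
#' order: atlas, constitutive model, specificity calls, motif annotation and
#' chromatin domains, then, as the optional inputs permit, differential
#' interaction, differential methylation, and mutation profiling. Missing
#' optional inputs skip their stage with an explicit status. Each stage
#' writes only into its own subdirectory of `out`, and a `run_manifest.json`
#' records the configuration, inputs and stage statuses.
#'
#' @param manifest Path to `scenario.json`.
#' @param out Output directory (default: `pipeline_out` beside the manifest).
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with the per-stage results and the summary
#'   tibble (also written as `summary/summary.tsv`).
#' @export
run_pipeline <- function(manifest, out = NULL, cfg = NULL) {
  man <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  if (is.null(cfg) && !is.null(man$pipeline_config)) {
    cfg <- do.call(pipeline_config, man$pipeline_config)
  }
  cfg <- as_config(cfg)
  base <- dirname(manifest)
  if (is.null(out)) out <- file.path(base, "pipeline_out")
  pth <- function(key) {
    rel <- man$files[[key]]
    if (is.null(rel)) NULL else file.path(base, rel)
  }
  required <- c("peaks_dir", "design", "signal")
  missing <- required[vapply(required, function(k) is.null(pth(k)), logical(1))]
  if (length(missing)) {
    stop("manifest lacks required input(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  status <- list()

  # atlas ----------------------------------------------------------------
  peak_files <- list.files(pth("peaks_dir"), full.names = TRUE)
  peak_datasets <- lapply(peak_files, read_peak_dataset, cfg = cfg)
  names(peak_datasets) <- vapply(peak_datasets,
                                 function(p) p$dataset_id[1], character(1))
  atlas <- build_union_atlas(peak_datasets, cfg)
  if (nrow(atlas) == 0L) {
    stop("no atlas sites: every peak dataset was excluded by the ",
         "min_peaks_per_dataset / fold-enrichment filters", call. = FALSE)
  }
  atlas <- compute_occupancy(atlas, peak_datasets, cfg)
  stage_dir <- file.path(out, "atlas")
  dir.create(stage_dir, showWarnings = FALSE)
  write_sites_bed(atlas, file.path(stage_dir, "atlas.bed"))
  status$atlas <- "complete"

  # constitutive ----------------------------------------------------------
  dist <- occupancy_distribution(atlas)
  fit <- tryCatch(fit_power_law(dist), error = function(e) NULL)
  A <- if (is.null(fit)) NA_integer_ else determine_cutoff(dist, fit,
                                                           cfg$excess_factor)
  constitutive <- select_constitutive(atlas, A, cfg)
  stage_dir <- file.path(out, "constitutive")
  dir.create(stage_dir, showWarnings = FALSE)
  jsonlite::write_json(
    list(A = A, rule = attr(constitutive, "rule"),
         min_score = attr(constitutive, "min_score"),
         fit = if (is.null(fit)) NULL else unclass(fit)[c("a", "b", "c")],
         n_constitutive = nrow(constitutive)),
    file.path(stage_dir, "fit.json"), auto_unbox = TRUE, digits = NA)
  status$constitutive <- "complete"

  # specificity -----------------------------------------------------------
  design <- tibble::as_tibble(utils::read.table(pth("design"), sep = "\t",
                                                header = TRUE,
                                                stringsAsFactors = FALSE))
  design[design == "NA"] <- NA
  mat <- read_signal_matrix(pth("signal"))
  mat <- align_matrix_to_atlas(mat, atlas)
  mat <- quantile_normalize(mat)
  cancer_type <- if (!is.null(man$cancer_type)) man$cancer_type else
    stats::na.omit(design$cancer_type)[1]
  calls <- call_cancer_specific_sites(atlas, peak_datasets, mat, design,
                                      cancer_type, cfg)
  stage_dir <- file.path(out, "specificity")
  dir.create(stage_dir, showWarnings = FALSE)
  utils::write.table(calls, file.path(stage_dir, "calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  status$specificity <- "complete"
  called <- calls[calls$call != "none", , drop = FALSE]

  # motif annotation + domains -------------------------------------------
  domains <- NULL
  if (!is.null(pth("genome")) && !is.null(pth("pfm"))) {
    genome <- as.character(read_genome(pth("genome")))
    names(genome) <- sub("\\s.*$", "", names(genome))
    pfm <- read_jaspar_pfm(pth("pfm"))
    const_annot <- scan_best_motif(constitutive, genome, pfm, cfg)
    const_annot$motif_strand[is.na(const_annot$motif_strand)] <- NA
    anchors <- atlas[atlas$site_id %in% called$site_id, , drop = FALSE]
    domains <- build_domains(anchors, const_annot, cfg)
    stage_dir <- file.path(out, "domains")
    dir.create(stage_dir, showWarnings = FALSE)
    utils::write.table(domains, file.path(stage_dir, "domains.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_sites_bed(const_annot, file.path(stage_dir, "constitutive.bed"))
    status$domains <- "complete"
  } else {
    status$domains <- "skipped"
  }

  # differential interaction ---------------------------------------------
  hic_res <- NULL
  if (!is.null(pth("hic_cancer")) && !is.null(pth("hic_normal"))) {
    map_c <- normalize_by_distance(read_contact_map(pth("hic_cancer"),
                                                    cfg$hic_bin_size))
    map_n <- normalize_by_distance(read_contact_map(pth("hic_normal"),
                                                    cfg$hic_bin_size))
    on_chrom <- called[called$site_id %in%
                         atlas$site_id[atlas$chrom == map_c$chrom], ,
                       drop = FALSE]
    hic_res <- purrr::map(on_chrom$site_id, function(sid) {
      differential_interaction(atlas[atlas$site_id == sid, ], map_c, map_n,
                               cfg)
    }) |> dplyr::bind_rows()
    stage_dir <- file.path(out, "hic")
    dir.create(stage_dir, showWarnings = FALSE)
    if (nrow(hic_res)) {
      utils::write.table(hic_res, file.path(stage_dir, "differential.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    status$hic <- "complete"
  } else {
    status$hic <- "skipped"
  }

  # methylation -----------------------------------------------------------
  meth_res <- NULL
  if (!is.null(pth("meth_cancer")) && !is.null(pth("meth_normal"))) {
    cpg_c <- read_cpg_table(pth("meth_cancer"))
    cpg_n <- read_cpg_table(pth("meth_normal"))
    meth_res <- region_differential_methylation_all(
      atlas[atlas$site_id %in% called$site_id, ], cpg_c, cpg_n, cfg)
    stage_dir <- file.path(out, "methylation")
    dir.create(stage_dir, showWarnings = FALSE)
    utils::write.table(meth_res, file.path(stage_dir, "regions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    status$methylation <- "complete"
  } else {
    status$methylation <- "skipped"
  }

  # mutation profiles ------------------------------------------------------
  mut_res <- NULL
  if (!is.null(pth("mutations"))) {
    muts <- read_mutations(pth("mutations"))
    groups <- list(lost = calls$site_id[calls$call == "lost"],
                   gained = calls$site_id[calls$call == "gained"],
                   constitutive = constitutive$site_id)
    mut_res <- purrr::imap(groups, function(ids, nm) {
      s <- atlas[atlas$site_id %in% ids, , drop = FALSE]
      if (!nrow(s)) return(NULL)
      dplyr::mutate(mutation_rate_profile(s, muts, cfg), group = nm)
    }) |> dplyr::bind_rows()
    stage_dir <- file.path(out, "mutation")
    dir.create(stage_dir, showWarnings = FALSE)
    utils::write.table(mut_res, file.path(stage_dir, "profiles.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    status$mutation <- "complete"
  } else {
    status$mutation <- "skipped"
  }

  # summary ----------------------------------------------------------------
  summary <- calls[, c("site_id", "call", "t_vs_others", "fdr_vs_others",
                       "mean_cancer_rpkm")]
  if (!is.null(domains)) {
    summary <- dplyr::left_join(
      summary, domains[, c("site_id", "found", "domain_start", "domain_end")],
      by = "site_id")
  } else {
    summary$found <- NA
  }
  if (!is.null(hic_res) && nrow(hic_res)) {
    summary <- dplyr::left_join(
      summary,
      dplyr::rename(hic_res[, c("site_id", "p_value", "mean_log2_fc")],
                    hic_p = "p_value", hic_log2_fc = "mean_log2_fc"),
      by = "site_id")
  }
  if (!is.null(meth_res) && nrow(meth_res)) {
    summary <- dplyr::left_join(
      summary,
      dplyr::rename(meth_res[, c("site_id", "status", "mean_delta")],
                    meth_status = "status", meth_delta = "mean_delta"),
      by = "site_id")
  }
  stage_dir <- file.path(out, "summary")
  dir.create(stage_dir, showWarnings = FALSE)
  utils::write.table(summary, file.path(stage_dir, "summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(config = unclass(cfg), manifest = normalizePath(manifest),
         inputs = man$files, stages = status,
         package_version = as.character(utils::packageVersion("ctcfscape")),
         seed = cfg$random_seed),
    file.path(out, "run_manifest.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  invisible(list(atlas = atlas, constitutive = constitutive, calls = calls,
                 domains = domains, hic = hic_res, methylation = meth_res,
                 mutation = mut_res, summary = summary, status = status,
                 out = out))
}
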