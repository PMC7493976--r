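test_that("the generator is deterministic given its seed", {
  s1 <- small_scenario(seed = 3)
  s2 <- small_scenario(seed = 3)
  expect_identical(s1$peak_datasets, s2$peak_datasets)
  expect_identical(s1$signal, s2$signal)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$truth$site_class, s2$truth$site_class)
  s3 <- small_scenario(seed = 4)
  expect_false(identical(s1$signal, s3$signal))
})

test_that("class fractions translate into exact planted counts", {
  cfg <- scenario_config(n_sites = 1000L, chrom_length = 1500000L,
                         class_fractions = c(constitutive = 0.10,
                                             common = 0.60,
                                             cancer_lost = 0.05,
                                             cancer_gained = 0.025,
                                             sample_specific = 0.225))
  scn <- generate_scenario(cfg)
  expect_equal(sum(scn$truth$site_class == "cancer_lost"), 50L)
  expect_equal(sum(scn$truth$site_class == "cancer_gained"), 25L)
  expect_equal(length(scn$truth$site_class), 1000L)
  # every emitted site id appears exactly once in the class map
  expect_identical(sort(names(scn$truth$site_class)), sort(scn$sites$site_id))
})

test_that("site packing respects the minimum spacing and fails when infeasible", {
  scn <- small_scenario(seed = 8)
  gaps <- scn$sites |>
    dplyr::group_by(.data$chrom) |>
    dplyr::reframe(gap = diff(.data$center))
  expect_true(all(gaps$gap >= 1000L))
  expect_error(generate_scenario(scenario_config(n_sites = 2000L,
                                                 chrom_length = 100000L)),
               "cannot place")
})

test_that("cancer signal at gained sites exceeds common sites", {
  # enough planted gained sites (25) for the one-sided site-level comparison
  scn <- generate_scenario(scenario_config(seed = 5, n_sites = 1000L,
                                           chrom_length = 1500000L))
  m <- as.matrix(scn$signal[, -1])
  rownames(m) <- scn$signal[[1]]
  cancer_cols <- scn$design$dataset_id[scn$design$cohort == "cancer"]
  cls <- scn$truth$site_class[rownames(m)]
  gained <- rowMeans(m[cls == "cancer_gained", cancer_cols, drop = FALSE])
  common <- rowMeans(m[cls == "common", cancer_cols, drop = FALSE])
  tt <- stats::t.test(gained, common, alternative = "greater")
  expect_lt(tt$p.value, 0.01)
  # lost sites are depleted in cancer relative to matched normal
  normal_cols <- scn$design$dataset_id[scn$design$cohort == "normal"]
  lost_c <- rowMeans(m[cls == "cancer_lost", cancer_cols, drop = FALSE])
  lost_n <- rowMeans(m[cls == "cancer_lost", normal_cols, drop = FALSE])
  expect_lt(stats::t.test(lost_c, lost_n, alternative = "less")$p.value, 0.01)
})

test_that("a naive occupancy oracle separates the planted classes", {
  scn <- small_scenario(seed = 6)
  occ <- rowMeans(scn$truth$presence)
  cls <- scn$truth$site_class[rownames(scn$truth$presence)]
  expect_gt(min(occ[cls == "constitutive"]), max(occ[cls == "sample_specific"]))
  expect_gt(mean(occ[cls == "common"]), 0.7)
  expect_lt(mean(occ[cls == "cancer_gained"]), 0.25)
})

test_that("the planted consensus sits at constitutive and gained site centers", {
  scn <- small_scenario(seed = 7)
  pfm <- ctcf_demo_pfm()
  consensus <- paste(rownames(pfm)[apply(pfm, 2, which.max)], collapse = "")
  sites <- scn$sites
  idx <- which(sites$class %in% c("constitutive", "cancer_gained"))[1:10]
  for (i in idx) {
    at <- sites$center[i] - nchar(consensus) %/% 2L
    seen <- substr(scn$genome[[sites$chrom[i]]], at + 1L,
                   at + nchar(consensus))
    want <- if (sites$planted_strand[i] == "+") consensus else
      chartr("ACGT", "TGCA",
             paste(rev(strsplit(consensus, "")[[1]]), collapse = ""))
    expect_equal(seen, want)
  }
})

test_that("contact maps are symmetric with a null pair exchangeable", {
  cfg <- scenario_config(seed = 9, n_sites = 100L, chrom_length = 400000L,
                         hic_interaction_boost = 1)
  scn <- generate_scenario(cfg)
  maps <- generate_contact_map_pair(cfg, scn$truth)
  # canonical storage: folding (j, i) onto (i, j) leaves the map unchanged
  expect_true(all(maps$cancer$entries$i <= maps$cancer$entries$j))
  refold <- contact_map(
    tibble::tibble(i = maps$cancer$entries$j, j = maps$cancer$entries$i,
                   count = maps$cancer$entries$count),
    maps$cancer$chrom, maps$cancer$bin_size, maps$cancer$n_bins)
  expect_equal(refold$entries, maps$cancer$entries)
  # same marginal model for the two maps under boost = 1
  expect_equal(sum(maps$cancer$entries$count),
               sum(maps$normal$entries$count), tolerance = 0.05)
})

test_that("planted boosts raise cancer counts near gained anchors", {
  cfg <- scenario_config(seed = 10, n_sites = 200L, chrom_length = 500000L,
                         hic_interaction_boost = 3)
  scn <- generate_scenario(cfg)
  maps <- generate_contact_map_pair(cfg, scn$truth)
  expect_gt(length(maps$boosted_anchor_bins), 0)
  a <- maps$boosted_anchor_bins[1]
  near <- function(map) {
    e <- map$entries
    sum(e$count[(e$i == a | e$j == a) & abs(e$j - e$i) <= 20 &
                  e$j != e$i])
  }
  expect_gt(near(maps$cancer), 1.5 * near(maps$normal))
})

test_that("methylation tables plant shifts at lost sites and coverage gaps", {
  cfg <- scenario_config(seed = 11, n_sites = 150L, chrom_length = 400000L)
  scn <- generate_scenario(cfg)
  meth <- generate_methylation_tables(cfg, scn$truth)
  res <- region_differential_methylation_all(scn$sites, meth$cancer,
                                             meth$normal)
  cls <- scn$truth$site_class[res$site_id]
  lost_ok <- res$site_id %in% names(cls)[cls == "cancer_lost"] &
    !res$site_id %in% meth$low_coverage_sites
  if (any(lost_ok)) {
    expect_gte(mean(res$status[lost_ok] == "hyper"), 0.8)
  }
  # planted low-coverage sites land in the insufficient partition
  low <- res[res$site_id %in% meth$low_coverage_sites, ]
  expect_true(all(low$status == "insufficient"))
  other <- res$status[!lost_ok & !res$site_id %in% meth$low_coverage_sites]
  expect_lte(mean(other != "unchanged"), 0.1)
})

test_that("background mutations match the Poisson expectation", {
  cfg <- scenario_config(seed = 12, n_sites = 100L, chrom_length = 400000L,
                         mutation_background_rate = 1e-4,
                         mutation_n_samples = 10L)
  scn <- generate_scenario(cfg)
  muts <- generate_mutations(cfg, scn$truth, scn$genome)
  lambda <- 1e-4 * 400 * 100 * 10
  expect_lt(abs(nrow(muts) - lambda), 3 * sqrt(lambda))
  expect_true(all(muts$ref != muts$alt))
  # zero background with one planted variant -> exactly that record
  cfg0 <- scenario_config(seed = 12, n_sites = 100L, chrom_length = 400000L,
                          mutation_background_rate = 0)
  planted <- tibble::tibble(chrom = "chr1", pos = 12345L, ref = "A",
                            alt = "T", sample_id = "p1")
  only <- generate_mutations(cfg0, scn$truth, scn$genome, planted = planted)
  expect_equal(nrow(only), 1L)
  expect_equal(only$pos, 12345L)
})

test_that("emitted files parse with the package readers without warnings", {
  scn <- generate_scenario(scenario_config(seed = 13, n_sites = 60L,
                                           chrom_length = 300000L,
                                           n_genes = 30L))
  dir <- withr::local_tempdir()
  expect_no_warning(write_scenario(scn, dir))
  expect_no_warning({
    pk <- read_peak_dataset(list.files(file.path(dir, "peaks"),
                                       full.names = TRUE)[1],
                            pipeline_config(min_peaks_per_dataset = 1L))
    sig <- read_signal_matrix(file.path(dir, "signal_rpkm.tsv"))
    gen <- read_genome(file.path(dir, "genome.fa"))
    pfm <- read_jaspar_pfm(file.path(dir, "motif.pfm"))
    gm <- read_gene_models(file.path(dir, "genes.tsv"))
    cm <- read_contact_map(file.path(dir, "hic_cancer.tsv"))
    cg <- read_cpg_table(file.path(dir, "meth_cancer.cov"))
    mu <- read_mutations(file.path(dir, "mutations.tsv"))
  })
  expect_equal(nrow(sig), 60L)
  expect_equal(dim(pfm), c(4L, 19L))
  expect_identical(sort(unname(as.character(gen))),
                   sort(unname(scn$genome)))
  # the signal matrix round-trips numerically
  expect_equal(as.matrix(sig[, -1]), as.matrix(scn$signal[, -1]),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("planted expression pairs carry the target correlation", {
  scn <- small_scenario(seed = 14)
  pairs <- scn$truth$planted_pairs
  rs <- vapply(seq_len(min(nrow(pairs), 40)), function(k) {
    x <- sqrt(scn$expression$site_signal[pairs$site_id[k], ])
    y <- sqrt(scn$expression$gene_expression[pairs$gene_id[k], ])
    stats::cor(x, y)
  }, numeric(1))
  expect_gt(stats::median(rs), 0.5)
})
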