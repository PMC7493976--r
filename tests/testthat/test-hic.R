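test_that("expected-at-distance normalization matches the worked 3-bin case", {
  ent <- tibble::tibble(i = c(0L, 1L, 0L), j = c(1L, 2L, 2L),
                        count = c(2, 4, 5))
  map <- contact_map(ent, "chr1", 5000L, n_bins = 3L)
  prof <- distance_profile(map)
  expect_equal(prof$mean_count, c(3, 5))
  norm <- normalize_by_distance(map)
  vals <- setNames(norm$entries$count,
                   paste(norm$entries$i, norm$entries$j))
  expect_equal(vals[["0 1"]], 2 / 3)
  expect_equal(vals[["1 2"]], 4 / 3)
  expect_equal(vals[["0 2"]], 1)
})

test_that("per-distance means of normalized entries equal one exactly", {
  set.seed(8)
  n_bins <- 60L
  pairs <- which(upper.tri(matrix(0, n_bins, n_bins)), arr.ind = TRUE)
  ent <- tibble::tibble(i = pairs[, 1] - 1L, j = pairs[, 2] - 1L,
                        count = stats::rpois(nrow(pairs), 20))
  norm <- normalize_by_distance(contact_map(ent, "chr1", 5000L, n_bins))
  for (k in c(1L, 5L, 30L)) {
    at_k <- norm$entries[norm$entries$j - norm$entries$i == k, ]
    total <- sum(at_k$count)  # implicit zeros add nothing
    expect_equal(total / (n_bins - k), 1, tolerance = 1e-9)
  }
  # a constant map normalizes to all ones
  ent2 <- tibble::tibble(i = pairs[, 1] - 1L, j = pairs[, 2] - 1L, count = 7)
  norm2 <- normalize_by_distance(contact_map(ent2, "chr1", 5000L, n_bins))
  expect_true(all(abs(norm2$entries$count - 1) < 1e-12))
})

test_that("flank vectors collect both sides, truncated at chromosome ends", {
  ent <- tibble::tibble(i = 0L, j = 1L, count = 1)
  map <- contact_map(ent, "chr1", 5000L, n_bins = 100L)
  map$normalized <- TRUE
  cfg <- pipeline_config(hic_flank_L = 15000L)
  site <- tibble::tibble(site_id = "s", start = 250000L, end = 250150L)
  v <- site_flank_vector(site, map, cfg)
  expect_equal(nrow(v), 6L)  # 3 bins per side
  expect_equal(v$offset, c(-3L, -2L, -1L, 1L, 2L, 3L))

  edge <- tibble::tibble(site_id = "s", start = 2000L, end = 2150L)
  ve <- site_flank_vector(edge, map, cfg)
  expect_equal(ve$offset, c(1L, 2L, 3L))  # left side truncated at bin 0
  expect_error(site_flank_vector(tibble::tibble(start = 10e6, end = 10e6 + 1),
                                 map, cfg), "outside")
})

test_that("paired differential interaction matches the closed-form t", {
  # normalized values planted directly on the maps
  mk <- function(vals) {
    m <- contact_map(tibble::tibble(i = 10L, j = 11:14, count = vals),
                     "chr1", 5000L, n_bins = 100L)
    m$normalized <- TRUE
    m
  }
  site <- tibble::tibble(site_id = "s", start = 52000L, end = 52150L)
  cfg <- pipeline_config(hic_flank_L = 20000L)
  res <- differential_interaction(site, mk(c(1.2, 0.8, 1.5, 1.1)),
                                  mk(c(0.9, 0.7, 1.0, 0.8)), cfg,
                                  sides = "right")
  expect_equal(res$t_statistic, 3.674, tolerance = 1e-3)
  expect_equal(res$p_value, 0.0349, tolerance = 1e-3)
  expect_equal(res$n_flank_bins, 4L)

  ident <- differential_interaction(site, mk(c(1, 2, 3, 4)),
                                    mk(c(1, 2, 3, 4)), cfg, sides = "right")
  expect_equal(ident$t_statistic, 0)
  expect_equal(ident$p_value, 1)
})

test_that("intra-domain differential regions obey both thresholds", {
  cfg <- pipeline_config()
  mk <- function(counts) {
    m <- contact_map(tibble::tibble(i = 40L, j = c(42L, 44L),
                                    count = counts), "chr1", 5000L, 200L)
    m$normalized <- TRUE
    m
  }
  sites <- tibble::tibble(site_id = "s", chrom = "chr1",
                          start = 202000L, end = 202150L)
  domains <- tibble::tibble(site_id = "s", found = TRUE,
                            domain_start = 200000L, domain_end = 240000L)
  # bin 42: IC 4 vs IN 1 -> log2 FC ~ 2, mean log2 interaction ~ 1 -> kept
  # bin 44: IC 0.4 vs IN 0.1 -> FC ~ 4 but mean log2 interaction < 0 -> dropped
  res <- find_differential_regions(sites, mk(c(4, 0.4)), mk(c(1, 0.1)),
                                   domains, cfg, direction = "increased")
  expect_equal(res$bin, 42L)
  expect_gt(res$log2_fc, 1)
  expect_gt(res$mean_log2_interaction, 0)

  none <- find_differential_regions(sites, mk(c(4, 0.4)), mk(c(4, 0.4)),
                                    domains, cfg, direction = "increased")
  expect_equal(nrow(none), 0L)

  skipped <- find_differential_regions(
    sites, mk(c(4, 0.4)), mk(c(1, 0.1)),
    tibble::tibble(site_id = "s", found = FALSE,
                   domain_start = NA_integer_, domain_end = NA_integer_),
    cfg, direction = "increased")
  expect_equal(nrow(skipped), 0L)
})

test_that("results are invariant to a constant bin offset on maps and sites", {
  set.seed(12)
  n_bins <- 80L
  pairs <- which(upper.tri(matrix(0, n_bins, n_bins)), arr.ind = TRUE)
  counts <- stats::rpois(nrow(pairs), 15)
  shift <- 20L
  mk <- function(off, nb) {
    normalize_by_distance(contact_map(
      tibble::tibble(i = pairs[, 1] - 1L + off, j = pairs[, 2] - 1L + off,
                     count = counts), "chr1", 5000L, nb))
  }
  cfg <- pipeline_config(hic_flank_L = 25000L)
  site0 <- tibble::tibble(site_id = "s", start = 40L * 5000L + 100L,
                          end = 40L * 5000L + 250L)
  site1 <- dplyr::mutate(site0, start = .data$start + shift * 5000L,
                         end = .data$end + shift * 5000L)
  # same chromosome size for both labelings so the per-distance pair counts
  # (the normalization denominators) agree
  v0 <- site_flank_vector(site0, mk(0L, n_bins + shift), cfg)
  v1 <- site_flank_vector(site1, mk(shift, n_bins + shift), cfg)
  expect_equal(v0$value, v1$value)
})
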