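test_that("RPKM follows the count / (kb x millions) formula", {
  counts <- tibble::tibble(site_id = "s1", d1 = 30)
  rpkm <- compute_rpkm(counts, site_lengths = 150, library_sizes = 1e7)
  expect_equal(rpkm$d1, 20)
  expect_equal(compute_rpkm(tibble::tibble(site_id = "s1", d1 = 0),
                            150, 1e7)$d1, 0)
  # doubling a library size halves that column only
  counts2 <- tibble::tibble(site_id = c("a", "b"), d1 = c(10, 20),
                            d2 = c(10, 20))
  r <- compute_rpkm(counts2, c(100, 100), c(1e6, 2e6))
  expect_equal(r$d1 / 2, r$d2)
  expect_error(compute_rpkm(counts, 150, 0), "library sizes")
})

test_that("quantile normalization maps columns to the common distribution", {
  m <- tibble::tibble(site_id = c("a", "b"), d1 = c(1, 3), d2 = c(2, 4))
  qn <- quantile_normalize(m)
  expect_equal(qn$d1, c(1.5, 3.5))
  expect_equal(qn$d2, c(1.5, 3.5))

  ident <- tibble::tibble(site_id = letters[1:4], d1 = c(4, 1, 3, 2),
                          d2 = c(4, 1, 3, 2))
  expect_equal(quantile_normalize(ident), ident)

  set.seed(2)
  big <- matrix(stats::rexp(300), ncol = 3,
                dimnames = list(paste0("s", 1:100), paste0("d", 1:3)))
  qb <- quantile_normalize(big)
  expect_equal(sort(qb[, 1]), sort(qb[, 2]), ignore_attr = TRUE)
  expect_equal(sort(qb[, 2]), sort(qb[, 3]), ignore_attr = TRUE)
})

test_that("pooled-variance t, Cohen's d and BH match hand-computed values", {
  m <- matrix(c(1, 2, 3, 3, 4, 5), nrow = 1,
              dimnames = list("s1", paste0("d", 1:6)))
  res <- differential_binding(m, paste0("d", 1:3), paste0("d", 4:6))
  expect_equal(res$t_statistic, -2.449, tolerance = 1e-3)
  expect_equal(res$df, 4L)
  expect_equal(res$p_value, 0.0705, tolerance = 1e-3)
  expect_equal(res$effect_size, -2)

  same <- matrix(c(1, 2, 3, 1, 2, 3), nrow = 1,
                 dimnames = list("s1", paste0("d", 1:6)))
  res2 <- differential_binding(same, paste0("d", 1:3), paste0("d", 4:6))
  expect_equal(res2$t_statistic, 0)
  expect_equal(res2$p_value, 1)

  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.04, 0.05), "BH"),
               c(0.04, 0.04, 0.05, 0.05))

  # zero pooled variance with unequal means is flagged degenerate
  deg <- matrix(c(1, 1, 2, 2), nrow = 1,
                dimnames = list("s1", paste0("d", 1:4)))
  res3 <- differential_binding(deg, c("d1", "d2"), c("d3", "d4"))
  expect_true(res3$degenerate)
  expect_equal(res3$p_value, 0)

  expect_error(differential_binding(m, "d1", paste0("d", 4:6)),
               "at least 2")
})

test_that("the lost criteria conjunction behaves on a hand-built cohort", {
  # 8 cancer + 5 normal + 27 other datasets; one strong lost site, one
  # control that fails only the RPKM bound
  ids <- c(paste0("c", 1:8), paste0("n", 1:5), paste0("o", 1:27))
  design <- tibble::tibble(
    dataset_id = ids,
    cohort = c(rep("cancer", 8), rep("normal", 5), rep("other", 27)),
    cancer_type = c(rep("X", 8), rep(NA, 32)),
    matched_normal = c(rep(NA, 8), rep("X", 5), rep(NA, 27)))
  # lost site: present in 1 cancer, 3 normal, 26 other -> freq 1/8, 0.6, 0.75
  present_lost <- c("c1", paste0("n", 1:3), paste0("o", 1:26))
  # second site identical occupancy but high cancer signal
  mk_peaks <- function(id) {
    s <- integer(0)
    if (id %in% present_lost) s <- c(s, 10000L)
    s <- c(s, 50000L)  # site 2 everywhere so it stays high-confidence
    if (id %in% present_lost) s <- c(s, 90000L)
    peaks_from_summits(s, id)
  }
  peaks <- lapply(ids, mk_peaks)
  atlas <- build_union_atlas(peaks)
  atlas <- compute_occupancy(atlas, peaks)
  set.seed(31)
  sig <- function(bound, high) {
    base <- ifelse(bound, 8, 1) + stats::rnorm(length(bound), 0, 0.2)
    if (high) base <- base + 7
    pmax(base, 0.05)
  }
  bound <- ids %in% present_lost
  m <- rbind(sig(bound, FALSE), sig(rep(TRUE, 40), FALSE), sig(bound, TRUE))
  dimnames(m) <- list(atlas$site_id, ids)
  calls <- call_cancer_specific_sites(atlas, peaks, m, design, "X")
  s1 <- calls[calls$site_id == atlas$site_id[1], ]
  expect_equal(s1$call, "lost")
  expect_true(all(unlist(s1[paste0("lost_c", 1:6)])))
  s3 <- calls[calls$site_id == atlas$site_id[3], ]
  expect_equal(s3$call, "none")
  expect_false(s3$lost_c6)  # mean cancer RPKM above the bound
  expect_true(s3$lost_c1 && s3$lost_c2 && s3$lost_c3)
})

test_that("calls are invariant to dataset column order", {
  scn <- small_scenario()
  res <- call_scenario(scn)
  perm <- c(1, sample(2:ncol(scn$signal)))
  scn2 <- scn
  scn2$signal <- scn$signal[, perm]
  scn2$peak_datasets <- rev(scn$peak_datasets)
  res2 <- call_scenario(scn2)
  merged <- dplyr::inner_join(res$calls[, c("site_id", "call")],
                              res2$calls[, c("site_id", "call")],
                              by = "site_id")
  expect_equal(merged$call.x, merged$call.y)
})

test_that("lost and gained are mutually exclusive by construction", {
  scn <- small_scenario()
  res <- call_scenario(scn)
  both <- res$calls$lost_c1 & res$calls$lost_c2 & res$calls$gained_c2
  # overall frequency >= 0.7 and <= 0.2 cannot hold together
  expect_false(any(res$calls$lost_c2 & res$calls$gained_c2))
  expect_false(any(both))
})

test_that("a missing matched-normal stratum disables calls explicitly", {
  scn <- small_scenario()
  design <- scn$design
  design$matched_normal <- NA_character_
  expect_error(call_scenario(list(peak_datasets = scn$peak_datasets,
                                  signal = scn$signal, design = design)),
               "matched normal")
})

test_that("accessibility scores are stratum mean ratios on the prepared scale", {
  m <- matrix(c(4, 6, 1, 1, 2), nrow = 1,
              dimnames = list("s1", paste0("d", 1:5)))
  res <- differential_accessibility_score(m, c("d1", "d2"),
                                          c("d3", "d4", "d5"),
                                          prepared = TRUE)
  expect_equal(res$accessibility_score, 3.75)
  ident <- differential_accessibility_score(m, c("d1", "d2"), c("d1", "d2"),
                                            prepared = TRUE)
  expect_equal(ident$accessibility_score, 1)
  expect_error(differential_accessibility_score(m, character(0), "d1"),
               "non-empty")
})
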