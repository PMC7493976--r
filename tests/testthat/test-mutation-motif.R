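test_that("mutation profiles count events per offset per site", {
  sites <- tibble::tibble(site_id = c("a", "b"), chrom = "chr1",
                          start = c(925L, 4925L), end = c(1075L, 5075L))
  muts <- tibble::tibble(chrom = "chr1", pos = c(1000L, 5000L),
                         ref = "A", alt = "T", sample_id = c("s1", "s2"))
  prof <- mutation_rate_profile(sites, muts)
  expect_equal(nrow(prof), 400L)
  expect_equal(prof$rate[prof$offset == 0L], 1)
  expect_equal(sum(prof$rate), 1)

  empty <- mutation_rate_profile(sites, muts[0, ])
  expect_true(all(empty$rate == 0))
  expect_error(mutation_rate_profile(sites[0, ], muts), "empty site set")
})

test_that("profile totals conserve in-window events and ignore site order", {
  set.seed(19)
  sites <- tibble::tibble(site_id = paste0("s", 1:20), chrom = "chr1",
                          start = seq(10000L, by = 2000L, length.out = 20),
                          end = seq(10150L, by = 2000L, length.out = 20))
  centers <- (sites$start + sites$end) %/% 2L
  pos <- as.integer(sample(centers, 60, replace = TRUE) +
                      sample(-200:199, 60, replace = TRUE))
  muts <- tibble::tibble(chrom = "chr1", pos = pos, ref = "C", alt = "A",
                         sample_id = sample(paste0("p", 1:5), 60, TRUE))
  prof <- mutation_rate_profile(sites, muts)
  in_window <- sum(vapply(pos, function(p) {
    any(p >= centers - 200L & p < centers + 200L)
  }, logical(1)))
  expect_equal(sum(prof$rate) * nrow(sites), in_window)
  prof2 <- mutation_rate_profile(sites[sample(nrow(sites)), ],
                                 muts[sample(nrow(muts)), ])
  expect_equal(prof, prof2)
})

test_that("a background-matched PWM scores zero for any sequence", {
  bg <- c(0.275, 0.225, 0.225, 0.275)
  pfm <- matrix(rep(bg * 1000, 19), nrow = 4,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm <- pwm_from_pfm(pfm, bg, pseudocount = 0)
  set.seed(2)
  for (k in 1:5) {
    expect_equal(motif_llr_score(random_seq(19), pwm), 0, tolerance = 1e-12)
  }
})

test_that("the consensus achieves the per-position maximal score", {
  pwm <- pwm_from_pfm(ctcf_demo_pfm())
  consensus <- paste(rownames(pwm)[apply(pwm, 2, which.max)], collapse = "")
  expect_equal(motif_llr_score(consensus, pwm), sum(apply(pwm, 2, max)))
  set.seed(3)
  for (k in 1:10) {
    expect_lte(motif_llr_score(random_seq(19), pwm),
               motif_llr_score(consensus, pwm))
  }
})

test_that("minus-strand scoring equals scoring the reverse complement", {
  pwm <- pwm_from_pfm(ctcf_demo_pfm())
  set.seed(4)
  s <- random_seq(19)
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  expect_equal(motif_llr_score(s, pwm, strand = "-"),
               motif_llr_score(rc, pwm, strand = "+"))
})

test_that("differential motif scores are antisymmetric over all single-base edits", {
  pwm <- pwm_from_pfm(ctcf_demo_pfm())
  set.seed(5)
  ref_seq <- random_seq(19)
  genome_fwd <- c(chr1 = paste0("AAAAA", ref_seq, "CCCCC"))
  site <- tibble::tibble(site_id = "s", chrom = "chr1", motif_start = 5L,
                         motif_strand = "+")
  bases <- c("A", "C", "G", "T")
  for (k in seq_len(19)) {
    ref_b <- substr(ref_seq, k, k)
    for (alt_b in setdiff(bases, ref_b)) {
      v_fwd <- tibble::tibble(chrom = "chr1", pos = 4L + k, ref = ref_b,
                              alt = alt_b)
      d_fwd <- differential_motif_score(site, v_fwd, genome_fwd, pwm)
      # mutated genome for the reverse edit
      alt_seq <- ref_seq
      substr(alt_seq, k, k) <- alt_b
      genome_alt <- c(chr1 = paste0("AAAAA", alt_seq, "CCCCC"))
      v_rev <- tibble::tibble(chrom = "chr1", pos = 4L + k, ref = alt_b,
                              alt = ref_b)
      d_rev <- differential_motif_score(site, v_rev, genome_alt, pwm)
      expect_equal(d_fwd$delta, -d_rev$delta)
    }
  }
})

test_that("the most disruptive edit hits the most informative column", {
  pwm <- pwm_from_pfm(ctcf_demo_pfm())
  consensus <- paste(rownames(pwm)[apply(pwm, 2, which.max)], collapse = "")
  genome <- c(chr1 = consensus)
  site <- tibble::tibble(site_id = "s", chrom = "chr1", motif_start = 0L,
                         motif_strand = "+")
  deltas <- c()
  worst <- -Inf
  for (k in seq_len(19)) {
    ref_b <- substr(consensus, k, k)
    for (alt_b in setdiff(c("A", "C", "G", "T"), ref_b)) {
      v <- tibble::tibble(chrom = "chr1", pos = k - 1L, ref = ref_b,
                          alt = alt_b)
      deltas <- c(deltas, differential_motif_score(site, v, genome, pwm)$delta)
    }
  }
  # oracle: largest achievable single-base drop from the consensus
  oracle <- min(apply(pwm, 2, function(col) min(col - max(col))))
  expect_equal(min(deltas), oracle)
  expect_true(all(deltas <= 0))
})

test_that("out-of-window and inconsistent variants are handled explicitly", {
  pwm <- pwm_from_pfm(ctcf_demo_pfm())
  genome <- c(chr1 = strrep("ACGT", 20))
  site <- tibble::tibble(site_id = "s", chrom = "chr1", motif_start = 10L,
                         motif_strand = "+")
  far <- tibble::tibble(chrom = "chr1", pos = 40L, ref = "A", alt = "T")
  res <- differential_motif_score(site, far, genome, pwm)
  expect_equal(res$delta, 0)
  expect_equal(res$status, "out_of_window")

  indel <- tibble::tibble(chrom = "chr1", pos = 12L, ref = "AC", alt = "A")
  expect_equal(differential_motif_score(site, indel, genome, pwm)$status,
               "indel_not_scored")

  wrong <- tibble::tibble(chrom = "chr1", pos = 12L, ref = "T", alt = "A")
  expect_error(differential_motif_score(site, wrong, genome, pwm),
               "disagrees")
})
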