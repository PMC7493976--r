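mk_const <- function(centers, strands, chrom = "chr1") {
  tibble::tibble(site_id = paste0("k", seq_along(centers)), chrom = chrom,
                 start = as.integer(centers - 75L),
                 end = as.integer(centers + 75L),
                 motif_strand = strands)
}

anchor_at <- function(center, chrom = "chr1") {
  tibble::tibble(site_id = "anchor", chrom = chrom,
                 start = as.integer(center - 75L),
                 end = as.integer(center + 75L))
}

test_that("divergent boundaries are the nearest qualifying constitutive sites", {
  const <- mk_const(c(850000, 1200000), c("-", "+"))
  dom <- build_domain(anchor_at(1000000), const)
  expect_true(dom$found)
  expect_equal(dom$domain_start, 850000L)
  expect_equal(dom$domain_end, 1200000L)
})

test_that("sites closer than the 100-kb side minimum are skipped, not blockers", {
  const <- mk_const(c(950000, 850000, 1200000), c("-", "-", "+"))
  dom <- build_domain(anchor_at(1000000), const)
  expect_true(dom$found)
  expect_equal(dom$left_site_id, "k2")  # 50-kb site skipped
})

test_that("a missing qualifying boundary on either side yields no domain", {
  const <- mk_const(c(850000), c("-"))  # nothing on the right within 1 Mb
  dom <- build_domain(anchor_at(1000000), const)
  expect_false(dom$found)
  # wrong orientation also disqualifies
  const2 <- mk_const(c(850000, 1200000), c("+", "+"))
  expect_false(build_domain(anchor_at(1000000), const2)$found)
})

test_that("domain building agrees with the exhaustive-pair oracle", {
  set.seed(17)
  for (mode in c("divergent", "convergent", "opposite_any")) {
    cfg <- pipeline_config(domain_orientation = mode)
    for (rep in 1:120) {
      n <- sample(3:12, 1)
      centers <- sort(sample(seq(100000L, 3000000L, by = 500L), n))
      strands <- sample(c("+", "-", NA), n, replace = TRUE,
                        prob = c(0.45, 0.45, 0.1))
      const <- mk_const(centers, strands)
      anchor_center <- sample(seq(200000L, 2800000L, by = 1000L), 1)
      got <- build_domain(anchor_at(anchor_center), const, cfg)
      want <- brute_force_domain(anchor_center, const, cfg)
      if (is.null(want)) {
        expect_false(got$found)
      } else {
        expect_true(got$found)
        expect_equal(got$left_site_id, want$left)
        expect_equal(got$right_site_id, want$right)
      }
    }
  }
})

test_that("CTCF-gene correlation follows Pearson r with a strict R2 cutoff", {
  ct <- paste0("t", 1:4)
  perfect <- correlate_ctcf_gene(setNames(c(1, 2, 3, 4), ct),
                                 setNames(c(2, 4, 6, 8), ct))
  expect_equal(perfect$r, 1)
  expect_true(perfect$highly_correlated)

  borderline <- correlate_ctcf_gene(setNames(c(1, 2, 3), paste0("t", 1:3)),
                                    setNames(c(1, 3, 2), paste0("t", 1:3)))
  expect_equal(borderline$r, 0.5)
  expect_equal(borderline$r_squared, 0.25)
  expect_false(borderline$highly_correlated)  # strictly greater than 0.25

  flat <- correlate_ctcf_gene(setNames(c(1, 2, 3), paste0("t", 1:3)),
                              setNames(c(2, 2, 2), paste0("t", 1:3)))
  expect_true(flat$undefined)
  expect_false(flat$highly_correlated)

  expect_error(correlate_ctcf_gene(setNames(1:2, c("a", "b")),
                                   setNames(1:2, c("a", "b"))),
               "3 shared")
})

test_that("target assignment gives promoter precedence then domain containment", {
  genes <- tibble::tibble(gene_id = paste0("g", 1:4), chrom = "chr1",
                          strand = "+",
                          tss = c(1001000L, 900000L, 1100000L, 5000000L))
  site <- anchor_at(1000000)  # 1 kb upstream of g1's TSS
  dom <- build_domain(site, mk_const(c(850000, 1200000), c("-", "+")))
  tg <- assign_candidate_targets(site, genes, dom)
  expect_equal(tg$category[tg$gene_id == "g1"], "promoter")
  # promoter precedence: in-domain genes are not intra_domain targets here
  expect_equal(tg$category[tg$gene_id == "g2"], "inter_domain")

  site2 <- anchor_at(1050000)  # no promoter overlap
  dom2 <- build_domain(site2, mk_const(c(900000, 1250000), c("-", "+")))
  tg2 <- assign_candidate_targets(site2, genes, dom2)
  expect_setequal(tg2$gene_id[tg2$category == "intra_domain"],
                  c("g1", "g2", "g3"))  # g2 sits exactly on the left boundary
  expect_equal(tg2$category[tg2$gene_id == "g4"], "inter_domain")

  # categories partition all same-chromosome genes, one label each
  expect_equal(nrow(tg2), 4L)
  expect_true(all(tg2$category %in%
                    c("promoter", "intra_domain", "inter_domain")))

  none <- assign_candidate_targets(site2, genes,
                                   tibble::tibble(found = FALSE))
  expect_true(all(none$category == "inter_domain"))
})

test_that("DE enrichment reproduces the hypergeometric worked example", {
  # table [[3,1],[1,3]]: 4 targets of 8 genes, 4 DE, overlap 3
  universe <- paste0("g", 1:8)
  de <- tibble::tibble(gene_id = universe,
                       log2fc = c(2, 2, 2, 0, 2, 0, 0, 0),
                       fdr = 1e-9)
  res <- de_enrichment(paste0("g", 1:4), de, universe)
  expect_equal(res$p_value, 34 / 70, tolerance = 1e-12)
  expect_equal(res$n_overlap, 3L)
  expect_equal(res$odds_ratio, 9)

  # degenerate margins: target set = universe
  res2 <- de_enrichment(universe, de, universe)
  expect_equal(res2$p_value, 1)
  expect_true(res2$continuity)
  expect_error(de_enrichment("g1", de, character(0)), "empty universe")
})

test_that("two-tailed Fisher p agrees with stats::fisher.test", {
  set.seed(23)
  for (rep in 1:40) {
    tab <- matrix(sample(0:12, 4, replace = TRUE), 2)
    skip_cond <- sum(tab) == 0
    if (skip_cond) next
    mine <- ctcfscape:::fisher_two_tailed(tab[1, 1], tab[1, 2],
                                          tab[2, 1], tab[2, 2])
    ref <- stats::fisher.test(tab)$p.value
    expect_equal(mine, ref, tolerance = 1e-9)
  }
})

test_that("the highly-correlated fraction shrinks as the R2 cutoff rises", {
  set.seed(5)
  ct <- paste0("t", 1:10)
  fracs <- vapply(c(0.1, 0.25, 0.5, 0.8), function(th) {
    cfg <- pipeline_config(r2_threshold = th)
    mean(vapply(1:60, function(k) {
      x <- setNames(stats::rnorm(10), ct)
      y <- setNames(0.5 * x + stats::rnorm(10), ct)
      correlate_ctcf_gene(x, y, cfg)$highly_correlated
    }, logical(1)))
  }, numeric(1))
  expect_true(all(diff(fracs) <= 0))
})
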