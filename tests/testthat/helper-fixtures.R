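# Small builders shared across test files. Everything is generated in code;
# no fixture files.

peaks_from_summits <- function(summits, dataset_id = "d1", chrom = "chr1",
                               fold = 10) {
  p <- tibble::tibble(
    dataset_id = dataset_id,
    chrom = chrom,
    start = summits - 100L,
    end = summits + 100L,
    summit = as.integer(summits),
    fold_enrichment = fold
  )
  attr(p, "included") <- TRUE
  p
}

random_pfm <- function(width, max_count = 50) {
  matrix(sample.int(max_count, 4 * width, replace = TRUE), nrow = 4,
         dimnames = list(c("A", "C", "G", "T"), NULL))
}

random_seq <- function(n, bg = c(A = 0.275, C = 0.225, G = 0.225, T = 0.275)) {
  paste(sample(names(bg), n, replace = TRUE, prob = bg), collapse = "")
}

# Brute-force tail p-value by enumerating all 4^w sequences of a PWM.
enumerate_pwm_pvalue <- function(score, pwm, background) {
  w <- ncol(pwm)
  grids <- rep(list(1:4), w)
  combos <- as.matrix(expand.grid(grids))
  scores <- numeric(nrow(combos))
  probs <- rep(1, nrow(combos))
  for (k in seq_len(w)) {
    scores <- scores + pwm[combos[, k] + 4 * (k - 1)]
    probs <- probs * background[combos[, k]]
  }
  sum(probs[scores >= score - 1e-9])
}

# Exhaustive-pair oracle for chromatin-domain building: test every pair of
# constitutive sites against the rules, keep the nearest qualifying one.
brute_force_domain <- function(anchor_center, constitutive, cfg) {
  ccent <- (constitutive$start + constitutive$end) %/% 2L
  dl <- anchor_center - ccent
  dr <- ccent - anchor_center
  has_strand <- !is.na(constitutive$motif_strand)
  okl <- dl >= cfg$domain_min_side & dl <= cfg$domain_max_side & has_strand
  okr <- dr >= cfg$domain_min_side & dr <= cfg$domain_max_side & has_strand
  mode <- cfg$domain_orientation
  if (mode %in% c("divergent", "convergent")) {
    ls <- if (mode == "divergent") "-" else "+"
    rs <- if (mode == "divergent") "+" else "-"
    lc <- which(okl & constitutive$motif_strand == ls)
    rc <- which(okr & constitutive$motif_strand == rs)
    if (!length(lc) || !length(rc)) return(NULL)
    li <- lc[which.min(dl[lc])]
    ri <- rc[which.min(dr[rc])]
  } else {
    best <- NULL
    for (i in which(okl)) for (j in which(okr)) {
      if (constitutive$motif_strand[i] == constitutive$motif_strand[j]) next
      key <- c(dl[i] + dr[j], dl[i])
      if (is.null(best) || key[1] < best$key[1] ||
          (key[1] == best$key[1] && key[2] < best$key[2])) {
        best <- list(li = i, ri = j, key = key)
      }
    }
    if (is.null(best)) return(NULL)
    li <- best$li
    ri <- best$ri
  }
  list(left = constitutive$site_id[li], right = constitutive$site_id[ri])
}

# Small scenario used by several files; kept tiny for speed.
small_scenario <- function(seed = 5, n_sites = 300) {
  generate_scenario(scenario_config(seed = seed, n_sites = n_sites,
                                    chrom_length = 600000L))
}
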