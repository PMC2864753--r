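make_tags <- function(mono_mass, net = 0.5, peptide_id = NULL,
                      locus_id = "L1", f_score = 5) {
  n <- length(mono_mass)
  tibble::tibble(
    peptide_id = peptide_id %||% sprintf("pep%02d", seq_len(n)),
    locus_id = rep_len(locus_id, n), mono_mass = mono_mass,
    net = rep_len(net, n), f_score = rep_len(f_score, n)
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

make_features <- function(mass, net = 0.5, abundance = 100,
                          sample_id = "s1", technical_replicate = 1L) {
  n <- length(mass)
  tibble::tibble(
    mass = mass, net = rep_len(net, n),
    abundance = rep_len(abundance, n),
    sample_id = rep_len(sample_id, n),
    technical_replicate = rep_len(technical_replicate, n)
  )
}

test_that("matching windows are inclusive at +/-6 ppm and +/-0.001 NET", {
  tags <- make_tags(1000)
  inside <- make_features(1000.005999)
  outside <- make_features(1000.006001)
  expect_equal(match_features(inside, tags)$peptide_id, "pep01")
  expect_equal(nrow(match_features(outside, tags)), 0)

  off_net <- make_features(1000, net = 0.502)
  expect_equal(nrow(match_features(off_net, tags)), 0)
  edge_net <- make_features(1000, net = 0.5009999)
  expect_equal(nrow(match_features(edge_net, tags)), 1)
})

test_that("ambiguous matches resolve by distance, then mass, then peptide id", {
  # two tags both in window; feature closer (normalized) to the second
  tags <- make_tags(c(1000, 1000.004), net = c(0.5, 0.5))
  f <- make_features(1000.003)
  expect_equal(match_features(f, tags)$peptide_id, "pep02")
  # perfectly symmetric in mass, same net: lexicographically smallest wins
  tags2 <- make_tags(c(1000, 1000.002), peptide_id = c("b", "a"))
  f2 <- make_features(1000.001)
  expect_equal(match_features(f2, tags2)$peptide_id, "a")
})

test_that("zero-jitter simulated features all match their generating tags", {
  cfg <- noise_free_config(n_genes = 60, n_proteins = 20, regulon_size = 10)
  px <- simulate_proteome(cfg)
  m <- match_features(px$features, px$tags)
  expect_equal(nrow(m), nrow(px$features))
  expect_equal(attr(m, "n_unmatched"), 0L)
  # every match agrees with the generating peptide
  key <- paste(px$features$sample_id, px$features$technical_replicate,
    px$features$abundance
  )
  mkey <- paste(m$sample_id, m$technical_replicate, m$abundance)
  expect_identical(
    m$peptide_id[match(key, mkey)], px$features$true_peptide_id
  )
})

test_that("replicate presence filter keeps 2-of-3 groups, against brute force", {
  m <- make_matched(
    peptide_id = c("p1", "p1", "p2"), locus_id = "L1", sample_id = "s1",
    technical_replicate = c(1L, 3L, 2L), abundance = c(10, 12, 9)
  )
  kept <- replicate_presence_filter(m)
  expect_identical(sort(unique(kept$peptide_id)), "p1")

  set.seed(3)
  big <- tidyr::expand_grid(
    peptide_id = sprintf("p%02d", 1:30), sample_id = c("s1", "s2"),
    technical_replicate = 1:3
  ) %>%
    dplyr::mutate(locus_id = "L1", abundance = 10^runif(dplyr::n(), 1, 3)) %>%
    dplyr::filter(runif(dplyr::n()) < 0.6)
  kept <- replicate_presence_filter(big)
  # brute-force oracle over all (peptide, sample) groups
  counts <- table(paste(big$peptide_id, big$sample_id))
  surviving <- names(counts)[counts >= 2]
  expect_setequal(paste(kept$peptide_id, kept$sample_id), surviving)
  expect_equal(nrow(kept), sum(counts[counts >= 2]))
})

test_that("MA normalization is exact on replicate scale shifts", {
  ab <- 10^c(1, 1.5, 2.5, 3)
  m <- dplyr::bind_rows(
    make_matched(sprintf("p%d", 1:4), "L1", "s1", 1L, ab),
    make_matched(sprintf("p%d", 1:4), "L1", "s1", 2L, ab)
  )
  norm <- ma_normalize(m)
  fits <- tidy(norm)
  expect_equal(fits$slope, 0, tolerance = 1e-12)
  expect_equal(fits$intercept, 0, tolerance = 1e-12)
  expect_equal(norm$x_prime, log10(m$abundance), tolerance = 1e-12)

  # replicate = reference x 10: fitted m* is identically 1
  m10 <- dplyr::bind_rows(
    make_matched(sprintf("p%d", 1:4), "L1", "s1", 1L, ab),
    make_matched(sprintf("p%d", 1:4), "L1", "s1", 2L, ab * 10)
  )
  norm10 <- ma_normalize(m10)
  fits10 <- tidy(norm10)
  expect_equal(fits10$slope, 0, tolerance = 1e-12)
  expect_equal(fits10$intercept, 1, tolerance = 1e-12)
  expect_equal(
    norm10$x_prime[norm10$technical_replicate == 2],
    log10(ab),
    tolerance = 1e-12
  )
})

test_that("planted intensity-dependent bias is recovered and removed", {
  log_ref <- seq(1, 4, length.out = 20)
  # construct replicate logs satisfying m = 0.1 a + 0.05 exactly
  log_rep <- (1.05 * log_ref + 0.05) / 0.95
  m <- dplyr::bind_rows(
    make_matched(sprintf("p%02d", 1:20), "L1", "s1", 1L, 10^log_ref),
    make_matched(sprintf("p%02d", 1:20), "L1", "s1", 2L, 10^log_rep)
  )
  norm <- ma_normalize(m)
  fits <- tidy(norm)
  expect_equal(fits$slope, 0.1, tolerance = 1e-6)
  expect_equal(fits$intercept, 0.05, tolerance = 1e-6)

  # applying the normalization again changes nothing (m is now 0)
  renorm <- ma_normalize(
    dplyr::mutate(norm, abundance = 10^x_prime) %>%
      dplyr::select(-x_prime)
  )
  expect_equal(renorm$x_prime, norm$x_prime, tolerance = 1e-9)
  expect_equal(tidy(renorm)$slope, 0, tolerance = 1e-9)

  one_shared <- make_matched(
    c("p1", "p1", "p2"), "L1", "s1", c(1L, 2L, 2L), c(10, 11, 12)
  )
  expect_error(ma_normalize(one_shared), "shared")
})

test_that("variability filter drops groups with SD above the mean", {
  m <- make_matched(
    rep(c("stable", "wild", "pair"), times = c(3, 3, 2)), "L1", "s1",
    c(1L, 2L, 3L, 1L, 2L, 3L, 1L, 2L),
    c(10, 10, 10, 1, 1, 100, 7, 7)
  )
  norm <- dplyr::mutate(m, x_prime = log10(abundance))
  kept <- variability_filter(norm)
  expect_setequal(unique(kept$peptide_id), c("stable", "pair"))
  # independent arithmetic: sd(1,1,100) = 57.16 > mean 34
  expect_gt(sd(c(1, 1, 100)), mean(c(1, 1, 100)))
})

test_that("F-score filter drops each protein's lowest floor(k/3) peptides", {
  tags <- make_tags(800 + 1:6,
    peptide_id = sprintf("p%d", 1:6),
    f_score = c(9, 8, 7, 6, 2, 1)
  )
  m <- make_matched(sprintf("p%d", 1:6), "L1", "s1", 1L, 100)
  kept <- fscore_filter(m, tags)
  expect_setequal(kept$peptide_id, sprintf("p%d", 1:4))

  tags4 <- tags[1:4, ]
  kept4 <- fscore_filter(m[1:4, ], tags4)
  expect_setequal(kept4$peptide_id, sprintf("p%d", 1:3))

  # k <= 2 untouched
  kept2 <- fscore_filter(m[1:2, ], tags[1:2, ])
  expect_equal(nrow(kept2), 2)

  # tie at the cut: the lexicographically larger peptide id is dropped
  tags_tie <- make_tags(800 + 1:3,
    peptide_id = c("pa", "pc", "pb"),
    f_score = c(9, 3, 3)
  )
  m_tie <- make_matched(c("pa", "pc", "pb"), "L1", "s1", 1L, 100)
  kept_tie <- fscore_filter(m_tie, tags_tie)
  expect_setequal(kept_tie$peptide_id, c("pa", "pb"))

  # brute-force oracle on a random protein set
  set.seed(9)
  tags_big <- make_tags(800 + 1:40,
    peptide_id = sprintf("q%02d", 1:40),
    locus_id = rep(sprintf("L%d", 1:5), each = 8),
    f_score = sample(1:12, 40, replace = TRUE)
  )
  m_big <- make_matched(
    tags_big$peptide_id, tags_big$locus_id, "s1", 1L, 100
  )
  kept_big <- fscore_filter(m_big, tags_big)
  for (loc in unique(tags_big$locus_id)) {
    sub <- tags_big[tags_big$locus_id == loc, ]
    ord <- sub[order(-sub$f_score, sub$peptide_id), ]
    expected <- ord$peptide_id[seq_len(nrow(ord) - floor(nrow(ord) / 3))]
    expect_setequal(
      kept_big$peptide_id[kept_big$locus_id == loc], expected
    )
  }
})

test_that("peptide ratios average replicates then log the sample quotient", {
  m <- dplyr::bind_rows(
    make_matched("p1", "L1", "s1", 1:3, c(90, 100, 110)),
    make_matched("p1", "L1", "s2", 1:3, c(9, 10, 11))
  ) %>%
    dplyr::mutate(x_prime = log10(abundance))
  pr <- peptide_ratios(m, "s1", "s2")
  expect_equal(pr$log10_ratio, 1, tolerance = 1e-12)
  expect_lt(pr$p_one_tailed, 0.01)
})

test_that("peptides opposing the protein direction get p = 1", {
  up <- function(p, s1, s2) {
    dplyr::bind_rows(
      make_matched(p, "L1", "s1", 1:3, s1),
      make_matched(p, "L1", "s2", 1:3, s2)
    )
  }
  m <- dplyr::bind_rows(
    up("p1", c(100, 110, 120), c(10, 11, 12)),
    up("p2", c(200, 210, 190), c(20, 21, 19)),
    up("p3", c(5, 6, 7), c(50, 60, 70)) # opposes the protein-average up
  ) %>%
    dplyr::mutate(x_prime = log10(abundance))
  pr <- peptide_ratios(m, "s1", "s2")
  expect_identical(pr$p_one_tailed[pr$peptide_id == "p3"], 1)
  expect_true(all(pr$p_one_tailed[pr$peptide_id != "p3"] < 1))

  # all members sharing the direction: no forced p = 1
  m2 <- dplyr::bind_rows(
    up("p1", c(100, 110, 120), c(10, 11, 12)),
    up("p2", c(300, 310, 320), c(30, 31, 32)),
    up("p3", c(50, 55, 60), c(5, 6, 7))
  ) %>%
    dplyr::mutate(x_prime = log10(abundance))
  expect_true(all(peptide_ratios(m2, "s1", "s2")$p_one_tailed < 1))
})

test_that("Fisher combination matches its closed forms", {
  one <- fisher_combine(0.05)
  expect_equal(one$chi_square, -2 * log(0.05), tolerance = 1e-12)
  expect_equal(one$df, 2L)
  expect_equal(one$combined_p, 0.05, tolerance = 1e-12)

  two <- fisher_combine(c(0.1, 0.1))
  expect_equal(two$chi_square, 9.2103, tolerance = 1e-4)
  expect_equal(
    two$combined_p, (1 + two$chi_square / 2) * exp(-two$chi_square / 2),
    tolerance = 1e-12
  )
  expect_equal(two$combined_p, 0.0561, tolerance = 1e-3)

  all_one <- fisher_combine(c(1, 1, 1))
  expect_equal(all_one$chi_square, 0)
  expect_equal(all_one$combined_p, 1)

  expect_error(fisher_combine(numeric(0)), "p-values")
  expect_error(fisher_combine(1.2), "0, 1")
})

test_that("protein rollup requires 3 peptides and averages log ratios", {
  pr <- tibble::tibble(
    peptide_id = sprintf("p%d", 1:5),
    locus_id = c(rep("L1", 3), rep("L2", 2)),
    log10_ratio = c(0.2, 0.4, 0.6, 1, 1),
    p_one_tailed = c(0.05, 0.01, 0.2, 0.01, 0.01)
  )
  out <- protein_rollup(pr)
  expect_identical(out$locus_id, "L1")
  expect_equal(out$log10_ratio, 0.4)
  expect_equal(out$n_peptides, 3L)
  expect_equal(out$df, 6L)
  expect_equal(
    out$chi_square, -2 * sum(log(c(0.05, 0.01, 0.2))),
    tolerance = 1e-12
  )
  expect_equal(
    out$combined_p, pchisq(out$chi_square, 6, lower.tail = FALSE),
    tolerance = 1e-15
  )

  # identical member ratios r give exactly log10(r)
  pr2 <- tibble::tibble(
    peptide_id = sprintf("p%d", 1:4), locus_id = "L1",
    log10_ratio = log10(2.5), p_one_tailed = 0.5
  )
  expect_equal(protein_rollup(pr2)$log10_ratio, log10(2.5))
})

test_that("protein induction filter is inclusive at the fold boundary", {
  tbl <- tibble::tibble(
    locus_id = c("a", "b", "c"), fold = c(1.4999, 1.5, 1.5001),
    log10_ratio = log10(c(1.4999, 1.5, 1.5001)), combined_p = 0.01
  )
  expect_identical(filter_up_proteins(tbl)$locus_id, c("b", "c"))
})

test_that("noise-free suppressed proteome quantifies to exactly 0.41", {
  cfg <- noise_free_config(
    n_genes = 60, n_proteins = 20, regulon_size = 10,
    marker_protein_fold = 0.41 # no induced protein: uniform suppression
  )
  px <- simulate_proteome(cfg)
  pq <- quantify_proteins(px$features, px$tags, "limited_d18", "replete_d18")
  expect_gt(nrow(pq), 0)
  expect_equal(pq$fold, rep(0.41, nrow(pq)), tolerance = 1e-12)
})

test_that("stage order only removes records and leaves abundances intact", {
  cfg <- small_config(seed = 21)
  px <- simulate_proteome(cfg)
  m <- match_features(px$features, px$tags)
  m2 <- replicate_presence_filter(m)
  expect_true(nrow(m2) <= nrow(m))
  norm <- ma_normalize(m2)
  expect_identical(norm$abundance, m2$abundance)
  m3 <- variability_filter(norm)
  expect_true(nrow(m3) <= nrow(norm))
  m4 <- fscore_filter(m3, px$tags)
  expect_true(nrow(m4) <= nrow(m3))
  expect_true(all(m4$x_prime %in% norm$x_prime))
})
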