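tx_tbl <- function(locus_id, ratio, p) {
  tibble::tibble(locus_id = locus_id, day = 18L, ratio = ratio, p_value = p)
}
pq_tbl <- function(locus_id, fold, p) {
  tibble::tibble(
    locus_id = locus_id, day = 18L, n_peptides = 3L,
    log10_ratio = log10(fold), fold = fold,
    chi_square = 1, df = 6L, combined_p = p
  )
}

test_that("pair building keeps loci significant on either platform", {
  tx <- tx_tbl(c("a", "b", "c"), c(2, 1.1, 3), c(0.01, 0.5, 0.2))
  pq <- pq_tbl(c("a", "b", "d"), c(0.5, 0.9, 2), c(0.9, 0.5, 0.001))
  pairs <- build_pairs(tx, pq)
  # a: mrna significant; b: neither; c/d: not on both platforms
  expect_identical(pairs$locus_id, "a")
  expect_equal(pairs$mrna_log10_ratio, log10(2))
  expect_equal(pairs$protein_log10_ratio, log10(0.5))

  set.seed(2)
  loci <- sprintf("g%02d", 1:50)
  tx_big <- tx_tbl(loci, 10^rnorm(50, 0, 0.3), runif(50))
  pq_big <- pq_tbl(loci, 10^rnorm(50, 0, 0.3), runif(50))
  pairs_big <- build_pairs(tx_big, pq_big)
  keep <- pmin(tx_big$p_value, pq_big$combined_p) <= 0.05
  expect_setequal(pairs_big$locus_id, loci[keep])
})

test_that("r_squared matches hand arithmetic and is affine-invariant", {
  perfect <- build_pairs(
    tx_tbl(c("a", "b", "c"), c(1, 2, 4), 0.01),
    pq_tbl(c("a", "b", "c"), c(1, 2, 4), 0.01)
  )
  expect_equal(r_squared(perfect), 1)

  x <- c(-1, 0, 1)
  y <- c(-1, 0.5, 1)
  pairs <- build_pairs(
    tx_tbl(c("a", "b", "c"), 10^x, 0.01),
    pq_tbl(c("a", "b", "c"), 10^y, 0.01)
  )
  # hand Pearson on the 3 centered points
  xc <- x - mean(x)
  yc <- y - mean(y)
  hand_r2 <- (sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2)))^2
  expect_equal(r_squared(pairs), hand_r2, tolerance = 1e-12)

  scaled <- dplyr::mutate(pairs,
    mrna_log10_ratio = 3 * mrna_log10_ratio - 2,
    protein_log10_ratio = -0.5 * protein_log10_ratio + 1
  )
  expect_equal(r_squared(scaled), hand_r2, tolerance = 1e-12)
  expect_error(r_squared(pairs[1:2, ]), "3")
})

test_that("decoupled platforms give near-zero R-squared", {
  set.seed(14)
  fails <- 0L
  for (i in 1:10) {
    loci <- sprintf("g%03d", 1:200)
    pairs <- build_pairs(
      tx_tbl(loci, 10^rnorm(200, 0, 0.4), 0.01),
      pq_tbl(loci, 10^rnorm(200, log10(0.41), 0.15), 0.01)
    )
    if (r_squared(pairs) >= 0.1) fails <- fails + 1L
  }
  expect_lte(fails, 1L)
})

test_that("proteome summary counts match a brute-force tally", {
  pq <- pq_tbl(c("a", "b", "c", "d"), c(0.41, 0.41, 1.2, 1),
    c(0.01, 0.2, 0.01, 0.04)
  )
  s <- proteome_summary(pq)
  expect_equal(s$n_detected, 4)
  expect_equal(s$n_significantly_down, 1) # only a: p<=0.05 and fold<1
  expect_equal(s$mean_percent_change, 100 * (mean(c(0.41, 0.41, 1.2, 1)) - 1))

  all_down <- pq_tbl(sprintf("p%d", 1:5), rep(0.41, 5), 1e-6)
  s2 <- proteome_summary(all_down)
  expect_equal(s2$mean_percent_change, -59, tolerance = 1e-9)
  expect_equal(s2$n_significantly_down, 5)
  expect_equal(
    proteome_summary(all_down, mean_type = "geometric")$mean_percent_change,
    -59,
    tolerance = 1e-9
  )

  flat <- pq_tbl(sprintf("p%d", 1:3), rep(1, 3), 1e-6)
  expect_equal(proteome_summary(flat)$n_significantly_down, 0)

  set.seed(5)
  rnd <- pq_tbl(sprintf("p%d", 1:80), 10^rnorm(80, -0.2, 0.3), runif(80))
  s3 <- proteome_summary(rnd)
  expect_equal(
    s3$n_significantly_down,
    sum(rnd$combined_p <= 0.05 & rnd$fold < 1)
  )
})

test_that("glance methods summarize fitted result objects", {
  pq <- pq_tbl(sprintf("p%d", 1:5), rep(0.41, 5), 1e-6)
  class(pq) <- c("protein_quant", class(pq))
  expect_equal(glance(pq)$mean_percent_change, -59, tolerance = 1e-9)
  pairs <- build_pairs(
    tx_tbl(c("a", "b", "c"), c(1, 2, 4), 0.01),
    pq_tbl(c("a", "b", "c"), c(1, 2, 4), 0.01)
  )
  g <- glance(pairs)
  expect_equal(g$n_pairs, 3)
  expect_equal(g$r_squared, 1)
})

test_that("marker report flags coupling per day and errors when absent", {
  tx <- dplyr::bind_rows(
    tx_tbl("marker", 16, 0.003),
    dplyr::mutate(tx_tbl("marker", 1.06, 0.7), day = 28L)
  )
  pq <- dplyr::bind_rows(
    pq_tbl("marker", 27, 1e-9),
    dplyr::mutate(pq_tbl("marker", 27, 1e-9), day = 28L)
  )
  rep_ <- marker_report(tx, pq, "marker")
  expect_equal(rep_$coupled, c(TRUE, FALSE))
  expect_equal(rep_$mrna_fold[1], 16)
  expect_equal(rep_$protein_fold[1], 27)

  weak <- marker_report(tx, dplyr::mutate(pq, fold = 1.2), "marker")
  expect_false(any(weak$coupled))

  expect_error(
    marker_report(tx, pq_tbl("other", 2, 0.1), "marker"),
    "absent from proteins: marker"
  )
  expect_error(
    marker_report(tx_tbl("other", 2, 0.1), pq, "marker"),
    "absent from transcripts: marker"
  )
})

test_that("coupled_loci applies both fold and significance thresholds", {
  tx <- tx_tbl(c("m", "x", "y"), c(16, 2, 2), c(0.001, 0.01, 0.5))
  pq <- pq_tbl(c("m", "x", "y"), c(27, 1.2, 3), c(0.001, 0.01, 0.01))
  # x fails the protein fold, y fails the mrna p-value
  expect_identical(coupled_loci(tx, pq), "m")
})
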