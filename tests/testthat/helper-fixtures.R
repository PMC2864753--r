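# Small in-code fixtures shared across the suite.

# chips metadata for `n_days` days x 2 treatments x 3 biological replicates
make_chips <- function(days = c(17L, 18L, 28L)) {
  grid <- expand.grid(
    treatment = c("iron_limited", "iron_replete"),
    day = days, biological_replicate = 1:3,
    stringsAsFactors = FALSE
  )
  grid <- grid[order(grid$treatment, grid$day, grid$biological_replicate), ]
  tibble::tibble(
    chip_id = sprintf("chip_%02d", seq_len(nrow(grid))),
    treatment = grid$treatment, day = grid$day,
    biological_replicate = grid$biological_replicate
  )
}

# long expression tibble from a gene x chip matrix
make_expr <- function(values, chips, loci = NULL) {
  values <- as.matrix(values)
  if (is.null(loci)) loci <- sprintf("g%02d", seq_len(nrow(values)))
  tibble::tibble(
    locus_id = rep(loci, each = ncol(values)),
    chip_id = rep(chips$chip_id[seq_len(ncol(values))], nrow(values)),
    fluorescence = as.vector(t(values))
  )
}

# one-day design: limited replicates `lim`, replete replicates `rep_` for a
# single gene
one_gene_expr <- function(lim, rep_, day = 18L) {
  chips <- make_chips(days = day)
  lim_chips <- chips$chip_id[chips$treatment == "iron_limited"]
  rep_chips <- chips$chip_id[chips$treatment == "iron_replete"]
  expr <- tibble::tibble(
    locus_id = "g01",
    chip_id = c(lim_chips, rep_chips),
    fluorescence = c(lim, rep_)
  )
  list(expr = expr, chips = chips)
}

# noise-free study configuration (exact planted folds everywhere)
noise_free_config <- function(...) {
  simulation_config(
    noise_sd = 0, protein_fold_sd = 0, ppm_jitter_sd = 0, net_jitter_sd = 0,
    detected_fraction = 1, decoy_fraction = 0, ...
  )
}

# small but fully structured study configuration for fast tests
small_config <- function(...) {
  simulation_config(
    n_genes = 80, n_proteins = 30, regulon_size = 10,
    peptides_per_protein = 5, ...
  )
}

# matched-observation tibble builder
make_matched <- function(peptide_id, locus_id, sample_id,
                         technical_replicate, abundance) {
  tibble::tibble(
    peptide_id = peptide_id, locus_id = locus_id, sample_id = sample_id,
    technical_replicate = technical_replicate, abundance = abundance
  )
}

# independent closed-form Fisher survival for integer df = 2k:
# P(X > x) = exp(-x/2) * sum_{j<k} (x/2)^j / j!
fisher_survival_closed_form <- function(chi, k) {
  exp(-chi / 2) * sum((chi / 2)^(0:(k - 1)) / factorial(0:(k - 1)))
}

# point-in-convex-polygon test (vertices in any order)
in_convex_hull <- function(px, py, hx, hy, tol = 1e-9) {
  ord <- order(atan2(hy - mean(hy), hx - mean(hx)))
  hx <- hx[ord]
  hy <- hy[ord]
  n <- length(hx)
  cross <- vapply(seq_len(n), function(i) {
    j <- if (i == n) 1L else i + 1L
    (hx[j] - hx[i]) * (py - hy[i]) - (hy[j] - hy[i]) * (px - hx[i])
  }, numeric(length(px)))
  if (is.null(dim(cross))) cross <- matrix(cross, nrow = 1)
  apply(cross, 1, function(z) all(z >= -tol) || all(z <= tol))
}
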