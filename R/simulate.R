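#' Configuration for the synthetic study generator
#'
#' Builds the parameter set for [simulate_transcriptome()] and
#' [simulate_proteome()]. The defaults emulate the iron-limitation study
#' design: six cultures (2 treatments x 3 biological replicates) sampled on
#' days 17, 18 and 28 for microarrays (18 chips), and 4 proteomic samples
#' (2 treatments x days 18/28) each run in 3 technical replicates. Four
#' expression programs are planted — `exponential` (elevated on day 17 in
#' both treatments), `stationary` (elevated on day 28 in the iron-replete
#' cultures, which are the only ones still growing into stationary phase),
#' `early_iron` (elevated in iron-limited cultures on day 18) and
#' `late_iron` (elevated in iron-limited cultures on day 28). One
#' `early_iron` member is the marker gene (the sfuC analogue): its mRNA is
#' induced `marker_mrna_fold` (default 16) on day 18 and its protein
#' `marker_protein_fold` (default 27) in iron-limited samples, against a
#' global proteome suppression of `proteome_suppression` (default 0.59,
#' i.e. iron-limited protein abundances scaled by 0.41).
#'
#' @param n_genes Number of genes on the array.
#' @param n_proteins Number of proteins with AMT tags (a prefix of the gene
#'   list; includes the marker).
#' @param regulons Tibble with columns `program`, `locus_id`, `fold`
#'   defining the planted expression programs. `NULL` builds the default:
#'   four programs of `regulon_size` genes each, folds `regulon_fold`, the
#'   first `early_iron` member promoted to the marker.
#' @param regulon_size Genes per default program.
#' @param regulon_fold Planted mRNA fold for default (non-marker) program
#'   members.
#' @param marker_locus Locus id of the coupled marker gene.
#' @param marker_mrna_fold Planted marker mRNA induction (iron-limited /
#'   iron-replete, day 18).
#' @param marker_protein_fold Planted marker protein induction in
#'   iron-limited samples (both proteomic days).
#' @param baseline_log10_mean,baseline_log10_sd Lognormal baseline
#'   (log10 scale) for fluorescence and protein abundance.
#' @param noise_sd Multiplicative lognormal measurement noise, as the sd of
#'   a normal deviate on the log10 scale, for both platforms.
#' @param proteome_suppression Fractional decrease of non-marker protein
#'   abundance in iron-limited samples (0.59 means abundances x 0.41).
#' @param protein_fold_sd Per-(protein, day) lognormal deviation of the
#'   planted protein fold around the suppression level (log10-scale sd).
#'   Zero plants exactly `1 - proteome_suppression` everywhere. This draw is
#'   independent of the mRNA programs, which is what decouples the two
#'   platforms.
#' @param peptides_per_protein Mean peptides per protein; counts are drawn
#'   as `3 + Poisson(mean - 3)` so every protein can pass the 3-peptide
#'   rollup requirement. Must be >= 1 (values below 3 are floored at 3).
#' @param detected_fraction Per-(peptide, replicate) Bernoulli detection
#'   probability.
#' @param ppm_jitter_sd Mass measurement jitter (sd, ppm).
#' @param net_jitter_sd Elution time jitter (sd, NET units).
#' @param decoy_fraction Probability that a feature is replaced by a decoy
#'   whose mass is guaranteed > 10 ppm from every tag.
#' @param seed Integer seed; identical configs and seeds give bit-identical
#'   output.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_genes = 2000,
                              n_proteins = 250,
                              regulons = NULL,
                              regulon_size = 50,
                              regulon_fold = 4,
                              marker_locus = NULL,
                              marker_mrna_fold = 16,
                              marker_protein_fold = 27,
                              baseline_log10_mean = 2,
                              baseline_log10_sd = 0.5,
                              noise_sd = 0.1,
                              proteome_suppression = 0.59,
                              protein_fold_sd = 0.15,
                              peptides_per_protein = 7,
                              detected_fraction = 0.9,
                              ppm_jitter_sd = 1,
                              net_jitter_sd = 2e-4,
                              decoy_fraction = 0.05,
                              seed = 1) {
  if (proteome_suppression < 0 || proteome_suppression >= 1) {
    abort("proteome_suppression must lie in [0, 1)")
  }
  if (detected_fraction < 0 || detected_fraction > 1) {
    abort("detected_fraction must lie in [0, 1]")
  }
  if (decoy_fraction < 0 || decoy_fraction > 1) {
    abort("decoy_fraction must lie in [0, 1]")
  }
  sds <- c(baseline_log10_sd, noise_sd, protein_fold_sd, ppm_jitter_sd, net_jitter_sd)
  if (any(sds < 0)) {
    abort("all standard deviations must be >= 0")
  }
  if (peptides_per_protein < 1) {
    abort("peptides_per_protein must be >= 1")
  }
  loci <- sprintf("PU_%04d", seq_len(n_genes))
  if (is.null(regulons)) {
    if (4 * regulon_size > n_genes) {
      abort("n_genes too small for four default regulons")
    }
    programs <- c("early_iron", "late_iron", "exponential", "stationary")
    regulons <- tibble(
      program = rep(programs, each = regulon_size),
      locus_id = loci[seq_len(4 * regulon_size)],
      fold = regulon_fold
    )
    if (is.null(marker_locus)) marker_locus <- regulons$locus_id[1]
    regulons$fold[regulons$locus_id == marker_locus &
      regulons$program == "early_iron"] <- marker_mrna_fold
  } else {
    regulons <- as_tibble(regulons)
    if (is.null(marker_locus)) marker_locus <- NA_character_
  }
  structure(
    list(
      n_genes = n_genes, n_proteins = n_proteins, loci = loci,
      regulons = regulons, marker_locus = marker_locus,
      marker_mrna_fold = marker_mrna_fold,
      marker_protein_fold = marker_protein_fold,
      baseline_log10_mean = baseline_log10_mean,
      baseline_log10_sd = baseline_log10_sd,
      noise_sd = noise_sd,
      proteome_suppression = proteome_suppression,
      protein_fold_sd = protein_fold_sd,
      peptides_per_protein = peptides_per_protein,
      detected_fraction = detected_fraction,
      ppm_jitter_sd = ppm_jitter_sd,
      net_jitter_sd = net_jitter_sd,
      decoy_fraction = decoy_fraction,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# (treatment, day) multiplier implied by a program label
program_conditions <- function(program) {
  switch(program,
    exponential = tibble(
      treatment = TREATMENT_LEVELS, day = c(17L, 17L)
    ),
    stationary = tibble(treatment = "iron_replete", day = 28L),
    early_iron = tibble(treatment = "iron_limited", day = 18L),
    late_iron = tibble(treatment = "iron_limited", day = 28L),
    abort(paste0("unknown expression program: ", program))
  )
}

#' Simulate the 18-chip microarray experiment
#'
#' Draws a lognormal baseline per gene, applies the planted program
#' multipliers per (treatment, day), and adds multiplicative lognormal
#' measurement noise per (gene, chip). With `noise_sd = 0` and no regulons
#' every replicate-mean limited/replete ratio is exactly 1; with planted
#' programs the downstream [transcript_ratio()] recovers the planted fold
#' exactly on noise-free data.
#'
#' @param config A [simulation_config()].
#' @return A list with `expression` (long tibble), `chips` (metadata
#'   tibble) and `truth` (list with `mrna` per-gene true limited/replete
#'   ratio per day, `multipliers`, and the `regulons` used).
#' @export
simulate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  unknown <- setdiff(config$regulons$locus_id, config$loci)
  if (length(unknown) > 0) {
    abort(paste0("regulon references unknown locus: ", toString(unknown)))
  }
  set.seed(config$seed)
  loci <- config$loci
  n <- length(loci)
  days <- c(17L, 18L, 28L)
  chips <- tidyr::expand_grid(
    treatment = TREATMENT_LEVELS, biological_replicate = 1:3, day = days
  ) %>%
    arrange(.data$treatment, .data$day, .data$biological_replicate) %>%
    mutate(chip_id = sprintf("chip_%02d", row_number()), .before = 1)

  # per-(gene, treatment, day) multipliers, default 1
  conds <- tidyr::expand_grid(treatment = TREATMENT_LEVELS, day = days) %>%
    mutate(cond = paste(.data$treatment, .data$day, sep = "_"))
  mult <- matrix(1, n, nrow(conds), dimnames = list(loci, conds$cond))
  for (i in seq_len(nrow(config$regulons))) {
    r <- config$regulons[i, ]
    on <- program_conditions(r$program) %>%
      mutate(cond = paste(.data$treatment, .data$day, sep = "_"))
    mult[r$locus_id, on$cond] <- mult[r$locus_id, on$cond] * r$fold
  }

  baseline <- 10^rnorm(n, config$baseline_log10_mean, config$baseline_log10_sd)
  chip_cond <- paste(chips$treatment, chips$day, sep = "_")
  signal <- baseline * mult[, chip_cond, drop = FALSE]
  noise <- matrix(10^rnorm(n * nrow(chips), 0, config$noise_sd), n, nrow(chips))
  values <- signal * noise
  colnames(values) <- chips$chip_id

  expression <- as_tibble(values) %>%
    mutate(locus_id = loci, .before = 1) %>%
    tidyr::pivot_longer(-"locus_id", names_to = "chip_id", values_to = "fluorescence")

  mrna_truth <- tidyr::expand_grid(locus_id = loci, day = days) %>%
    mutate(true_ratio = mult[cbind(
      .data$locus_id, paste("iron_limited", .data$day, sep = "_")
    )] / mult[cbind(
      .data$locus_id, paste("iron_replete", .data$day, sep = "_")
    )])

  list(
    expression = validate_expression(expression),
    chips = validate_chips(chips),
    truth = list(
      mrna = mrna_truth, multipliers = mult, regulons = config$regulons
    )
  )
}

# rejection-sample masses > min_ppm away from every tag mass
draw_decoy_masses <- function(n, tag_masses, min_ppm = 10,
                              range = c(800, 3000)) {
  sorted <- sort(tag_masses)
  out <- numeric(0)
  while (length(out) < n) {
    cand <- runif(n - length(out), range[1], range[2])
    idx <- findInterval(cand, sorted)
    lo <- ifelse(idx >= 1, sorted[pmax(idx, 1)], Inf)
    hi <- ifelse(idx < length(sorted), sorted[pmin(idx + 1, length(sorted))], Inf)
    d_lo <- ifelse(idx >= 1, abs(cand - lo), Inf)
    d_hi <- ifelse(idx < length(sorted), abs(hi - cand), Inf)
    ok <- pmin(d_lo, d_hi) / (cand * 1e-6) > min_ppm
    out <- c(out, cand[ok])
  }
  out
}

#' Simulate the AMT tag library and LC-MS features
#'
#' Generates tags for a prefix of the gene list, then features for
#' 4 samples (2 treatments x days 18/28) x 3 technical replicates.
#' Iron-limited abundances are globally scaled by
#' `1 - proteome_suppression` (times an independent lognormal
#' per-(protein, day) deviation of sd `protein_fold_sd`), except the marker
#' protein, which is induced `marker_protein_fold`. Because the protein
#' folds are drawn independently of the mRNA programs, the two platforms
#' are decoupled by construction — only the marker is coupled. Measurement
#' jitter is applied to mass (ppm) and NET; a `decoy_fraction` of features
#' is replaced by decoys guaranteed to fall outside every tag's matching
#' window.
#'
#' @param config A [simulation_config()].
#' @param truth The `truth` element of [simulate_transcriptome()] (used to
#'   carry the mRNA ground truth alongside the protein truth).
#' @return A list with `tags`, `features` (the extra columns
#'   `true_peptide_id` and `is_decoy` carry ground truth and are ignored by
#'   the pipeline), `samples`, and an extended `truth` with elements
#'   `protein` (locus_id, day, true_fold) and `peptides`.
#' @export
simulate_proteome <- function(config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$peptides_per_protein < 1) {
    abort("peptides_per_protein must be >= 1")
  }
  set.seed(config$seed + 1L)
  prot_loci <- config$loci[seq_len(min(config$n_proteins, config$n_genes))]
  n_prot <- length(prot_loci)
  if (!is.na(config$marker_locus) && !config$marker_locus %in% prot_loci) {
    abort("marker_locus has no AMT tags in this configuration")
  }

  k <- 3L + rpois(n_prot, max(config$peptides_per_protein - 3, 0))
  tags <- tibble(
    locus_id = rep(prot_loci, k)
  ) %>%
    group_by(.data$locus_id) %>%
    mutate(peptide_id = sprintf("%s_pep%02d", .data$locus_id, row_number())) %>%
    ungroup() %>%
    mutate(
      mono_mass = runif(n(), 800, 3000),
      net = runif(n(), 0.05, 0.95),
      f_score = rnorm(n(), 5, 2)
    ) %>%
    select("peptide_id", "locus_id", "mono_mass", "net", "f_score")

  samples <- tidyr::expand_grid(treatment = TREATMENT_LEVELS, day = c(18L, 28L)) %>%
    mutate(sample_id = paste0(
      ifelse(.data$treatment == "iron_limited", "limited", "replete"),
      "_d", .data$day
    ))

  base_abund <- setNames(
    10^rnorm(n_prot, config$baseline_log10_mean + 4, config$baseline_log10_sd),
    prot_loci
  )
  protein_truth <- tidyr::expand_grid(locus_id = prot_loci, day = c(18L, 28L)) %>%
    mutate(
      true_fold = (1 - config$proteome_suppression) *
        10^rnorm(n(), 0, config$protein_fold_sd)
    )
  if (!is.na(config$marker_locus)) {
    protein_truth$true_fold[protein_truth$locus_id == config$marker_locus] <-
      config$marker_protein_fold
  }

  ion <- setNames(10^rnorm(nrow(tags), 0, 0.3), tags$peptide_id)

  grid <- tidyr::expand_grid(
    peptide_id = tags$peptide_id,
    sample_id = samples$sample_id,
    technical_replicate = 1:3
  ) %>%
    left_join(select(tags, "peptide_id", "locus_id", "mono_mass", "net"),
      by = "peptide_id"
    ) %>%
    left_join(select(samples, "sample_id", "treatment", "day"), by = "sample_id") %>%
    left_join(protein_truth, by = c("locus_id", "day"))

  detected <- rbinom(nrow(grid), 1, config$detected_fraction) == 1
  feats <- grid[detected, ]
  fold <- ifelse(feats$treatment == "iron_limited", feats$true_fold, 1)
  abund <- base_abund[feats$locus_id] * fold * ion[feats$peptide_id] *
    10^rnorm(nrow(feats), 0, config$noise_sd)
  mass <- feats$mono_mass *
    (1 + rnorm(nrow(feats), 0, config$ppm_jitter_sd) * 1e-6)
  net <- pmin(pmax(feats$net + rnorm(nrow(feats), 0, config$net_jitter_sd), 0), 1)

  is_decoy <- rbinom(nrow(feats), 1, config$decoy_fraction) == 1
  if (any(is_decoy)) {
    mass[is_decoy] <- draw_decoy_masses(sum(is_decoy), tags$mono_mass)
  }

  features <- tibble(
    mass = mass, net = net, abundance = abund,
    sample_id = feats$sample_id,
    technical_replicate = feats$technical_replicate,
    true_peptide_id = ifelse(is_decoy, NA_character_, feats$peptide_id),
    is_decoy = is_decoy
  )

  truth <- c(truth, list(
    protein = protein_truth,
    peptides = select(tags, "peptide_id", "locus_id"),
    marker_locus = config$marker_locus
  ))
  list(
    tags = validate_tags(tags),
    features = validate_features(features),
    samples = samples,
    truth = truth
  )
}

#' Simulate the full study (transcriptome + proteome)
#'
#' @param config A [simulation_config()].
#' @return A list merging the outputs of [simulate_transcriptome()] and
#'   [simulate_proteome()].
#' @export
simulate_study <- function(config = simulation_config()) {
  tx <- simulate_transcriptome(config)
  px <- simulate_proteome(config, tx$truth)
  list(
    expression = tx$expression, chips = tx$chips,
    tags = px$tags, features = px$features, samples = px$samples,
    truth = px$truth
  )
}
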