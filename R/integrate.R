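#' Pair transcript and protein log ratios per locus
#'
#' Inner join of a differential-transcript table and a protein
#' quantitation table on `locus_id`, keeping loci with a significant
#' change in either measurement (`min(mrna_p, protein_p) <= alpha`).
#' Only loci quantified on both platforms enter the set.
#'
#' @param transcripts Tibble with `locus_id`, `ratio`, `p_value` (one
#'   comparison, e.g. [differential_transcripts()] subset to one day).
#' @param proteins A `protein_quant` tibble for the matching comparison.
#' @param alpha Significance threshold (default 0.05).
#' @param comparison Optional label recorded in the `comparison` column.
#' @return A tibble `locus_id`, `mrna_log10_ratio`, `protein_log10_ratio`,
#'   `mrna_p`, `protein_p`, `comparison` of class `omics_pairs`.
#' @export
build_pairs <- function(transcripts, proteins, alpha = 0.05,
                        comparison = NA_character_) {
  tx <- as_tibble(transcripts) %>%
    mutate(mrna_log10_ratio = log10(.data$ratio)) %>%
    select("locus_id", "mrna_log10_ratio", mrna_p = "p_value")
  px <- as_tibble(proteins) %>%
    select("locus_id",
      protein_log10_ratio = "log10_ratio", protein_p = "combined_p"
    )
  out <- inner_join(tx, px, by = "locus_id") %>%
    filter(pmin(.data$mrna_p, .data$protein_p) <= .env$alpha) %>%
    mutate(comparison = comparison)
  structure(out, class = c("omics_pairs", class(out)))
}

#' Coefficient of determination between the two platforms
#'
#' Squared Pearson correlation of protein versus mRNA log10 ratios.
#' Invariant under affine rescaling of either axis.
#'
#' @param pairs An `omics_pairs` tibble (>= 3 rows).
#' @return A single number in `[0, 1]`.
#' @export
r_squared <- function(pairs) {
  if (nrow(pairs) < 3) abort("r_squared needs at least 3 pairs")
  cor(pairs$mrna_log10_ratio, pairs$protein_log10_ratio)^2
}

#' Summarize global proteome suppression
#'
#' Counts detected proteins, those significantly less abundant
#' (`combined_p <= alpha` and fold < 1), and the mean percent change of
#' the proteome, `100 * (mean(fold) - 1)`. The fold average is
#' arithmetic on the linear scale by default; a geometric alternative is
#' available since the headline "average decrease" convention is not
#' uniquely determined.
#'
#' @param proteins A `protein_quant` tibble.
#' @param alpha Significance threshold (default 0.05).
#' @param mean_type `"arithmetic"` (default) or `"geometric"` fold
#'   average.
#' @return A one-row tibble `n_detected`, `n_significantly_down`,
#'   `mean_percent_change`.
#' @export
proteome_summary <- function(proteins, alpha = 0.05,
                             mean_type = c("arithmetic", "geometric")) {
  mean_type <- match.arg(mean_type)
  proteins <- as_tibble(proteins)
  fold <- if ("fold" %in% names(proteins)) {
    proteins$fold
  } else {
    10^proteins$log10_ratio
  }
  mean_fold <- switch(mean_type,
    arithmetic = mean(fold),
    geometric = 10^mean(log10(fold))
  )
  tibble(
    n_detected = nrow(proteins),
    n_significantly_down = sum(proteins$combined_p <= alpha & fold < 1),
    mean_percent_change = 100 * (mean_fold - 1)
  )
}

#' Report the iron-limitation marker gene across timepoints
#'
#' Joins the marker locus's transcript and protein measurements per day
#' and flags the marker "coupled" on days where both folds meet
#' `min_fold`. The sfuC analogue — the periplasmic iron(III)-binding
#' transporter subunit — is the motivating case: it is expected to be
#' the only locus induced on both platforms.
#'
#' @param transcripts Tibble `locus_id`, `day`, `ratio`, `p_value`.
#' @param proteins Tibble with `locus_id`, `day`, a fold (or
#'   `log10_ratio`) and `combined_p` (e.g. per-day [quantify_proteins()]
#'   results bound together with a `day` column).
#' @param marker_locus Locus id of the marker gene.
#' @param min_fold Coupling fold threshold (default 1.5, inclusive).
#' @return A tibble with one row per day present on both platforms:
#'   `locus_id`, `day`, `mrna_fold`, `mrna_p`, `protein_fold`,
#'   `protein_p`, `coupled`.
#' @export
marker_report <- function(transcripts, proteins, marker_locus,
                          min_fold = 1.5) {
  tx <- filter(as_tibble(transcripts), .data$locus_id == marker_locus)
  if (nrow(tx) == 0) {
    abort(paste0("marker locus absent from transcripts: ", marker_locus))
  }
  px <- as_tibble(proteins)
  if (!"fold" %in% names(px)) px <- mutate(px, fold = 10^.data$log10_ratio)
  px <- filter(px, .data$locus_id == marker_locus)
  if (nrow(px) == 0) {
    abort(paste0("marker locus absent from proteins: ", marker_locus))
  }
  inner_join(
    select(tx, "locus_id", "day", mrna_fold = "ratio", mrna_p = "p_value"),
    select(px, "locus_id", "day", protein_fold = "fold", protein_p = "combined_p"),
    by = c("locus_id", "day")
  ) %>%
    mutate(coupled = .data$mrna_fold >= min_fold & .data$protein_fold >= min_fold)
}

#' Loci induced on both platforms
#'
#' Returns the loci whose transcript and protein folds both meet
#' `min_fold` with both p-values at or below `alpha` on at least one
#' shared day — the coupling criterion under which the marker gene is
#' expected to be unique.
#'
#' @inheritParams marker_report
#' @param alpha Significance threshold (default 0.05).
#' @return Character vector of coupled locus ids.
#' @export
coupled_loci <- function(transcripts, proteins, min_fold = 1.5, alpha = 0.05) {
  px <- as_tibble(proteins)
  if (!"fold" %in% names(px)) px <- mutate(px, fold = 10^.data$log10_ratio)
  inner_join(
    select(as_tibble(transcripts), "locus_id", "day",
      mrna_fold = "ratio", mrna_p = "p_value"
    ),
    select(px, "locus_id", "day", protein_fold = "fold", protein_p = "combined_p"),
    by = c("locus_id", "day")
  ) %>%
    filter(
      .data$mrna_fold >= min_fold, .data$protein_fold >= min_fold,
      .data$mrna_p <= alpha, .data$protein_p <= alpha
    ) %>%
    pull("locus_id") %>%
    unique()
}
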