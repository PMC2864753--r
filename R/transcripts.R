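#' Normalize fluorescence across chips by global-median scaling
#'
#' Each chip is rescaled so its median gene fluorescence equals the global
#' median of per-chip medians. This removes chip-level intensity offsets
#' while preserving the within-chip ordering, and is idempotent. The
#' original study normalized over all 18 chips without naming a method;
#' median scaling is the robust default here and the step is an explicit,
#' separate verb so an alternative can be substituted.
#'
#' @param expr Long expression tibble (`locus_id`, `chip_id`,
#'   `fluorescence`).
#' @return The expression tibble with rescaled fluorescence.
#' @export
normalize_chips <- function(expr) {
  expr <- validate_expression(expr)
  if (n_distinct(expr$chip_id) < 2) {
    abort("normalization needs at least 2 chips")
  }
  meds <- expr %>%
    group_by(.data$chip_id) %>%
    summarise(med = median(.data$fluorescence), .groups = "drop")
  if (any(meds$med == 0)) {
    bad <- meds$chip_id[meds$med == 0]
    abort(paste0("chip(s) with zero median fluorescence: ", toString(bad)))
  }
  target <- median(meds$med)
  expr %>%
    left_join(meds, by = "chip_id") %>%
    mutate(fluorescence = .data$fluorescence * .env$target / .data$med) %>%
    select(-"med")
}

# per-(gene, day) group means/vars for one treatment arm
arm_stats <- function(expr, chips, arm) {
  arm_chips <- filter(chips, .data$treatment == arm)
  expr %>%
    semi_join(arm_chips, by = "chip_id") %>%
    left_join(select(arm_chips, "chip_id", "day"), by = "chip_id") %>%
    group_by(.data$locus_id, .data$day) %>%
    summarise(
      m = mean(.data$fluorescence), v = var(.data$fluorescence),
      n = n(), .groups = "drop"
    )
}

#' Replicate-averaged differential transcript table
#'
#' For every gene and sampling day, computes the ratio of the mean
#' iron-limited fluorescence over the mean iron-replete fluorescence
#' (three biological replicates per arm) and a two-tailed Student
#' (pooled-variance) t-test comparing the two arms. No multiple-testing
#' correction is applied; raw p-values are reported, matching the original
#' table convention.
#'
#' @param expr Long expression tibble (normalize first with
#'   [normalize_chips()] if chips carry intensity offsets).
#' @param chips Chip metadata.
#' @param days Days to test; default all days present in both arms.
#' @return A tibble `locus_id`, `day`, `ratio`, `p_value`.
#' @export
differential_transcripts <- function(expr, chips, days = NULL) {
  expr <- validate_expression(expr)
  chips <- validate_chips(chips)
  lim <- arm_stats(expr, chips, "iron_limited")
  rep_ <- arm_stats(expr, chips, "iron_replete")
  out <- inner_join(lim, rep_,
    by = c("locus_id", "day"), suffix = c("_lim", "_rep")
  )
  if (!is.null(days)) out <- filter(out, .data$day %in% .env$days)
  if (nrow(out) == 0) {
    abort("no (gene, day) group has chips in both treatment arms")
  }
  if (any(out$m_rep == 0)) {
    abort("iron-replete replicate mean of zero: ratio undefined")
  }
  out %>%
    mutate(
      ratio = .data$m_lim / .data$m_rep,
      p_value = pooled_t_pvalue(
        .data$m_lim, .data$m_rep, .data$v_lim, .data$v_rep,
        .data$n_lim, .data$n_rep
      )
    ) %>%
    select("locus_id", "day", "ratio", "p_value") %>%
    arrange(.data$day, .data$locus_id)
}

#' Single-gene fold ratio between treatment arms
#'
#' Arithmetic mean of the iron-limited replicate fluorescences divided by
#' the arithmetic mean of the iron-replete replicates for one gene and day.
#'
#' @inheritParams differential_transcripts
#' @param day Sampling day.
#' @param gene Locus id.
#' @return A single ratio.
#' @export
transcript_ratio <- function(expr, chips, day, gene) {
  row <- one_gene_day(expr, chips, day, gene)
  if (row$m_rep == 0) abort("iron-replete replicate mean of zero: ratio undefined")
  row$m_lim / row$m_rep
}

#' Single-gene two-tailed Student t-test between treatment arms
#'
#' Pooled-variance two-sample t-test on the biological replicates. Zero
#' variance in both arms gives p = 1 when the means are equal and p = 0
#' when they differ (the t statistic is infinite), by convention.
#'
#' @inheritParams transcript_ratio
#' @return A two-tailed p-value.
#' @export
transcript_ttest <- function(expr, chips, day, gene) {
  row <- one_gene_day(expr, chips, day, gene)
  pooled_t_pvalue(row$m_lim, row$m_rep, row$v_lim, row$v_rep, row$n_lim, row$n_rep)
}

one_gene_day <- function(expr, chips, day, gene) {
  expr <- validate_expression(expr)
  chips <- validate_chips(chips)
  expr <- filter(expr, .data$locus_id == .env$gene)
  if (nrow(expr) == 0) abort(paste0("unknown locus: ", gene))
  lim <- arm_stats(expr, chips, "iron_limited") %>% filter(.data$day == .env$day)
  rep_ <- arm_stats(expr, chips, "iron_replete") %>% filter(.data$day == .env$day)
  if (nrow(lim) == 0 || nrow(rep_) == 0) {
    abort(paste0("no chips for both arms on day ", day))
  }
  inner_join(lim, rep_, by = c("locus_id", "day"), suffix = c("_lim", "_rep"))
}

#' Filter up-regulated transcripts
#'
#' Keeps rows whose `ratio` meets the fold threshold. The boundary is
#' inclusive: "at least 50 percent more abundant" means `ratio >= 1.5`.
#'
#' @param table A tibble with `locus_id` and `ratio` columns, e.g. from
#'   [differential_transcripts()].
#' @param min_ratio Inclusive fold threshold (default 1.5).
#' @return The passing rows, sorted by `locus_id`.
#' @export
filter_upregulated <- function(table, min_ratio = 1.5) {
  if (min_ratio <= 0) abort("min_ratio must be positive")
  table <- as_tibble(table)
  if (nrow(table) == 0) abort("empty differential table")
  table %>%
    filter(.data$ratio >= .env$min_ratio) %>%
    arrange(.data$locus_id)
}
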