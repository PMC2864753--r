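#' Match LC-MS features to AMT tags
#'
#' A feature matches tag `t` iff `|mass - t$mono_mass| <=
#' ppm_tol * 1e-6 * t$mono_mass` and `|net - t$net| <= net_tol` (both
#' boundaries inclusive). Among multiple candidate tags the smallest
#' combined normalized distance wins (Euclidean distance after dividing
#' the mass offset by the tag's ppm window and the NET offset by
#' `net_tol`); remaining ties go to the closest mass, then the
#' lexicographically smallest `peptide_id`. If several features claim the
#' same (peptide, sample, replicate) slot, the closest is kept so each
#' slot holds at most one record. Unmatched features are dropped and
#' counted in the `n_unmatched` attribute.
#'
#' @param features Feature tibble (see [read_features()]).
#' @param tags AMT tag tibble (see [read_tag_library()]).
#' @param ppm_tol Mass tolerance in ppm (default 6).
#' @param net_tol Elution-time tolerance in absolute NET units
#'   (default 0.001).
#' @return A tibble `peptide_id`, `locus_id`, `sample_id`,
#'   `technical_replicate`, `abundance` of matched observations.
#' @export
match_features <- function(features, tags, ppm_tol = 6, net_tol = 0.001) {
  features <- validate_features(features)
  tags <- validate_tags(tags)
  if (nrow(tags) == 0) abort("tag library is empty")
  empty <- tibble(
    peptide_id = character(), locus_id = character(),
    sample_id = character(), technical_replicate = integer(),
    abundance = numeric()
  )
  if (nrow(features) == 0) {
    return(structure(empty, n_unmatched = 0L))
  }

  ord <- order(tags$mono_mass)
  tg <- tags[ord, ]
  # generous candidate window, exact predicate applied below
  w <- features$mass * ppm_tol * 2e-6
  lo <- findInterval(features$mass - w, tg$mono_mass)
  hi <- findInterval(features$mass + w, tg$mono_mass)
  counts <- pmax(hi - lo, 0L)
  if (sum(counts) == 0) {
    return(structure(empty, n_unmatched = nrow(features)))
  }
  fi <- rep(seq_len(nrow(features)), counts)
  ti <- sequence(counts, from = lo + 1L)

  dm <- features$mass[fi] - tg$mono_mass[ti]
  dn <- features$net[fi] - tg$net[ti]
  win <- ppm_tol * 1e-6 * tg$mono_mass[ti]
  ok <- abs(dm) <= win & abs(dn) <= net_tol
  fi <- fi[ok]
  ti <- ti[ok]
  if (length(fi) == 0) {
    return(structure(empty, n_unmatched = nrow(features)))
  }
  cand <- tibble(
    feature = fi,
    peptide_id = tg$peptide_id[ti],
    locus_id = tg$locus_id[ti],
    dist = sqrt((dm[ok] / win[ok])^2 + (dn[ok] / net_tol)^2),
    abs_dm = abs(dm[ok])
  )
  best <- cand %>%
    arrange(.data$feature, .data$dist, .data$abs_dm, .data$peptide_id) %>%
    distinct(.data$feature, .keep_all = TRUE)
  matched <- best %>%
    mutate(
      sample_id = features$sample_id[.data$feature],
      technical_replicate = features$technical_replicate[.data$feature],
      abundance = features$abundance[.data$feature]
    ) %>%
    # one record per (peptide, sample, replicate): keep the closest feature
    arrange(
      .data$peptide_id, .data$sample_id, .data$technical_replicate,
      .data$dist, .data$abs_dm
    ) %>%
    distinct(.data$peptide_id, .data$sample_id, .data$technical_replicate,
      .keep_all = TRUE
    ) %>%
    select(
      "peptide_id", "locus_id", "sample_id", "technical_replicate", "abundance"
    )
  structure(matched,
    n_unmatched = nrow(features) - n_distinct(best$feature)
  )
}

#' Recalibrate feature elution times against the tag library
#'
#' Optional global linear NET recalibration: features are matched once,
#' a least-squares line of tag NET on feature NET is fitted over the
#' matched pairs, feature NETs are mapped through it, and the corrected
#' features are returned for a single rematch. Off by default in
#' [quantify_proteins()]; inputs are normally assumed already aligned.
#'
#' @inheritParams match_features
#' @return `features` with recalibrated `net`.
#' @export
recalibrate_net <- function(features, tags, ppm_tol = 6, net_tol = 0.001) {
  features <- validate_features(features)
  matched <- match_features(features, tags, ppm_tol, net_tol * 10)
  if (nrow(matched) < 2) {
    warn("too few matches for NET recalibration; features unchanged")
    return(features)
  }
  # recover the matched (feature net, tag net) pairs
  key <- features %>%
    mutate(.row = row_number())
  pairs <- matched %>%
    inner_join(select(tags, "peptide_id", tag_net = "net"), by = "peptide_id") %>%
    inner_join(
      select(key, ".row", "sample_id", "technical_replicate", "abundance",
        feat_net = "net"
      ),
      by = c("sample_id", "technical_replicate", "abundance")
    )
  fit <- lm(tag_net ~ feat_net, data = pairs)
  features$net <- pmin(pmax(
    predict(fit, tibble(feat_net = features$net)), 0
  ), 1)
  features
}

#' Keep peptides observed in at least 2 of 3 technical replicates
#'
#' Removes every (peptide, sample) group with fewer than two replicate
#' observations. Absence is encoded by row absence, so the filter simply
#' counts rows per group.
#'
#' @param matched Matched-observation tibble from [match_features()].
#' @param min_replicates Minimum replicate observations (default 2).
#' @return The filtered tibble.
#' @export
replicate_presence_filter <- function(matched, min_replicates = 2) {
  matched %>%
    group_by(.data$peptide_id, .data$sample_id) %>%
    filter(n_distinct(.data$technical_replicate) >= min_replicates) %>%
    ungroup()
}

#' Minus-versus-average regression normalization of technical replicates
#'
#' Within each sample, every non-reference technical replicate is
#' normalized against the reference replicate (default: replicate 1).
#' Over the peptides shared with the reference, each pair of log10
#' abundances is transformed to MA space — `m = log10(A_i) -
#' log10(A_ref)`, `a = (log10(A_i) + log10(A_ref)) / 2` — a least-squares
#' line `m*(a)` is fitted, and the corrected log abundance is
#' `x' = log10(A_i) - m*(a)`. The reference replicate's `x'` is its
#' log10 abundance unchanged. Peptides without a reference partner are
#' corrected with the fitted line evaluated at their own log10 abundance
#' (the best available intensity estimate when no pair exists).
#'
#' @param matched Matched observations (after
#'   [replicate_presence_filter()]).
#' @param reference_replicate Technical replicate used as reference
#'   (default 1).
#' @return `matched` with an `x_prime` column (class `ma_normalized`);
#'   the per-replicate regression fits are attached as attribute `fits`
#'   and available via [tidy()].
#' @export
ma_normalize <- function(matched, reference_replicate = 1) {
  matched <- mutate(as_tibble(matched), log_a = log10(.data$abundance))
  ref <- matched %>%
    filter(.data$technical_replicate == reference_replicate) %>%
    select("peptide_id", "sample_id", log_ref = "log_a")
  if (nrow(ref) == 0) {
    abort("reference replicate has no observations")
  }
  fits <- list()
  out <- matched %>%
    mutate(.row = row_number(), x_prime = NA_real_)
  out$x_prime[out$technical_replicate == reference_replicate] <-
    out$log_a[out$technical_replicate == reference_replicate]

  groups <- out %>%
    filter(.data$technical_replicate != reference_replicate) %>%
    distinct(.data$sample_id, .data$technical_replicate)
  for (g in seq_len(nrow(groups))) {
    sid <- groups$sample_id[g]
    rep_i <- groups$technical_replicate[g]
    rows <- out$sample_id == sid & out$technical_replicate == rep_i
    sub <- out[rows, ] %>%
      left_join(filter(ref, .data$sample_id == sid) %>% select(-"sample_id"),
        by = "peptide_id"
      )
    shared <- !is.na(sub$log_ref)
    a_shared <- (sub$log_a[shared] + sub$log_ref[shared]) / 2
    if (sum(shared) < 2 || n_distinct(a_shared) < 2) {
      abort(paste0(
        "fewer than 2 shared peptides (distinct intensities) between ",
        "replicate ", rep_i, " and the reference in sample ", sid
      ))
    }
    m <- sub$log_a[shared] - sub$log_ref[shared]
    fit <- lm(m ~ a_shared)
    co <- coef(fit)
    a_all <- ifelse(shared, (sub$log_a + sub$log_ref) / 2, sub$log_a)
    m_star <- co[[1]] + co[[2]] * a_all
    out$x_prime[sub$.row] <- sub$log_a - m_star
    fits[[g]] <- tibble(
      sample_id = sid, technical_replicate = rep_i,
      intercept = co[[1]], slope = co[[2]], n_shared = sum(shared)
    )
  }
  out <- select(out, -"log_a", -".row")
  structure(out,
    fits = bind_rows(fits),
    class = c("ma_normalized", class(out))
  )
}

#' @rdname ma_normalize
#' @param x An `ma_normalized` tibble.
#' @param ... Unused.
#' @return For `tidy()`: the per-replicate regression fits
#'   (`sample_id`, `technical_replicate`, `intercept`, `slope`,
#'   `n_shared`).
#' @method tidy ma_normalized
#' @export
tidy.ma_normalized <- function(x, ...) {
  attr(x, "fits")
}

#' Drop peptides whose replicate variability exceeds their mean
#'
#' For each (peptide, sample) group the sample standard deviation and
#' mean of the normalized linear-scale abundances (`10^x_prime`) are
#' compared; groups with SD > mean are removed. Groups with a single
#' observation have undefined SD and are kept.
#'
#' @param matched Normalized matched observations (with `x_prime`).
#' @return The filtered tibble.
#' @export
variability_filter <- function(matched) {
  if (!"x_prime" %in% names(matched)) {
    abort("variability_filter requires normalized abundances (run ma_normalize)")
  }
  matched %>%
    group_by(.data$peptide_id, .data$sample_id) %>%
    filter({
      lin <- 10^.data$x_prime
      s <- sd(lin)
      is.na(s) || s <= mean(lin)
    }) %>%
    ungroup()
}

#' Drop each protein's lowest-confidence third of peptides
#'
#' Peptides of a protein are ranked by their maximum PeptideProphet
#' F-score (from the tag library); the lowest `floor(k/3)` of the `k`
#' distinct peptides are removed entirely. Ties at the cut are broken by
#' dropping the lexicographically larger `peptide_id`. Proteins with two
#' or fewer peptides are unchanged.
#'
#' @param matched Matched observations.
#' @param tags Tag library providing `peptide_id` and `f_score`.
#' @return The filtered tibble.
#' @export
fscore_filter <- function(matched, tags) {
  scores <- tags %>%
    group_by(.data$peptide_id) %>%
    summarise(f_score = max(.data$f_score), .groups = "drop")
  missing <- setdiff(unique(matched$peptide_id), scores$peptide_id)
  if (length(missing) > 0) {
    abort(paste0("peptide(s) without an F-score in the tag library: ",
      toString(head(missing, 5))
    ))
  }
  keep <- matched %>%
    distinct(.data$locus_id, .data$peptide_id) %>%
    left_join(scores, by = "peptide_id") %>%
    group_by(.data$locus_id) %>%
    arrange(dplyr::desc(.data$f_score), .data$peptide_id, .by_group = TRUE) %>%
    slice(seq_len(max(n() - floor(n() / 3), 0))) %>%
    ungroup()
  semi_join(matched, keep, by = c("locus_id", "peptide_id"))
}

#' Peptide log ratios and directional one-tailed p-values
#'
#' For each peptide passing all filters in both samples, replicate
#' abundances (linear scale, `10^x_prime`) are averaged per sample and
#' the sample-1 over sample-2 ratio is log10 transformed. Significance
#' is a one-tailed two-sample Student t-test on the replicates' `x'`
#' values, taken in the direction of the protein-level mean ratio
#' (computed from a provisional equal-weight average of the protein's
#' peptide log ratios); peptides whose own ratio opposes the protein
#' direction are assigned p = 1. Peptides present in only one sample are
#' excluded.
#'
#' @param matched Normalized, filtered matched observations.
#' @param sample_1,sample_2 Sample ids to compare (ratio is
#'   sample_1 / sample_2).
#' @return A tibble `peptide_id`, `locus_id`, `log10_ratio`,
#'   `p_one_tailed`.
#' @export
peptide_ratios <- function(matched, sample_1, sample_2) {
  if (!"x_prime" %in% names(matched)) {
    abort("peptide_ratios requires normalized abundances (run ma_normalize)")
  }
  stats_tbl <- matched %>%
    filter(.data$sample_id %in% c(sample_1, sample_2)) %>%
    group_by(.data$peptide_id, .data$locus_id, .data$sample_id) %>%
    summarise(
      mean_lin = mean(10^.data$x_prime),
      mean_log = mean(.data$x_prime),
      var_log = var(.data$x_prime),
      n = n(),
      .groups = "drop"
    )
  s1 <- filter(stats_tbl, .data$sample_id == sample_1)
  s2 <- filter(stats_tbl, .data$sample_id == sample_2)
  both <- inner_join(s1, s2, by = c("peptide_id", "locus_id"), suffix = c("1", "2"))
  if (nrow(both) == 0) {
    abort("no peptide passed the filters in both samples")
  }
  both <- mutate(both, log10_ratio = log10(.data$mean_lin1 / .data$mean_lin2))

  direction <- both %>%
    group_by(.data$locus_id) %>%
    summarise(protein_dir = sign(mean(.data$log10_ratio)), .groups = "drop")

  both %>%
    left_join(direction, by = "locus_id") %>%
    mutate(
      protein_dir = ifelse(.data$protein_dir == 0, 1, .data$protein_dir),
      p_up = pooled_t_pvalue(
        .data$mean_log1, .data$mean_log2, .data$var_log1, .data$var_log2,
        .data$n1, .data$n2,
        tail = "greater"
      ),
      p_down = pooled_t_pvalue(
        .data$mean_log1, .data$mean_log2, .data$var_log1, .data$var_log2,
        .data$n1, .data$n2,
        tail = "less"
      ),
      opposes = sign(.data$log10_ratio) != 0 &
        sign(.data$log10_ratio) != .data$protein_dir,
      p_one_tailed = dplyr::case_when(
        opposes ~ 1,
        protein_dir > 0 ~ p_up,
        TRUE ~ p_down
      )
    ) %>%
    select("peptide_id", "locus_id", "log10_ratio", "p_one_tailed")
}

#' Combine independent p-values with Fisher's method
#'
#' `chi^2 = -2 * sum(ln p)` on `2k` degrees of freedom; the combined
#' p-value is the upper-tail chi-square probability. Underflowing
#' p-values are floored at `p_floor` before the logarithm. For a single
#' p-value the method is the identity.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param p_floor Positive floor applied before `log` (default 1e-300).
#' @return A one-row tibble `chi_square`, `df`, `combined_p`.
#' @export
fisher_combine <- function(p, p_floor = 1e-300) {
  if (length(p) == 0) abort("no p-values to combine")
  if (any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  chi <- -2 * sum(log(pmax(p, p_floor)))
  df <- 2L * length(p)
  tibble(
    chi_square = chi, df = df,
    combined_p = pchisq(chi, df, lower.tail = FALSE)
  )
}

#' Roll peptide ratios up to protein quantities
#'
#' Proteins with at least `min_peptides` passing peptides get a
#' log10 ratio equal to the arithmetic mean of their member peptide
#' log10 ratios, and a combined significance from Fisher's method over
#' the member one-tailed p-values.
#'
#' @param peptide_ratios Output of [peptide_ratios()].
#' @param min_peptides Minimum member peptides (default 3).
#' @param p_floor Floor for member p-values before `log`.
#' @return A tibble `locus_id`, `n_peptides`, `log10_ratio`, `fold`,
#'   `chi_square`, `df`, `combined_p` of class `protein_quant`.
#' @export
protein_rollup <- function(peptide_ratios, min_peptides = 3, p_floor = 1e-300) {
  out <- peptide_ratios %>%
    group_by(.data$locus_id) %>%
    filter(n() >= min_peptides) %>%
    summarise(
      n_peptides = n(),
      log10_ratio = mean(.data$log10_ratio),
      chi_square = -2 * sum(log(pmax(.data$p_one_tailed, p_floor))),
      .groups = "drop"
    ) %>%
    mutate(
      fold = 10^.data$log10_ratio,
      df = 2L * .data$n_peptides,
      combined_p = pchisq(.data$chi_square, .data$df, lower.tail = FALSE)
    ) %>%
    select(
      "locus_id", "n_peptides", "log10_ratio", "fold",
      "chi_square", "df", "combined_p"
    )
  structure(out, class = c("protein_quant", class(out)))
}

#' Filter proteins induced under iron limitation
#'
#' Keeps proteins whose linear fold (`fold`, or `10^log10_ratio` when no
#' `fold` column is present) meets the inclusive threshold.
#'
#' @param proteins A protein quantitation tibble.
#' @param min_fold Inclusive fold threshold (default 1.5).
#' @return The passing rows.
#' @export
filter_up_proteins <- function(proteins, min_fold = 1.5) {
  if (min_fold <= 0) abort("min_fold must be positive")
  proteins <- as_tibble(proteins)
  fold <- if ("fold" %in% names(proteins)) {
    proteins$fold
  } else if ("log10_ratio" %in% names(proteins)) {
    10^proteins$log10_ratio
  } else {
    abort("proteins table needs a fold or log10_ratio column")
  }
  proteins[fold >= min_fold, ]
}

#' AMT-tag quantitation pipeline for one sample comparison
#'
#' Runs the fixed stage order — match, replicate-presence filter, MA
#' normalization, variability filter, F-score filter, peptide ratios,
#' protein rollup — comparing `sample_1` against `sample_2`. Every filter
#' only removes records; only the normalization alters abundances.
#'
#' @inheritParams match_features
#' @param sample_1,sample_2 Sample ids to compare (fold is
#'   sample_1 / sample_2).
#' @param reference_replicate Reference technical replicate for
#'   [ma_normalize()].
#' @param min_peptides Minimum peptides per protein (default 3).
#' @param recalibrate Apply the optional global linear NET recalibration
#'   before matching (default `FALSE`; inputs are assumed aligned).
#' @return A `protein_quant` tibble (see [protein_rollup()]).
#' @export
quantify_proteins <- function(features, tags, sample_1, sample_2,
                              ppm_tol = 6, net_tol = 0.001,
                              reference_replicate = 1, min_peptides = 3,
                              recalibrate = FALSE) {
  if (recalibrate) {
    features <- recalibrate_net(features, tags, ppm_tol, net_tol)
  }
  matched <- match_features(features, tags, ppm_tol, net_tol)
  if (nrow(matched) == 0) abort("no feature matched the tag library")
  matched %>%
    replicate_presence_filter() %>%
    ma_normalize(reference_replicate = reference_replicate) %>%
    variability_filter() %>%
    fscore_filter(tags) %>%
    peptide_ratios(sample_1, sample_2) %>%
    protein_rollup(min_peptides = min_peptides)
}
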