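#' Log-scale sample signals for the radial layout
#'
#' Collapses chips to samples (by default one sample per treatment x day,
#' six samples for the study design) and computes
#' `S[i, g] = log10(mean fluorescence of gene g over sample i's chips)`.
#' Fluorescence is floored at `eps` before averaging so zeros never reach
#' the logarithm; the default floor is the smallest positive value in the
#' matrix.
#'
#' @param expr Long expression tibble.
#' @param chips Chip metadata.
#' @param eps Positive floor applied to fluorescence before averaging.
#' @return A tibble `locus_id`, `sample_id`, `s` (log10 signal).
#' @export
compute_log_signals <- function(expr, chips, eps = NULL) {
  expr <- validate_expression(expr)
  chips <- validate_chips(chips)
  if (is.null(eps)) {
    pos <- expr$fluorescence[expr$fluorescence > 0]
    if (length(pos) == 0) abort("all fluorescence zero: supply eps")
    eps <- min(pos)
  }
  if (eps <= 0) abort("eps must be positive")
  chips <- mutate(chips, sample_id = sample_label(.data$treatment, .data$day))
  out <- expr %>%
    inner_join(select(chips, "chip_id", "sample_id"), by = "chip_id") %>%
    group_by(.data$locus_id, .data$sample_id) %>%
    summarise(
      s = log10(mean(pmax(.data$fluorescence, .env$eps))),
      .groups = "drop"
    )
  if (any(!is.finite(out$s))) abort("non-finite log signal computed")
  out
}

sample_label <- function(treatment, day) {
  paste0(ifelse(treatment == "iron_limited", "limited", "replete"), "_d", day)
}

#' Place dimensional anchors on the unit circle
#'
#' Anchors are placed at the supplied angles, or evenly spaced starting at
#' the top (90 degrees) and proceeding counter-clockwise.
#'
#' @param sample_ids Character vector of unique sample labels (>= 3).
#' @param angles Optional explicit angles in degrees (same length).
#' @return A tibble `sample_id`, `angle`, `x`, `y` with `x^2 + y^2 = 1`.
#' @export
place_anchors <- function(sample_ids, angles = NULL) {
  if (anyDuplicated(sample_ids)) abort("duplicate sample_id among anchors")
  n <- length(sample_ids)
  if (n < 3) abort("radial layout needs at least 3 anchors")
  if (is.null(angles)) {
    angles <- (90 + (seq_len(n) - 1) * 360 / n) %% 360
  } else if (length(angles) != n) {
    abort("angles must match sample_ids in length")
  }
  tibble(
    sample_id = as.character(sample_ids), angle = angles,
    x = cospi(angles / 180), y = sinpi(angles / 180)
  )
}

#' Study-design anchor arrangement
#'
#' The six treatment x day samples arranged as in the original figure
#' prose: iron-limited samples on the left, iron-replete on the right,
#' exponential growth (day 17) at the bottom, stationary phase (day 28) at
#' the top.
#'
#' @return An anchor tibble for the six study samples.
#' @export
study_anchors <- function() {
  place_anchors(
    c(
      "replete_d18", "replete_d28", "limited_d28",
      "limited_d18", "limited_d17", "replete_d17"
    ),
    angles = c(0, 60, 120, 180, 240, 300)
  )
}

#' Default cluster label per study anchor
#'
#' @return Named character vector mapping anchor sample ids to the four
#'   expression-program labels.
#' @export
study_sector_map <- function() {
  c(
    limited_d17 = "exponential", replete_d17 = "exponential",
    limited_d18 = "early_iron", replete_d18 = "stationary",
    limited_d28 = "late_iron", replete_d28 = "stationary"
  )
}

#' Position genes inside the anchor circle
#'
#' Each gene is attracted to the samples in which it is most abundant:
#' with per-gene weights `w[i] = S[i, g] - min_j S[j, g]`, normalized to
#' sum to one (uniform when all signals are equal), the gene's point is
#' the convex combination `sum_i w[i] * anchor[i]`. A gene equally
#' abundant everywhere sits at the anchor centroid; a gene elevated in
#' exactly one sample sits on that sample's anchor.
#'
#' @param signals Log-signal tibble from [compute_log_signals()].
#' @param anchors Anchor tibble from [place_anchors()].
#' @return A tibble `locus_id`, `x`, `y`.
#' @export
gene_position <- function(signals, anchors) {
  check_signal_anchors(signals, anchors)
  signals %>%
    inner_join(select(anchors, "sample_id",
      ax = "x", ay = "y"
    ), by = "sample_id") %>%
    group_by(.data$locus_id) %>%
    summarise(
      x = weighted_coord(.data$s, .data$ax),
      y = weighted_coord(.data$s, .data$ay),
      .groups = "drop"
    )
}

weighted_coord <- function(s, coord) {
  w <- s - min(s)
  tot <- sum(w)
  if (tot == 0) w <- rep(1 / length(s), length(s)) else w <- w / tot
  sum(w * coord)
}

check_signal_anchors <- function(signals, anchors) {
  if (any(!is.finite(signals$s))) abort("non-finite log signal")
  got <- sort(unique(signals$sample_id))
  want <- sort(anchors$sample_id)
  if (!identical(got, want)) {
    abort("signals and anchors must cover the same samples")
  }
}

#' Size genes by their largest expression change
#'
#' `s[g]` is the largest pairwise difference in log10 signal across
#' samples, i.e. max minus min. Constant genes get size 0; the size is
#' invariant to adding a constant to all of a gene's log signals (and
#' hence to global rescaling of raw fluorescence).
#'
#' @param signals Log-signal tibble.
#' @return A tibble `locus_id`, `size`.
#' @export
gene_size <- function(signals) {
  if (n_distinct(signals$sample_id) < 2) abort("gene_size needs >= 2 samples")
  signals %>%
    group_by(.data$locus_id) %>%
    summarise(size = max(.data$s) - min(.data$s), .groups = "drop")
}

#' Assign genes to condition clusters by nearest anchor
#'
#' Genes within `min_radius` (a fraction of the circumradius) of the
#' anchor centroid are uninformative and left `unassigned`; all other
#' genes take the cluster label of their nearest anchor (exact ties are
#' left `unassigned`).
#'
#' @param points Tibble with `locus_id`, `x`, `y`.
#' @param anchors Anchor tibble.
#' @param sector_map Named character vector mapping every anchor
#'   `sample_id` to a cluster label.
#' @param min_radius Unassigned-core radius as a fraction of the
#'   circumradius (default 0.1).
#' @return `points` with a `cluster` column added.
#' @export
assign_clusters <- function(points, anchors, sector_map = study_sector_map(),
                            min_radius = 0.1) {
  missing <- setdiff(anchors$sample_id, names(sector_map))
  if (length(missing) > 0) {
    abort(paste0("sector_map lacks anchor(s): ", toString(missing)))
  }
  cx <- mean(anchors$x)
  cy <- mean(anchors$y)
  circumradius <- max(sqrt((anchors$x - cx)^2 + (anchors$y - cy)^2))
  d2anchor <- function(x, y) {
    outer(x, anchors$x, "-")^2 + outer(y, anchors$y, "-")^2
  }
  d2 <- d2anchor(points$x, points$y)
  nearest <- apply(d2, 1, which.min)
  mins <- d2[cbind(seq_len(nrow(d2)), nearest)]
  tied <- rowSums(abs(d2 - mins) < 1e-24) > 1
  core <- sqrt((points$x - cx)^2 + (points$y - cy)^2) < min_radius * circumradius
  cluster <- unname(sector_map[anchors$sample_id[nearest]])
  cluster[tied | core] <- "unassigned"
  mutate(points, cluster = cluster)
}

#' Full radial-coordinate layout of an expression matrix
#'
#' Runs [compute_log_signals()], [gene_position()], [gene_size()] and
#' [assign_clusters()] in sequence. With the default anchors and sector
#' map this reproduces the study's six-sample arrangement; use
#' [autoplot()] on the result for the figure.
#'
#' @inheritParams compute_log_signals
#' @param anchors Anchor tibble; default [study_anchors()] when the
#'   grouped samples are exactly the six study samples, otherwise evenly
#'   spaced anchors in sample order.
#' @param sector_map Named cluster map; default [study_sector_map()] for
#'   the study samples, otherwise one cluster per anchor named after it.
#' @param min_radius Unassigned-core fraction (default 0.1).
#' @return A tibble `locus_id`, `x`, `y`, `size`, `cluster` of class
#'   `radial_layout`, with the anchors attached as attribute `anchors`.
#' @export
radial_layout <- function(expr, chips, anchors = NULL, sector_map = NULL,
                          eps = NULL, min_radius = 0.1) {
  signals <- compute_log_signals(expr, chips, eps = eps)
  ids <- unique(signals$sample_id)
  if (is.null(anchors)) {
    anchors <- if (setequal(ids, study_anchors()$sample_id)) {
      study_anchors()
    } else {
      place_anchors(ids)
    }
  }
  if (is.null(sector_map)) {
    sector_map <- if (setequal(ids, names(study_sector_map()))) {
      study_sector_map()
    } else {
      setNames(anchors$sample_id, anchors$sample_id)
    }
  }
  out <- gene_position(signals, anchors) %>%
    left_join(gene_size(signals), by = "locus_id") %>%
    assign_clusters(anchors, sector_map, min_radius)
  structure(out, anchors = anchors, class = c("radial_layout", class(out)))
}
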