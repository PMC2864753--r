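#' Typed tabular I/O for the iron-limitation pipeline
#'
#' All stage inputs and outputs are tab-separated text with a mandatory
#' header line. Four tables are exchanged between stages:
#'
#' * `chips.tsv` — one row per microarray chip: `chip_id`, `treatment`
#'   (`iron_limited` or `iron_replete`), `day`, `biological_replicate`.
#' * `expression.tsv` — wide fluorescence matrix: `locus_id` plus one
#'   numeric column per `chip_id`.
#' * `tags.tsv` — AMT tag library: `peptide_id`, `locus_id`, `mono_mass`
#'   (Da), `net` (normalized elution time in \[0, 1\]), `f_score`.
#' * `features.tsv` — LC-MS features: `mass`, `net`, `abundance`,
#'   `sample_id`, `technical_replicate`.
#'
#' Missing observations are encoded by row absence, never by zero: the
#' technical-replicate presence filter counts rows. Unknown columns are
#' preserved on read but ignored by the pipeline.
#'
#' @name ferrolimit-io
NULL

TREATMENT_LEVELS <- c("iron_limited", "iron_replete")

# Exact TSV reader: base R's strtod parsing is correctly rounded, so a
# write_tsv/read round trip reproduces doubles bit-exactly.
read_tsv_exact <- function(path) {
  df <- utils::read.delim(path,
    sep = "\t", check.names = FALSE, stringsAsFactors = FALSE
  )
  as_tibble(df)
}


#' Read and validate chip metadata
#'
#' @param path Path to a tab-separated file with columns `chip_id`,
#'   `treatment`, `day`, `biological_replicate`.
#' @return A tibble of chip metadata, one row per chip, in file order.
#' @export
read_chips <- function(path) {
  chips <- read_tsv_exact(path)
  validate_chips(chips)
}

#' @rdname read_chips
#' @param chips A data frame of chip metadata.
#' @export
validate_chips <- function(chips) {
  chips <- as_tibble(chips)
  required <- c("chip_id", "treatment", "day", "biological_replicate")
  missing <- setdiff(required, names(chips))
  if (length(missing) > 0) {
    abort(paste0("chip metadata lacks column(s): ", toString(missing)))
  }
  chips$chip_id <- as.character(chips$chip_id)
  if (anyDuplicated(chips$chip_id)) {
    abort("duplicate chip_id in chip metadata")
  }
  bad <- setdiff(unique(chips$treatment), TREATMENT_LEVELS)
  if (length(bad) > 0) {
    abort(paste0("unknown treatment level(s): ", toString(bad)))
  }
  key <- paste(chips$treatment, chips$day, chips$biological_replicate)
  if (anyDuplicated(key)) {
    abort("(treatment, day, biological_replicate) must be unique per experiment")
  }
  chips
}

#' Read a fluorescence matrix in long (tidy) form
#'
#' Reads a wide expression table (`locus_id` plus one column per chip) and
#' returns it pivoted to one row per (gene, chip). Every chip column must be
#' described in `chips`; fluorescence must be non-negative.
#'
#' @param path Path to the wide expression TSV.
#' @param chips Chip metadata, as returned by [read_chips()].
#' @return A tibble with columns `locus_id`, `chip_id`, `fluorescence`,
#'   preserving the file's gene (row) and chip (column) order.
#' @export
read_expression <- function(path, chips) {
  wide <- read_tsv_exact(path)
  if (!"locus_id" %in% names(wide)) {
    abort("expression file lacks a locus_id column")
  }
  chips <- validate_chips(chips)
  chip_cols <- setdiff(names(wide), "locus_id")
  unknown <- setdiff(chip_cols, chips$chip_id)
  if (length(unknown) > 0) {
    abort(paste0("chip(s) absent from metadata: ", toString(unknown)))
  }
  expr <- tidyr::pivot_longer(wide, -"locus_id",
    names_to = "chip_id", values_to = "fluorescence"
  )
  validate_expression(expr)
}

#' @rdname read_expression
#' @param expr A long expression tibble (`locus_id`, `chip_id`, `fluorescence`).
#' @export
validate_expression <- function(expr) {
  expr <- as_tibble(expr)
  required <- c("locus_id", "chip_id", "fluorescence")
  missing <- setdiff(required, names(expr))
  if (length(missing) > 0) {
    abort(paste0("expression table lacks column(s): ", toString(missing)))
  }
  expr$locus_id <- as.character(expr$locus_id)
  if (anyNA(expr$fluorescence)) {
    abort("missing fluorescence values are not allowed (encode absence by row absence)")
  }
  if (any(expr$fluorescence < 0)) {
    abort("negative fluorescence values found")
  }
  if (anyDuplicated(paste(expr$locus_id, expr$chip_id))) {
    abort("duplicate (locus_id, chip_id) in expression table")
  }
  n_per_gene <- table(expr$locus_id)
  if (length(unique(n_per_gene)) > 1) {
    abort("expression table is ragged: genes are missing chip entries")
  }
  expr
}

#' Convenience reader returning the matrix and its metadata together
#'
#' @inheritParams read_expression
#' @param metadata_path Path to the chip metadata TSV.
#' @return A list with elements `expression` (long tibble) and `chips`.
#' @export
read_expression_matrix <- function(path, metadata_path) {
  chips <- read_chips(metadata_path)
  list(expression = read_expression(path, chips), chips = chips)
}

#' Write a long expression table as a wide TSV
#'
#' Inverse of [read_expression()]: genes become rows (first-appearance
#' order), chips become columns (first-appearance order). Write-then-read
#' is the identity.
#'
#' @param expr Long expression tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  expr <- validate_expression(expr)
  wide <- tidyr::pivot_wider(expr,
    names_from = "chip_id", values_from = "fluorescence"
  )
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Read an AMT tag library
#'
#' @param path Path to a TSV with columns `peptide_id`, `locus_id`,
#'   `mono_mass`, `net`, `f_score`.
#' @return A tibble of validated tags; extra columns are kept.
#' @export
read_tag_library <- function(path) {
  tags <- read_tsv_exact(path)
  validate_tags(tags)
}

#' @rdname read_tag_library
#' @param tags A data frame of AMT tags.
#' @export
validate_tags <- function(tags) {
  tags <- as_tibble(tags)
  required <- c("peptide_id", "locus_id", "mono_mass", "net", "f_score")
  missing <- setdiff(required, names(tags))
  if (length(missing) > 0) {
    abort(paste0("tag library lacks column(s): ", toString(missing)))
  }
  if (nrow(tags) == 0) {
    return(tags)
  }
  tags$peptide_id <- as.character(tags$peptide_id)
  tags$locus_id <- as.character(tags$locus_id)
  if (any(tags$mono_mass <= 0)) {
    abort("tag mono_mass must be positive")
  }
  if (any(tags$net < 0 | tags$net > 1)) {
    abort("tag net must lie in [0, 1]")
  }
  if (anyDuplicated(tags$peptide_id)) {
    abort("duplicate peptide_id in tag library")
  }
  tags
}

#' Read LC-MS feature observations
#'
#' @param path Path to a TSV with columns `mass`, `net`, `abundance`,
#'   `sample_id`, `technical_replicate`.
#' @return A tibble of validated features; extra columns are kept.
#' @export
read_features <- function(path) {
  feats <- read_tsv_exact(path)
  validate_features(feats)
}

#' @rdname read_features
#' @param features A data frame of feature observations.
#' @export
validate_features <- function(features) {
  features <- as_tibble(features)
  required <- c("mass", "net", "abundance", "sample_id", "technical_replicate")
  missing <- setdiff(required, names(features))
  if (length(missing) > 0) {
    abort(paste0("feature table lacks column(s): ", toString(missing)))
  }
  if (nrow(features) == 0) {
    return(features)
  }
  features$sample_id <- as.character(features$sample_id)
  if (any(features$mass <= 0)) {
    abort("feature mass must be positive")
  }
  if (any(features$net < 0 | features$net > 1)) {
    abort("feature net must lie in [0, 1]")
  }
  if (any(features$abundance <= 0)) {
    abort("feature abundance must be positive")
  }
  features
}

#' Write any typed table as TSV
#'
#' Thin wrapper around [readr::write_tsv()]; doubles are written with full
#' round-trip precision so write-then-read is the identity.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}
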