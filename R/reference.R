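#' Bundled reference tables of iron-responsive genes
#'
#' Curated worked-example tables from the published iron-limitation study
#' of *Ca.* Pelagibacter ubique, shipped as plain TSV under `extdata`.
#'
#' `reference_transcripts()` lists the 23 transcripts at least 50 percent
#' more abundant in iron-limited cultures 24 hours after siderophore
#' addition (`locus_id`, `gene`, `description`, `ratio` — replicate-mean
#' iron-limited/iron-replete fluorescence, `p_value` — two-tailed Student
#' t-test, `cluster` — radial-layout cluster membership where assigned).
#'
#' `reference_proteins()` lists the proteins at least 50 percent more
#' abundant in iron-limited cultures on proteomic days 18 and 28
#' (`day`, `locus_id`, `gene`, `description`, `fold` — mean peptide
#' ratio, `p_value` — Fisher-combined one-tailed t-tests).
#'
#' @return A tibble.
#' @export
reference_transcripts <- function() {
  path <- system.file("extdata", "sar11_iron_transcripts.tsv",
    package = "ferrolimit", mustWork = TRUE
  )
  read_tsv_exact(path)
}

#' @rdname reference_transcripts
#' @export
reference_proteins <- function() {
  path <- system.file("extdata", "sar11_iron_proteins.tsv",
    package = "ferrolimit", mustWork = TRUE
  )
  read_tsv_exact(path)
}
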