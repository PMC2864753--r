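#' Pipeline configuration
#'
#' Collects the thresholds and (optionally) input paths for
#' [run_pipeline()]. With `simulate = TRUE` (default) inputs are generated
#' by [simulate_study()] from `sim`; otherwise the four TSV paths in
#' `inputs` are read.
#'
#' @param simulate Generate inputs with the synthetic study generator.
#' @param sim A [simulation_config()] (simulation mode).
#' @param inputs Named list of paths: `expression`, `chips`, `tags`,
#'   `features`, `samples` (file mode).
#' @param min_ratio Transcript/protein induction threshold (default 1.5).
#' @param alpha Significance threshold (default 0.05).
#' @param ppm_tol,net_tol Feature-matching windows (defaults 6 ppm,
#'   0.001 NET).
#' @param marker_locus Marker gene locus (default: the simulation's
#'   marker in simulation mode).
#' @param figures Write PNG figures alongside the TSV outputs.
#' @param seed Integer seed overriding `sim$seed` when given.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = TRUE, sim = simulation_config(),
                            inputs = NULL, min_ratio = 1.5, alpha = 0.05,
                            ppm_tol = 6, net_tol = 0.001,
                            marker_locus = NULL, figures = FALSE,
                            seed = NULL) {
  if (min_ratio <= 0 || alpha <= 0 || ppm_tol <= 0 || net_tol <= 0) {
    abort("thresholds must be positive")
  }
  if (!is.null(seed)) {
    sim <- modifyList(sim, list(seed = as.integer(seed)))
    class(sim) <- "sim_config"
  }
  if (is.null(marker_locus) && simulate) marker_locus <- sim$marker_locus
  structure(
    list(
      simulate = simulate, sim = sim, inputs = inputs,
      min_ratio = min_ratio, alpha = alpha,
      ppm_tol = ppm_tol, net_tol = net_tol,
      marker_locus = marker_locus, figures = figures
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the `sim`
#' key holds [simulation_config()] arguments.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim_args <- raw$sim %||% list()
  raw$sim <- do.call(simulation_config, sim_args)
  do.call(pipeline_config, raw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  })
}

#' Run the full iron-limitation analysis pipeline
#'
#' Orchestrates simulate (or load) -> transcript differential analysis ->
#' radial layout -> AMT-tag protein quantitation (one comparison per
#' proteomic day) -> integration, writing every stage output as TSV under
#' `out_dir`. Reruns with the same configuration and seed reproduce
#' identical checksums.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return A manifest tibble (`file`, `n_rows`, `md5`) of the TSV
#'   outputs, invisibly classed `pipeline_manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = ".") {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  data <- run_stage("simulate", {
    if (config$simulate) {
      simulate_study(config$sim)
    } else {
      paths <- config$inputs
      needed <- c("expression", "chips", "tags", "features", "samples")
      for (key in needed) {
        if (is.null(paths[[key]]) || !file.exists(paths[[key]])) {
          abort(paste0("missing input file for '", key, "': ",
            paths[[key]] %||% "<unset>"
          ))
        }
      }
      chips <- read_chips(paths$chips)
      list(
        expression = read_expression(paths$expression, chips),
        chips = chips,
        tags = read_tag_library(paths$tags),
        features = read_features(paths$features),
        samples = read_tsv_exact(paths$samples),
        truth = NULL
      )
    }
  })

  outputs <- list()
  emit <- function(x, name) {
    path <- file.path(out_dir, name)
    write_table(as_tibble(x), path)
    outputs[[name]] <<- nrow(x)
    path
  }
  emit_expr <- function(x, name) {
    path <- file.path(out_dir, name)
    write_expression(x, path)
    outputs[[name]] <<- n_distinct(x$locus_id)
    path
  }

  run_stage("write_inputs", {
    emit_expr(data$expression, "expression.tsv")
    emit(data$chips, "chips.tsv")
    emit(data$tags, "tags.tsv")
    emit(data$features, "features.tsv")
    emit(data$samples, "samples.tsv")
    if (!is.null(data$truth)) {
      emit(data$truth$mrna, "ground_truth_mrna.tsv")
      emit(data$truth$protein, "ground_truth_protein.tsv")
    }
  })

  transcripts <- run_stage("transcripts", {
    normalized <- normalize_chips(data$expression)
    differential_transcripts(normalized, data$chips) %>%
      mutate(passes_filter = .data$ratio >= config$min_ratio)
  })
  emit(transcripts, "differential_transcripts.tsv")

  layout <- run_stage("layout", {
    radial_layout(data$expression, data$chips)
  })
  emit(layout, "gene_points.tsv")

  proteins <- run_stage("proteins", {
    days <- sort(unique(data$samples$day))
    purrr::map_dfr(days, function(d) {
      sids <- data$samples[data$samples$day == d, ]
      s_lim <- sids$sample_id[sids$treatment == "iron_limited"]
      s_rep <- sids$sample_id[sids$treatment == "iron_replete"]
      quantify_proteins(
        data$features, data$tags, s_lim, s_rep,
        ppm_tol = config$ppm_tol, net_tol = config$net_tol
      ) %>%
        mutate(day = d, .before = 1)
    }) %>%
      mutate(passes_filter = .data$fold >= config$min_ratio)
  })
  emit(proteins, "protein_quant.tsv")

  integration <- run_stage("integrate", {
    days <- intersect(unique(transcripts$day), unique(proteins$day))
    pairs <- purrr::map_dfr(days, function(d) {
      build_pairs(
        filter(transcripts, .data$day == d),
        filter(proteins, .data$day == d),
        alpha = config$alpha,
        comparison = paste0("limited_vs_replete_d", d)
      )
    })
    summary_tbl <- purrr::map_dfr(days, function(d) {
      proteome_summary(filter(proteins, .data$day == d), alpha = config$alpha) %>%
        mutate(day = d, .before = 1)
    })
    marker <- if (!is.null(config$marker_locus)) {
      marker_report(transcripts, proteins, config$marker_locus,
        min_fold = config$min_ratio
      )
    } else {
      NULL
    }
    list(pairs = pairs, summary = summary_tbl, marker = marker)
  })
  emit(integration$pairs, "omics_pairs.tsv")
  emit(integration$summary, "summary.tsv")
  if (!is.null(integration$marker)) emit(integration$marker, "marker_report.tsv")

  if (isTRUE(config$figures)) {
    run_stage("figures", {
      ggplot2::ggsave(file.path(out_dir, "radial_layout.png"),
        autoplot(layout),
        width = 7, height = 6, dpi = 150
      )
      if (nrow(integration$pairs) >= 3) {
        ggplot2::ggsave(file.path(out_dir, "omics_pairs.png"),
          autoplot(structure(integration$pairs,
            class = c("omics_pairs", class(integration$pairs))
          )),
          width = 7, height = 6, dpi = 150
        )
      }
    })
  }

  files <- names(outputs)
  manifest <- tibble(
    file = files,
    n_rows = unlist(outputs, use.names = FALSE),
    md5 = unname(tools::md5sum(file.path(out_dir, files)))
  )
  invisible(structure(manifest, class = c("pipeline_manifest", class(manifest))))
}
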