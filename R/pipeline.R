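#' Build and validate a pipeline run configuration
#'
#' A run is driven either by input files (`input:` block) or by the
#' synthetic generator (`simulation:` block) — exactly one of the two.
#' Settings may come from a YAML file or an equivalent nested list.
#'
#' Recognized fields:
#' * `input`: `matrix`, `sample_sheet` (required), optional `gene_lengths`,
#'   `traits`, `edges`, `gene_sets` file paths.
#' * `simulation`: arguments for [sim_config()] (e.g. `n_genes`,
#'   `n_reps_per_group`, `effect_size`, `dispersion`, `mode_fractions`);
#'   optional `edges`/`gene_sets` paths may still be given at the top level.
#' * `deg`: `p_cutoff`, `lfc_cutoff`, `use_adjusted`, `method`, `min_mean`.
#' * `pattern`: `p_cutoff`, `lfc_cutoff`, `use_adjusted`, `min_mpv`,
#'   `additive_band`.
#' * `normalization`: `"median_ratios"` (default, composition-robust) or
#'   `"fpkm"`/`"total_count"` (raw library totals).
#' * `network`: `top_k`; `enrich`: `universe` (`"expressed"` or `"all"`).
#' * `traits`: `alpha` for the Tukey letters.
#' * `seed`: integer master seed.
#'
#' @param config A YAML file path or a nested list.
#' @return A validated `RunConfig` list.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop_usage("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_config("config must be a list or a YAML file path")
  has_input <- !is.null(config$input)
  has_sim <- !is.null(config$simulation)
  if (has_input == has_sim) {
    stop_config("exactly one of 'input' and 'simulation' must be given")
  }
  seed <- as.integer(config$seed %||% 1L)
  deg <- config$deg %||% list()
  pattern <- config$pattern %||% list()
  out <- list(
    input = config$input,
    simulation = config$simulation,
    edges = config$edges %||% config$input$edges,
    gene_sets = config$gene_sets %||% config$input$gene_sets,
    deg = list(
      thresholds = deg_thresholds(deg$p_cutoff %||% 0.05,
                                  deg$lfc_cutoff %||% 1,
                                  deg$use_adjusted %||% FALSE),
      method = deg$method %||% "moderated",
      min_mean = deg$min_mean %||% 1
    ),
    pattern = pattern_call_config(
      thresholds = deg_thresholds(pattern$p_cutoff %||% 0.05,
                                  pattern$lfc_cutoff %||% 0,
                                  pattern$use_adjusted %||% FALSE),
      min_mpv = pattern$min_mpv %||% 1,
      additive_band = pattern$additive_band %||% 20
    ),
    normalization = match.arg(config$normalization %||% "median_ratios",
                              c("median_ratios", "fpkm", "total_count")),
    network = list(top_k = config$network$top_k %||% 10),
    enrich = list(universe = match.arg(config$enrich$universe %||% "expressed",
                                       c("expressed", "all"))),
    traits = list(alpha = config$traits$alpha %||% 0.05),
    seed = seed
  )
  if (has_sim) {
    sim_args <- config$simulation
    sim_args$seed <- sim_args$seed %||% seed
    if (!is.null(sim_args$mode_fractions)) {
      sim_args$mode_fractions <- unlist(sim_args$mode_fractions)
    }
    for (f in c("libsize_range", "base_range")) {
      if (!is.null(sim_args[[f]])) sim_args[[f]] <- as.numeric(unlist(sim_args[[f]]))
    }
    out$simulation <- do.call(sim_config, sim_args)
  } else {
    need <- c("matrix", "sample_sheet")
    missing <- need[!need %in% names(config$input)]
    if (length(missing)) {
      stop_config("input block missing field(s): %s", paste(missing, collapse = ", "))
    }
  }
  structure(out, class = "RunConfig")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full heterosis analysis pipeline
#'
#' Stages: obtain counts (simulate or read) -> FPKM/CPM normalization ->
#' expression filter -> DEG contrasts at the volcano thresholds ->
#' classification contrasts at the pattern thresholds -> MPV/MPH/BPH and
#' pattern classification -> candidate ranking -> optional hub genes and
#' gene-set enrichment -> optional trait summaries and gene-trait
#' correlations. All stage outputs are written as TSV under `output_dir`
#' together with a machine-readable `summary.json` and the resolved
#' configuration; identical configuration and seed reproduce identical
#' files.
#'
#' @param config A [run_config()] (or list / YAML path accepted by it).
#' @param output_dir Output directory (created if needed).
#' @param force Overwrite a non-empty output directory.
#' @return The run summary (list of stage counts), invisibly classed
#'   `RunSummary`.
#' @export
run_pipeline <- function(config, output_dir, force = FALSE) {
  if (!inherits(config, "RunConfig")) config <- run_config(config)
  if (dir.exists(output_dir) && length(list.files(output_dir)) && !force) {
    stop_usage("output directory %s is not empty (use force = TRUE)", output_dir)
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(...) file.path(output_dir, ...)
  set.seed(config$seed)

  truth <- NULL
  traits <- NULL
  gene_lengths <- NULL
  if (!is.null(config$simulation)) {
    sim <- stage("simulate", simulate_expression(config$simulation))
    counts <- sim$expr
    truth <- sim$truth
    write_expression(counts, path("counts.tsv"), path("sample_sheet.tsv"))
    write_tsv(truth, path("truth_table.tsv"))
    traits <- stage("simulate", {
      spec <- default_trait_spec(truth)
      simulate_traits(counts, spec, seed = config$seed + 1L)
    })
    write_tsv(traits, path("trait_table.tsv"))
  } else {
    counts <- stage("read", read_expression(config$input$matrix,
                                            config$input$sample_sheet))
    if (!is.null(config$input$gene_lengths)) {
      gene_lengths <- stage("read", read_gene_lengths(config$input$gene_lengths))
    }
    if (!is.null(config$input$traits)) {
      traits <- stage("read", read_trait_table(config$input$traits))
    }
  }

  norm_method <- if (config$normalization == "median_ratios") {
    "median_ratios"
  } else {
    "total_count"
  }
  abundance <- stage("normalize", suppressWarnings(
    normalize_abundance(counts, gene_lengths, method = norm_method)))
  expressed <- stage("filter", suppressMessages(
    filter_expressed(abundance, config$deg$min_mean)))
  write_expression(expressed, path("abundance.tsv"))

  deg_a <- stage("deg", run_contrast(expressed, "parentA", "hybrid",
                                     config$deg$thresholds, config$deg$method))
  deg_b <- stage("deg", run_contrast(expressed, "parentB", "hybrid",
                                     config$deg$thresholds, config$deg$method))
  deg_ab <- stage("deg", run_contrast(expressed, "parentA", "parentB",
                                      config$deg$thresholds, config$deg$method))
  write_tsv(deg_a, path("deg_hybrid_vs_parentA.tsv"))
  write_tsv(deg_b, path("deg_hybrid_vs_parentB.tsv"))
  write_tsv(deg_ab, path("deg_parentB_vs_parentA.tsv"))

  cls_a <- stage("classify", run_contrast(expressed, "parentA", "hybrid",
                                          config$pattern$thresholds,
                                          config$deg$method))
  cls_b <- stage("classify", run_contrast(expressed, "parentB", "hybrid",
                                          config$pattern$thresholds,
                                          config$deg$method))
  het <- stage("heterosis", suppressMessages(
    compute_heterosis_stats(expressed, min_mpv = config$pattern$min_mpv)))
  het <- stage("classify", classify_patterns(het, cls_a, cls_b, config$pattern))
  write_tsv(het, path("heterosis.tsv"))

  up_set <- sort(het$gene_id[het$pattern == "transgressive_up"])
  if (!identical(up_set, intersect_upregulated(cls_a, cls_b))) {
    stop("[classify] internal inconsistency: intersected up-sets differ from transgressive_up")
  }
  candidates <- stage("candidates", select_candidates(het))
  write_tsv(data.frame(gene_id = candidates,
                       bph_pct = het$bph_pct[match(candidates, het$gene_id)],
                       stringsAsFactors = FALSE),
            path("candidates.tsv"))

  hubs <- NULL
  if (!is.null(config$edges)) {
    edges <- stage("network", read_edge_list(config$edges))
    down_set <- het$gene_id[het$pattern == "transgressive_down"]
    hubs <- stage("network", hub_genes(edges, query = c(up_set, down_set),
                                       k = config$network$top_k))
    write_tsv(hubs, path("hubs.tsv"))
  }

  if (!is.null(config$gene_sets)) {
    sets <- stage("enrich", read_gmt(config$gene_sets))
    universe <- if (config$enrich$universe == "expressed") {
      rownames(expressed$values)
    } else {
      rownames(counts$values)
    }
    enr_up <- stage("enrich", suppressMessages(enrich(up_set, sets, universe)))
    write_tsv(enr_up, path("enrichment_transgressive_up.tsv"))
    down_set <- het$gene_id[het$pattern == "transgressive_down"]
    enr_dn <- stage("enrich", suppressMessages(enrich(down_set, sets, universe)))
    write_tsv(enr_dn, path("enrichment_transgressive_down.tsv"))
  }

  if (!is.null(traits)) {
    tsum <- stage("traits", summarize_traits(traits, alpha = config$traits$alpha))
    write_tsv(tsum, path("trait_summary.tsv"))
    corr_genes <- if (!is.null(hubs) && nrow(hubs)) {
      hubs$gene_id
    } else {
      utils::head(candidates, config$network$top_k)
    }
    if (length(corr_genes)) {
      corr <- stage("traits", correlate_genes_traits(expressed, traits,
                                                     genes = corr_genes))
      write_tsv(corr, path("gene_trait_correlations.tsv"))
    }
  }

  summary <- list(
    seed = config$seed,
    n_genes_input = nrow(counts$values),
    n_genes_expressed = nrow(expressed$values),
    deg = list(
      hybrid_vs_parentA = list(up = sum(deg_a$call == "up_in_test"),
                               down = sum(deg_a$call == "down_in_test")),
      hybrid_vs_parentB = list(up = sum(deg_b$call == "up_in_test"),
                               down = sum(deg_b$call == "down_in_test")),
      parentB_vs_parentA = list(up = sum(deg_ab$call == "up_in_test"),
                                down = sum(deg_ab$call == "down_in_test"))
    ),
    patterns = as.list(table(factor(het$pattern, levels = PATTERN_LEVELS))),
    n_transgressive_up = sum(het$pattern == "transgressive_up"),
    n_transgressive_down = sum(het$pattern == "transgressive_down"),
    n_candidates = length(candidates),
    n_hubs = if (is.null(hubs)) 0L else nrow(hubs),
    version = as.character(utils::packageVersion("hvigor"))
  )
  jsonlite::write_json(summary, path("summary.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  yaml::write_yaml(serialize_config(config), path("config_resolved.yaml"))
  invisible(structure(summary, class = "RunSummary"))
}

# Default trait coupling for simulated runs: tenderness-like trait driven
# negatively by the strongest overdominant genes, a color-like trait driven
# positively, and a thickness-like trait on additive genes.
default_trait_spec <- function(truth) {
  over <- truth$gene_id[truth$mode == "overdominant"]
  addv <- truth$gene_id[truth$mode == "additive"]
  if (length(over) < 2 || length(addv) < 1) {
    stop_config("default trait simulation needs >= 2 overdominant and >= 1 additive genes")
  }
  trait_sim_spec(list(
    shear_force = stats::setNames(c(-1, -0.5), over[1:2]),
    meat_color = stats::setNames(c(1, 0.5), over[1:2]),
    backfat = stats::setNames(1, addv[1])
  ), noise_sd = 0.5)
}

serialize_config <- function(config) {
  x <- unclass(config)
  x$simulation <- if (!is.null(x$simulation)) {
    s <- unclass(x$simulation)
    s$mode_fractions <- as.list(s$mode_fractions)
    s
  }
  x$deg$thresholds <- unclass(x$deg$thresholds)
  x$pattern <- {
    p <- unclass(x$pattern)
    p$thresholds <- unclass(p$thresholds)
    p
  }
  x
}
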