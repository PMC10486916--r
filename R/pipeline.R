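#' Read and write generator scenarios as YAML
#'
#' @param scenario A [generator_scenario()].
#' @param path File path.
#' @return `read_scenario()` returns a `generator_scenario`;
#'   `write_scenario()` returns `path` invisibly.
#' @export
write_scenario <- function(scenario, path) {
  yaml::write_yaml(list(
    bean_type_counts = as.list(scenario$bean_type_counts),
    marginals = df_to_rowlist(scenario$marginals),
    spearman_targets = purrr::map(scenario$spearman_targets, function(m) {
      apply(m, 1, as.list, simplify = FALSE)
    }),
    lods = as.list(scenario$lods),
    area_weights = as.list(scenario$area_weights),
    seed = scenario$seed
  ), path, precision = 15)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  raw <- yaml::read_yaml(path)
  targets <- purrr::map(raw$spearman_targets, function(rows) {
    m <- do.call(rbind, purrr::map(rows, \(r) unlist(r)))
    rownames(m) <- colnames(m)
    m
  })
  generator_scenario(
    bean_type_counts = unlist(raw$bean_type_counts),
    marginals = rowlist_to_df(raw$marginals),
    spearman_targets = targets,
    lods = unlist(raw$lods),
    area_weights = unlist(raw$area_weights),
    seed = raw$seed
  )
}

#' Pipeline run configuration
#'
#' Describes one end-to-end run: the data source (a concentration CSV or a
#' generator scenario), the stages to execute, the population groups, the
#' Monte Carlo size and seed, and the output directory.
#'
#' @param input Path to a concentration CSV, or `NULL` to use `scenario`.
#' @param scenario A [generator_scenario()], a scenario YAML path, or
#'   `"default"`; used when `input` is `NULL`.
#' @param stages Subset of `c("prep", "summary", "correlation", "cluster",
#'   "risk", "sensitivity")`.
#' @param populations Population names for the risk stages.
#' @param n_iter Monte Carlo iterations.
#' @param seed Integer seed; required when any stochastic stage (risk,
#'   sensitivity, or scenario generation) is selected.
#' @param out_dir Output directory (created if absent).
#' @return A `run_config` object.
#' @export
run_config <- function(input = NULL, scenario = "default",
                       stages = c("prep", "summary", "correlation",
                                  "cluster", "risk", "sensitivity"),
                       populations = c("children", "teens", "adults"),
                       n_iter = 10000, seed = NULL, out_dir = "beanrisk-out") {
  all_stages <- c("prep", "summary", "correlation", "cluster",
                  "risk", "sensitivity")
  if (length(stages) == 0) abort("at least one stage must be selected")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  needs_prep <- setdiff(stages, "prep")
  if (length(needs_prep) > 0 && !"prep" %in% stages) {
    abort("every stage depends on 'prep'; include it in `stages`")
  }
  stochastic <- any(c("risk", "sensitivity") %in% stages) || is.null(input)
  if (stochastic && is.null(seed)) {
    abort("a seed is required when a stochastic stage or synthetic data is used")
  }
  if ("sensitivity" %in% stages && !"risk" %in% stages) {
    abort("'sensitivity' requires the 'risk' stage")
  }
  if (!is.null(input) && !file.exists(input)) {
    abort(paste0("input file not found: ", input))
  }
  structure(
    list(input = input, scenario = scenario, stages = stages,
         populations = populations, n_iter = n_iter, seed = seed,
         out_dir = out_dir),
    class = "run_config"
  )
}

#' Load a run configuration from YAML
#'
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @return A `run_config` object.
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw[intersect(names(raw), names(formals(run_config)))])
}

#' Execute a pipeline run
#'
#' Runs the selected stages in dependency order — data preparation
#' (reading or generating records plus non-detect substitution), summary
#' statistics, correlation analysis, area clustering, Monte Carlo risk
#' assessment and sensitivity analysis — writing each stage's artifacts to
#' the output directory, plus a JSON manifest listing every produced file
#' with the configuration hash and seed. A rerun with an identical
#' configuration reproduces identical numeric outputs.
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  files <- character(0)
  emit <- function(name) {
    files <<- c(files, name)
    file.path(config$out_dir, name)
  }

  # --- prep ---
  if (!is.null(config$input)) {
    say("reading records from ", config$input)
    records <- read_concentration_csv(config$input)
  } else {
    sc <- config$scenario
    if (is.character(sc)) {
      sc <- if (identical(sc, "default"))
        generator_scenario(seed = config$seed) else read_scenario(sc)
    }
    say("generating synthetic records (seed ", sc$seed, ")")
    records <- generate_samples(sc)
  }
  records <- substitute_nondetects(records)
  write_concentration_csv(records, emit("prepared_records.csv"))
  write.csv(censoring_report(records), emit("censoring_report.csv"),
            row.names = FALSE)

  if ("summary" %in% config$stages) {
    say("summarising concentrations")
    smry <- summarize_concentrations(records)
    write.csv(smry, emit("summary.csv"), row.names = FALSE)
  }
  if ("correlation" %in% config$stages) {
    say("computing Spearman correlations")
    write.csv(spearman_matrix(records, by = "pooled"),
              emit("correlation_pooled.csv"), row.names = FALSE)
    write.csv(spearman_matrix(records, by = "bean_type"),
              emit("correlation_by_type.csv"), row.names = FALSE)
  }
  if ("cluster" %in% config$stages) {
    say("clustering areas")
    cl <- cluster_areas(records)
    jsonlite::write_json(
      list(clusters = cl$clusters, merge_tree = cluster_merge_tree(cl)),
      emit("area_clusters.json"), auto_unbox = TRUE, digits = NA
    )
    writeLines(cluster_newick(cl), emit("area_dendrogram.nwk"))
  }

  dists <- list()
  if ("risk" %in% config$stages) {
    specs <- fit_concentration_specs(records)
    for (i in seq_along(config$populations)) {
      pop <- config$populations[i]
      say("risk simulation: ", pop)
      rd <- run_simulation(specs, pop, n_iter = config$n_iter,
                           seed = config$seed + i)
      dists[[pop]] <- rd
      write.csv(risk_percentiles(rd),
                emit(paste0("risk_percentiles_", pop, ".csv")),
                row.names = FALSE)
      exc <- bind_rows(
        exceedance(rd, "HI", 1),
        if ("As" %in% colnames(rd$cr)) exceedance(rd, "CR-As", 1e-4)
      )
      jsonlite::write_json(exc, emit(paste0("exceedance_", pop, ".json")),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
    }
  }
  if ("sensitivity" %in% config$stages) {
    for (pop in names(dists)) {
      say("sensitivity: ", pop)
      sens <- sensitivity(dists[[pop]], "HI")
      jsonlite::write_json(as_tibble(sens),
                           emit(paste0("sensitivity_", pop, ".json")),
                           auto_unbox = TRUE, digits = NA,
                           dataframe = "rows")
    }
  }

  manifest <- list(
    created = format(Sys.time(), tz = "UTC"),
    seed = config$seed,
    n_iter = config$n_iter,
    stages = config$stages,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    files = files
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
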