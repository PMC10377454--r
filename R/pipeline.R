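config_defaults <- function() {
  list(
    gamma = 0.25, rule = "AND",
    nlambda = 100, lambda_min_ratio = 0.01,
    n_random_graphs = 1000,
    stability_proportions = seq(0.05, 0.75, by = 0.05),
    stability_n_boot = 1000,
    n_perm = 1000,
    layout_iterations = 500,
    seed = 1L,
    simulate = NULL,   # list(n_per_group=, params_paths=, dsm_constraint=)
    input_csv = NULL,
    out_dir = "isingnet-output"
  )
}

#' Analysis configuration for the full pipeline
#'
#' Collects all estimator, metric, stability and comparison settings plus a
#' master seed; every random stage derives its own seed deterministically
#' from the master seed. Unknown keys are rejected by name. Configurations
#' round-trip through JSON (and YAML when the yaml package is available).
#'
#' @param ... Named settings overriding the defaults: `gamma`, `rule`,
#'   `nlambda`, `lambda_min_ratio`, `n_random_graphs`,
#'   `stability_proportions`, `stability_n_boot`, `n_perm`,
#'   `layout_iterations`, `seed`, `simulate`, `input_csv`, `out_dir`.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(...) {
  cfg <- config_defaults()
  override <- list(...)
  if (length(override) > 0 &&
      (is.null(names(override)) || any(names(override) == "")))
    stop("all configuration entries must be named")
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(override)] <- override
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "analysis_config")
}

#' Read and write analysis configurations
#'
#' @param config An [analysis_config].
#' @param path File path; `.yaml`/`.yml` uses YAML, anything else JSON.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  obj <- unclass(config)
  obj <- obj[!vapply(obj, is.null, logical(1))]
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(analysis_config, obj)
}

stage_seeds <- function(master_seed, stages) {
  set.seed(master_seed)
  stats::setNames(sample.int(.Machine$integer.max - 1, length(stages)), stages)
}

#' Bundled two-group demonstration cohort
#'
#' Samples the synthetic "MDE"-like and "PPD"-like cohorts from the bundled
#' parameter sets under the DSM-5 diagnostic constraint, at the study's
#' group sizes by default (871 and 486).
#'
#' @param n_mde,n_ppd Group sizes.
#' @param seed Integer seed.
#' @return Named list of two [symptom_dataset]s.
#' @export
demo_cohort <- function(n_mde = 871, n_ppd = 486, seed = 1L) {
  spec <- cohort_spec(
    c(MDE = n_mde, PPD = n_ppd),
    list(MDE = example_parameters("mde"), PPD = example_parameters("ppd")),
    constraint = dsm_constraint(), seed = seed)
  sample_cohort(spec)
}

#' Run the full symptom-network comparison pipeline
#'
#' Executes the whole workflow on a two-group cohort: symptom frequencies
#' and adjusted comparison, per-group Ising estimation (with Pearson matrix
#' and layout), centrality and small-world measures, case-dropping bootstrap
#' stability, and the permutation network comparison test. All outputs are
#' written under `config$out_dir` together with a JSON manifest recording
#' the package version, seeds, configuration hash and stage outputs.
#'
#' @param config An [analysis_config]. The cohort comes from
#'   `config$input_csv` (a cohort CSV with exactly two groups) or, when
#'   `NULL`, from [demo_cohort()].
#' @param cohort Optionally, a named list of exactly two [symptom_dataset]s
#'   overriding both input sources.
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config = analysis_config(), cohort = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  seeds <- stage_seeds(config$seed,
                       c("simulate", "layout", "smallworld", "stability",
                         "nct"))
  if (is.null(cohort)) {
    cohort <- if (!is.null(config$input_csv)) read_cohort_csv(config$input_csv)
    else demo_cohort(seed = seeds[["simulate"]])
  }
  if (length(cohort) != 2)
    stop("the pipeline compares exactly two groups, got ", length(cohort))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  groups <- names(cohort)
  outputs <- character(0)
  emit <- function(writer, obj, file, ...) {
    writer(obj, file.path(out_dir, file), ...)
    outputs <<- c(outputs, file)
  }
  run_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[isingnet] %-12s done in %.1fs", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }

  freq <- run_stage("frequencies", {
    tab <- adjusted_comparison(cohort[[1]], cohort[[2]])
    emit(write_frequency_csv, tab, "frequency_comparison.csv")
    tab
  })

  networks <- run_stage("estimation", {
    nets <- lapply(cohort, fit_ising, gamma = config$gamma,
                   rule = config$rule, nlambda = config$nlambda,
                   lambda_min_ratio = config$lambda_min_ratio)
    for (g in groups) {
      emit(write_network_json, nets[[g]], paste0("network_", g, ".json"))
      emit(write_edge_list, nets[[g]], paste0("edges_", g, ".tsv"))
      emit(function(x, p) utils::write.csv(x, p, quote = FALSE),
           pearson_matrix(cohort[[g]]), paste0("pearson_", g, ".csv"))
      emit(function(x, p) utils::write.csv(x, p, row.names = FALSE,
                                           quote = FALSE),
           fr_layout(nets[[g]], seed = seeds[["layout"]],
                     iterations = config$layout_iterations),
           paste0("layout_", g, ".csv"))
    }
    nets
  })

  inference <- run_stage("centrality", {
    res <- lapply(groups, function(g) {
      cent <- centrality_table(networks[[g]])
      emit(write_centrality_csv, cent, paste0("centrality_", g, ".csv"))
      sw <- small_world(networks[[g]], n_random = config$n_random_graphs,
                        seed = seeds[["smallworld"]])
      emit(function(x, p) jsonlite::write_json(
        x[c("clustering", "avg_path_length", "c_random", "l_random",
            "index")], p, digits = NA, auto_unbox = TRUE),
        sw, paste0("small_world_", g, ".json"))
      list(centrality = cent, small_world = sw)
    })
    stats::setNames(res, groups)
  })

  stability <- run_stage("stability", {
    res <- lapply(groups, function(g) {
      # sparse networks can make a genuine metric constant (e.g. all-zero
      # betweenness); drop those rather than aborting the run
      net <- networks[[g]]
      metrics <- c("strength", "closeness", "betweenness",
                   "expected_influence")
      ok <- vapply(metrics, function(m)
        stats::sd(centrality_vector(net$weights, m)) > 0, logical(1))
      if (!all(ok))
        warning("constant full-sample centralit(ies) skipped for group ", g,
                ": ", paste(metrics[!ok], collapse = ", "))
      if (!any(ok))
        stop("all centrality metrics are constant for group ", g)
      st <- case_drop_bootstrap(cohort[[g]], metrics = metrics[ok],
                                n_boot = config$stability_n_boot,
                                proportions = config$stability_proportions,
                                seed = seeds[["stability"]],
                                gamma = config$gamma, rule = config$rule)
      emit(write_stability_csv, st, paste0("stability_", g, ".csv"))
      emit(function(x, p) jsonlite::write_json(as.list(x$cs_coefficient), p,
                                               digits = NA,
                                               auto_unbox = TRUE),
           st, paste0("cs_coefficient_", g, ".json"))
      st
    })
    stats::setNames(res, groups)
  })

  comparison <- run_stage("nct", {
    res <- nct(cohort[[1]], cohort[[2]], n_perm = config$n_perm,
               seed = seeds[["nct"]], gamma = config$gamma,
               rule = config$rule)
    emit(write_nct_json, res, "nct.json")
    res
  })

  cfg_file <- file.path(out_dir, "config.json")
  write_config(config, cfg_file)
  # the hash covers the analysis settings, not where they were written
  hash_cfg <- unclass(config)
  hash_cfg$out_dir <- NULL
  hash_cfg$input_csv <- NULL
  hash_file <- tempfile(fileext = ".json")
  on.exit(unlink(hash_file), add = TRUE)
  jsonlite::write_json(hash_cfg, hash_file, digits = NA, auto_unbox = TRUE)
  manifest <- list(
    package = "isingnet",
    version = as.character(utils::packageVersion("isingnet")),
    master_seed = config$seed,
    stage_seeds = as.list(seeds),
    config_hash = unname(tools::md5sum(hash_file)),
    groups = groups,
    n_per_group = vapply(cohort, function(d) d$n, numeric(1)),
    stages = list(frequencies = "frequency_comparison.csv",
                  estimation = grep("^(network|edges|pearson|layout)_",
                                    outputs, value = TRUE),
                  centrality = grep("^(centrality|small_world)_", outputs,
                                    value = TRUE),
                  stability = grep("^(stability|cs_coefficient)_", outputs,
                                   value = TRUE),
                  nct = "nct.json"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(frequencies = freq, networks = networks,
                 inference = inference, stability = stability,
                 nct = comparison, manifest = manifest))
}
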