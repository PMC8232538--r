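#' @name pipeline
#' @title Config-driven pipeline and command-line entry point
#'
#' @description
#' The analysis is driven by one YAML config with sections `data`
#' (input files and column mapping), `model` (level, covariates,
#' smooths, priors), `engine` (iterations, burn-in, seed), `simulate`
#' (generator settings) and `report` (output directory).  Each stage is
#' an ordinary function (`run_simulate`, `run_tabulate`, `run_fit`,
#' `run_report`); `cli_main()` dispatches the corresponding subcommands
#' for shell use, writes CSV outputs only, and records a machine-
#' readable run record (seed, config hash, rows dropped by the
#' complete-case rule) next to every result set.
NULL

read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  yaml::read_yaml(path)
}

config_hash <- function(config) {
  raw <- serialize(config, NULL, version = 2)
  sprintf("%08x", sum(as.integer(raw) * seq_along(raw)) %% .Machine$integer.max)
}

model_from_config <- function(mcfg) {
  mcfg <- mcfg %||% list()
  lvl <- mcfg$level %||% "M3"
  all_levels <- default_fixed_levels()
  fx_names <- mcfg$fixed %||% names(all_levels)
  fixed <- all_levels[intersect(fx_names, names(all_levels))]
  if (!is.null(mcfg$levels)) fixed[names(mcfg$levels)] <- mcfg$levels
  sm_names <- mcfg$smooths %||% c("age", "age_first_birth", "anc_visits")
  smooths <- lapply(sm_names, function(nm) {
    sar_smooth(nm, k = mcfg$k %||% 20, degree = mcfg$degree %||% 3)
  })
  pc <- mcfg$priors %||% list()
  sar_model(level = lvl, fixed = fixed, smooths = smooths,
            priors = sar_priors(a = pc$a %||% 0.001, b = pc$b %||% 0.001,
                                fixed_prec = pc$fixed_prec %||% 1e-6))
}

write_run_record <- function(dir, config, seed, extra = list()) {
  rec <- c(list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                package_version = as.character(utils::packageVersion("sarlogit")),
                r_version = as.character(getRversion()),
                config_hash = config_hash(config), seed = seed), extra)
  jsonlite::write_json(rec, file.path(dir, "run_record.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Simulate stage: write a synthetic dataset
#'
#' @param config config list (section `simulate` holds generator
#'   overrides for [sim_config()]).
#' @param out_dir output directory.
#' @param seed integer seed.
#' @return invisibly, the written file paths.
#' @export
run_simulate <- function(config, out_dir, seed) {
  sc <- do.call(sim_config, config$simulate %||% list())
  sim <- simulate_dataset(sc, seed = seed)
  paths <- write_dataset(sim, out_dir)
  write_run_record(out_dir, config, seed,
                   list(stage = "simulate", n_women = nrow(sim$records)))
  invisible(paths)
}

#' Tabulate stage: descriptive knowledge and covariate tables
#'
#' @param config config list; `data$women` is the survey CSV and
#'   `data$column_map` an optional rename map.
#' @param out_dir output directory for `knowledge_table.csv` and
#'   `covariate_table.csv`.
#' @return invisibly, the two tables.
#' @export
run_tabulate <- function(config, out_dir) {
  dcfg <- config$data %||% stop("config has no [data] section", call. = FALSE)
  records <- read_women_csv(dcfg$women, dcfg$column_map)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  kt <- tabulate_knowledge(records)
  covs <- dcfg$covariates %||%
    intersect(names(default_fixed_levels()), names(records))
  ct <- tabulate_covariates(records, covs)
  write.csv(kt, file.path(out_dir, "knowledge_table.csv"), row.names = FALSE)
  write.csv(ct, file.path(out_dir, "covariate_table.csv"), row.names = FALSE)
  write_run_record(out_dir, config, NA,
                   list(stage = "tabulate", n = attr(kt, "n")))
  invisible(list(knowledge = kt, covariates = ct))
}

#' Fit stage: run the sampler and persist results as CSV
#'
#' Writes per-block posterior summary tables, the retained draws needed
#' by the report stage, DIC, and a run record.
#'
#' @param config config list with `data`, `model` and `engine` sections.
#' @param out_dir results directory.
#' @param seed optional seed override for the engine.
#' @return invisibly, the fitted model object.
#' @export
run_fit <- function(config, out_dir, seed = NULL) {
  dcfg <- config$data %||% stop("config has no [data] section", call. = FALSE)
  records <- read_women_csv(dcfg$women, dcfg$column_map)
  graph <- read_neighbor_list(dcfg$neighbors)
  outcome <- dcfg$outcome %||% "sufficient"
  if (!outcome %in% names(records) &&
      all(knowledge_questions() %in% names(records))) {
    records <- score_responses(records)
    outcome <- "sufficient"
  }
  n0 <- nrow(records)
  if (all(knowledge_questions() %in% names(records))) {
    records <- filter_complete_cases(records)
  }
  model <- model_from_config(config$model)
  ecfg <- config$engine %||% list()
  engine <- sar_engine(iterations = ecfg$iterations %||% 4000,
                       burnin = ecfg$burnin %||% 1000,
                       seed = seed %||% ecfg$seed %||%
                         stop("engine seed required", call. = FALSE))
  fit <- fit_sar(records, graph, model, engine, outcome = outcome)
  save_fit_results(fit, out_dir)
  write_run_record(out_dir, config, engine$seed,
                   list(stage = "fit", level = model$level,
                        n_rows_in = n0, n_rows_used = nrow(records),
                        n_dropped = n0 - nrow(records),
                        min_ess = fit$diagnostics$min_ess))
  invisible(fit)
}

#' Persist a fitted model as plain-text results files
#'
#' @param fit a [fit_sar()] result.
#' @param dir results directory.
#' @return invisibly `dir`.
#' @export
save_fit_results <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, nm) {
    write.csv(cbind(parameter = rownames(df), df),
              file.path(dir, nm), row.names = FALSE)
  }
  wr(fit$summaries$fixed, "fixed_summary.csv")
  wr(fit$summaries$spatial, "spatial_summary.csv")
  wr(fit$summaries$variances, "variance_summary.csv")
  write.csv(fit$draws$fixed, file.path(dir, "draws_fixed.csv"),
            row.names = FALSE)
  write.csv(fit$draws$spatial, file.path(dir, "draws_spatial.csv"),
            row.names = FALSE)
  for (nm in names(fit$smooth_info)) {
    j <- match(nm, names(fit$smooth_info))
    write.csv(fit$draws$theta[[j]],
              file.path(dir, paste0("draws_smooth_", nm, ".csv")),
              row.names = FALSE)
  }
  d <- dic(fit)
  write.csv(data.frame(model = d$model, Dbar = d$Dbar, Dhat = d$Dhat,
                       pD = d$pD, DIC = d$DIC),
            file.path(dir, "dic.csv"), row.names = FALSE)
  meta <- list(
    level = fit$level,
    fixed = fit$model$fixed,
    smooths = lapply(fit$smooth_info, function(s) {
      list(knots = s$knots, degree = s$degree, uz = s$uz)
    }),
    regions = rownames(fit$summaries$spatial),
    fingerprint = fit$fingerprint
  )
  yaml::write_yaml(meta, file.path(dir, "fit_meta.yaml"))
  invisible(dir)
}

#' Reload persisted results for reporting
#'
#' @param dir results directory written by [save_fit_results()].
#' @return lightweight `sar_fit` object sufficient for
#'   [classify_regions()], [or_table()] and [smooth_report()].
#' @export
load_fit_results <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "fit_meta.yaml"))
  rd <- function(nm) {
    df <- read.csv(file.path(dir, nm))
    rownames(df) <- df$parameter
    df$parameter <- NULL
    df
  }
  draws_fixed <- as.matrix(read.csv(file.path(dir, "draws_fixed.csv"),
                                    check.names = FALSE))
  draws_spatial <- as.matrix(read.csv(file.path(dir, "draws_spatial.csv"),
                                      check.names = FALSE))
  smooth_info <- lapply(meta$smooths, function(s) {
    list(knots = unlist(s$knots), degree = s$degree, uz = unlist(s$uz))
  })
  theta <- lapply(names(smooth_info), function(nm) {
    as.matrix(read.csv(file.path(dir, paste0("draws_smooth_", nm, ".csv")),
                       check.names = FALSE))
  })
  fit <- list(
    level = meta$level,
    model = list(fixed = meta$fixed),
    summaries = list(fixed = rd("fixed_summary.csv"),
                     spatial = rd("spatial_summary.csv"),
                     variances = rd("variance_summary.csv")),
    draws = list(fixed = draws_fixed, spatial = draws_spatial,
                 theta = theta),
    smooth_info = setNames(smooth_info, names(meta$smooths)),
    fingerprint = meta$fingerprint
  )
  class(fit) <- "sar_fit"
  fit
}

#' Report stage: tables, significance map and smooth curves
#'
#' A pure function of the persisted results files: re-running it on the
#' same results directory writes byte-identical outputs.
#'
#' @param config config list (unused fields are ignored).
#' @param results_dir directory written by [run_fit()].
#' @param out_dir report output directory.
#' @return invisibly, the list of written files.
#' @export
run_report <- function(config, results_dir, out_dir) {
  fit <- load_fit_results(results_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  ort <- or_table(fit)
  p <- file.path(out_dir, "odds_ratios.csv")
  write.csv(ort, p, row.names = FALSE); written <- c(written, p)
  smap <- classify_regions(fit)
  p <- file.path(out_dir, "significance_map.csv")
  write.csv(smap, p, row.names = FALSE); written <- c(written, p)
  for (nm in names(fit$smooth_info)) {
    cur <- smooth_report(fit, nm)
    p <- file.path(out_dir, paste0("smooth_", nm, ".csv"))
    write.csv(cur, p, row.names = FALSE); written <- c(written, p)
  }
  invisible(written)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `tabulate`, `fit`, `report`.  All take
#' `--config <yaml>` and `--out <dir>`; `simulate` and `fit` take
#' `--seed <int>` (overriding the config); `report` takes
#' `--results <dir>`.  Returns 0 on success, 2 on validation failure.
#'
#' @param argv character vector of command-line arguments.
#' @return integer exit status.
#' @export
cli_main <- function(argv) {
  if (length(argv) < 1L) {
    message("usage: sarlogit <simulate|tabulate|fit|report> ",
            "--config <yaml> --out <dir> [--seed <int>] [--results <dir>]")
    return(2L)
  }
  cmd <- argv[[1]]
  opts <- list(
    optparse::make_option("--config", type = "character"),
    optparse::make_option("--out", type = "character"),
    optparse::make_option("--seed", type = "integer", default = NA),
    optparse::make_option("--results", type = "character", default = NA)
  )
  status <- tryCatch({
    oo <- optparse::parse_args(optparse::OptionParser(option_list = opts),
                               args = argv[-1])
    if (is.null(oo$config) || is.null(oo$out)) {
      stop("--config and --out are required", call. = FALSE)
    }
    config <- read_config(oo$config)
    seed <- if (is.na(oo$seed)) NULL else oo$seed
    switch(cmd,
      simulate = run_simulate(config, oo$out,
                              seed = seed %||% config$simulate$seed %||%
                                stop("simulate needs --seed", call. = FALSE)),
      tabulate = run_tabulate(config, oo$out),
      fit = run_fit(config, oo$out, seed = seed),
      report = {
        if (is.na(oo$results)) stop("report needs --results", call. = FALSE)
        run_report(config, oo$results, oo$out)
      },
      stop("unknown subcommand: ", cmd, call. = FALSE)
    )
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  status
}
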