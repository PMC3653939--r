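DATASET_COLUMNS <- c("plot_id", "station_id", "quadrat_id", "species_code",
                     "aug_multiple", "seeds_added", "ambient_seed_rain",
                     "conspecific_density", "census_month", "seedling_count")

#' Validate a quadrat-record table
#'
#' Checks the dataset invariants: all schema columns present, counts and
#' seeds non-negative, control quadrats (augmentation 0) carry zero sown
#' seeds, and seedling counts are non-increasing over censuses within every
#' quadrat (counts reflect pure post-emergence mortality). Violations are
#' reported with row numbers.
#'
#' @param records A data.frame of quadrat records.
#' @return `records`, invisibly, if valid; otherwise an error.
#' @export
validate_records <- function(records) {
  miss <- setdiff(DATASET_COLUMNS, names(records))
  if (length(miss)) {
    stop("dataset schema error: missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  num_cols <- c("aug_multiple", "seeds_added", "ambient_seed_rain",
                "conspecific_density", "census_month", "seedling_count")
  for (cl in num_cols) {
    v <- records[[cl]]
    if (!is.numeric(v) || anyNA(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) | is.na(v))
      stop("dataset error: unparseable or missing '", cl, "' at row(s) ",
           paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
    }
  }
  checks <- list(
    c("seedling_count", "seedling_count must be >= 0"),
    c("seeds_added", "seeds_added must be >= 0"),
    c("aug_multiple", "aug_multiple must be >= 0")
  )
  for (chk in checks) {
    bad <- which(records[[chk[1]]] < 0)
    if (length(bad)) {
      stop("dataset error: ", chk[2], " (row(s) ",
           paste(utils::head(bad, 10), collapse = ", "), ")", call. = FALSE)
    }
  }
  bad <- which(records$aug_multiple == 0 & records$seeds_added != 0)
  if (length(bad)) {
    stop("dataset error: control quadrats must have seeds_added = 0 (row(s) ",
         paste(utils::head(bad, 10), collapse = ", "), ")", call. = FALSE)
  }
  ord <- order(records$quadrat_id, records$species_code,
               records$census_month)
  r <- records[ord, , drop = FALSE]
  same <- r$quadrat_id[-1] == r$quadrat_id[-nrow(r)]
  rising <- r$seedling_count[-1] > r$seedling_count[-nrow(r)]
  bad <- which(same & rising)
  if (length(bad)) {
    rows <- ord[bad + 1]
    stop("dataset error: seedling_count increases over censuses within a ",
         "quadrat (row(s) ", paste(utils::head(rows, 10), collapse = ", "),
         ")", call. = FALSE)
  }
  invisible(records)
}

#' Read a quadrat-record dataset from CSV
#'
#' Columns are matched by name (any order); the schema and invariants of
#' [validate_records()] are enforced.
#'
#' @param path CSV path.
#' @return A validated data.frame of quadrat records in schema column order.
#' @export
read_dataset <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_records(x)
  x[, DATASET_COLUMNS]
}

#' Write a quadrat-record dataset to CSV
#'
#' @param records Quadrat records (validated before writing).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(records, path) {
  validate_records(records)
  utils::write.csv(records[, DATASET_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' Write plot-level effect sizes to CSV
#' @param effects Output of [plot_effect_sizes()] or
#'   [effect_size_time_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_effects <- function(effects, path) {
  utils::write.csv(effects, path, row.names = FALSE)
  invisible(path)
}

#' Write a recruitment fit as JSON
#'
#' Serialises a [fit_model()] result with a stable key order so identical
#' fits produce byte-identical files.
#'
#' @param fit A `recruit_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "recruit_fit"))
  obj <- list(
    model = fit$model,
    census_month = fit$census_month,
    estimates = fit$estimates[c("P0", "Rmax", "k", "sigma_plot", "S_amb")],
    ci = fit$ci,
    loglik = fit$loglik,
    aic = fit$aic,
    n_obs = fit$n_obs,
    n_free_params = fit$n_free_params,
    converged = fit$converged,
    boundary = fit$boundary,
    n_quadrature_nodes = fit$n_quadrature_nodes
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a recruitment fit written by [write_fit_json()]
#' @param path JSON path.
#' @return A [bh_params()] plus fit metadata (list).
#' @export
read_fit_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  est <- obj$estimates
  obj$estimates <- bh_params(P0 = est$P0,
                             Rmax = if (is.null(est$Rmax)) Inf else est$Rmax,
                             k = est$k, sigma_plot = est$sigma_plot,
                             S_amb = est$S_amb)
  obj
}

#' Write a limitation curve (CSV) and its crossovers (JSON)
#' @param curve A [limitation_curve()].
#' @param csv_path,json_path Output paths; either may be `NULL` to skip.
#' @return Invisibly, the paths written.
#' @export
write_limitation <- function(curve, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(curve, "limitation_curve"))
  if (!is.null(csv_path)) {
    utils::write.csv(as.data.frame(curve), csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(crossover_seed_establishment =
             attr(curve, "crossover_seed_establishment"),
           crossover_dd_di = attr(curve, "crossover_dd_di")),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  invisible(c(csv_path, json_path))
}

# ---- pipeline ----------------------------------------------------------

#' Assemble a pipeline configuration
#'
#' @param design An [experiment_design()].
#' @param truth A [true_params()] (used when `simulate = TRUE`).
#' @param rng_seed Integer seed; mandatory whenever any stochastic stage
#'   (simulation, MCMC) is enabled.
#' @param simulate Generate the dataset (`TRUE`) or read it from
#'   `dataset_path`.
#' @param dataset_path CSV to read when `simulate = FALSE`.
#' @param fit Fitting options: `models` (default `c("DD", "DI")`),
#'   `censuses` (`NULL` = all), plus any [fit_model()] `options`.
#' @param mcmc MCMC options: `enabled` (default `FALSE`), `chains`,
#'   `burn_in`, `draws`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(design = experiment_design(),
                            truth = true_params(),
                            rng_seed = NULL,
                            simulate = TRUE,
                            dataset_path = NULL,
                            fit = list(),
                            mcmc = list()) {
  fit <- utils::modifyList(list(models = c("DD", "DI"), censuses = NULL,
                                n_nodes = 12, n_starts = 5), fit)
  mcmc <- utils::modifyList(list(enabled = FALSE, chains = 3,
                                 burn_in = 1000, draws = 1000), mcmc)
  if ((simulate || mcmc$enabled) && is.null(rng_seed)) {
    stop("rng_seed is mandatory when simulation or MCMC is enabled",
         call. = FALSE)
  }
  if (!simulate && is.null(dataset_path)) {
    stop("dataset_path required when simulate = FALSE", call. = FALSE)
  }
  structure(list(design = design, truth = truth, rng_seed = rng_seed,
                 simulate = simulate, dataset_path = dataset_path,
                 fit = fit, mcmc = mcmc),
            class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  plain <- rapply(unclass(config), unclass, how = "replace")
  jsonlite::write_json(plain, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

pipeline_log <- function(level, ...) {
  message(sprintf("[%s] %s %s", level, format(Sys.time(), "%H:%M:%S"),
                  paste0(...)))
}

run_stage <- function(name, manifest_env, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  manifest_env$timings[[name]] <- proc.time()[["elapsed"]] - t0
  pipeline_log("INFO", "stage ", name, " done in ",
               sprintf("%.2fs", manifest_env$timings[[name]]))
  res
}

#' Run the full seed-limitation pipeline
#'
#' Simulate (or load) a dataset, compute effect sizes, optionally fit the
#' hierarchical GLMM, fit the recruitment models at each census, decompose
#' limitation with crossovers, and compute temporal trends. Every artifact
#' is written under `out_dir` and listed, with an MD5 checksum, in
#' `manifest.json` together with the configuration hash, the seed and stage
#' timings. Reruns with the same configuration and seed are
#' checksum-identical.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly (list with `config_hash`, `rng_seed`,
#'   `timings`, `artifacts`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  env <- new.env()
  env$timings <- list()
  paths <- character()

  records <- run_stage("simulate", env, {
    if (config$simulate) {
      r <- simulate_experiment(config$design, config$truth, config$rng_seed)
      write_dataset(r, file.path(out_dir, "dataset.csv"))
      r
    } else {
      read_dataset(config$dataset_path)
    }
  })
  if (config$simulate) paths <- c(paths, file.path(out_dir, "dataset.csv"))

  effects <- run_stage("effects", env, {
    e <- effect_size_time_series(records)
    write_effects(e, file.path(out_dir, "effects.csv"))
    e
  })
  paths <- c(paths, file.path(out_dir, "effects.csv"))

  if (config$mcmc$enabled) {
    run_stage("glmm", env, {
      s <- fit_effect_glmm(records, min(records$census_month),
                           glmm_spec("per_seed"),
                           chains = config$mcmc$chains,
                           burn_in = config$mcmc$burn_in,
                           draws = config$mcmc$draws,
                           rng_seed = config$rng_seed)
      utils::write.csv(s, file.path(out_dir, "glmm_summary.csv"),
                       row.names = FALSE)
      write_draws(s, file.path(out_dir, "glmm_draws.csv"))
      s
    })
    paths <- c(paths, file.path(out_dir, "glmm_summary.csv"),
               file.path(out_dir, "glmm_draws.csv"))
  }

  censuses <- config$fit$censuses %||% sort(unique(records$census_month))
  fit_opts <- config$fit[setdiff(names(config$fit), c("models", "censuses"))]
  fits <- run_stage("fit", env, {
    out <- list()
    for (m in censuses) {
      for (mod in config$fit$models) {
        f <- fit_model(records, m, mod, options = fit_opts)
        p <- file.path(out_dir, sprintf("fit_%s_m%02d.json", tolower(mod), m))
        write_fit_json(f, p)
        paths <- c(paths, p)
        out[[sprintf("%s_m%02d", mod, m)]] <- f
      }
      cmp <- compare_models(out[sprintf("%s_m%02d", config$fit$models, m)])
      cmp$census_month <- m
      p <- file.path(out_dir, sprintf("model_comparison_m%02d.csv", m))
      utils::write.csv(cmp, p, row.names = FALSE)
      paths <- c(paths, p)
    }
    out
  })

  dd_fits <- Filter(function(f) f$model == "DD" && is.finite(f$estimates$Rmax),
                    fits)
  curves <- run_stage("decompose", env, {
    out <- list()
    for (f in dd_fits) {
      cv <- limitation_curve(f$estimates)
      m <- f$census_month
      write_limitation(cv,
                       file.path(out_dir, sprintf("limitation_m%02d.csv", m)),
                       file.path(out_dir, sprintf("crossovers_m%02d.json", m)))
      paths <- c(paths,
                  file.path(out_dir, sprintf("limitation_m%02d.csv", m)),
                  file.path(out_dir, sprintf("crossovers_m%02d.json", m)))
      out[[as.character(m)]] <- cv
    }
    out
  })

  trends <- run_stage("trends", env, {
    out <- list()
    if (length(dd_fits) >= 3) {
      months <- vapply(dd_fits, function(f) f$census_month, numeric(1))
      amb <- vapply(dd_fits, function(f) f$estimates$S_amb, numeric(1))
      for (comp in c("L_S", "L_DI", "L_DD", "L_E")) {
        vals <- mapply(function(f, a) {
          limitation_at(a, f$estimates)[[comp]]
        }, dd_fits, amb)
        tr <- temporal_trend(vals, months, quantity = comp)
        out[[comp]] <- tr[c("quantity", "pearson_r", "t_stat", "df",
                            "p_value", "flag")]
      }
    }
    es <- effect_time_slope(effects)
    out$effect_size_slope <- es
    jsonlite::write_json(out, file.path(out_dir, "trends.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         pretty = TRUE)
    out
  })
  paths <- c(paths, file.path(out_dir, "trends.json"))

  paths <- unique(paths[file.exists(paths)])
  manifest <- list(
    config_hash = config_hash(config),
    rng_seed = config$rng_seed,
    timings = env$timings,
    artifacts = lapply(paths, function(p) {
      list(path = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
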