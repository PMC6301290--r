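# End-to-end orchestration: read -> features -> classify -> model -> report.

#' Build a pipeline configuration
#'
#' Collects every stage's settings in one schema-validated object. Also
#' accepts a YAML file with the same keys via [read_pipeline_config()].
#'
#' @param deployment path to the deployment/physiology CSV.
#' @param accel_dir directory of accelerometer CSVs named
#'   `<event_id>_accel.csv`.
#' @param out_dir output directory.
#' @param window_s,overlap feature-window settings, see [window_features()].
#' @param criteria a [cutoff_criteria()] (or plain list with the same
#'   fields).
#' @param ph_corr a [ph_correction()] (or plain list).
#' @param responses endpoint columns to model.
#' @param n_sims posterior draws per endpoint.
#' @param seed integer master seed.
#' @param k clusters per individual.
#' @param dialect an [accel_dialect()].
#' @return a validated `pipeline_config`.
#' @export
pipeline_config <- function(deployment, accel_dir, out_dir,
                            window_s = 30, overlap = 0.5,
                            criteria = cutoff_criteria(),
                            ph_corr = ph_correction(),
                            responses = c("ph", "lactate", "glucose",
                                          "haematocrit", "sodium", "potassium",
                                          "chloride", "calcium"),
                            n_sims = 1000, seed = 1, k = 3,
                            dialect = accel_dialect()) {
  cfg <- list(deployment = deployment, accel_dir = accel_dir, out_dir = out_dir,
              window_s = window_s, overlap = overlap, criteria = criteria,
              ph_corr = ph_corr, responses = responses, n_sims = n_sims,
              seed = seed, k = k, dialect = dialect)
  validate_pipeline_config(cfg)
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys mirror [pipeline_config()] arguments.
#' @return a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  validate_pipeline_config(y)
}

#' Validate a pipeline configuration before any stage runs
#' @param cfg list of settings.
#' @return the config, classed `pipeline_config`.
#' @export
validate_pipeline_config <- function(cfg) {
  required <- c("deployment", "accel_dir", "out_dir", "window_s", "overlap",
                "criteria", "ph_corr", "responses", "n_sims", "seed")
  miss <- required[vapply(required, function(f) is.null(cfg[[f]]), logical(1))]
  if (length(miss)) {
    stopf("config schema error: missing field(s): %s", paste(miss, collapse = ", "))
  }
  for (f in c("high_amp_g", "low_amp_g", "cycle_s")) {
    if (is.null(cfg$criteria[[f]])) {
      stopf("config schema error: missing criteria$%s", f)
    }
  }
  cfg$criteria <- cutoff_criteria(cfg$criteria$high_amp_g,
                                  cfg$criteria$low_amp_g, cfg$criteria$cycle_s)
  if (is.null(cfg$ph_corr$mode)) stopf("config schema error: missing ph_corr$mode")
  cfg$ph_corr <- ph_correction(cfg$ph_corr$mode, cfg$ph_corr$slope %||% 0)
  if (cfg$overlap < 0 || cfg$overlap >= 1) {
    stopf("config schema error: overlap must lie in [0, 1)")
  }
  if (cfg$window_s < 10) stopf("config schema error: window_s must be >= 10")
  if (is.null(cfg$k)) cfg$k <- 3
  if (is.null(cfg$dialect)) cfg$dialect <- accel_dialect()
  if (!inherits(cfg$dialect, "accel_dialect")) {
    cfg$dialect <- do.call(accel_dialect, cfg$dialect)
  }
  structure(cfg, class = "pipeline_config")
}

.stage <- function(stage, record, expr) {
  tryCatch(expr, error = function(e) {
    stopf("stage '%s' failed for '%s': %s", stage, record, conditionMessage(e))
  })
}

#' Run the full analysis pipeline
#'
#' Stages: read the deployment table; per shark, read the accelerometer
#' trace, compute the vectorial sum and window features, cluster and assign
#' intensity levels, and derive exercise metrics; temperature-correct pH
#' and flag hyperkalemia; fit the endpoint models per species with
#' posterior-simulation intervals; write the labels, metrics and model
#' report plus a run log. Deterministic (byte-identical numeric outputs)
#' for a fixed config and seed. Any stage failure aborts with the stage
#' name and the offending record id.
#'
#' @param config a [pipeline_config()], or a path to a YAML config.
#' @return (invisibly) list: `metrics`, `labels`, `table`, `deployment`,
#'   `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- validate_pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  dep <- .stage("read_deployment", config$deployment,
                read_deployment_table(config$deployment))

  metrics_rows <- list()
  label_rows <- list()
  for (i in seq_len(nrow(dep))) {
    id <- dep$event_id[i]
    path <- file.path(config$accel_dir, paste0(id, "_accel.csv"))
    trace <- .stage("read_accel", id,
                    read_accel_csv(path, dialect = config$dialect, event_id = id))
    res <- .stage("classify", id, classify_trace(
      trace, capture_duration_min = dep$capture_duration_min[i],
      window_s = config$window_s, overlap = config$overlap,
      criteria = config$criteria, k = config$k,
      seed = derive_seed(config$seed, "pipeline", i)
    ))
    metrics_rows[[i]] <- res$metrics
    label_rows[[i]] <- data.frame(
      event_id = id, t_s = res$vs$t_s,
      level = as.character(res$labeled$second_level)
    )
  }
  metrics <- do.call(rbind, metrics_rows)
  labels <- do.call(rbind, label_rows)

  dep <- .stage("physio", "deployment", {
    dep$ph <- correct_ph(dep$ph37, dep$sst_c, config$ph_corr)
    dep$hyperkalemia <- flag_hyperkalemia(dep)
    dep
  })

  merged <- merge(as.data.frame(dep), metrics[, c("event_id", "p_low", "p_med",
                                                  "p_high", "n_seconds")],
                  by = "event_id")
  cis <- list()
  for (sp in unique(merged$species)) {
    sub <- merged[merged$species == sp, , drop = FALSE]
    for (resp in config$responses) {
      ci <- tryCatch({
        fits <- fit_study_models(sub, responses = resp, species = NULL,
                                 n_sims = config$n_sims,
                                 seed = derive_seed(config$seed, "posterior",
                                                    length(cis) + 1L))
        ci <- fits$cis[[resp]]
        ci$species <- sp
        ci
      }, error = function(e) {
        message(sprintf("model skipped for %s/%s: %s", sp, resp,
                        conditionMessage(e)))
        NULL
      })
      if (!is.null(ci)) cis[[paste(sp, resp, sep = ".")]] <- ci
    }
  }
  tab <- significance_table(cis)

  paths <- list(
    metrics = file.path(config$out_dir, "metrics.csv"),
    labels = file.path(config$out_dir, "labels.csv"),
    report_csv = file.path(config$out_dir, "model_report.csv"),
    report_txt = file.path(config$out_dir, "model_report.txt"),
    run_log = file.path(config$out_dir, "run_log.txt")
  )
  write_metrics_table(metrics, paths$metrics)
  utils::write.csv(labels, paths$labels, row.names = FALSE)
  utils::write.csv(as.data.frame(tab), paths$report_csv, row.names = FALSE)
  format_significance_table(tab, paths$report_txt)
  writeLines(c(
    sprintf("fightphys %s | R %s", as.character(utils::packageVersion("fightphys")),
            paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("seed: %d  n_sims: %d  window_s: %g  overlap: %g",
            config$seed, config$n_sims, config$window_s, config$overlap),
    sprintf("criteria: high_amp %g g, low_amp %g g, cycle %g s",
            config$criteria$high_amp_g, config$criteria$low_amp_g,
            config$criteria$cycle_s),
    sprintf("ph correction: %s (slope %g)", config$ph_corr$mode,
            config$ph_corr$slope),
    sprintf("events processed: %d", nrow(metrics)),
    sprintf("models fitted: %d", length(cis))
  ), paths$run_log)

  invisible(list(metrics = metrics, labels = labels, table = tab,
                 deployment = dep, paths = paths))
}
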