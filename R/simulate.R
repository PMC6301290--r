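# Synthetic capture events and blood panels with known ground truth.

# Simulate a per-second level sequence from a row-stochastic matrix using
# geometric dwell times (exactly equivalent to a per-second chain).
.sim_level_seq <- function(n, P, init) {
  lv <- c("low", "med", "high")
  out <- character(0)
  s <- init
  t <- 0L
  while (t < n) {
    p_stay <- P[s, s]
    dwell <- if (p_stay >= 1) n - t else stats::rgeom(1L, 1 - p_stay) + 1L
    dwell <- min(dwell, n - t)
    out <- c(out, rep(s, dwell))
    t <- t + dwell
    if (t < n) {
      off <- P[s, setdiff(lv, s)]
      s <- sample(setdiff(lv, s), 1L, prob = off)
    }
  }
  out
}

# Stationary distribution of a row-stochastic matrix (left eigenvector).
.stationary <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

.truncnorm1 <- function(mean, sd, lower) max(stats::rnorm(1L, mean, sd), lower)

#' Simulate one capture event recorded by a tri-axial logger
#'
#' Generates a hidden per-second exercise-intensity sequence (low/med/high)
#' from the configured Markov chain --- optionally preceded by a single
#' front-loaded struggle bout of high-intensity exercise --- and renders it
#' as a 1-Hz tri-axial acceleration trace. Within each bout the vectorial
#' sum follows `baseline + range * (1 - cos(2*pi*t/period)) / 2`, with the
#' peak-to-trough range and period drawn from that level's distributions;
#' bursts raise the mean signal magnitude above baseline, as thrashing does
#' on a real logger. The target vectorial sum is decomposed onto a fixed
#' random unit orientation per event (hooking orientation is uncontrolled in
#' the field), then each axis is quantized to the logger resolution and
#' clipped to the logger range.
#'
#' @param config a [bout_model_config()].
#' @param seed integer master seed for the event; all internal draws use
#'   documented streams derived from it (see [derive_seed()]).
#' @param duration_min optional capture duration in minutes; if `NULL`,
#'   drawn uniformly from `config$duration_range_min`.
#' @return a list with `trace` (an `accel_trace` data frame: `event_id`,
#'   `t_s`, `x_g`, `y_g`, `z_g`) and `truth` (a `truth_record`: per-second
#'   `level`, exact `p_low`/`p_med`/`p_high`, `duration_min`, `struggle_s`).
#' @examples
#' ev <- simulate_capture_event(bout_model_config(), seed = 1, duration_min = 5)
#' head(ev$trace)
#' ev$truth$p_low + ev$truth$p_med + ev$truth$p_high  # exactly 1
#' @export
simulate_capture_event <- function(config, seed, duration_min = NULL) {
  config <- validate_bout_model_config(config)
  if (config$sample_rate_hz != 1) {
    stopf("only 1-Hz sampling is supported (logger records at 1 Hz)")
  }
  if (is.null(duration_min)) {
    duration_min <- with_stream_seed(seed, "duration", 0L,
      stats::runif(1L, config$duration_range_min[1], config$duration_range_min[2]))
  }
  if (duration_min < config$duration_range_min[1] - 1e-9 ||
      duration_min > config$duration_range_min[2] + 1e-9) {
    stopf("duration_min %.2f outside configured range [%.2f, %.2f]",
          duration_min, config$duration_range_min[1], config$duration_range_min[2])
  }
  n <- max(1L, as.integer(round(duration_min * 60)))

  struggle_s <- 0L
  if (isTRUE(config$front_loaded_struggle)) {
    struggle_s <- with_stream_seed(seed, "struggle", 0L,
      as.integer(round(stats::rexp(1L, 1 / config$struggle_mean_s))))
    struggle_s <- min(struggle_s, n)
  }

  levels_seq <- with_stream_seed(seed, "levels", 0L, {
    rest <- n - struggle_s
    tail_seq <- if (rest > 0) {
      init <- if (struggle_s > 0) "med" else {
        sample(c("low", "med", "high"), 1L, prob = pmax(.stationary(config$transition), 0))
      }
      .sim_level_seq(rest, config$transition, init)
    } else character(0)
    c(rep("high", struggle_s), tail_seq)
  })

  vs_target <- with_stream_seed(seed, "waveform", 0L, {
    runs <- rle(levels_seq)
    segs <- vector("list", length(runs$lengths))
    for (i in seq_along(runs$lengths)) {
      lv <- runs$values[i]
      len <- runs$lengths[i]
      rng <- .truncnorm1(config$amplitude_g[[lv]][["mean"]],
                         config$amplitude_g[[lv]][["sd"]], 0)
      per <- .truncnorm1(config$cycle_s[[lv]][["mean"]],
                         config$cycle_s[[lv]][["sd"]], config$min_cycle_s)
      t_loc <- seq_len(len) - 1
      segs[[i]] <- config$baseline_g + rng * (1 - cos(2 * pi * t_loc / per)) / 2
    }
    unlist(segs, use.names = FALSE)
  })

  u <- with_stream_seed(seed, "orientation", 0L, {
    z <- stats::rnorm(3L)
    z / sqrt(sum(z^2))
  })

  q <- config$quantization_g
  quantize <- function(v) {
    pmin(pmax(round(v / q) * q, -config$clip_g), config$clip_g)
  }
  trace <- data.frame(
    event_id = "event",
    t_s = seq_len(n) - 1,
    x_g = quantize(u[1] * vs_target),
    y_g = quantize(u[2] * vs_target),
    z_g = quantize(u[3] * vs_target)
  )
  class(trace) <- c("accel_trace", "data.frame")
  attr(trace, "sample_rate_hz") <- 1

  lev <- factor(levels_seq, levels = c("low", "med", "high"))
  cnt <- tabulate(lev, nbins = 3L)
  p_low <- cnt[1] / n
  p_med <- cnt[2] / n
  truth <- structure(
    # p_high as the complement of the *rounded* sum keeps
    # p_low + p_med + p_high identically 1 in floating point
    list(level = lev, p_low = p_low, p_med = p_med,
         p_high = 1 - (p_low + p_med),
         duration_min = duration_min, struggle_s = struggle_s),
    class = "truth_record"
  )
  list(trace = trace, truth = truth)
}

#' Simulate one shark's blood panel from exercise metrics and covariates
#'
#' Each endpoint is drawn as `linear predictor + Gaussian noise`, where the
#' linear predictor is `intercept + b1 * logit(p_low) + b2 * duration +
#' b3 * SST + b4 * TL` with the configured coefficients. With residual sd 0
#' the endpoint equals the linear predictor exactly. Concentrations are
#' floored at zero (assay detection floor).
#'
#' @param metrics list or one-row data frame with `p_low` and
#'   `capture_duration_min`.
#' @param covariates list with `sst_c` (deg C) and `tl_cm` (cm).
#' @param config a [physio_response_config()].
#' @param seed integer seed.
#' @return one-row data frame with columns `ph37`, `lactate`, `glucose`,
#'   `haematocrit`, `sodium`, `potassium`, `chloride`, `calcium`
#'   (mmol l^-1 for concentrations, % for haematocrit, i-STAT pH units).
#' @export
simulate_physiology <- function(metrics, covariates, config, seed) {
  for (f in c("p_low", "capture_duration_min")) {
    v <- metrics[[f]]
    if (is.null(v) || length(v) != 1 || is.na(v)) stopf("missing covariate: %s", f)
  }
  for (f in c("sst_c", "tl_cm")) {
    v <- covariates[[f]]
    if (is.null(v) || length(v) != 1 || is.na(v) || !is.finite(v)) {
      stopf("missing covariate: %s", f)
    }
  }
  if (metrics$p_low < 0 || metrics$p_low > 1) stopf("p_low must lie in [0, 1]")
  x <- c(1, logratio_transform(metrics$p_low),
         metrics$capture_duration_min, covariates$sst_c, covariates$tl_cm)
  mu <- drop(config$coefficients %*% x)
  vals <- with_stream_seed(seed, "physio", 0L,
                           mu + stats::rnorm(length(mu)) * config$sigma)
  conc <- c("lactate", "glucose", "sodium", "potassium", "chloride", "calcium")
  vals[conc] <- pmax(vals[conc], 0)
  vals["haematocrit"] <- min(max(vals[["haematocrit"]], 0), 100)
  out <- as.data.frame(as.list(vals))
  names(out)[names(out) == "ph"] <- "ph37"
  out
}

# Draw covariates (SST, TL, p_low, duration) from the configured study
# distributions; shared by simulate_panel_study() and simulate_study().
.draw_covariates <- function(n, config, seed) {
  cv <- config$covariates
  with_stream_seed(seed, "covariates", 0L, {
    clamp <- function(x, r) pmin(pmax(x, r[["min"]]), r[["max"]])
    data.frame(
      p_low = stats::rbeta(n, cv$p_low_shape[["a"]], cv$p_low_shape[["b"]]),
      capture_duration_min = stats::runif(n, cv$duration_range_min[1],
                                          cv$duration_range_min[2]),
      sst_c = clamp(stats::rnorm(n, cv$sst_c[["mean"]], cv$sst_c[["sd"]]), cv$sst_c),
      tl_cm = clamp(stats::rnorm(n, cv$tl_cm[["mean"]], cv$tl_cm[["sd"]]), cv$tl_cm)
    )
  })
}

#' Simulate a study of blood panels without accelerometer traces
#'
#' Fast path for statistical validation: draws exercise/covariate values
#' from the configured study distributions (beta-distributed `p_low`,
#' uniform capture duration, truncated-normal SST and TL) and generates the
#' blood panel from the linear response models. Used to check estimator
#' calibration (coverage, type-I error, power to recover the configured
#' effects) at study sizes matching the field data.
#'
#' @param n_sharks number of sharks.
#' @param config a [physio_response_config()].
#' @param seed integer seed.
#' @return data frame with `event_id`, `species`, the exercise/covariate
#'   columns and the eight panel endpoints (`ph37`, ...).
#' @export
simulate_panel_study <- function(n_sharks, config, seed) {
  stopifnot(n_sharks >= 1)
  cov <- .draw_covariates(n_sharks, config, seed)
  X <- cbind(1, logratio_transform(cov$p_low), cov$capture_duration_min,
             cov$sst_c, cov$tl_cm)
  mu <- X %*% t(config$coefficients)  # n x 8
  noise <- with_stream_seed(seed, "physio", 0L, {
    matrix(stats::rnorm(n_sharks * ncol(mu)), n_sharks) *
      rep(config$sigma, each = n_sharks)
  })
  panel <- mu + noise
  colnames(panel) <- .panel_endpoints
  conc <- c("lactate", "glucose", "sodium", "potassium", "chloride", "calcium")
  panel[, conc] <- pmax(panel[, conc], 0)
  panel[, "haematocrit"] <- pmin(pmax(panel[, "haematocrit"], 0), 100)
  out <- data.frame(
    event_id = sprintf("ev%03d", seq_len(n_sharks)),
    species = config$species, cov, panel
  )
  names(out)[names(out) == "ph"] <- "ph37"
  out
}

#' Simulate a full study: accelerometer files, deployment table, truth
#'
#' Generates `n_sharks` capture events with the bout model, draws SST and TL
#' per shark, generates blood panels from the *true* exercise metrics (so
#' downstream recovery tests have a known target), and writes the same file
#' formats the readers consume: one accelerometer CSV per shark, a
#' deployment/physiology CSV, and a JSON truth sidecar (true proportions,
#' run-length-encoded level sequence, coefficients used).
#'
#' @param n_sharks number of sharks (>= 1).
#' @param bout_cfg a [bout_model_config()].
#' @param physio_cfg a [physio_response_config()].
#' @param seed integer master seed.
#' @param dir output directory (created if needed).
#' @return (invisibly) list with `deployment` (data frame), `truth` (list of
#'   `truth_record`s keyed by event id), and the written `paths`.
#' @export
simulate_study <- function(n_sharks, bout_cfg, physio_cfg, seed, dir) {
  stopifnot(n_sharks >= 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cov <- .draw_covariates(n_sharks, physio_cfg, derive_seed(seed, "study", 0L))

  rows <- vector("list", n_sharks)
  truth <- list()
  accel_paths <- character(n_sharks)
  for (i in seq_len(n_sharks)) {
    id <- sprintf("ev%03d", i)
    ev_seed <- derive_seed(seed, "study", i)
    ev <- simulate_capture_event(bout_cfg, seed = ev_seed)
    ev$trace$event_id <- id
    panel <- simulate_physiology(
      metrics = list(p_low = ev$truth$p_low,
                     capture_duration_min = ev$truth$duration_min),
      covariates = list(sst_c = cov$sst_c[i], tl_cm = cov$tl_cm[i]),
      config = physio_cfg, seed = derive_seed(ev_seed, "physio", i)
    )
    accel_paths[i] <- file.path(dir, paste0(id, "_accel.csv"))
    write_accel_csv(ev$trace, accel_paths[i])
    rows[[i]] <- data.frame(
      event_id = id, species = physio_cfg$species,
      tl_cm = round(cov$tl_cm[i], 1), sst_c = round(cov$sst_c[i], 1),
      capture_duration_min = round(ev$truth$duration_min, 2), panel
    )
    truth[[id]] <- ev$truth
  }
  deployment <- do.call(rbind, rows)
  dep_path <- file.path(dir, "deployment.csv")
  write_deployment_table(deployment, dep_path)

  truth_json <- lapply(truth, function(tr) {
    r <- rle(as.character(tr$level))
    list(p_low = tr$p_low, p_med = tr$p_med, p_high = tr$p_high,
         duration_min = tr$duration_min, struggle_s = tr$struggle_s,
         level_rle = list(lengths = r$lengths, values = r$values))
  })
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(seed = seed, species = physio_cfg$species,
         coefficients = as.data.frame(physio_cfg$coefficients),
         sigma = as.list(physio_cfg$sigma), events = truth_json),
    truth_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(list(
    deployment = deployment, truth = truth,
    paths = list(accel = accel_paths, deployment = dep_path, truth = truth_path)
  ))
}
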