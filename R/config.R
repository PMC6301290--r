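#' Default per-second transition matrix for the bout model
#'
#' Row-stochastic matrix of per-second transition probabilities between the
#' three exercise-intensity levels. The defaults correspond to mean bout
#' dwell times of 600 s (low), 180 s (medium) and 90 s (high) --- resting
#' bouts lasting minutes, struggling bouts lasting around a minute and a
#' half --- with exits from each level split 3:1 towards the nearer level.
#'
#' @param dwell_s named numeric vector of mean dwell times in seconds for
#'   `low`, `med`, `high`.
#' @return a 3x3 row-stochastic matrix with dimnames `low`, `med`, `high`.
#' @export
default_transition_matrix <- function(dwell_s = c(low = 600, med = 180, high = 90)) {
  stopifnot(all(c("low", "med", "high") %in% names(dwell_s)), all(dwell_s > 0))
  leave <- 1 / dwell_s
  P <- rbind(
    low  = c(1 - leave[["low"]],        0.75 * leave[["low"]],  0.25 * leave[["low"]]),
    med  = c(0.75 * leave[["med"]],     1 - leave[["med"]],     0.25 * leave[["med"]]),
    high = c(0.25 * leave[["high"]],    0.75 * leave[["high"]], 1 - leave[["high"]])
  )
  colnames(P) <- c("low", "med", "high")
  P
}

#' Bout-model configuration for synthetic capture events
#'
#' Describes the generative model for a capture event recorded by a 1-Hz
#' tri-axial logger: a hidden per-second Markov chain over the three
#' exercise-intensity levels, a within-bout oscillation whose peak-to-trough
#' range ("amplitude") and period ("cycle") are drawn per bout from
#' level-specific normal distributions, a static vectorial-sum baseline near
#' 1 g, and the logger's quantization and clipping. An optional front-loaded
#' struggle --- a single initial high-intensity bout of exponential duration
#' --- reproduces the field observation that struggling concentrates early
#' in the capture event.
#'
#' Amplitude means must be ordered low < med < high. Defaults straddle the
#' classification cutoffs (0.05 g and 0.25 g) with wide margins but are
#' otherwise uncalibrated: the source data report only the cutoffs, not
#' per-level signal distributions.
#'
#' @param amplitude_g per-level `c(mean, sd)` of the peak-to-trough
#'   vectorial-sum range within a bout, in g.
#' @param cycle_s per-level `c(mean, sd)` of the oscillation period, s.
#' @param transition 3x3 row-stochastic per-second transition matrix
#'   (rows/cols low, med, high).
#' @param baseline_g static vectorial-sum offset; a motionless logger reads
#'   1 g.
#' @param sample_rate_hz sampling rate; the supported logger records at 1 Hz.
#' @param quantization_g logger resolution (0.025 g).
#' @param clip_g logger range (+- 3 g).
#' @param duration_range_min min/max of the uniform capture-duration draw,
#'   minutes; default spans the durations observed in the field study the
#'   generator emulates (2.57-264.88 min).
#' @param front_loaded_struggle if `TRUE` (default) every event starts with
#'   a single high-intensity struggle bout.
#' @param struggle_mean_s mean duration (s) of the initial struggle bout.
#' @param min_cycle_s floor for drawn cycle periods; 1-Hz sampling cannot
#'   resolve cycles below 2 s, so draws are truncated just above that.
#' @return an object of class `bout_model_config`.
#' @export
bout_model_config <- function(amplitude_g = list(low = c(mean = 0.02, sd = 0.005),
                                                 med = c(mean = 0.15, sd = 0.03),
                                                 high = c(mean = 0.60, sd = 0.10)),
                              cycle_s = list(low = c(mean = 10, sd = 2),
                                             med = c(mean = 7, sd = 1),
                                             high = c(mean = 3, sd = 0.4)),
                              transition = default_transition_matrix(),
                              baseline_g = 1.0,
                              sample_rate_hz = 1,
                              quantization_g = 0.025,
                              clip_g = 3.0,
                              duration_range_min = c(2.57, 264.88),
                              front_loaded_struggle = TRUE,
                              struggle_mean_s = 180,
                              min_cycle_s = 2.2) {
  cfg <- structure(
    list(amplitude_g = amplitude_g, cycle_s = cycle_s, transition = transition,
         baseline_g = baseline_g, sample_rate_hz = sample_rate_hz,
         quantization_g = quantization_g, clip_g = clip_g,
         duration_range_min = duration_range_min,
         front_loaded_struggle = front_loaded_struggle,
         struggle_mean_s = struggle_mean_s, min_cycle_s = min_cycle_s),
    class = "bout_model_config"
  )
  validate_bout_model_config(cfg)
}

validate_bout_model_config <- function(cfg) {
  lv <- c("low", "med", "high")
  P <- cfg$transition
  if (!is.matrix(P) || !all(dim(P) == c(3, 3))) {
    stopf("transition matrix must be 3x3")
  }
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-12)) {
    stopf("transition matrix must be row-stochastic (rows sum to 1 within 1e-12)")
  }
  if (!all(lv %in% names(cfg$amplitude_g)) || !all(lv %in% names(cfg$cycle_s))) {
    stopf("amplitude_g and cycle_s must have entries for low, med, high")
  }
  amp_means <- vapply(cfg$amplitude_g[lv], function(x) x[["mean"]], numeric(1))
  if (!(amp_means[1] < amp_means[2] && amp_means[2] < amp_means[3])) {
    stopf("amplitude means must be ordered low < med < high")
  }
  pars <- unlist(c(cfg$amplitude_g, cfg$cycle_s))
  if (any(!is.finite(pars)) || any(pars < 0)) {
    stopf("amplitude/cycle distribution parameters must be finite and non-negative")
  }
  if (cfg$quantization_g <= 0) stopf("quantization_g must be > 0")
  if (cfg$clip_g <= 0) stopf("clip_g must be > 0")
  d <- cfg$duration_range_min
  if (length(d) != 2 || d[1] <= 0 || d[2] < d[1]) {
    stopf("duration_range_min must be an increasing positive pair")
  }
  if (cfg$sample_rate_hz <= 0) stopf("sample_rate_hz must be > 0")
  cfg
}

.panel_endpoints <- c("ph", "lactate", "glucose", "haematocrit",
                      "sodium", "potassium", "chloride", "calcium")
.coef_terms <- c("intercept", "p_low_lr", "capture_duration_min", "sst_c", "tl_cm")

#' Physiological-response configuration
#'
#' Coefficients of the per-endpoint linear response models used by the
#' blood-panel generator: each endpoint is
#' `intercept + b1 * logit(p_low) + b2 * duration + b3 * SST + b4 * TL`
#' plus Gaussian noise. Also carries the draw distributions for covariates
#' used when panels are simulated without accelerometer traces.
#'
#' @param species `"nurse"`, `"caribbean_reef"` or `"other"`.
#' @param coefficients numeric matrix, one row per endpoint (`ph`, `lactate`,
#'   `glucose`, `haematocrit`, `sodium`, `potassium`, `chloride`, `calcium`),
#'   columns `intercept`, `p_low_lr`, `capture_duration_min`, `sst_c`,
#'   `tl_cm`.
#' @param sigma named vector of residual standard deviations per endpoint
#'   (units of the endpoint); all must be >= 0.
#' @param covariates list with `sst_c = c(mean, sd, min, max)` (deg C),
#'   `tl_cm = c(mean, sd, min, max)` (cm), `p_low_shape = c(a, b)` (beta
#'   shape parameters for the proportion of time at low intensity) and
#'   `duration_range_min = c(min, max)` (minutes).
#' @return an object of class `physio_response_config`.
#' @seealso [nurse_physio_config()], [reef_physio_config()]
#' @export
physio_response_config <- function(species, coefficients, sigma, covariates) {
  if (is.data.frame(coefficients)) coefficients <- as.matrix(coefficients)
  if (!all(.panel_endpoints %in% rownames(coefficients))) {
    stopf("coefficients must have rows for: %s",
          paste(.panel_endpoints, collapse = ", "))
  }
  if (!all(.coef_terms %in% colnames(coefficients))) {
    stopf("coefficients must have columns: %s", paste(.coef_terms, collapse = ", "))
  }
  if (!all(.panel_endpoints %in% names(sigma))) {
    stopf("sigma must be named for every endpoint")
  }
  if (any(sigma < 0) || any(!is.finite(sigma))) {
    stopf("residual sds must be finite and >= 0")
  }
  if (any(!is.finite(coefficients))) stopf("coefficients must be finite")
  for (f in c("sst_c", "tl_cm", "p_low_shape", "duration_range_min")) {
    if (is.null(covariates[[f]])) stopf("covariates must include '%s'", f)
  }
  structure(
    list(species = species,
         coefficients = coefficients[.panel_endpoints, .coef_terms],
         sigma = sigma[.panel_endpoints], covariates = covariates),
    class = "physio_response_config"
  )
}

.make_coef <- function(rows) {
  m <- matrix(0, nrow = length(.panel_endpoints), ncol = length(.coef_terms),
              dimnames = list(.panel_endpoints, .coef_terms))
  for (ep in names(rows)) m[ep, names(rows[[ep]])] <- rows[[ep]]
  m
}

#' Nurse-shark calibrated physiology generator
#'
#' Calibrated so that simulated endpoint means and spreads approximate the
#' descriptive statistics reported for longline-captured nurse sharks, with
#' nonzero slopes only for the effects that study found credible: blood pH
#' increases with the (logit-transformed) proportion of low-intensity
#' exercise and with capture duration; glucose and plasma potassium increase
#' with SST; potassium decreases with TL. Residual standard deviations come
#' from decomposing the reported total SDs into covariate-explained and
#' residual parts.
#'
#' @return a [physio_response_config()].
#' @export
nurse_physio_config <- function() {
  # intercepts place the endpoint mean at the mean covariate vector
  # (logit(0.529) = 0.115, 95.7 min, 27.5 C, 206.7 cm)
  coef <- .make_coef(list(
    ph          = c(intercept = 7.3260, p_low_lr = 0.065,
                    capture_duration_min = 8e-04),
    lactate     = c(intercept = 1.13),
    glucose     = c(intercept = -14.83, sst_c = 1.265),
    haematocrit = c(intercept = 17.42),
    sodium      = c(intercept = 255.94),
    potassium   = c(intercept = -5.60, sst_c = 0.53, tl_cm = -0.015),
    chloride    = c(intercept = 247.41),
    calcium     = c(intercept = 4.91)
  ))
  sigma <- c(ph = 0.07, lactate = 0.82, glucose = 4.70, haematocrit = 4.41,
             sodium = 35.1, potassium = 0.76, chloride = 16.4, calcium = 0.98)
  physio_response_config(
    species = "nurse", coefficients = coef, sigma = sigma,
    covariates = list(
      sst_c = c(mean = 27.51, sd = 2.14, min = 22.8, max = 30.0),
      tl_cm = c(mean = 206.68, sd = 27.06, min = 125, max = 260),
      p_low_shape = c(a = 5.99, b = 5.34),
      duration_range_min = c(5.33, 264.88)
    )
  )
}

#' Caribbean-reef-shark calibrated physiology generator
#'
#' Same structure as [nurse_physio_config()], calibrated to the reef-shark
#' descriptive statistics: blood lactate increases and plasma chloride
#' decreases with capture duration; other endpoints carry no covariate
#' effect.
#'
#' @return a [physio_response_config()].
#' @export
reef_physio_config <- function() {
  coef <- .make_coef(list(
    ph          = c(intercept = 7.30),
    lactate     = c(intercept = 2.90, capture_duration_min = 0.075),
    glucose     = c(intercept = 10.39),
    haematocrit = c(intercept = 20.32),
    sodium      = c(intercept = 269.67),
    potassium   = c(intercept = 6.34),
    chloride    = c(intercept = 244.82, capture_duration_min = -0.125),
    calcium     = c(intercept = 5.51)
  ))
  sigma <- c(ph = 0.18, lactate = 5.0, glucose = 3.43, haematocrit = 5.74,
             sodium = 39.3, potassium = 1.44, chloride = 9.2, calcium = 1.07)
  physio_response_config(
    species = "caribbean_reef", coefficients = coef, sigma = sigma,
    covariates = list(
      sst_c = c(mean = 26.58, sd = 2.01, min = 23.5, max = 31.6),
      tl_cm = c(mean = 148.97, sd = 31.34, min = 82, max = 211),
      p_low_shape = c(a = 7.68, b = 7.53),
      duration_range_min = c(2.57, 179.58)
    )
  )
}
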