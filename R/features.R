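# Vectorial-sum signal and windowed amplitude/cycle features.

#' Vectorial sum of a tri-axial trace
#'
#' Per-sample magnitude `sqrt(x^2 + y^2 + z^2)` of the tri-axial
#' acceleration, in g. A motionless logger reads 1 g regardless of
#' orientation, which is why the downstream amplitude feature is defined as
#' a peak-to-trough *range* rather than a raw magnitude.
#'
#' @param trace an `accel_trace` (columns `event_id`, `t_s`, `x_g`, `y_g`,
#'   `z_g`).
#' @return a `vs_trace` data frame (`event_id`, `t_s`, `vs_g`).
#' @examples
#' tr <- data.frame(event_id = "e", t_s = 0:2,
#'                  x_g = c(3, 0, 0), y_g = c(4, 0, 0), z_g = c(0, 1, 0))
#' vectorial_sum(tr)$vs_g  # 5, 1, 0
#' @export
vectorial_sum <- function(trace) {
  need <- c("t_s", "x_g", "y_g", "z_g")
  miss <- setdiff(need, names(trace))
  if (length(miss)) stopf("trace missing column(s): %s", paste(miss, collapse = ", "))
  out <- data.frame(
    event_id = if (!is.null(trace$event_id)) trace$event_id else "event",
    t_s = trace$t_s,
    vs_g = sqrt(trace$x_g^2 + trace$y_g^2 + trace$z_g^2)
  )
  class(out) <- c("vs_trace", "data.frame")
  out
}

# Local maxima of a vector with adjacent-valley prominence, robust to the
# flat-topped plateaus a quantized logger produces. Returns fractional
# 0-based sample positions (plateau centres).
.find_peaks <- function(x, prom_min) {
  r <- rle(x)
  v <- r$values
  m <- length(v)
  if (m < 3) return(numeric(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  centers <- (starts + ends) / 2 - 1  # 0-based
  cand <- which(v[2:(m - 1)] > v[1:(m - 2)] & v[2:(m - 1)] > v[3:m]) + 1L
  if (!length(cand)) return(numeric(0))
  keep <- logical(length(cand))
  for (j in seq_along(cand)) {
    i <- cand[j]
    left_lo <- if (j == 1) min(v[1:(i - 1)]) else min(v[cand[j - 1]:(i - 1)])
    right_hi <- if (j == length(cand)) m else cand[j + 1]
    right_lo <- min(v[(i + 1):right_hi])
    keep[j] <- (v[i] - max(left_lo, right_lo)) >= prom_min
  }
  centers[cand[keep]]
}

#' Windowed amplitude and cycle features of a vectorial-sum trace
#'
#' Tiles the trace with windows of `window_s` seconds at the given overlap
#' and computes, per window: `amplitude_g`, the peak-to-trough range
#' `max(vs) - min(vs)` (translation-invariant, so the ~1 g static baseline
#' drops out); and `cycle_s`, the mean spacing of local maxima of the
#' mean-removed signal whose prominence exceeds
#' `max(prom_frac * amplitude, min_prom_g)`. The absolute prominence floor
#' (default two logger quanta, 0.05 g) keeps 0.025-g quantization noise from
#' generating spurious cycles in near-static windows. Windows with fewer
#' than two qualifying peaks get the no-cycle sentinel `cycle_s = window_s`
#' (treated as a slow, > 5 s cycle downstream, with `no_cycle = TRUE`).
#' Estimated cycles below `min_cycle_s` are floored there and flagged:
#' 1-Hz sampling cannot resolve cycles shorter than 2 s.
#'
#' @param vs a `vs_trace` from [vectorial_sum()].
#' @param window_s window length in seconds (>= 10 at 1 Hz, or cycle
#'   estimation is degenerate).
#' @param overlap fractional overlap between consecutive windows, in
#'   `[0, 1)`.
#' @param prom_frac peak prominence threshold as a fraction of the window
#'   amplitude.
#' @param min_prom_g absolute prominence floor in g.
#' @param min_cycle_s resolution floor for estimated cycles, s.
#' @return a `feature_windows` data frame (`event_id`, `start_s`, `end_s`
#'   half-open, `n_samples`, `amplitude_g`, `cycle_s`, `no_cycle`,
#'   `cycle_floored`), with attributes `window_s`, `overlap`, `n_seconds`.
#' @export
window_features <- function(vs, window_s = 30, overlap = 0.5,
                            prom_frac = 0.25, min_prom_g = 0.05,
                            min_cycle_s = 2) {
  if (window_s < 10) stopf("window_s must be >= 10 s at 1 Hz sampling")
  if (overlap < 0 || overlap >= 1) stopf("overlap must lie in [0, 1)")
  x <- vs$vs_g
  n <- length(x)
  if (any(!is.finite(x)) || any(x < 0)) stopf("vectorial sum must be finite and >= 0")
  w <- as.integer(round(window_s))
  if (w > n) {
    warnf("window (%d s) longer than trace (%d s); using a single full-trace window",
          w, n)
    w <- n
  }
  step <- max(1L, as.integer(round(w * (1 - overlap))))
  starts <- seq(0L, n - w, by = step)
  feats <- lapply(starts, function(s) {
    seg <- x[(s + 1):(s + w)]
    amp <- max(seg) - min(seg)
    no_cycle <- TRUE
    floored <- FALSE
    cyc <- as.numeric(window_s)
    if (amp > 0) {
      pk <- .find_peaks(seg - mean(seg), max(prom_frac * amp, min_prom_g))
      if (length(pk) >= 2) {
        no_cycle <- FALSE
        cyc <- mean(diff(pk))
        if (cyc < min_cycle_s) {
          cyc <- min_cycle_s
          floored <- TRUE
        }
      }
    }
    c(amp = amp, cyc = cyc, no_cycle = as.numeric(no_cycle),
      floored = as.numeric(floored))
  })
  feats <- do.call(rbind, feats)
  out <- data.frame(
    event_id = vs$event_id[1],
    start_s = as.numeric(starts),
    end_s = as.numeric(starts + w),
    n_samples = w,
    amplitude_g = feats[, "amp"],
    cycle_s = feats[, "cyc"],
    no_cycle = feats[, "no_cycle"] > 0,
    cycle_floored = feats[, "floored"] > 0
  )
  class(out) <- c("feature_windows", "data.frame")
  attr(out, "window_s") <- window_s
  attr(out, "overlap") <- overlap
  attr(out, "n_seconds") <- n
  out
}

#' Write a feature table as CSV
#' @param features a `feature_windows` data frame.
#' @param path output file.
#' @export
write_feature_table <- function(features, path) {
  utils::write.csv(
    features[, c("event_id", "start_s", "end_s", "amplitude_g", "cycle_s")],
    path, row.names = FALSE)
  invisible(path)
}
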