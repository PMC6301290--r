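# k-means segmentation, cutoff-rule assignment, exercise metrics.

make_blob_features <- function(n_per = 20, seed = 4) {
  withr::with_seed(seed, {
    amps <- c(rnorm(n_per, 0.02, 0.002), rnorm(n_per, 0.12, 0.005),
              rnorm(n_per, 0.50, 0.01))
    cycs <- c(rnorm(n_per, 10, 0.5), rnorm(n_per, 7, 0.3), rnorm(n_per, 3, 0.1))
  })
  fw <- data.frame(event_id = "e", start_s = seq(0, by = 15,
                                                 length.out = 3 * n_per),
                   end_s = seq(30, by = 15, length.out = 3 * n_per),
                   n_samples = 30, amplitude_g = pmax(amps, 0.001),
                   cycle_s = pmax(cycs, 2), no_cycle = FALSE,
                   cycle_floored = FALSE)
  class(fw) <- c("feature_windows", "data.frame")
  attr(fw, "n_seconds") <- max(fw$end_s)
  fw
}

test_that("well-separated feature blobs are partitioned exactly", {
  fw <- make_blob_features()
  cl <- cluster_event(fw, k = 3, seed = 9)
  truth <- rep(1:3, each = 20)
  expect_equal(cl$cluster, truth)  # relabelled by ascending centroid amplitude
  # oracle: brute-force nearest-centre assignment on the standardized space
  X <- scale(cbind(fw$amplitude_g, log(fw$cycle_s)))
  centers <- apply(X, 2, function(col) tapply(col, cl$cluster, mean))
  d <- as.matrix(dist(rbind(X, centers)))[1:60, 61:63]
  expect_equal(unname(apply(d, 1, which.min)), cl$cluster)
})

test_that("clustering is deterministic for a fixed seed and collapses when degenerate", {
  fw <- make_blob_features()
  a <- cluster_event(fw, k = 3, seed = 1)
  b <- cluster_event(fw, k = 3, seed = 1)
  expect_identical(a$cluster, b$cluster)
  flat <- fw
  flat$amplitude_g <- 0.1
  flat$cycle_s <- 6
  expect_warning(cl <- cluster_event(flat, k = 3, seed = 1), "k reduced")
  expect_equal(cl$k, 1)
  expect_true(all(cl$cluster == 1))
})

test_that("the cutoff rule matches the published criteria on all branches", {
  crit <- cutoff_criteria()
  expect_equal(as.character(intensity_level(0.30, 3, crit)), "high")
  expect_equal(as.character(intensity_level(0.30, 8, crit)), "med")
  expect_equal(as.character(intensity_level(0.03, 2, crit)), "low")
  expect_equal(as.character(intensity_level(0.10, 2, crit)), "med")
  # strict inequalities: boundary values fall to medium
  expect_equal(as.character(intensity_level(0.25, 3, crit)), "med")
  expect_equal(as.character(intensity_level(0.05, 10, crit)), "med")
  expect_equal(as.character(intensity_level(0.30, 5, crit)), "med")
})

test_that("level assignment is monotone in cluster amplitude", {
  crit <- cutoff_criteria()
  ranks <- c(low = 1, med = 2, high = 3)
  for (cyc in c(2, 4.9, 5, 8)) {
    lev <- ranks[as.character(intensity_level(seq(0.001, 0.6, by = 0.001),
                                              cyc, crit))]
    expect_true(all(diff(lev) >= 0))
  }
})

test_that("labels are invariant to cluster index permutation", {
  fw <- make_blob_features()
  cl <- cluster_event(fw, k = 3, seed = 2)
  lab <- assign_levels(cl, fw)
  perm <- c(2, 3, 1)
  cl2 <- cl
  cl2$cluster <- perm[cl$cluster]
  lab2 <- assign_levels(cl2, fw)
  expect_identical(lab2$window_level, lab$window_level)
  expect_identical(lab2$second_level, lab$second_level)
})

test_that("cluster medians, not single windows, drive the level", {
  fw <- make_blob_features()
  cl <- cluster_event(fw, k = 3, seed = 2)
  lab <- assign_levels(cl, fw)
  expect_equal(lab$cluster_level, c("low", "med", "high"))
  expect_true(all(as.character(lab$window_level) ==
                    lab$cluster_level[cl$cluster]))
  # every second labelled exactly once
  expect_false(anyNA(lab$second_level))
  expect_length(lab$second_level, attr(fw, "n_seconds"))
  # window mode applies the rule per window
  labw <- assign_levels(cl, fw, mode = "window")
  expect_equal(as.character(labw$window_level),
               as.character(intensity_level(fw$amplitude_g, fw$cycle_s)))
})

test_that("exercise metrics count labelled seconds and integrate the signal", {
  lab <- structure(list(event_id = "e",
                        second_level = factor(rep(c("low", "high"), each = 50),
                                              levels = c("low", "med", "high")),
                        k = 2),
                   class = "labeled_event")
  vs <- as_vs_trace(rep(0.5, 100))
  m <- exercise_metrics(lab, vs, capture_duration_min = 100 / 60)
  expect_equal(m$p_low, 0.5)
  expect_equal(m$p_med, 0)
  expect_equal(m$p_high, 0.5)
  expect_identical(m$p_low + m$p_med + m$p_high, 1)
  # vs = 0.5 g over 120 samples in 2 min -> 30 g/min
  vs2 <- as_vs_trace(rep(0.5, 120))
  lab2 <- structure(list(event_id = "e",
                         second_level = factor(rep("low", 120),
                                               levels = c("low", "med", "high")),
                         k = 1),
                    class = "labeled_event")
  m2 <- exercise_metrics(lab2, vs2, capture_duration_min = 2)
  expect_equal(m2$mean_fight_intensity, 30)
  expect_equal(m2$p_low, 1)
  expect_error(exercise_metrics(lab2, vs2, capture_duration_min = 0), "> 0")
})

test_that("proportions sum to exactly one for simulated events end to end", {
  for (s in 1:5) {
    ev <- simulate_capture_event(short_bout_config(), seed = s)
    res <- classify_trace(ev$trace, capture_duration_min = ev$truth$duration_min,
                          seed = s)
    expect_identical(res$metrics$p_low + res$metrics$p_med + res$metrics$p_high, 1)
  }
})
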