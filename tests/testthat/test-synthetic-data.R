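# Bout-model and blood-panel generators: determinism, ground truth,
# logger artefacts, calibration.

test_that("an absorbing low state yields p_low = 1", {
  P <- rbind(low = c(1, 0, 0), med = c(0.2, 0.8, 0), high = c(0, 0.2, 0.8))
  colnames(P) <- c("low", "med", "high")
  cfg <- bout_model_config(transition = P, front_loaded_struggle = FALSE)
  ev <- simulate_capture_event(cfg, seed = 3, duration_min = 5)
  expect_identical(ev$truth$p_low, 1)
  expect_true(all(ev$truth$level == "low"))
})

test_that("the same config and seed reproduce the trace exactly", {
  cfg <- bout_model_config()
  a <- simulate_capture_event(cfg, seed = 42)
  b <- simulate_capture_event(cfg, seed = 42)
  expect_identical(a$trace, b$trace)
  expect_identical(a$truth$level, b$truth$level)
  c <- simulate_capture_event(cfg, seed = 43)
  expect_false(identical(a$trace$x_g, c$trace$x_g))
})

test_that("level occupancy converges to the chain's stationary distribution", {
  # rows all equal to the target distribution; oracle: eigen-decomposition
  target <- c(low = 0.5, med = 0.3, high = 0.2)
  P <- rbind(low = target, med = target, high = target)
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  stat <- v / sum(v)
  expect_equal(stat, unname(target), tolerance = 1e-12)
  cfg <- bout_model_config(transition = P, front_loaded_struggle = FALSE)
  ev <- simulate_capture_event(cfg, seed = 5, duration_min = 10000 / 60)
  occ <- as.numeric(table(ev$truth$level) / length(ev$truth$level))
  expect_true(all(abs(occ - stat) <= 0.03))
})

test_that("trace values are quantized multiples within the logger range", {
  cfg <- bout_model_config()
  ev <- simulate_capture_event(cfg, seed = 8, duration_min = 20)
  for (ax in c("x_g", "y_g", "z_g")) {
    v <- ev$trace[[ax]]
    expect_true(all(abs(v / cfg$quantization_g - round(v / cfg$quantization_g)) < 1e-9))
    expect_true(all(v >= -cfg$clip_g & v <= cfg$clip_g))
  }
  expect_identical(ev$truth$p_low + ev$truth$p_med + ev$truth$p_high, 1)
  expect_length(ev$truth$level, nrow(ev$trace))
})

test_that("invalid bout configs are rejected", {
  P <- default_transition_matrix()
  P[1, 1] <- P[1, 1] + 1e-6
  expect_error(bout_model_config(transition = P), "row-stochastic")
  expect_error(bout_model_config(quantization_g = 0), "quantization")
  expect_error(
    bout_model_config(amplitude_g = list(low = c(mean = 0.5, sd = 0.01),
                                         med = c(mean = 0.15, sd = 0.03),
                                         high = c(mean = 0.6, sd = 0.1))),
    "ordered")
  expect_error(
    simulate_capture_event(bout_model_config(), seed = 1, duration_min = 400),
    "outside configured range")
})

test_that("zero-noise panels equal the linear predictor", {
  coef <- matrix(0, 8, 5,
                 dimnames = list(c("ph", "lactate", "glucose", "haematocrit",
                                   "sodium", "potassium", "chloride", "calcium"),
                                 c("intercept", "p_low_lr",
                                   "capture_duration_min", "sst_c", "tl_cm")))
  coef["ph", "intercept"] <- 7.41
  sigma <- setNames(rep(0, 8), rownames(coef))
  cfg <- physio_response_config("nurse", coef, sigma,
                                nurse_physio_config()$covariates)
  panel <- simulate_physiology(list(p_low = 0.5, capture_duration_min = 60),
                               list(sst_c = 27, tl_cm = 200), cfg, seed = 1)
  expect_equal(panel$ph37, 7.41)
  # hand-computed predictor with known coefficients
  coef["lactate", ] <- c(0.5, 0.2, 0.01, 0.03, -0.001)
  cfg2 <- physio_response_config("nurse", coef, sigma,
                                 nurse_physio_config()$covariates)
  panel2 <- simulate_physiology(list(p_low = 0.75, capture_duration_min = 100),
                                list(sst_c = 28, tl_cm = 180), cfg2, seed = 1)
  expect_equal(panel2$lactate,
               0.5 + 0.2 * log(3) + 0.01 * 100 + 0.03 * 28 - 0.001 * 180,
               tolerance = 1e-12)
})

test_that("panel noise has the configured residual sd", {
  cfg <- nurse_physio_config()
  cfg$sigma[] <- 0
  cfg$sigma["ph"] <- 0.11
  draws <- vapply(1:1000, function(i) {
    simulate_physiology(list(p_low = 0.5, capture_duration_min = 60),
                        list(sst_c = 27, tl_cm = 200), cfg,
                        seed = derive_seed(77, "study", i))$ph37
  }, numeric(1))
  expect_lt(abs(sd(draws) - 0.11) / 0.11, 0.15)
})

test_that("missing covariates are reported by name", {
  cfg <- nurse_physio_config()
  expect_error(simulate_physiology(list(p_low = 0.5, capture_duration_min = 60),
                                   list(tl_cm = 200), cfg, seed = 1),
               "missing covariate: sst_c")
  expect_error(simulate_physiology(list(p_low = 0.5),
                                   list(sst_c = 27, tl_cm = 200), cfg, seed = 1),
               "missing covariate: capture_duration_min")
})

test_that("simulate_study writes consumable files that round-trip", {
  dir <- withr::local_tempdir()
  st <- simulate_study(5, short_bout_config(), nurse_physio_config(),
                       seed = 21, dir = dir)
  expect_length(st$paths$accel, 5)
  expect_true(all(file.exists(st$paths$accel)))
  dep <- read_deployment_table(st$paths$deployment)
  expect_equal(nrow(dep), 5)
  tr <- read_accel_csv(st$paths$accel[1])
  ev <- simulate_capture_event(short_bout_config(),
                               seed = derive_seed(21, "study", 1))
  expect_equal(tr$x_g, ev$trace$x_g, tolerance = 1e-9)
  expect_equal(tr$t_s, ev$trace$t_s)
  truth <- jsonlite::read_json(st$paths$truth)
  expect_equal(truth$events$ev001$p_low, st$truth$ev001$p_low, tolerance = 1e-12)
})

test_that("a study the size of the field sample reproduces calibrated means", {
  dir <- withr::local_tempdir()
  st <- simulate_study(36, short_bout_config(), nurse_physio_config(),
                       seed = 1, dir = dir)
  dep <- st$deployment
  cfg <- nurse_physio_config()
  # predictor at each shark's covariates gives the configured expectation
  X <- cbind(1, logratio_transform(vapply(st$truth, `[[`, 1, "p_low")),
             dep$capture_duration_min, dep$sst_c, dep$tl_cm)
  mu <- X %*% t(cfg$coefficients)
  colnames(mu) <- rownames(cfg$coefficients)
  # pH at 2 SE (the headline endpoint), all endpoints jointly at 3 SE
  se_ph <- sd(dep$ph37) / sqrt(36)
  expect_lt(abs(mean(dep$ph37) - mean(mu[, "ph"])), 2 * se_ph)
  cols <- c(ph = "ph37", lactate = "lactate", glucose = "glucose",
            haematocrit = "haematocrit", sodium = "sodium",
            potassium = "potassium", chloride = "chloride", calcium = "calcium")
  for (ep in names(cols)) {
    v <- dep[[cols[[ep]]]]
    expect_lt(abs(mean(v) - mean(mu[, ep])), 3 * sd(v) / sqrt(36) + 1e-12)
  }
})
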