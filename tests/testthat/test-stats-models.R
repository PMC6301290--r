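# Log-ratio transform, OLS fitting, posterior-simulation intervals.

test_that("the log-ratio transform has its closed-form values", {
  expect_equal(logratio_transform(0.5), 0)
  expect_equal(logratio_transform(0.75), log(3), tolerance = 1e-12)
  expect_equal(logratio_transform(1.0), log((1 - 1e-6) / 1e-6), tolerance = 1e-9)
  expect_equal(logratio_transform(1.0), 13.8155, tolerance = 1e-4)
  expect_equal(logratio_transform(0, n_seconds = 500), log(0.001 / 0.999),
               tolerance = 1e-12)
  expect_error(logratio_transform(1.2), "\\[0, 1\\]")
  expect_equal(logratio_transform(0.6, type = "alr", p_high = 0.3),
               log(2), tolerance = 1e-12)
})

test_that("exact linear data are interpolated exactly", {
  d <- data.frame(y = 2 + 3 * (1:6), x = 1:6)
  # summary.lm warns about the essentially perfect fit; that is the point
  fit <- suppressWarnings(fit_linear_model(d, model_spec("y", "x")))
  expect_equal(unname(fit$coefficients), c(2, 3), tolerance = 1e-10)
  expect_equal(fit$sigma, 0, tolerance = 1e-10)
})

test_that("OLS matches the independent normal-equations solution", {
  withr::with_seed(7, {
    for (rep in 1:10) {
      n <- 30
      X <- cbind(1, matrix(rnorm(n * 4), n))
      beta <- rnorm(5)
      y <- X %*% beta + rnorm(n)
      d <- data.frame(y = y, x1 = X[, 2], x2 = X[, 3], x3 = X[, 4], x4 = X[, 5])
      fit <- fit_linear_model(d, model_spec("y", paste0("x", 1:4)))
      oracle <- solve(crossprod(X), crossprod(X, y))
      expect_lt(max(abs(fit$coefficients - oracle)), 1e-8)
    }
  })
})

test_that("degenerate designs raise informative errors", {
  d <- data.frame(y = rnorm(10), x1 = 1:10)
  d$x2 <- 2 * d$x1
  expect_error(fit_linear_model(d, model_spec("y", c("x1", "x2"))),
               "collinear term\\(s\\): x2")
  small <- data.frame(y = rnorm(3), x1 = rnorm(3))
  expect_error(fit_linear_model(small, model_spec("y", "x1")),
               "insufficient observations")
  expect_error(fit_linear_model(d, model_spec("z", "x1")), "missing column")
})

test_that("posterior simulation is seed-deterministic", {
  withr::with_seed(5, d <- data.frame(y = rnorm(40), x = rnorm(40)))
  fit <- fit_linear_model(d, model_spec("y", "x"))
  a <- simulate_posterior(fit, n_sims = 1000, seed = 2)
  b <- simulate_posterior(fit, n_sims = 1000, seed = 2)
  expect_identical(a$summary, b$summary)
  expect_error(simulate_posterior(fit, n_sims = 1000), "seed is required")
  expect_warning(simulate_posterior(fit, n_sims = 50, seed = 1), "small")
})

test_that("posterior intervals agree with classical t intervals at large n", {
  withr::with_seed(11, {
    n <- 500
    d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
    d$y <- 1 + 0.5 * d$x1 + rnorm(n)
  })
  fit <- fit_linear_model(d, model_spec("y", c("x1", "x2")))
  ci <- simulate_posterior(fit, n_sims = 20000, seed = 4)
  sm <- summary(fit$lm)
  se <- sm$coefficients[, "Std. Error"]
  hw <- stats::qt(0.975, fit$df) * se
  t_lo <- fit$coefficients - hw
  t_hi <- fit$coefficients + hw
  expect_true(all(abs(ci$summary$ci_lower - t_lo) <= 0.05 * hw))
  expect_true(all(abs(ci$summary$ci_upper - t_hi) <= 0.05 * hw))
  expect_true(all(ci$summary$ci_lower < ci$summary$ci_upper))
})

test_that("CI half-widths shrink roughly as 1/sqrt(n)", {
  hw_at <- function(n, seed) {
    mean(vapply(1:10, function(r) {
      withr::with_seed(seed + r, {
        d <- data.frame(x = rnorm(n))
        d$y <- 0.5 * d$x + rnorm(n)
      })
      fit <- fit_linear_model(d, model_spec("y", "x"))
      ci <- simulate_posterior(fit, n_sims = 1000, seed = seed + r)
      diff(c(ci$summary$ci_lower[2], ci$summary$ci_upper[2])) / 2
    }, numeric(1)))
  }
  hws <- c(hw_at(20, 100), hw_at(80, 200), hw_at(320, 300))
  expect_equal(hws[1] / hws[2], 2, tolerance = 0.35)
  expect_equal(hws[2] / hws[3], 2, tolerance = 0.35)
})

test_that("significance tables report bounds and flags consistently", {
  expect_equal(nrow(significance_table(list())), 0)
  withr::with_seed(6, d <- data.frame(y = rnorm(30), x = rnorm(30)))
  fit <- fit_linear_model(d, model_spec("y", "x"))
  ci <- simulate_posterior(fit, n_sims = 1000, seed = 3)
  tab <- significance_table(list(ci))
  expect_equal(tab$ci_lower, ci$summary$ci_lower)
  expect_equal(tab$significant, tab$ci_lower > 0 | tab$ci_upper < 0)
  expect_true(all(tab$ci_lower < tab$ci_upper))
  txt <- format_significance_table(tab)
  expect_true(length(txt) == nrow(tab) + 2)
  # header-only rendering for empty input
  expect_length(format_significance_table(significance_table(list())), 2)
})

test_that("fit_study_models reproduces per-endpoint complete-case n", {
  d <- simulate_panel_study(30, nurse_physio_config(), seed = 12)
  d$ph <- d$ph37
  d$ph[1:5] <- NA
  res <- fit_study_models(d, c("ph", "glucose"), n_sims = 200, seed = 5)
  expect_equal(res$fits$ph$n, 25)
  expect_equal(res$fits$glucose$n, 30)
  expect_equal(sort(unique(res$table$response)), c("glucose", "ph"))
})
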