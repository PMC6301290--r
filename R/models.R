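# Linear models of physiological endpoints with posterior-simulation CIs.

#' Log-ratio transform of a proportion
#'
#' Proportions of a capture event sum to one and are not independent; the
#' analysis therefore enters the low-intensity proportion on a log-ratio
#' scale. The default is the logit, `log(p / (1 - p))` (low vs not-low);
#' an additive-log-ratio variant against the high-intensity proportion,
#' `log(p_low / p_high)`, is available via `type = "alr"`. Proportions are
#' clamped away from 0 and 1 by `eps` before the log --- set
#' `n_seconds` to use the half-count rule `eps = 1 / (2 * n_seconds)`.
#'
#' @param p proportion(s) in `[0, 1]`.
#' @param eps clamp width (default `1e-6`).
#' @param n_seconds optional event length in seconds; overrides `eps` with
#'   the half-count rule.
#' @param type `"logit"` (default) or `"alr"`.
#' @param p_high high-intensity proportion, required for `type = "alr"`.
#' @return numeric vector on the log-ratio scale.
#' @examples
#' logratio_transform(0.5)   # 0
#' logratio_transform(0.75)  # log(3)
#' @export
logratio_transform <- function(p, eps = 1e-6, n_seconds = NULL,
                               type = c("logit", "alr"), p_high = NULL) {
  type <- match.arg(type)
  if (any(!is.na(p) & (p < 0 | p > 1))) stopf("proportions must lie in [0, 1]")
  if (!is.null(n_seconds)) eps <- 1 / (2 * n_seconds)
  pc <- pmin(pmax(p, eps), 1 - eps)
  if (type == "logit") {
    return(log(pc / (1 - pc)))
  }
  if (is.null(p_high)) stopf("type = 'alr' requires p_high")
  ph <- pmin(pmax(p_high, eps), 1 - eps)
  log(pc / ph)
}

#' Specification of one endpoint model
#'
#' @param response endpoint column name (e.g. `"ph"`, `"lactate"`).
#' @param covariates ordered covariate columns; the default is the study's
#'   four: log-ratio-transformed `p_low`, capture duration (min), SST
#'   (deg C) and TL (cm).
#' @param species optional species filter applied before fitting.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(response,
                       covariates = c("p_low_lr", "capture_duration_min",
                                      "sst_c", "tl_cm"),
                       species = NULL) {
  structure(list(response = response, covariates = covariates,
                 species = species), class = "model_spec")
}

#' Fit one endpoint's linear model by ordinary least squares
#'
#' Complete-case fit of `response ~ covariates` (with intercept). Requires
#' at least two more observations than model terms and a full-rank design;
#' rank deficiency is an error naming the collinear terms. Residual
#' standard deviation uses `n - terms` degrees of freedom.
#'
#' @param data data frame holding response and covariate columns (and
#'   optionally `species`).
#' @param spec a [model_spec()].
#' @return an `endpoint_fit`: `coefficients`, `cov_unscaled`
#'   (`(X'X)^-1`), `sigma`, `df`, `n`, `response`, `species`, plus the
#'   underlying `lm` fit.
#' @export
fit_linear_model <- function(data, spec) {
  if (!is.null(spec$species) && !is.null(data$species)) {
    data <- data[data$species == spec$species, , drop = FALSE]
  }
  need <- c(spec$response, spec$covariates)
  miss <- setdiff(need, names(data))
  if (length(miss)) stopf("data missing column(s): %s", paste(miss, collapse = ", "))
  cc <- data[stats::complete.cases(data[, need, drop = FALSE]), need, drop = FALSE]
  p <- length(spec$covariates) + 1L
  if (nrow(cc) < p + 2L) {
    stopf("insufficient observations for '%s': need at least %d complete cases, have %d",
          spec$response, p + 2L, nrow(cc))
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(cc[, spec$covariates, drop = FALSE]))
  qrX <- qr(X)
  if (qrX$rank < p) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stopf("rank-deficient design for '%s': collinear term(s): %s",
          spec$response, paste(aliased, collapse = ", "))
  }
  fm <- stats::reformulate(spec$covariates, response = spec$response)
  fit <- stats::lm(fm, data = cc)
  sm <- summary(fit)
  structure(
    list(coefficients = stats::coef(fit), cov_unscaled = sm$cov.unscaled,
         sigma = sm$sigma, df = fit$df.residual, n = nrow(cc),
         response = spec$response, species = spec$species,
         covariates = spec$covariates, lm = fit),
    class = "endpoint_fit"
  )
}

#' Posterior-simulation confidence intervals for a fitted linear model
#'
#' Noninformative-prior posterior simulation in the standard scheme for
#' linear models: each draw takes the residual variance from its scaled
#' inverse-chi-square posterior, `sigma*^2 = df * s^2 / chi2_df`, then the
#' coefficient vector from `N(beta_hat, sigma*^2 (X'X)^-1)`. The reported
#' interval is the empirical 2.5 %/97.5 % band of the draws, and a term is
#' flagged significant iff that band excludes zero.
#'
#' @param fit an [fit_linear_model()] result.
#' @param n_sims number of posterior draws (default 1000; fewer than 100
#'   warns).
#' @param seed integer seed (required: the interval is an empirical
#'   quantile of random draws).
#' @return a `posterior_ci`: data frame `summary` (`term`, `estimate`,
#'   `ci_lower`, `ci_upper`, `significant`) plus `draws` (n_sims x terms),
#'   `response`, `species`, `n`.
#' @export
simulate_posterior <- function(fit, n_sims = 1000, seed) {
  if (missing(seed)) stopf("seed is required for reproducible posterior draws")
  if (n_sims < 100) warnf("n_sims = %d is small; intervals will be noisy", n_sims)
  p <- length(fit$coefficients)
  draws <- withr::with_seed(derive_seed(seed, "posterior"), {
    sig <- fit$sigma * sqrt(fit$df / stats::rchisq(n_sims, fit$df))
    R <- chol(fit$cov_unscaled)
    Z <- matrix(stats::rnorm(n_sims * p), n_sims, p)
    sweep(Z %*% R, 1, sig, "*") +
      matrix(fit$coefficients, n_sims, p, byrow = TRUE)
  })
  colnames(draws) <- names(fit$coefficients)
  qs <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  summary <- data.frame(
    term = names(fit$coefficients),
    estimate = unname(fit$coefficients),
    ci_lower = qs[1, ], ci_upper = qs[2, ],
    significant = qs[1, ] > 0 | qs[2, ] < 0,
    row.names = NULL
  )
  structure(
    list(summary = summary, draws = draws, response = fit$response,
         species = fit$species, n = fit$n, n_sims = n_sims),
    class = "posterior_ci"
  )
}

#' Assemble a significance report table
#'
#' One row per species x response x term with the 2.5 %/97.5 % bounds and
#' the CI-excludes-zero significance flag, in the layout of the study's
#' model-output table.
#'
#' @param cis list of [simulate_posterior()] results (may be empty).
#' @return data frame (`species`, `response`, `term`, `estimate`,
#'   `ci_lower`, `ci_upper`, `significant`, `n`), zero rows for empty
#'   input, of class `significance_table`.
#' @export
significance_table <- function(cis) {
  if (length(cis) == 0) {
    out <- data.frame(species = character(0), response = character(0),
                      term = character(0), estimate = numeric(0),
                      ci_lower = numeric(0), ci_upper = numeric(0),
                      significant = logical(0), n = integer(0))
  } else {
    out <- do.call(rbind, lapply(cis, function(ci) {
      data.frame(species = ci$species %||% NA_character_,
                 response = ci$response, ci$summary, n = ci$n)
    }))
    rownames(out) <- NULL
  }
  class(out) <- c("significance_table", "data.frame")
  out
}

#' Render a significance table as aligned text
#'
#' Significant terms (interval excluding zero) are marked with `*`.
#'
#' @param tab a [significance_table()].
#' @param path optional file to write to.
#' @return character vector of lines, invisibly if `path` is given.
#' @export
format_significance_table <- function(tab, path = NULL) {
  header <- sprintf("%-15s %-12s %-22s %10s %10s %10s %4s",
                    "species", "response", "term", "estimate",
                    "2.5%", "97.5%", "sig")
  lines <- c(header, strrep("-", nchar(header)))
  if (nrow(tab) > 0) {
    lines <- c(lines, vapply(seq_len(nrow(tab)), function(i) {
      sprintf("%-15s %-12s %-22s %10.4f %10.4f %10.4f %4s",
              tab$species[i], tab$response[i], tab$term[i], tab$estimate[i],
              tab$ci_lower[i], tab$ci_upper[i],
              if (isTRUE(tab$significant[i])) "*" else "")
    }, character(1)))
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Fit all endpoint models for one study
#'
#' Adds the log-ratio-transformed low-intensity proportion to the data,
#' then fits each requested endpoint by complete-case OLS (per-endpoint n
#' varies with missingness, as in the field data) and computes
#' posterior-simulation intervals.
#'
#' @param data merged deployment + metrics data frame (needs `p_low`, the
#'   covariates and the endpoint columns).
#' @param responses endpoint columns to model.
#' @param species optional species filter.
#' @param n_sims posterior draws per endpoint.
#' @param seed integer master seed; each endpoint uses a derived stream.
#' @param transform `"logit"` or `"alr"` for the proportion transform
#'   (`"alr"` requires a `p_high` column).
#' @param covariates covariate columns (default: the study's four).
#' @return list: `fits`, `cis`, `table` (a [significance_table()]).
#' @export
fit_study_models <- function(data, responses, species = NULL, n_sims = 1000,
                             seed = 1, transform = c("logit", "alr"),
                             covariates = c("p_low_lr", "capture_duration_min",
                                            "sst_c", "tl_cm")) {
  transform <- match.arg(transform)
  if (is.null(data$p_low)) stopf("data must contain p_low")
  data$p_low_lr <- if (transform == "logit") {
    logratio_transform(data$p_low, n_seconds = data$n_seconds %||% NULL)
  } else {
    logratio_transform(data$p_low, type = "alr", p_high = data$p_high)
  }
  fits <- list()
  cis <- list()
  for (i in seq_along(responses)) {
    resp <- responses[i]
    fit <- fit_linear_model(data, model_spec(resp, covariates, species))
    ci <- simulate_posterior(fit, n_sims = n_sims,
                             seed = derive_seed(seed, "posterior", i))
    fits[[resp]] <- fit
    cis[[resp]] <- ci
  }
  list(fits = fits, cis = cis, table = significance_table(cis))
}
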