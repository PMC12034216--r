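minimal_spec <- function(encoding = "group_dummies", base = "0c") {
  soc_model_spec(
    rotation_encoding = encoding, base_group = base,
    latitude = FALSE, weather = FALSE, texture = FALSE,
    region_fe = FALSE, month_fe = FALSE
  )
}

test_that("noiseless simulation is identified exactly", {
  truth <- generative_params(
    sigma = 0, latitude_coef = 0.01, layer_dispersion = Inf
  )
  sim <- simulate_rotation_study(400, truth, seed = 3)
  spec <- soc_model_spec(weather = FALSE, texture = FALSE,
                         region_fe = FALSE, month_fe = FALSE)
  # the zero-residual fit trips lm's "essentially perfect fit" warning
  fit <- suppressWarnings(fit_soc_model(sim, spec))
  est <- coef(fit$fit)
  expect_equal(unname(est["(Intercept)"]), truth$intercept_log,
               tolerance = 1e-8)
  expect_equal(unname(est["latitude"]), 0.01, tolerance = 1e-8)
  expect_equal(unname(est["rotation_group1c"]), log(1.300), tolerance = 1e-8)
  expect_equal(unname(est["rotation_group2c"]), log(1.424), tolerance = 1e-8)
  expect_equal(unname(est["rotation_group3c"]), log(1.713), tolerance = 1e-8)
  # percent effects of exact coefficients hit the reported values exactly
  pe <- percent_effects(fit)
  expect_equal(pe$pct_effect, c(30.0, 42.4, 71.3), tolerance = 1e-8)
})

test_that("a six-row design matches the normal-equations oracle", {
  df <- tibble::tibble(
    site_id = sprintf("S%d", 1:6),
    rotation_group = c("0c", "1c", "2c", "3c", "1c", "2c"),
    corn_years = c(0, 1, 2, 3, 1, 2),
    soc_total = c(100, 130, 140, 170, 125, 150)
  )
  fit <- fit_soc_model(df, minimal_spec("continuous_years"))
  X <- cbind(1, df$corn_years)
  beta <- ols_oracle(X, log(df$soc_total))
  expect_equal(unname(coef(fit$fit)), unname(beta), tolerance = 1e-10)
})

test_that("OLS equals the normal equations on random full-rank designs", {
  set.seed(23)
  for (i in 1:5) {
    n <- sample(20:50, 1)
    sim <- simulate_rotation_study(n, generative_params(sigma = 0.3),
                                   seed = 100 + i)
    fit <- fit_soc_model(
      sim,
      soc_model_spec(weather = FALSE, texture = FALSE,
                     region_fe = FALSE, month_fe = FALSE)
    )
    X <- model.matrix(fit$fit)
    beta <- ols_oracle(X, fit$fit$model$.log_outcome)
    expect_equal(unname(coef(fit$fit)), unname(beta), tolerance = 1e-8)
  }
})

test_that("group percent effects recover truth at n = 5000 within 3 s.e.", {
  truth <- generative_params(sigma = 0.5)
  sim <- simulate_rotation_study(5000, truth, seed = 2024)
  fit <- fit_soc_model(sim, minimal_spec())
  pe <- percent_effects(fit)
  targets <- c(30.0, 42.4, 71.3)
  for (i in 1:3) {
    # s.e. of the percent effect by the delta method: 100 * exp(b) * se(b)
    se_pct <- 100 * exp(pe$estimate[i]) * pe$std.error[i]
    expect_lt(abs(pe$pct_effect[i] - targets[i]), 3 * se_pct)
  }
})

test_that("the percent-effect transform is exact, monotone and zero at zero", {
  df <- tibble::tibble(
    site_id = sprintf("S%d", 1:8),
    rotation_group = rep(c("0c", "1c", "2c", "3c"), 2),
    corn_years = rep(0:3, 2),
    soc_total = rep(c(100, 125.08, 156.45, 195.69), 2)
  )
  fit <- fit_soc_model(df, minimal_spec("continuous_years"))
  pe <- percent_effects(fit, "corn_years")
  expect_equal(pe$pct_effect, 100 * (exp(pe$estimate) - 1), tolerance = 1e-12)
  # strictly increasing transform; 0 maps to 0
  b <- seq(-0.5, 0.6, by = 0.1)
  pct <- 100 * (exp(b) - 1)
  expect_true(all(diff(pct) > 0))
  expect_equal(100 * (exp(0) - 1), 0)
  expect_equal(100 * (exp(log(1.713)) - 1), 71.3, tolerance = 1e-10)
  expect_equal(100 * (exp(0.2238) - 1), 25.086, tolerance = 1e-3)
  expect_error(percent_effects(fit, "nope"), "Unknown coefficient")
})

test_that("changing the base group leaves fitted values unchanged", {
  sim <- simulate_rotation_study(600, generative_params(sigma = 0.4),
                                 seed = 12)
  fit0 <- fit_soc_model(sim, minimal_spec(base = "0c"))
  fit1 <- fit_soc_model(sim, minimal_spec(base = "1c"))
  expect_lt(max(abs(fitted(fit0$fit) - fitted(fit1$fit))), 1e-10)
  # contrasts differ: 3c-vs-1c equals the difference of 0c-base effects
  b0 <- coef(fit0$fit)
  b1 <- coef(fit1$fit)
  expect_equal(unname(b1["rotation_group3c"]),
               unname(b0["rotation_group3c"] - b0["rotation_group1c"]),
               tolerance = 1e-10)
})

test_that("rank-deficient designs fail naming the collinear column", {
  sim <- simulate_rotation_study(60, generative_params(sigma = 0.3), seed = 4)
  sim$region <- "R1"
  spec <- soc_model_spec(weather = FALSE, texture = FALSE, month_fe = FALSE)
  # single-level region factor is dropped silently, not an error
  expect_s3_class(fit_soc_model(sim, spec), "soc_fit")
  # a constant covariate is collinear with the intercept and is named
  sim$latitude <- 42
  expect_error(fit_soc_model(sim, spec), "latitude")
})

test_that("robust and classical covariances differ under heteroskedasticity", {
  sim <- simulate_rotation_study(800, generative_params(sigma = 0.5), seed = 6)
  # inflate noise for 3c sites to break homoskedasticity
  infl <- sim$rotation_group == "3c"
  sim$soc_total[infl] <- sim$soc_total[infl] * exp(rnorm(sum(infl), sd = 0.8))
  fr <- fit_soc_model(sim, minimal_spec())
  spec_c <- minimal_spec(); spec_c$se_type <- "classical"
  fc <- fit_soc_model(sim, spec_c)
  expect_equal(coef(fr$fit), coef(fc$fit))
  expect_false(isTRUE(all.equal(diag(fr$vcov), diag(fc$vcov))))
})

test_that("tidy and glance expose broom-shaped results", {
  sim <- simulate_rotation_study(300, generative_params(sigma = 0.4), seed = 8)
  fit <- fit_soc_model(sim, minimal_spec())
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error", "statistic", "p.value",
                    "conf.low", "conf.high") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$nobs, fit$n_used)
  expect_true(gl$r.squared > 0 && gl$r.squared <= 1)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})

test_that("excluded sequences are dropped and missing covariates deleted listwise", {
  sim <- simulate_rotation_study(
    300, generative_params(sigma = 0.4), seed = 9,
    group_probs = c("0c" = 0.22, "1c" = 0.22, "2c" = 0.22, "3c" = 0.22,
                    "excluded" = 0.12)
  )
  sim$latitude[1:5] <- NA
  spec <- soc_model_spec(weather = FALSE, texture = FALSE,
                         region_fe = FALSE, month_fe = FALSE)
  expect_message(fit <- fit_soc_model(sim, spec), "Dropping 5")
  n_excluded <- sum(sim$rotation_group == "excluded")
  n_na <- sum(is.na(sim$latitude[sim$rotation_group != "excluded"]))
  expect_equal(fit$n_used, 300 - n_excluded - n_na)
})

test_that("effects are recovered on average with nominal interval coverage", {
  truth <- generative_params(sigma = 0.5)
  true_b <- unname(truth$group_log_effects)
  n_rep <- 200
  est <- matrix(NA_real_, n_rep, 3)
  cover <- matrix(NA, n_rep, 3)
  for (r in seq_len(n_rep)) {
    sim <- simulate_rotation_study(2000, truth, seed = 5000 + r)
    fit <- fit_soc_model(sim, minimal_spec())
    td <- tidy(fit)
    rows <- match(paste0("rotation_group", c("1c", "2c", "3c")), td$term)
    est[r, ] <- td$estimate[rows]
    cover[r, ] <- td$conf.low[rows] <= true_b & true_b <= td$conf.high[rows]
  }
  mc_se <- apply(est, 2, sd) / sqrt(n_rep)
  expect_true(all(abs(colMeans(est) - true_b) <= 3 * mc_se))
  coverage <- mean(cover)
  expect_gte(coverage, 0.92)
  expect_lte(coverage, 0.98)
})
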