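#' Specify a log-linear SOC regression
#'
#' Describes one model of `log(SOC stock)` at a chosen depth on rotation
#' terms plus controls. Three rotation encodings are supported:
#' `by_lag_crop` (separate corn dummies for the measurement year and the
#' two prior years), `group_dummies` (categorical `0c`-`3c` with a
#' configurable reference group), and `continuous_years` (linear in the
#' number of corn years, whose slope transforms to the
#' percent-per-additional-corn-year effect). Controls are latitude, the
#' 8 windowed climate features, soil-texture dummies, and region +
#' measurement-month fixed effects; each can be switched off.
#'
#' @param outcome Depth of the modelled stock: `"0-100"` (default),
#'   `"0-5"`, `"5-30"` or `"30-100"` cm.
#' @param rotation_encoding `"group_dummies"`, `"by_lag_crop"` or
#'   `"continuous_years"`.
#' @param base_group Reference rotation group for `group_dummies`.
#' @param latitude,weather,texture,region_fe,month_fe Logical switches
#'   for the control blocks.
#' @param se_type `"robust"` (heteroskedasticity-consistent, HC1,
#'   default) or `"classical"`.
#'
#' @return An object of class `soc_model_spec`.
#' @examples
#' soc_model_spec(rotation_encoding = "continuous_years", weather = FALSE)
#' @export
soc_model_spec <- function(outcome = c("0-100", "0-5", "5-30", "30-100"),
                           rotation_encoding = c(
                             "group_dummies", "by_lag_crop", "continuous_years"
                           ),
                           base_group = "0c",
                           latitude = TRUE, weather = TRUE, texture = TRUE,
                           region_fe = TRUE, month_fe = TRUE,
                           se_type = c("robust", "classical")) {
  outcome <- match.arg(outcome)
  rotation_encoding <- match.arg(rotation_encoding)
  se_type <- match.arg(se_type)
  if (!base_group %in% c("0c", "1c", "2c", "3c")) {
    abort("`base_group` must be one of 0c, 1c, 2c, 3c.")
  }
  structure(
    list(
      outcome = outcome, rotation_encoding = rotation_encoding,
      base_group = base_group, latitude = latitude, weather = weather,
      texture = texture, region_fe = region_fe, month_fe = month_fe,
      se_type = se_type
    ),
    class = "soc_model_spec"
  )
}

outcome_column <- function(outcome) {
  c(
    "0-100" = "soc_total", "0-5" = "soc_0_5",
    "5-30" = "soc_5_30", "30-100" = "soc_30_100"
  )[[outcome]]
}

#' Fit a log-linear SOC regression
#'
#' Ordinary least squares on the log stock with dummy-encoded
#' categoricals (reference levels dropped). Sites whose 3-year sequence
#' contains a non-corn/soy crop (`rotation_group == "excluded"`) are
#' dropped, as are rows with missing covariates (listwise deletion; the
#' dropped count is reported via a message). A rank-deficient design is
#' an error naming the collinear columns.
#'
#' @param sites Site tibble with layer stocks (from [generate_soc()] or
#'   read from file).
#' @param spec A [soc_model_spec()].
#' @param sequences Optional sequence tibble to join by `site_id` (not
#'   needed if `sites` already has `rotation_group` / `corn_years`).
#' @param features Optional climate-feature tibble to join by `site_id`.
#'
#' @return An object of class `soc_fit`: the underlying `lm` fit, the
#'   spec, the coefficient covariance per `spec$se_type`, and `n_used` /
#'   `n_input`. Use [tidy()], [glance()], [percent_effects()] and
#'   [autoplot()] on it.
#' @export
fit_soc_model <- function(sites, spec = soc_model_spec(), sequences = NULL,
                          features = NULL) {
  stopifnot(inherits(spec, "soc_model_spec"))
  df <- sites
  if (!is.null(sequences)) {
    df <- dplyr::left_join(
      dplyr::select(df, -dplyr::any_of(c("rotation_group", "corn_years"))),
      sequences[, c("site_id", "rotation_group", "corn_years")],
      by = "site_id"
    )
  }
  if (!is.null(features)) {
    df <- dplyr::left_join(df, features, by = "site_id")
  }
  if (!"rotation_group" %in% names(df)) {
    abort("`rotation_group` not found; supply `sequences`.")
  }
  n_input <- nrow(df)
  df <- df[df$rotation_group != "excluded", , drop = FALSE]

  ycol <- outcome_column(spec$outcome)
  if (!ycol %in% names(df)) {
    if (ycol == "soc_total") {
      df <- aggregate_depth_layers(df)
    } else {
      abort(paste0("Outcome column `", ycol, "` not found."))
    }
  }
  if (any(df[[ycol]] <= 0, na.rm = TRUE)) {
    abort("Stocks must be positive to take logs.")
  }
  df$.log_outcome <- log(df[[ycol]])

  terms <- switch(spec$rotation_encoding,
    group_dummies = {
      lv <- c(spec$base_group, setdiff(c("0c", "1c", "2c", "3c"),
                                       spec$base_group))
      df$rotation_group <- factor(df$rotation_group, levels = lv)
      "rotation_group"
    },
    continuous_years = "corn_years",
    by_lag_crop = {
      cm <- cdl_code_map()
      for (k in 0:2) {
        col <- paste0("crop_y", k)
        if (!col %in% names(df)) {
          abort(paste0("`by_lag_crop` needs column `", col,
                       "` (join `sequences` with crop codes)."))
        }
        df[[paste0("corn_y", k)]] <- as.integer(df[[col]] == cm$corn)
      }
      c("corn_y0", "corn_y1", "corn_y2")
    }
  )
  if (spec$latitude) terms <- c(terms, "latitude")
  if (spec$weather) terms <- c(terms, climate_feature_names())
  if (spec$texture) {
    df$texture_class <- factor(df$texture_class)
    terms <- c(terms, "texture_class")
  }
  if (spec$region_fe) {
    df$region <- factor(df$region)
    terms <- c(terms, "region")
  }
  if (spec$month_fe) {
    df$measurement_month <- factor(df$measurement_month)
    terms <- c(terms, "measurement_month")
  }
  missing_terms <- setdiff(terms, names(df))
  if (length(missing_terms)) {
    abort(paste0(
      "Missing covariate column(s): ", paste(missing_terms, collapse = ", "),
      " (supply `features`?)"
    ))
  }

  complete <- complete.cases(df[c(".log_outcome", terms)])
  if (sum(!complete) > 0) {
    message(sprintf("Dropping %d row(s) with missing values.", sum(!complete)))
  }
  df <- df[complete, , drop = FALSE]
  p <- length(terms)
  if (nrow(df) < p + 5) {
    abort(sprintf("Need at least %d complete rows, have %d.", p + 5, nrow(df)))
  }

  # drop single-level factors (e.g. one region) rather than failing in lm
  for (tm in terms) {
    if (is.factor(df[[tm]])) df[[tm]] <- droplevels(df[[tm]])
  }
  terms <- terms[vapply(
    terms, function(tm) !is.factor(df[[tm]]) || nlevels(df[[tm]]) > 1, TRUE
  )]

  fml <- as.formula(paste(".log_outcome ~", paste(terms, collapse = " + ")))
  fit <- lm(fml, data = df)
  if (anyNA(coef(fit))) {
    abort(paste0(
      "Rank-deficient design; collinear column(s): ",
      paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")
    ))
  }
  V <- if (spec$se_type == "robust") {
    sandwich::vcovHC(fit, type = "HC1")
  } else {
    vcov(fit)
  }
  structure(
    list(
      fit = fit, spec = spec, vcov = V,
      n_used = nrow(df), n_input = n_input,
      terms = terms
    ),
    class = "soc_fit"
  )
}

#' @export
print.soc_fit <- function(x, ...) {
  cat(sprintf(
    "<soc_fit> log(SOC %s cm) ~ %s, %s SEs, n = %d (of %d input rows)\n",
    x$spec$outcome, x$spec$rotation_encoding, x$spec$se_type,
    x$n_used, x$n_input
  ))
  print(tidy(x), n = 8)
  invisible(x)
}

rotation_terms <- function(x) {
  switch(x$spec$rotation_encoding,
    group_dummies = grep("^rotation_group", names(coef(x$fit)), value = TRUE),
    continuous_years = "corn_years",
    by_lag_crop = c("corn_y0", "corn_y1", "corn_y2")
  )
}

#' @export
tidy.soc_fit <- function(x, conf.int = TRUE, conf.level = 0.95, ...) {
  est <- coef(x$fit)
  se <- sqrt(diag(x$vcov))
  stat <- est / se
  dfres <- x$fit$df.residual
  out <- tibble::tibble(
    term = names(est), estimate = unname(est), std.error = unname(se),
    statistic = unname(stat),
    p.value = 2 * pt(abs(stat), df = dfres, lower.tail = FALSE)
  )
  if (conf.int) {
    tcrit <- qt(1 - (1 - conf.level) / 2, df = dfres)
    out$conf.low <- out$estimate - tcrit * out$std.error
    out$conf.high <- out$estimate + tcrit * out$std.error
  }
  out
}

#' @export
glance.soc_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
    sigma = s$sigma, df.residual = x$fit$df.residual,
    nobs = x$n_used, se_type = x$spec$se_type,
    outcome = x$spec$outcome, encoding = x$spec$rotation_encoding
  )
}

#' Percent effects from log-scale coefficients
#'
#' Transforms coefficients of a log-outcome model into percent effects
#' `100 * (exp(beta) - 1)` with endpoint-transformed confidence
#' intervals `100 * (exp(beta +/- z * se) - 1)`. The transform is
#' strictly increasing and maps 0 to 0%. By default the rotation terms
#' of the fit are transformed.
#'
#' @param fit A [fit_soc_model()] result.
#' @param labels Coefficient names to transform (default: rotation
#'   terms); unknown names are an error.
#' @param conf_level Confidence level.
#'
#' @return A tibble `term`, `estimate` (log scale), `std.error`,
#'   `pct_effect`, `conf.low`, `conf.high` (percent scale).
#' @examples
#' # log(1.713) transforms to +71.3%
#' 100 * (exp(log(1.713)) - 1)
#' @export
percent_effects <- function(fit, labels = NULL, conf_level = 0.95) {
  stopifnot(inherits(fit, "soc_fit"))
  est <- coef(fit$fit)
  if (is.null(labels)) labels <- rotation_terms(fit)
  unknown <- setdiff(labels, names(est))
  if (length(unknown)) {
    abort(paste0("Unknown coefficient label(s): ", paste(unknown, collapse = ", ")))
  }
  b <- est[labels]
  se <- sqrt(diag(fit$vcov))[labels]
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    term = labels,
    estimate = unname(b),
    std.error = unname(se),
    pct_effect = 100 * (exp(unname(b)) - 1),
    conf.low = 100 * (exp(unname(b) - z * unname(se)) - 1),
    conf.high = 100 * (exp(unname(b) + z * unname(se)) - 1)
  )
}

#' @export
autoplot.soc_fit <- function(object, ...) {
  pe <- percent_effects(object)
  pe$term <- sub("^rotation_group", "", pe$term)
  ggplot2::ggplot(pe, ggplot2::aes(x = .data$term, y = .data$pct_effect)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high)
    ) +
    ggplot2::labs(
      x = "rotation term",
      y = "effect on SOC stock (%)",
      title = sprintf("Marginal effects on SOC (%s cm), base %s",
                      object$spec$outcome, object$spec$base_group)
    ) +
    ggplot2::theme_minimal()
}
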