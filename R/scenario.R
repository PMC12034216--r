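#' SOC gain from converting an area to a more corn-intensive rotation
#'
#' The accounting primitive of the scenario analysis:
#' `delta = area (ha) x baseline group-mean stock (Mg C/ha) x percent
#' effect (fraction)`, the aggregate SOC gain in Mg C when all of `area`
#' moves from its current rotation to one whose stocks are
#' `pct_effect` higher.
#'
#' @param area Area converted, hectares (`>= 0`).
#' @param base_mean_soc Mean 0-100 cm stock of the current rotation
#'   group, Mg C/ha (`>= 0`).
#' @param pct_effect Relative stock increase as a fraction, e.g. 0.300
#'   for +30.0% (`>= 0` for a gain).
#'
#' @return SOC gain in Mg C.
#' @examples
#' scenario_delta(737955, 109.73, 0.300) / 1e6 # ~24.3 million Mg C
#' @export
scenario_delta <- function(area, base_mean_soc, pct_effect) {
  if (any(area < 0) || any(base_mean_soc < 0)) {
    abort("`area` and `base_mean_soc` must be non-negative.")
  }
  area * base_mean_soc * pct_effect
}

#' Run rotation-conversion scenarios
#'
#' Computes per-state SOC gains for a set of conversion scenarios
#' (`from_group` -> `to_group` with strictly more corn years) and appends
#' per-scenario "Corn Belt" totals across states.
#'
#' @param areas Tibble `state`, `from_group`, `area_ha`: land currently
#'   in each rotation group.
#' @param group_means Tibble `group`, `mean_soc` (Mg C/ha): baseline
#'   0-100 cm mean per rotation group.
#' @param effects Tibble `from_group`, `to_group`, `pct_effect`
#'   (fraction): relative stock increase of `to_group` over `from_group`.
#' @param defs Tibble `from_group`, `to_group`: the scenarios to run.
#'
#' @return A tibble `state`, `from_group`, `to_group`, `area_ha`,
#'   `base_mean_soc`, `pct_effect`, `delta_soc` (Mg C), `is_total`
#'   (`TRUE` for the appended across-state rows, `state = "Corn Belt"`).
#' @export
run_scenarios <- function(areas, group_means, effects, defs) {
  cy_from <- corn_years_of_group(defs$from_group)
  cy_to <- corn_years_of_group(defs$to_group)
  if (anyNA(cy_from) || anyNA(cy_to) || any(cy_to <= cy_from)) {
    abort("Every scenario needs to_group with strictly more corn years than from_group.")
  }
  rows <- purrr::pmap_dfr(defs, function(from_group, to_group) {
    eff <- effects$pct_effect[
      effects$from_group == from_group & effects$to_group == to_group
    ]
    if (length(eff) != 1) {
      abort(sprintf("No percent effect for conversion %s -> %s.",
                    from_group, to_group))
    }
    mean_soc <- group_means$mean_soc[group_means$group == from_group]
    if (length(mean_soc) != 1) {
      abort(sprintf("No group mean for group %s.", from_group))
    }
    a <- areas[areas$from_group == from_group, ]
    if (nrow(a) == 0) {
      abort(sprintf("No area rows for from_group %s.", from_group))
    }
    tibble::tibble(
      state = a$state, from_group = from_group, to_group = to_group,
      area_ha = a$area_ha, base_mean_soc = mean_soc, pct_effect = eff,
      delta_soc = scenario_delta(a$area_ha, mean_soc, eff)
    )
  })
  rows$is_total <- FALSE
  totals <- dplyr::summarise(
    dplyr::group_by(rows, .data$from_group, .data$to_group,
                    .data$base_mean_soc, .data$pct_effect),
    state = "Corn Belt",
    area_ha = sum(.data$area_ha),
    delta_soc = sum(.data$delta_soc),
    is_total = TRUE,
    .groups = "drop"
  )
  dplyr::bind_rows(rows, totals)[
    , c("state", "from_group", "to_group", "area_ha", "base_mean_soc",
        "pct_effect", "delta_soc", "is_total")
  ]
}

#' Aggregate scenario results under a policy
#'
#' Sums per-state SOC gains over the conversions a policy applies. The
#' policy's conversions must be mutually exclusive: each
#' `(state, from_group)` cell may be converted at most once; overlap is
#' an error.
#'
#' @param results Scenario tibble (from [run_scenarios()], or any table
#'   with `state`, `from_group`, `to_group`, `delta_soc`; rows flagged
#'   `is_total` are ignored).
#' @param policy Tibble `from_group`, `to_group`: conversions included.
#'
#' @return Total SOC gain in Mg C (a single number).
#' @export
aggregate_policy <- function(results, policy) {
  if (nrow(policy) == 0) return(0)
  if ("is_total" %in% names(results)) {
    results <- results[!results$is_total, ]
  }
  if (anyDuplicated(policy$from_group)) {
    dup <- unique(policy$from_group[duplicated(policy$from_group)])
    abort(paste0(
      "Policy converts from_group(s) more than once (overlapping cells): ",
      paste(dup, collapse = ", ")
    ))
  }
  sel <- dplyr::inner_join(results, policy, by = c("from_group", "to_group"))
  missing_defs <- dplyr::anti_join(
    policy, results, by = c("from_group", "to_group")
  )
  if (nrow(missing_defs)) {
    abort(paste0(
      "No scenario results for: ",
      paste(missing_defs$from_group, "->", missing_defs$to_group,
            collapse = ", ")
    ))
  }
  if (anyDuplicated(sel[c("state", "from_group")])) {
    abort("Overlapping (state, from_group) cells in policy results.")
  }
  sum(sel$delta_soc)
}

#' Value aggregate SOC gains at the social cost of carbon
#'
#' Multiplies a total SOC gain (Mg C, 1 Mg = 1 t) by a social cost of
#' carbon in USD per t C. The default 678 USD/t C is in 2020 dollars.
#'
#' @param total_mg_c Total SOC gain in Mg C (`>= 0`).
#' @param scc Social cost of carbon, USD per t C (`>= 0`).
#'
#' @return A one-row tibble `total_mg_c`, `scc`, `value_usd`.
#' @examples
#' monetize(172942685) # ~117 billion USD
#' @export
monetize <- function(total_mg_c, scc = 678) {
  if (total_mg_c < 0 || scc < 0) abort("Inputs must be non-negative.")
  tibble::tibble(
    total_mg_c = total_mg_c, scc = scc, value_usd = total_mg_c * scc
  )
}

#' Reference Corn Belt accounting inputs
#'
#' Published accounting inputs for the four-state Corn Belt analysis
#' (Ohio, Indiana, Iowa, Illinois; 2019-2021 rotation areas): per-state
#' areas currently in each rotation group, baseline group-mean stocks,
#' pairwise percent effects, per-state reference SOC gains for the six
#' conversion scenarios, and the social cost of carbon. The `0c` mean
#' (109.73 Mg C/ha) and the `0c`-base effects (+30.0/+42.4/+71.3%) and
#' the 3c-vs-1c effect (+31.8%) are reported values; the `1c`/`2c` group
#' means and the remaining cross effects are *derived calibrations*
#' back-solved from the reference per-state gains (they are not
#' independently reported), marked `derived = TRUE`.
#'
#' @return A list: `areas`, `group_means`, `effects`, `defs`,
#'   `reference_results` (per-state reference gains, Mg C), `policies`
#'   (named list of policy tibbles: `max_corn`, `two_of_three`), `scc`.
#' @export
cornbelt_reference <- function() {
  states <- c("OH", "IA", "IL", "IN")
  areas <- tibble::tibble(
    state = rep(states, 3),
    from_group = rep(c("0c", "1c", "2c"), each = 4),
    area_ha = c(
      352647, 31700, 178870, 174739,
      1434097, 3270538, 3387646, 1895721,
      880021, 4571320, 3708637, 1615100
    )
  )
  # reference per-state gains (Mg C) for each conversion
  reference_results <- tibble::tibble(
    state = rep(states, 6),
    from_group = rep(c("0c", "0c", "0c", "1c", "1c", "2c"), each = 4),
    to_group = rep(c("1c", "2c", "3c", "2c", "3c", "3c"), each = 4),
    delta_soc = c(
      11589507, 1041791, 5878430, 5742692,
      16438138, 1477639, 8337753, 8145227,
      27574900, 2478732, 13986541, 13663581,
      19892410, 45365749, 46990159, 26295609,
      65578921, 149556379, 154911542, 86688221,
      31218324, 162165459, 131562148, 57294931
    ),
    is_total = FALSE
  )
  # derived calibration: back-solve the unreported 1c/2c means and cross
  # effects from the reference totals (see the methods vignette)
  area_1c <- sum(areas$area_ha[areas$from_group == "1c"]) # 9,988,002
  area_2c <- sum(areas$area_ha[areas$from_group == "2c"]) # 10,775,078
  gain_1c_3c <- sum(reference_results$delta_soc[
    reference_results$from_group == "1c" & reference_results$to_group == "3c"
  ])
  gain_1c_2c <- sum(reference_results$delta_soc[
    reference_results$from_group == "1c" & reference_results$to_group == "2c"
  ])
  gain_2c_3c <- sum(reference_results$delta_soc[
    reference_results$from_group == "2c" & reference_results$to_group == "3c"
  ])
  mean_1c <- gain_1c_3c / (area_1c * 0.318)
  eff_1c_2c <- gain_1c_2c / (area_1c * mean_1c)
  eff_2c_3c <- 1.713 / 1.424 - 1
  mean_2c <- gain_2c_3c / (area_2c * eff_2c_3c)

  group_means <- tibble::tibble(
    group = c("0c", "1c", "2c", "3c"),
    mean_soc = c(109.73, mean_1c, mean_2c, 300.20),
    derived = c(FALSE, TRUE, TRUE, FALSE)
  )
  effects <- tibble::tibble(
    from_group = c("0c", "0c", "0c", "1c", "1c", "2c"),
    to_group = c("1c", "2c", "3c", "2c", "3c", "3c"),
    pct_effect = c(0.300, 0.424, 0.713, eff_1c_2c, 0.318, eff_2c_3c),
    derived = c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE)
  )
  defs <- effects[, c("from_group", "to_group")]
  policies <- list(
    max_corn = tibble::tibble(
      from_group = c("0c", "1c", "2c"), to_group = c("3c", "3c", "3c")
    ),
    two_of_three = tibble::tibble(
      from_group = c("0c", "1c"), to_group = c("2c", "2c")
    )
  )
  list(
    areas = areas, group_means = group_means, effects = effects,
    defs = defs, reference_results = reference_results,
    policies = policies, scc = 678
  )
}
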