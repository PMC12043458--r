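# Ex-ante DALY health and economic impact of biofortified (OFS) grain.
#
# Chain per nutrient, treatment, scenario and demographic group:
#   delta grain content -> additional daily intake (milling recovery)
#   -> intake with OFS -> % of RNI -> deficit gap closure
#   -> DALYs saved = baseline burden x coverage x gap closure
#   -> % burden reduction and economic benefit (PCNI valuation minus
#      organic fertilizer cost).

#' Additional daily nutrient intake from biofortified flour
#'
#' `delta_content * (wheat_intake / 1000) * recovery`: the grain content
#' increase carried into flour after milling, scaled by daily flour
#' consumption.
#'
#' @param delta_content Grain content change, mg kg^-1 (may be negative).
#' @param wheat_intake Daily wheat-flour consumption, g day^-1 (>= 0).
#' @param recovery Milling recovery fraction in `[0, 1]` (0.310 for Zn,
#'   0.217 for Fe).
#' @return Additional intake, mg day^-1. Vectorized.
#' @export
#' @examples
#' additional_intake(1.0, 300, 0.31)  # 0.093 mg/day
additional_intake <- function(delta_content, wheat_intake, recovery) {
  if (anyNA(recovery)) {
    stop("recovery is undefined (NA) for this nutrient", call. = FALSE)
  }
  if (any(recovery < 0) || any(recovery > 1)) {
    stop("recovery must be in [0, 1]", call. = FALSE)
  }
  if (any(wheat_intake < 0)) stop("wheat_intake must be >= 0", call. = FALSE)
  delta_content * (wheat_intake / 1000) * recovery
}

#' Daily intake with OFS grain
#'
#' Status-quo intake plus the additional intake from the biofortified
#' grain, floored at zero.
#'
#' @param baseline_intake Status-quo intake, mg day^-1 (>= 0).
#' @param additional Additional intake, mg day^-1.
#' @return Intake with OFS, mg day^-1. Vectorized.
#' @export
intake_with_ofs <- function(baseline_intake, additional) {
  if (any(baseline_intake < 0)) {
    stop("baseline_intake must be >= 0", call. = FALSE)
  }
  pmax(0, baseline_intake + additional)
}

#' Intake as a percentage of the recommended nutrient intake
#'
#' @param intake Daily intake, mg day^-1.
#' @param rni Recommended nutrient intake, mg day^-1 (> 0).
#' @return `100 * intake / rni`. Vectorized.
#' @export
pct_rni <- function(intake, rni) {
  if (any(rni <= 0)) stop("rni must be > 0", call. = FALSE)
  100 * intake / rni
}

#' Current DALY burden of a deficiency in a population group
#'
#' De Steur-style burden:
#' `population * (mortality * L_discounted + sum(incidence * duration *
#' disability_weight))`, where `L_discounted = L` at discount rate 0 and
#' `(1 - exp(-r * L)) / r` otherwise.
#'
#' @param population Group size, persons.
#' @param mortality Annual attributable mortality fraction.
#' @param life_expectancy Remaining life expectancy at death, years.
#' @param outcomes Data frame with columns `incidence` (annual fraction),
#'   `duration` (years) and `disability_weight` (in `[0, 1]`), one row per
#'   morbidity outcome. May be empty.
#' @param discount_rate Annual discount rate `r >= 0`; default 0.
#' @return DALYs lost per year.
#' @export
#' @examples
#' dalys_lost(1e6, 0, 30, data.frame(incidence = 0.01, duration = 1,
#'                                   disability_weight = 0.1))
dalys_lost <- function(population, mortality, life_expectancy,
                       outcomes = data.frame(incidence = numeric(),
                                             duration = numeric(),
                                             disability_weight = numeric()),
                       discount_rate = 0) {
  if (population < 0 || mortality < 0 || life_expectancy < 0 ||
      discount_rate < 0 ||
      any(outcomes$incidence < 0) || any(outcomes$duration < 0) ||
      any(outcomes$disability_weight < 0)) {
    stop("all rates and durations must be >= 0", call. = FALSE)
  }
  l_disc <- if (discount_rate > 0) {
    (1 - exp(-discount_rate * life_expectancy)) / discount_rate
  } else {
    life_expectancy
  }
  yld <- sum(outcomes$incidence * outcomes$duration *
               outcomes$disability_weight)
  population * (mortality * l_disc + yld)
}

#' Fraction of the intake deficit closed by the biofortified grain
#'
#' Linear deficit model: `min(1, additional / (rni - baseline_intake))`,
#' clamped below at 0. Groups already at or above the RNI have no deficit
#' and return 0.
#'
#' @param baseline_intake Status-quo intake, mg day^-1 (>= 0).
#' @param additional Additional intake from OFS grain, mg day^-1.
#' @param rni Recommended nutrient intake, mg day^-1 (> 0).
#' @return Gap-closure fraction in `[0, 1]`. Vectorized.
#' @export
#' @examples
#' gap_closure(4.90, 0.06, 6.90)  # 0.03
gap_closure <- function(baseline_intake, additional, rni) {
  if (any(rni <= 0)) stop("rni must be > 0", call. = FALSE)
  if (any(baseline_intake < 0)) {
    stop("baseline_intake must be >= 0", call. = FALSE)
  }
  deficit <- rni - baseline_intake
  out <- ifelse(deficit <= 0, 0, additional / deficit)
  pmin(1, pmax(0, out))
}

#' DALYs saved under a coverage scenario
#'
#' `baseline_burden * coverage * gap_closure`; linear in coverage, so a
#' 60% scenario saves exactly three times a 20% scenario.
#'
#' @param baseline_burden Current DALYs lost per year (>= 0).
#' @param coverage Fraction of the population consuming OFS grain, `[0, 1]`.
#' @param gap_closure Deficit gap-closure fraction, `[0, 1]`.
#' @return DALYs saved per year. Vectorized.
#' @export
dalys_saved <- function(baseline_burden, coverage, gap_closure) {
  if (any(coverage < 0) || any(coverage > 1) ||
      any(gap_closure < 0) || any(gap_closure > 1)) {
    stop("coverage and gap_closure must be in [0, 1]", call. = FALSE)
  }
  if (any(baseline_burden < 0)) {
    stop("baseline_burden must be >= 0", call. = FALSE)
  }
  baseline_burden * coverage * gap_closure
}

#' Percent reduction of the current health burden
#'
#' `100 * saved / baseline_burden`.
#'
#' @param saved DALYs saved per year.
#' @param baseline_burden Current DALYs lost per year (> 0).
#' @return Percent reduction. Vectorized.
#' @export
pct_burden_reduction <- function(saved, baseline_burden) {
  if (any(baseline_burden <= 0)) {
    stop("baseline_burden must be > 0", call. = FALSE)
  }
  100 * saved / baseline_burden
}

#' Economic benefit of the OFS strategy
#'
#' `total_dalys_saved * pcni - fertilizer_cost_per_ha * area`: DALYs
#' valued at the per capita net income (PCNI) minus the organic fertilizer
#' cost over the cultivated area. May be negative.
#'
#' @param total_dalys_saved Total DALYs saved per year.
#' @param pcni Monetary value of one DALY, RMB.
#' @param fertilizer_cost_per_ha Organic fertilizer cost, RMB ha^-1
#'   (default 900).
#' @param area Cultivated area, ha (default 4.0e6).
#' @return Net benefit, RMB. Vectorized.
#' @export
economic_benefit <- function(total_dalys_saved, pcni,
                             fertilizer_cost_per_ha = 900, area = 4.0e6) {
  if (any(total_dalys_saved < 0) || any(pcni < 0) ||
      any(fertilizer_cost_per_ha < 0) || any(area < 0)) {
    stop("all inputs must be >= 0", call. = FALSE)
  }
  as.numeric(total_dalys_saved) * as.numeric(pcni) -
    as.numeric(fertilizer_cost_per_ha) * as.numeric(area)
}

#' Load health-model parameters from YAML
#'
#' Reads a parameter file with the reference treatment, per-treatment grain
#' contents, milling recoveries, demographic groups (wheat intake, baseline
#' intake, RNI, baseline DALY burden per nutrient), coverage scenarios and
#' economic constants. The packaged default,
#' `inst/extdata/health_params_synthetic.yaml`, is a synthetic parameter
#' set back-solved to be consistent with the published 15% substitution
#' scenario table (derivations in the file's comments).
#'
#' @param path Path to a YAML file; default the packaged synthetic set.
#' @return A list: `reference_treatment`, `recovery` (named numeric),
#'   `contents` (tibble nutrient/treatment/content), `groups` (tibble),
#'   `scenarios` (tibble name/coverage), `economics` (list).
#' @export
load_health_params <- function(path = system.file(
  "extdata", "health_params_synthetic.yaml", package = "ofsgrain")) {
  if (!nzchar(path) || !file.exists(path)) {
    stop("parameter file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  contents <- purrr::imap_dfr(raw$contents, function(by_trt, nutrient) {
    tibble::tibble(nutrient = nutrient,
                   treatment = names(by_trt),
                   content = unlist(by_trt, use.names = FALSE))
  })
  groups <- purrr::map_dfr(raw$groups, tibble::as_tibble)
  required <- c("nutrient", "group", "wheat_intake", "baseline_intake",
                "rni", "baseline_burden")
  for (f in required) {
    if (!f %in% names(groups) || anyNA(groups[[f]])) {
      stop("health parameter file: missing or incomplete field '", f,
           "' in groups", call. = FALSE)
    }
  }
  list(
    reference_treatment = raw$reference_treatment,
    recovery = unlist(raw$recovery),
    contents = contents,
    groups = groups,
    scenarios = purrr::map_dfr(raw$scenarios, tibble::as_tibble),
    economics = raw$economics
  )
}

#' Run the full health and economic impact assessment
#'
#' Composes the health-model operations for every nutrient, OFS treatment
#' and coverage scenario: content difference against the reference
#' treatment, additional intake through milling recovery, intake with OFS,
#' percent of RNI, deficit gap closure, DALYs saved, percent reduction of
#' the current burden, and the economic benefit of the combined (all
#' nutrients) DALYs saved.
#'
#' @param params A parameter list as returned by [load_health_params()].
#' @param contents Optional tibble `nutrient`/`treatment`/`content`
#'   (mg kg^-1) overriding `params$contents` — e.g. treatment means
#'   computed from a plot table.
#' @param reference_treatment Optional override of the reference treatment.
#' @return An object of class `ofs_health`: a list of tibbles `groups`
#'   (per nutrient x treatment x scenario x group: delta_content,
#'   additional_intake, intake_with_ofs, pct_rni, gap_closure,
#'   dalys_saved), `burden` (per nutrient x treatment x scenario:
#'   total_dalys_saved, total_burden, pct_burden_reduction) and
#'   `economics` (per treatment x scenario: total_dalys_saved,
#'   economic_benefit in RMB).
#' @export
#' @examples
#' res <- run_health_assessment(load_health_params())
#' res$burden
run_health_assessment <- function(params = load_health_params(),
                                  contents = NULL,
                                  reference_treatment = NULL) {
  contents <- if (is.null(contents)) params$contents else
    tibble::as_tibble(contents)
  ref <- if (is.null(reference_treatment)) params$reference_treatment else
    reference_treatment
  if (!ref %in% contents$treatment) {
    stop("reference treatment '", ref, "' not present in contents",
         call. = FALSE)
  }
  groups <- params$groups
  scenarios <- params$scenarios
  miss <- setdiff(unique(groups$nutrient), names(params$recovery))
  if (length(miss) > 0) {
    stop("no milling recovery defined for nutrient(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  ofs_trts <- setdiff(unique(contents$treatment), ref)

  per_group <- tidyr::expand_grid(
    nutrient = unique(groups$nutrient),
    treatment = ofs_trts,
    scenario = scenarios$name
  ) |>
    dplyr::left_join(scenarios, by = c(scenario = "name")) |>
    dplyr::inner_join(groups, by = "nutrient",
                      relationship = "many-to-many") |>
    dplyr::left_join(dplyr::rename(contents, content_ofs = "content"),
                     by = c("nutrient", "treatment")) |>
    dplyr::left_join(
      contents |>
        dplyr::filter(.data$treatment == ref) |>
        dplyr::select("nutrient", content_ref = "content"),
      by = "nutrient"
    )
  if (anyNA(per_group$content_ofs) || anyNA(per_group$content_ref)) {
    stop("contents must cover every nutrient for the reference and OFS ",
         "treatments", call. = FALSE)
  }
  per_group <- per_group |>
    dplyr::mutate(
      delta_content = .data$content_ofs - .data$content_ref,
      additional_intake = additional_intake(
        .data$delta_content, .data$wheat_intake,
        unname(params$recovery[.data$nutrient])),
      intake_with_ofs = intake_with_ofs(.data$baseline_intake,
                                        .data$additional_intake),
      pct_rni = pct_rni(.data$intake_with_ofs, .data$rni),
      gap_closure = gap_closure(.data$baseline_intake,
                                .data$additional_intake, .data$rni),
      dalys_saved = dalys_saved(.data$baseline_burden, .data$coverage,
                                .data$gap_closure)
    ) |>
    dplyr::select("nutrient", "treatment", "scenario", "coverage", "group",
                  "delta_content", "additional_intake", "baseline_intake",
                  "intake_with_ofs", "rni", "pct_rni", "gap_closure",
                  "baseline_burden", "dalys_saved")

  burden <- per_group |>
    dplyr::group_by(.data$nutrient, .data$treatment, .data$scenario) |>
    dplyr::summarise(
      total_dalys_saved = sum(.data$dalys_saved),
      total_burden = sum(.data$baseline_burden),
      .groups = "drop"
    ) |>
    dplyr::mutate(pct_burden_reduction = pct_burden_reduction(
      .data$total_dalys_saved, .data$total_burden))

  econ <- params$economics
  economics <- burden |>
    dplyr::group_by(.data$treatment, .data$scenario) |>
    dplyr::summarise(total_dalys_saved = sum(.data$total_dalys_saved),
                     .groups = "drop") |>
    dplyr::mutate(economic_benefit = economic_benefit(
      .data$total_dalys_saved, econ$pcni, econ$fertilizer_cost_per_ha,
      econ$area_ha))

  structure(list(groups = per_group, burden = burden, economics = economics,
                 reference_treatment = ref),
            class = "ofs_health")
}

#' @export
print.ofs_health <- function(x, ...) {
  cat("<ofs_health> reference treatment:", x$reference_treatment, "\n")
  print(x$burden)
  invisible(x)
}

#' Tidy a health assessment
#'
#' @param x An `ofs_health` object.
#' @param ... Unused.
#' @return The per-group results tibble.
#' @export
tidy.ofs_health <- function(x, ...) x$groups

#' Glance at a health assessment
#'
#' @param x An `ofs_health` object.
#' @param ... Unused.
#' @return The per-treatment x scenario economics tibble.
#' @export
glance.ofs_health <- function(x, ...) x$economics
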