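# Nutritional yield and phytate-based bioavailability.
#
# Nutritional yield NY = C * GY / DRI / 365: the number of adults whose
# annual reference intake of a nutrient is met by one hectare's harvest.
# Units are reconciled internally: grain content C in mg kg^-1 (or MJ kg^-1
# for energy), dry grain yield GY in Mg ha^-1 (1 Mg = 1000 kg), DRI in
# mg day^-1 (MJ day^-1 for energy).

#' Nutritional yield of a mineral
#'
#' `NY = C * GY / DRI / 365` in adults ha^-1 year^-1: grain mineral output
#' per hectare divided by one adult's annual reference intake.
#'
#' @param content Grain mineral content, mg kg^-1.
#' @param grain_yield Dry grain yield, Mg ha^-1.
#' @param dri Daily reference intake, mg day^-1 (> 0).
#' @return Nutritional yield, adults ha^-1. Vectorized.
#' @export
#' @examples
#' nutritional_yield(37.13, 9.06, 13.00) # ~70.9 adults ha^-1
nutritional_yield <- function(content, grain_yield, dri) {
  if (any(dri <= 0)) stop("dri must be > 0", call. = FALSE)
  if (any(content < 0) || any(grain_yield < 0)) {
    stop("content and grain_yield must be >= 0", call. = FALSE)
  }
  content * (grain_yield * 1000) / dri / 365
}

#' Nutritional yield of energy
#'
#' Converts the grain energy density from kcal per 100 g to MJ kg^-1 with
#' the thermochemical factor 4.184 kJ kcal^-1, then applies the
#' nutritional-yield formula against the daily energy reference intake.
#'
#' @param grain_yield Dry grain yield, Mg ha^-1 (> 0).
#' @param energy_density Energy density, kcal per 100 g; default 339 (wheat).
#' @param dri_energy Daily energy reference intake, MJ day^-1; default 8.47.
#' @return Nutritional yield, adults ha^-1. Vectorized over `grain_yield`.
#' @export
#' @examples
#' energy_nutritional_yield(8.00)  # ~36.7 adults ha^-1
energy_nutritional_yield <- function(grain_yield, energy_density = 339,
                                     dri_energy = 8.47) {
  if (any(grain_yield <= 0) || energy_density <= 0 || dri_energy <= 0) {
    stop("all inputs must be > 0", call. = FALSE)
  }
  mj_per_kg <- energy_density * 10 * 4.184 / 1000   # kcal/100 g -> MJ/kg
  mj_per_kg * (grain_yield * 1000) / dri_energy / 365
}

#' Phytate-to-mineral molar ratio
#'
#' `(PA / M_PA) / (mineral / M_mineral)` with both concentrations on the
#' same mass basis; a unitless mol/mol ratio used as a simplified inverse
#' index of mineral bioavailability (higher ratio, stronger chelation,
#' lower absorption). Molar masses: phytic acid 660.04, Fe 55.845,
#' Mn 54.938, Cu 63.546, Zn 65.38 g mol^-1.
#'
#' @param phytic_acid Phytic acid content, g kg^-1 (> 0).
#' @param mineral_content Mineral content, mg kg^-1 (> 0).
#' @param mineral One of `"Fe"`, `"Mn"`, `"Cu"`, `"Zn"`.
#' @return Unitless molar ratio. Vectorized over the concentrations.
#' @export
#' @examples
#' phytate_molar_ratio(8.20, 24.61, "Zn")  # ~33
phytate_molar_ratio <- function(phytic_acid, mineral_content, mineral) {
  specs <- default_nutrient_specs()
  mineral <- match.arg(mineral, c("Fe", "Mn", "Cu", "Zn"))
  m_min <- specs$molar_mass[specs$nutrient == mineral]
  if (any(phytic_acid <= 0) || any(mineral_content <= 0)) {
    stop("phytic_acid and mineral_content must be > 0", call. = FALSE)
  }
  (phytic_acid / phytic_acid_molar_mass()) /
    ((mineral_content / 1000) / m_min)
}

#' Bioavailability threshold flag for Fe and Zn
#'
#' Minerals are considered well absorbed when the phytate molar ratio falls
#' below the conventional thresholds: PA/Zn < 15 and PA/Fe < 1. No
#' threshold is defined for Mn or Cu.
#'
#' @param ratio Phytate-to-mineral molar ratio.
#' @param mineral `"Fe"` or `"Zn"`.
#' @return Logical: `TRUE` when the ratio is below the mineral's threshold.
#' @export
#' @examples
#' bioavailability_flag(31.19, "Zn")  # FALSE: still above 15
bioavailability_flag <- function(ratio, mineral) {
  mineral <- match.arg(mineral, c("Fe", "Zn"))
  threshold <- c(Fe = 1, Zn = 15)[[mineral]]
  ratio < threshold
}

#' Percent change relative to a reference
#'
#' `100 * (value - reference) / reference`.
#'
#' @param reference Reference value (nonzero).
#' @param value New value.
#' @return Percent change. Vectorized.
#' @export
#' @examples
#' percent_change(8.00, 9.58)  # 19.75
percent_change <- function(reference, value) {
  if (any(reference == 0)) stop("reference must be nonzero", call. = FALSE)
  100 * (value - reference) / reference
}

#' Per-plot nutritional yields for all nutrients
#'
#' Computes the nutritional yield of Fe, Mn, Cu, Zn and energy for every
#' plot, then (optionally) the per-treatment mean, SD and significance
#' letters. The per-plot-then-average mode matches how treatment tables are
#' usually reported (NY computed per plot, averaged within treatment); the
#' alternative applies the formula to treatment means directly.
#'
#' @param plots A plot table.
#' @param specs Nutrient specifications; default [default_nutrient_specs()].
#' @param energy_density Grain energy density, kcal per 100 g; default 339.
#' @return A long tibble: one row per plot x nutrient with columns `site`,
#'   `treatment`, `replicate`, `nutrient`, `ny` (adults ha^-1).
#' @seealso [nutritional_yield_summary()]
#' @export
nutritional_yield_table <- function(plots, specs = default_nutrient_specs(),
                                    energy_density = 339) {
  plots <- validate_plot_table(plots)
  content_cols <- c(Fe = "grain_fe", Mn = "grain_mn", Cu = "grain_cu",
                    Zn = "grain_zn")
  mineral_rows <- purrr::map_dfr(names(content_cols), function(nm) {
    dri <- specs$dri[specs$nutrient == nm]
    dplyr::transmute(
      plots, site = .data$site, treatment = .data$treatment,
      replicate = .data$replicate, nutrient = nm,
      ny = nutritional_yield(.data[[content_cols[[nm]]]], .data$yield, dri)
    )
  })
  dri_e <- specs$dri[specs$nutrient == "energy"]
  energy_rows <- dplyr::transmute(
    plots, site = .data$site, treatment = .data$treatment,
    replicate = .data$replicate, nutrient = "energy",
    ny = energy_nutritional_yield(.data$yield, energy_density, dri_e)
  )
  out <- dplyr::bind_rows(mineral_rows, energy_rows)
  out$nutrient <- factor(out$nutrient, levels = c("Fe", "Mn", "Cu", "Zn",
                                                  "energy"))
  out
}

#' Treatment-level nutritional yield summary with letters
#'
#' Averages per-plot nutritional yields within treatment and attaches
#' Fisher-LSD significance letters per nutrient.
#'
#' @inheritParams nutritional_yield_table
#' @param alpha Significance level for the letters; default 0.05.
#' @return A tibble: `nutrient`, `treatment`, `n`, `mean`, `sd`, `letters`.
#' @export
#' @examples
#' plots <- generate_trial(generator_config(), seed = 1)
#' nutritional_yield_summary(plots)
nutritional_yield_summary <- function(plots, specs = default_nutrient_specs(),
                                      energy_density = 339, alpha = 0.05) {
  ny <- nutritional_yield_table(plots, specs, energy_density)
  purrr::map_dfr(levels(ny$nutrient), function(nm) {
    d <- dplyr::filter(ny, .data$nutrient == nm)
    if (dplyr::n_distinct(d$treatment) < 2) {
      d |>
        dplyr::group_by(treatment = .data$treatment) |>
        dplyr::summarise(n = dplyr::n(), mean = mean(.data$ny),
                         sd = stats::sd(.data$ny), .groups = "drop") |>
        dplyr::mutate(nutrient = nm, letters = NA_character_, .before = 1)
    } else {
      res <- fisher_lsd(d, ny, treatment, alpha = alpha)
      dplyr::mutate(res$summary, nutrient = nm, .before = 1) |>
        dplyr::rename(treatment = "group")
    }
  }) |>
    dplyr::select("nutrient", "treatment", "n", "mean", "sd", "letters")
}

#' Per-plot phytate molar ratios
#'
#' PA/Fe, PA/Mn, PA/Cu and PA/Zn molar ratios for every plot, with the
#' Fe/Zn bioavailability threshold flags.
#'
#' @param plots A plot table.
#' @return A long tibble: `site`, `treatment`, `replicate`, `mineral`,
#'   `ratio`, `bioavailable` (logical; `NA` for Mn and Cu).
#' @export
#' @examples
#' plots <- generate_trial(generator_config(), seed = 1)
#' head(molar_ratio_table(plots))
molar_ratio_table <- function(plots) {
  plots <- validate_plot_table(plots)
  cols <- c(Fe = "grain_fe", Mn = "grain_mn", Cu = "grain_cu", Zn = "grain_zn")
  purrr::map_dfr(names(cols), function(nm) {
    ratio <- phytate_molar_ratio(plots$phytic_acid, plots[[cols[[nm]]]], nm)
    flag <- if (nm %in% c("Fe", "Zn")) bioavailability_flag(ratio, nm) else NA
    tibble::tibble(
      site = plots$site, treatment = plots$treatment,
      replicate = plots$replicate, mineral = nm, ratio = ratio,
      bioavailable = flag
    )
  })
}
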