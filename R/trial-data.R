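# Plot-level field-trial data model: fixed columns, fixed units, strict
# validation. Units are never inferred from the file (Mg ha^-1 for yield,
# mg kg^-1 for grain minerals, g kg^-1 for phytic acid).

#' Treatment levels of the fertilizer trial
#'
#' The five treatments of the multi-site wheat trial, in canonical order:
#' unfertilized control (`CK`), farmers' practice (`FP`), optimized
#' fertilization (`OPT`), and substitution of 15% (`OF15`) or 30% (`OF30`)
#' of chemical nitrogen by organic fertilizer.
#'
#' @return Character vector of the five treatment codes.
#' @export
#' @examples
#' ofs_treatments()
ofs_treatments <- function() {
  c("CK", "FP", "OPT", "OF15", "OF30")
}

# Aliases accepted on input ("15%OF" is the common literature spelling).
.treatment_aliases <- c(
  "CK" = "CK", "FP" = "FP", "OPT" = "OPT",
  "OF15" = "OF15", "OF30" = "OF30",
  "15%OF" = "OF15", "30%OF" = "OF30",
  "15OF" = "OF15", "30OF" = "OF30"
)

#' Normalize treatment labels to canonical codes
#'
#' Maps accepted spellings (e.g. `"15%OF"`) onto the canonical codes of
#' [ofs_treatments()] and returns a factor with the canonical level order.
#'
#' @param x Character or factor vector of treatment labels.
#' @return Factor with levels `CK, FP, OPT, OF15, OF30`.
#' @export
as_treatment <- function(x) {
  x <- as.character(x)
  code <- unname(.treatment_aliases[x])
  bad <- unique(x[is.na(code) & !is.na(x)])
  if (length(bad) > 0) {
    stop("unknown treatment label(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(names(.treatment_aliases), collapse = ", "),
         call. = FALSE)
  }
  factor(code, levels = ofs_treatments())
}

# Required and optional columns of a plot table, with their units.
.plot_required <- c(
  site = "label", treatment = "factor", replicate = "integer >= 1",
  yield = "Mg ha-1", grain_fe = "mg kg-1", grain_mn = "mg kg-1",
  grain_cu = "mg kg-1", grain_zn = "mg kg-1", phytic_acid = "g kg-1"
)
.plot_soil <- c(
  "soil_ph", "soil_om", "soil_tn", "soil_avail_p", "soil_avail_k",
  "soil_dtpa_fe", "soil_dtpa_mn", "soil_dtpa_cu", "soil_dtpa_zn"
)

#' Validate a plot-level trial table
#'
#' Checks the invariants of a plot table: required columns present, yield
#' strictly positive, concentrations non-negative, replicate a positive
#' integer, treatment one of the five levels, and `(site, treatment,
#' replicate)` unique. Errors name the offending column and row.
#'
#' @param plots A data frame of plot records.
#' @return The validated table as a tibble, invisibly unchanged apart from
#'   treatment being normalized to a factor. Row order is preserved.
#' @export
validate_plot_table <- function(plots) {
  plots <- tibble::as_tibble(plots)
  missing <- setdiff(names(.plot_required), names(plots))
  if (length(missing) > 0) {
    stop("plot table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  plots$treatment <- as_treatment(plots$treatment)

  num_cols <- c("yield", "grain_fe", "grain_mn", "grain_cu", "grain_zn",
                "phytic_acid")
  for (col in c(num_cols, "replicate")) {
    v <- plots[[col]]
    if (!is.numeric(v)) {
      stop("column '", col, "' must be numeric", call. = FALSE)
    }
    if (anyNA(v)) {
      stop("column '", col, "' has missing values in row(s) ",
           paste(which(is.na(v)), collapse = ", "), call. = FALSE)
    }
  }
  bad_yield <- which(plots$yield <= 0)
  if (length(bad_yield) > 0) {
    stop("yield must be > 0; violated in row(s) ",
         paste(bad_yield, collapse = ", "), call. = FALSE)
  }
  for (col in setdiff(num_cols, "yield")) {
    bad <- which(plots[[col]] < 0)
    if (length(bad) > 0) {
      stop("column '", col, "' must be >= 0; violated in row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  bad_rep <- which(plots$replicate < 1 | plots$replicate != round(plots$replicate))
  if (length(bad_rep) > 0) {
    stop("replicate must be a positive integer; violated in row(s) ",
         paste(bad_rep, collapse = ", "), call. = FALSE)
  }
  key <- paste(plots$site, plots$treatment, plots$replicate, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop("duplicate (site, treatment, replicate) in row(s) ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  plots
}

#' Read a plot-level trial table from CSV
#'
#' Reads a UTF-8 CSV with a header row and "." decimal separator, validates
#' every record, and returns a tibble in file order. Column units are fixed
#' by name: `yield` in Mg ha^-1 dry grain, `grain_fe`/`grain_mn`/`grain_cu`/
#' `grain_zn` in mg kg^-1, `phytic_acid` in g kg^-1; optional `soil_*`
#' covariates are carried through untouched.
#'
#' @param path Path to a CSV file.
#' @param col_map Optional named character vector mapping file header names
#'   onto the canonical column names, e.g. `c(Yield = "yield")`.
#' @param moisture_fraction Grain moisture fraction in `[0, 1)` of the
#'   reported yields; yields are converted to dry mass by multiplying with
#'   `1 - moisture_fraction`. Default 0 (yields already dry).
#' @return A tibble of validated plot records.
#' @seealso [write_plot_table()], [validate_plot_table()]
#' @export
read_plot_table <- function(path, col_map = NULL, moisture_fraction = 0) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  stopifnot(moisture_fraction >= 0, moisture_fraction < 1)
  plots <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                           comment = "#")
  if (!is.null(col_map)) {
    hit <- names(plots) %in% names(col_map)
    names(plots)[hit] <- unname(col_map[names(plots)[hit]])
  }
  if (moisture_fraction > 0 && "yield" %in% names(plots)) {
    plots$yield <- plots$yield * (1 - moisture_fraction)
  }
  validate_plot_table(plots)
}

#' Write a plot-level trial table to CSV
#'
#' Writes records at full double precision so that
#' `read_plot_table(write_plot_table(x, f))` reproduces `x` exactly on all
#' numeric fields.
#'
#' @param plots A valid plot table (see [validate_plot_table()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_plot_table <- function(plots, path) {
  if (nrow(plots) > 0) plots <- validate_plot_table(plots)
  out <- tibble::as_tibble(plots)
  if ("treatment" %in% names(out)) out$treatment <- as.character(out$treatment)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Reference nutrient specifications
#'
#' The five nutrients tracked by the pipeline with their molar masses,
#' daily reference intakes (DRI) used in the nutritional-yield denominator,
#' and the fraction recovered in flour after milling (bran removal), used by
#' the health-impact model. DRIs are 8.47 MJ day^-1 for energy and 13.00,
#' 2.05, 0.90 and 9.50 mg day^-1 for Fe, Mn, Cu and Zn; milling recovery is
#' 0.217 for Fe and 0.310 for Zn (Mn, Cu and energy have no recovery in the
#' model and carry `NA`).
#'
#' @return A tibble with columns `nutrient`, `molar_mass` (g mol^-1, `NA`
#'   for energy), `dri` (mg day^-1 for minerals, MJ day^-1 for energy),
#'   `dri_unit`, and `recovery` (fraction in `[0, 1]`).
#' @export
#' @examples
#' default_nutrient_specs()
default_nutrient_specs <- function() {
  tibble::tibble(
    nutrient   = c("Fe", "Mn", "Cu", "Zn", "energy"),
    molar_mass = c(55.845, 54.938, 63.546, 65.38, NA_real_),
    dri        = c(13.00, 2.05, 0.90, 9.50, 8.47),
    dri_unit   = c(rep("mg day-1", 4), "MJ day-1"),
    recovery   = c(0.217, NA_real_, NA_real_, 0.310, NA_real_)
  )
}

#' Molar mass of phytic acid
#'
#' Phytic acid (myo-inositol hexakisphosphate, C6H18O24P6), 660.04 g mol^-1.
#' Used as the numerator basis of the phytate-to-mineral molar ratios.
#'
#' @return A single number, g mol^-1.
#' @export
phytic_acid_molar_mass <- function() 660.04
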