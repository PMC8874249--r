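#' Convert a molar assay concentration to mass units
#'
#' @param conc Concentration in uM.
#' @param molecular_weight Molecular weight, g/mol.
#' @return Concentration in mg/L (`conc * molecular_weight / 1000`).
#' @examples
#' um_to_mgl(0.01, 228.291)  # 2.28e-3 mg/L
#' um_to_mgl(70, 228.291)    # 16.0 mg/L
#' @export
um_to_mgl <- function(conc, molecular_weight) {
  if (any(conc < 0)) stop("concentration must be >= 0")
  if (molecular_weight <= 0) stop("molecular_weight must be > 0")
  conc * molecular_weight / 1000
}

#' Assay well set-up for the in vitro fate model
#'
#' Default well geometries per plate format.  The 24-well defaults describe
#' a standard plate (1 mL working medium, 1.9 cm2 growth area, wetted
#' surface ~4.5 cm2, ~2.4 mL headspace); the 384-well defaults a standard
#' low-volume plate.  Geometry constants are package defaults, not
#' measurements from any specific laboratory.
#'
#' @param plate_format `"24-well"` or `"384-well"`.
#' @param serum_fraction Volume fraction of serum in the medium.
#' @param medium_volume,headspace_volume Litres; defaults per plate format.
#' @param well_surface_area Wetted plastic area, m2.
#' @param cell_count Cells per well.
#' @param cell_volume Single-cell volume, L.
#' @param exposure_duration Exposure time, h (used only for the optional
#'   degradation correction).
#' @return An `assay_setup` list.
#' @export
assay_setup <- function(plate_format = c("24-well", "384-well"),
                        serum_fraction = 0.05,
                        medium_volume = NULL, headspace_volume = NULL,
                        well_surface_area = NULL, cell_count = NULL,
                        cell_volume = 3e-15, exposure_duration = 24) {
  plate_format <- match.arg(plate_format)
  def <- switch(plate_format,
    "24-well" = list(medium = 1e-3, head = 2.4e-3, area = 4.5e-4,
                     cells = 2e5),
    "384-well" = list(medium = 4e-5, head = 8e-5, area = 3.5e-5,
                      cells = 8e3)
  )
  if (serum_fraction < 0 || serum_fraction > 1) {
    stop("serum_fraction must be in [0, 1]")
  }
  out <- list(
    plate_format = plate_format,
    serum_fraction = serum_fraction,
    medium_volume = medium_volume %||% def$medium,
    headspace_volume = headspace_volume %||% def$head,
    well_surface_area = well_surface_area %||% def$area,
    cell_count = cell_count %||% def$cells,
    cell_volume = cell_volume,
    exposure_duration = exposure_duration
  )
  if (any(unlist(out[3:5]) <= 0)) stop("volumes and area must be > 0")
  structure(out, class = "assay_setup")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Kow-regression coefficients for the serum and plastic distribution ratios.
# The serum intercept is a calibration constant: with 5% serum in a 24-well
# plate it reproduces the free:nominal ratio of ~0.499 predicted for BPA by
# the original in vitro fate-and-distribution run (see the methods vignette).
vcba_regression <- function() {
  list(
    serum_logk = c(slope = 0.71, intercept = -1.0785),   # L/L serum
    plastic_logk = c(slope = 0.97, intercept = -5.29),   # L/m2
    cell_logk = c(slope = 0.76, intercept = -0.25),      # L/L cells
    temperature = 310.15                                 # K, 37 C
  )
}

#' Partition a nominal assay concentration over the well compartments
#'
#' Equilibrium mass-balance allocation of the chemical among the aqueous
#' medium, serum constituents, well plastic, headspace (Henry's law) and
#' cells.  Serum, plastic and cell affinities are log-Kow regressions with
#' coefficients exposed via `vcba_regression()`.
#'
#' @param nominal Nominal concentration, mg/L of medium.
#' @param chem Named list of physicochemical constants ([bpa_physchem()]
#'   layout: `molecular_weight`, `henry_constant`, `log_kow`,
#'   `degradation_rate_water`, ...).
#' @param setup An [assay_setup()].
#' @param degradation If `TRUE`, additionally report the surviving fraction
#'   after first-order abiotic degradation over the exposure duration.
#' @return A `partition_result` list: the five mass fractions (summing to 1),
#'   `free_concentration` (mg/L, `nominal * fraction_free_medium`) and
#'   `degradation_factor`.
#' @examples
#' partition(um_to_mgl(0.01, 228.291), bpa_physchem(), assay_setup("24-well"))
#' @export
partition <- function(nominal, chem, setup = assay_setup(),
                      degradation = FALSE) {
  if (nominal < 0) stop("nominal concentration must be >= 0")
  if (!inherits(setup, "assay_setup")) stop("setup must be an assay_setup")
  reg <- vcba_regression()
  lkow <- chem$log_kow
  v_med <- setup$medium_volume
  v_ser <- setup$serum_fraction * v_med
  v_aq <- v_med - v_ser
  d_ser <- 10^(reg$serum_logk[["slope"]] * lkow +
                 reg$serum_logk[["intercept"]])
  k_pl <- 10^(reg$plastic_logk[["slope"]] * lkow +
                reg$plastic_logk[["intercept"]])
  d_cell <- 10^(reg$cell_logk[["slope"]] * lkow +
                  reg$cell_logk[["intercept"]])
  k_aw <- chem$henry_constant / (8.314462 * reg$temperature)
  v_cell <- setup$cell_count * setup$cell_volume

  cap_aq <- v_aq
  cap_ser <- d_ser * v_ser
  cap_pl <- k_pl * setup$well_surface_area
  cap_hs <- k_aw * setup$headspace_volume
  cap_cell <- d_cell * v_cell
  cap_tot <- cap_aq + cap_ser + cap_pl + cap_hs + cap_cell

  fr <- c(fraction_free_medium = cap_aq, fraction_serum_bound = cap_ser,
          fraction_plastic = cap_pl, fraction_headspace = cap_hs,
          fraction_cells = cap_cell) / cap_tot
  deg <- exp(-chem$degradation_rate_water * 3600 * setup$exposure_duration)
  structure(c(as.list(fr), list(
    free_concentration = nominal * fr[["fraction_free_medium"]] *
      if (degradation) deg else 1,
    nominal = nominal,
    degradation_factor = deg
  )), class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat("<partition_result> free/nominal =",
      signif(x$fraction_free_medium, 4), "\n")
  invisible(x)
}

#' Augment an assay table with nominal and free mass concentrations
#'
#' Takes a ToxCast-dashboard-style concentration-response table (uM
#' concentrations) and adds the nominal mg/L, free mg/L and free:nominal
#' ratio columns computed by [partition()], reproducing the layout of the
#' published free-concentration tables.
#'
#' @param raw Tibble with columns `conc_um`, `response`, `response_type`
#'   (and optionally `assay`); [bpa_assays()] returns this layout.
#' @param chem Physicochemical constants ([bpa_physchem()] layout).
#' @param setup An [assay_setup()].
#' @return The input tibble with `nominal_mgl`, `free_mgl` and `ratio`
#'   columns appended.
#' @export
transform_assay_table <- function(raw, chem = bpa_physchem(),
                                  setup = assay_setup()) {
  required <- c("conc_um", "response", "response_type")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("assay table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(raw) == 0) {
    return(dplyr::mutate(raw, nominal_mgl = numeric(0),
                         free_mgl = numeric(0), ratio = numeric(0)))
  }
  bad <- which(!is.finite(raw$conc_um) | raw$conc_um < 0)
  if (length(bad) > 0) {
    stop("malformed concentration in row(s): ", paste(bad, collapse = ", "))
  }
  nominal <- um_to_mgl(raw$conc_um, chem$molecular_weight)
  part <- lapply(nominal, partition, chem = chem, setup = setup)
  dplyr::mutate(raw,
    nominal_mgl = nominal,
    free_mgl = purrr::map_dbl(part, "free_concentration"),
    ratio = purrr::map_dbl(part, "fraction_free_medium")
  )
}
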