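# Reverse-dosimetry unit bridge.
#
# Connects culture-insert exposure concentrations to airway surface
# deposition with plain arithmetic: per-area in vitro dose
# (concentration x collection volume / insert area), tracheobronchial
# surface-area aggregation over airway generations, and deposited mass per
# region area. Full aerosol deposition physics (the MPPD model) is out of
# scope; its published input parameters ship as a YAML fixture for a future
# integration.

#' In vitro exposure specification
#'
#' @param concentration nicotine concentration in the collected dose,
#'   ug/mL.
#' @param collection_volume collected liquid volume, mL (the reference
#'   study collected 110 uL, i.e. 0.110 mL).
#' @param insert_area culture-insert surface area, cm^2 (reference:
#'   0.33 cm^2).
#' @param label free-text label.
#' @return object of class `"exposure_spec"`.
#' @export
exposure_spec <- function(concentration, collection_volume = 0.110,
                          insert_area = 0.33, label = NULL) {
  assert_scalar_pos(concentration, "concentration")
  assert_scalar_pos(collection_volume, "collection_volume")
  assert_scalar_pos(insert_area, "insert_area")
  structure(list(concentration = concentration,
                 collection_volume = collection_volume,
                 insert_area = insert_area,
                 label = label %||% sprintf("%g ug/mL", concentration)),
            class = "exposure_spec")
}

#' Per-area in vitro dose
#'
#' `concentration x collection_volume / insert_area`, in
#' ug/cigarette/cm^2/day (one in vitro exposure corresponds to one
#' cigarette per day). Reported rounded to 2 decimals by convention;
#' pass `digits = NULL` for full precision.
#'
#' @param spec an [exposure_spec()].
#' @param digits decimal places for rounding (default 2; `NULL` = none).
#' @return per-area dose in ug/cigarette/cm^2/day.
#' @examples
#' per_area_dose(exposure_spec(0.51))  # 0.17
#' per_area_dose(exposure_spec(1.62))  # 0.54
#' per_area_dose(exposure_spec(4.49))  # 1.50
#' @export
per_area_dose <- function(spec, digits = 2) {
  stopifnot(inherits(spec, "exposure_spec"))
  x <- spec$concentration * spec$collection_volume / spec$insert_area
  if (is.null(digits)) x else round(x, digits)
}

#' Read an airway geometry table
#'
#' CSV with columns `generation` (integer, >= 0, unique) and `area_cm2`
#' (positive total surface area of that generation). The packaged fixture
#' `system.file("extdata", "airway_geometry_weibel.csv", package =
#' "qaopbn")` is computed from the Weibel model "A" morphometry
#' (cylindrical airways: area = pi x diameter x length x count).
#'
#' @param path CSV path.
#' @return data.frame of class `"airway_geometry"`.
#' @export
read_airway_geometry <- function(path = system.file("extdata",
                                                    "airway_geometry_weibel.csv",
                                                    package = "qaopbn")) {
  g <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("generation", "area_cm2") %in% names(g))) {
    stop_domain("geometry CSV needs columns 'generation' and 'area_cm2'")
  }
  if (anyDuplicated(g$generation)) stop_domain("generations must be unique")
  if (any(g$area_cm2 <= 0)) stop_domain("areas must be positive")
  class(g) <- c("airway_geometry", "data.frame")
  g
}

#' Tracheobronchial surface area over a generation range
#'
#' Sums the per-generation surface areas over the inclusive range
#' `[gen_min, gen_max]`. The default 0-6 covers the region where goblet
#' cells occur (none are found at generation 7 or deeper), i.e. the tissue
#' relevant to goblet-cell metaplasia/hyperplasia.
#'
#' @param geometry an `airway_geometry` data.frame.
#' @param gen_min,gen_max inclusive generation range.
#' @return total surface area, cm^2.
#' @export
tb_surface_area <- function(geometry, gen_min = 0, gen_max = 6) {
  wanted <- seq(gen_min, gen_max)
  missing <- setdiff(wanted, geometry$generation)
  if (length(missing)) {
    stop_domain("geometry lacks generation(s): ",
                paste(missing, collapse = ", "))
  }
  sum(geometry$area_cm2[geometry$generation %in% wanted])
}

#' Deposition concentration in a real-use scenario
#'
#' Deposited mass per region surface area, ug/cm^2/cigarette.
#'
#' @param deposited_mass mass deposited on the region per cigarette, ug
#'   (an input — e.g. an MPPD-model output; deposition physics is not
#'   computed here).
#' @param region_area region surface area, cm^2.
#' @return deposition concentration, ug/cm^2/cigarette.
#' @export
deposition_concentration <- function(deposited_mass, region_area) {
  assert_scalar_pos(deposited_mass, "deposited_mass")
  assert_scalar_pos(region_area, "region_area")
  deposited_mass / region_area
}

#' Compare in vitro per-area doses with a real-use deposition scenario
#'
#' @param in_vitro list of [exposure_spec()] objects.
#' @param real_use_concentration real-use deposition concentration,
#'   ug/cm^2/cigarette (see [deposition_concentration()]).
#' @param digits rounding for the reported per-area doses.
#' @return data.frame with columns `label`, `per_area_dose`,
#'   `real_use`, `ratio`.
#' @export
compare_scenarios <- function(in_vitro, real_use_concentration, digits = 2) {
  if (!length(in_vitro)) stop_domain("empty in vitro specification list")
  assert_scalar_pos(real_use_concentration, "real_use_concentration")
  rows <- lapply(in_vitro, function(s) {
    pad <- per_area_dose(s, digits = digits)
    data.frame(label = s$label, per_area_dose = pad,
               real_use = real_use_concentration,
               ratio = pad / real_use_concentration,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Packaged MPPD input-parameter fixture
#'
#' Reads the YAML fixture of published model inputs for the aerosol
#' deposition model (smoking topography, aerosol properties, respiratory
#' tract properties and smoke-constituent physical properties). These are
#' metadata for a future deposition-model integration; no deposition
#' physics is computed in this package.
#'
#' @param path YAML path (default: the packaged fixture).
#' @return named list of the four parameter tables.
#' @export
read_mppd_parameters <- function(path = system.file("extdata",
                                                    "mppd_parameters.yaml",
                                                    package = "qaopbn")) {
  yaml::read_yaml(path)
}
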