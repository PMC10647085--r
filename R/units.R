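# Unit registry: dimensions, canonical units and provider spelling aliases.
#
# Canonical units are SI-aligned with two field-driven exceptions: temperature
# is kept in kelvin and pressure in kilopascal (the unit query results are
# reported in), concentrations and densities in kg/m^3, molar mass in g/mol.

KIND_DIMENSIONS <- c(
  BoilingPoint = "temperature",
  MeltingPoint = "temperature",
  FlashPoint = "temperature",
  AutoignitionTemperature = "temperature",
  VaporPressure = "pressure",
  Density = "mass_density",
  Solubility = "mass_concentration",
  MolecularWeight = "molar_mass",
  Charge = "charge"
)

DIMENSION_CANONICAL <- c(
  temperature = "K",
  pressure = "kPa",
  mass_density = "kg/m^3",
  mass_concentration = "kg/m^3",
  molar_mass = "g/mol",
  charge = "e"
)

# Built-in alias table. `factor` converts to the canonical unit of the
# dimension (temperature is non-linear and handled by convert_temperature).
# `metric` records whether the spelling belongs to the metric system; the
# curation tie-break prefers metric originals.
default_unit_aliases <- function() {
  rows <- list(
    # temperature
    c("K", "K", "temperature", NA, TRUE), c("kelvin", "K", "temperature", NA, TRUE),
    c("°C", "°C", "temperature", NA, TRUE),
    c("C", "°C", "temperature", NA, TRUE),
    c("deg C", "°C", "temperature", NA, TRUE),
    c("degC", "°C", "temperature", NA, TRUE),
    c("celsius", "°C", "temperature", NA, TRUE),
    c("°F", "°F", "temperature", NA, FALSE),
    c("F", "°F", "temperature", NA, FALSE),
    c("deg F", "°F", "temperature", NA, FALSE),
    c("degF", "°F", "temperature", NA, FALSE),
    c("fahrenheit", "°F", "temperature", NA, FALSE),
    # pressure
    c("kPa", "kPa", "pressure", 1, TRUE),
    c("Pa", "Pa", "pressure", 0.001, TRUE),
    c("hPa", "hPa", "pressure", 0.1, TRUE),
    c("bar", "bar", "pressure", 100, TRUE),
    c("mbar", "mbar", "pressure", 0.1, TRUE),
    c("mmHg", "mmHg", "pressure", 101.325 / 760, FALSE),
    c("mm Hg", "mmHg", "pressure", 101.325 / 760, FALSE),
    c("torr", "mmHg", "pressure", 101.325 / 760, FALSE),
    c("atm", "atm", "pressure", 101.325, FALSE),
    # mass concentration (solubility)
    c("kg/m^3", "kg/m^3", "mass_concentration", 1, TRUE),
    c("kg/m3", "kg/m^3", "mass_concentration", 1, TRUE),
    c("mg/L", "mg/L", "mass_concentration", 0.001, TRUE),
    c("mg/l", "mg/L", "mass_concentration", 0.001, TRUE),
    c("g/L", "g/L", "mass_concentration", 1, TRUE),
    c("g/l", "g/L", "mass_concentration", 1, TRUE),
    c("mg/mL", "mg/mL", "mass_concentration", 1, TRUE),
    c("mg/ml", "mg/mL", "mass_concentration", 1, TRUE),
    c("ug/mL", "ug/mL", "mass_concentration", 0.001, TRUE),
    c("µg/mL", "ug/mL", "mass_concentration", 0.001, TRUE),
    c("g/100mL", "g/100mL", "mass_concentration", 10, TRUE),
    c("g/100 mL", "g/100mL", "mass_concentration", 10, TRUE),
    # mass density
    c("g/cm^3", "g/cm^3", "mass_density", 1000, TRUE),
    c("g/cm3", "g/cm^3", "mass_density", 1000, TRUE),
    c("g/cu cm", "g/cm^3", "mass_density", 1000, TRUE),
    c("g/mL", "g/mL", "mass_density", 1000, TRUE),
    c("g/ml", "g/mL", "mass_density", 1000, TRUE),
    # molar mass
    c("g/mol", "g/mol", "molar_mass", 1, TRUE),
    c("kg/mol", "kg/mol", "molar_mass", 1000, TRUE),
    c("Da", "Da", "molar_mass", 1, TRUE),
    c("amu", "amu", "molar_mass", 1, TRUE),
    # elementary charge
    c("e", "e", "charge", 1, TRUE)
  )
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("alias", "unit", "dimension", "factor", "metric")
  df$factor <- as.numeric(df$factor)
  df$metric <- as.logical(df$metric)
  df
}

unit_alias_env <- new.env(parent = emptyenv())

#' The unit-alias table
#'
#' Maps provider unit spellings (e.g. `"deg F"`, `"mm Hg"`, `"torr"`) to a
#' canonical spelling, its dimension, the multiplicative factor to the
#' dimension's canonical unit (NA for the non-linear temperature scales) and
#' whether the spelling is metric.
#'
#' @return a data frame with columns `alias`, `unit`, `dimension`, `factor`,
#'   `metric`.
#' @export
unit_aliases <- function() {
  if (is.null(unit_alias_env$table)) unit_alias_env$table <- default_unit_aliases()
  unit_alias_env$table
}

#' Extend the unit-alias table
#'
#' @param alias new spelling as it appears in provider strings.
#' @param unit canonical spelling it maps to.
#' @param dimension one of the registry dimensions (see [canonical_unit()]).
#' @param factor multiplicative factor to the dimension's canonical unit
#'   (ignored for temperature).
#' @param metric whether the spelling is a metric unit.
#' @return the updated alias table, invisibly.
#' @export
register_unit_alias <- function(alias, unit, dimension, factor = NA_real_,
                                metric = TRUE) {
  tab <- unit_aliases()
  stopifnot(dimension %in% names(DIMENSION_CANONICAL))
  tab <- rbind(tab, data.frame(alias = alias, unit = unit,
                               dimension = dimension,
                               factor = as.numeric(factor),
                               metric = isTRUE(metric),
                               stringsAsFactors = FALSE))
  unit_alias_env$table <- tab
  invisible(tab)
}

lookup_unit <- function(unit_text) {
  tab <- unit_aliases()
  i <- match(unit_text, tab$alias)
  if (is.na(i)) NULL else tab[i, , drop = FALSE]
}

#' Canonical unit and dimension of a property kind
#'
#' @param kind property-kind label, e.g. `"BoilingPoint"`.
#' @return for `canonical_unit`, the canonical unit string, or `NA` for kinds
#'   outside the registry (such kinds are stored unconstrained); for
#'   `kind_dimension`, the dimension name or `NA`.
#' @export
canonical_unit <- function(kind) {
  dim <- kind_dimension(kind)
  if (is.na(dim)) NA_character_ else unname(DIMENSION_CANONICAL[dim])
}

#' @rdname canonical_unit
#' @export
kind_dimension <- function(kind) {
  if (kind %in% names(KIND_DIMENSIONS)) unname(KIND_DIMENSIONS[kind]) else NA_character_
}

#' Convert a temperature to kelvin
#'
#' Exact affine conversions, no rounding: K passes through, Celsius adds
#' 273.15, Fahrenheit maps via (value - 32) * 5/9 + 273.15.
#'
#' @param value numeric temperature value(s).
#' @param unit `"K"`, `"°C"` or `"°F"` (any registered alias).
#' @return temperature in kelvin.
#' @examples
#' convert_temperature(134.4, "°F")
#' @export
convert_temperature <- function(value, unit) {
  u <- lookup_unit(unit)
  if (is.null(u) || u$dimension != "temperature") {
    stop(sprintf("unknown temperature unit %s", dQuote(unit)), call. = FALSE)
  }
  switch(u$unit,
         "K" = value,
         "°C" = value + 273.15,
         "°F" = (value - 32) * 5 / 9 + 273.15)
}

#' Convert a pressure to kilopascal
#'
#' Standard conversion factors; mmHg is defined as 101.325/760 kPa.
#'
#' @param value numeric pressure value(s), > 0.
#' @param unit a registered pressure unit (`"kPa"`, `"Pa"`, `"mmHg"`,
#'   `"atm"`, `"bar"`, ...).
#' @return pressure in kPa.
#' @examples
#' convert_pressure(760, "mmHg")
#' @export
convert_pressure <- function(value, unit) {
  u <- lookup_unit(unit)
  if (is.null(u) || u$dimension != "pressure") {
    stop(sprintf("unknown pressure unit %s", dQuote(unit)), call. = FALSE)
  }
  value * u$factor
}

convert_to_canonical <- function(value, unit) {
  u <- lookup_unit(unit)
  if (is.null(u)) {
    stop(sprintf("unknown unit %s", dQuote(unit)), call. = FALSE)
  }
  if (u$dimension == "temperature") {
    list(value = convert_temperature(value, unit),
         unit = "K", dimension = "temperature")
  } else {
    list(value = value * u$factor,
         unit = unname(DIMENSION_CANONICAL[u$dimension]),
         dimension = u$dimension)
  }
}
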