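#' Supported concentration units
#'
#' Sediment concentrations are handled on a dry-weight mass-fraction basis in
#' one of two units: milligrams per kilogram (`"mg/kg"`) or nanograms per gram
#' (`"ng/g"`). The canonical internal unit throughout the package is mg/kg;
#' ng/g appears only at I/O boundaries and in hazard/target report tables.
#'
#' @keywords internal
#' @name sed-units
NULL

.sed_units <- c("mg/kg", "ng/g")

# Accepts "mg/kg", "mg/kg dw", "ng/g", "ng/g dw" (case-insensitive).
normalize_unit <- function(unit) {
  u <- tolower(trimws(unit))
  u <- sub("\\s*dw$", "", u)
  if (!all(u %in% .sed_units)) {
    bad <- unique(unit[!u %in% .sed_units])
    stop("unknown concentration unit: ", paste(sQuote(bad), collapse = ", "),
         " (supported: mg/kg dw, ng/g dw)", call. = FALSE)
  }
  u
}

#' Convert between sediment concentration units
#'
#' Converts mass-fraction concentrations between mg/kg dry weight and
#' ng/g dry weight (factor 1000). Same-unit conversion is the identity.
#'
#' @param value numeric vector of concentrations.
#' @param from,to unit tags, one of `"mg/kg"` or `"ng/g"` (an optional
#'   `" dw"` suffix is accepted).
#' @return numeric vector in the `to` unit.
#' @examples
#' convert_units(0.36, "mg/kg", "ng/g")  # 360
#' convert_units(46.2, "ng/g", "mg/kg")  # 0.0462
#' @export
convert_units <- function(value, from, to) {
  from <- normalize_unit(from)
  to <- normalize_unit(to)
  stopifnot(is.numeric(value))
  # mg/kg -> ng/g is *1000; encode each unit as a power of 1000 relative
  # to mg/kg and scale by the difference.
  pow <- c("mg/kg" = 0, "ng/g" = 1)
  value * 1000^(pow[[to]] - pow[[from]])
}
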