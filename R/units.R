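# Unit conversion. All analysis runs in molar and seconds; conversion
# happens once, at the I/O boundary.

.conc_units <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12)
.time_units <- c(s = 1, min = 60, h = 3600)

#' Convert concentrations to molar
#'
#' The package's internal convention is molar for every concentration and
#' seconds for every time; raw assay tables may carry doses in any of
#' `M`, `mM`, `uM`, `nM`, `pM`. Conversion is a single multiplication and
#' is exactly invertible.
#'
#' @param x numeric vector of concentrations.
#' @param unit concentration unit, one of `"M"`, `"mM"`, `"uM"`, `"nM"`,
#'   `"pM"` (a vector of units, one per element, is accepted).
#' @return numeric vector in molar.
#' @examples
#' conc_to_molar(3.5, "nM")
#' @export
conc_to_molar <- function(x, unit) {
  unit <- sub("µ", "u", unit)  # accept micro sign
  bad <- setdiff(unique(unit), names(.conc_units))
  if (length(bad)) {
    stop("unknown concentration unit(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  as.numeric(x) * unname(.conc_units[unit])
}

#' Convert times to seconds
#'
#' @param x numeric vector of times.
#' @param unit time unit, one of `"s"`, `"min"`, `"h"`.
#' @return numeric vector in seconds.
#' @examples
#' time_to_seconds(2, "min")
#' @export
time_to_seconds <- function(x, unit) {
  bad <- setdiff(unique(unit), names(.time_units))
  if (length(bad)) {
    stop("unknown time unit(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  as.numeric(x) * unname(.time_units[unit])
}
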