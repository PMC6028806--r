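## ---------------------------------------------------------------------------
## Unit frame. Canonical internally: millimolar, seconds, millivolts,
## microamperes (HH injected current, per cm^2). Readers convert on ingest,
## writers convert on demand.
## ---------------------------------------------------------------------------

UNIT_TABLE <- c(
  ## concentration -> mM
  M = 1e3, mM = 1, uM = 1e-3, nM = 1e-6, pM = 1e-9,
  ## time -> s
  s = 1, ms = 1e-3, min = 60, h = 3600,
  ## voltage -> mV
  mV = 1,
  ## current -> uA
  pA = 1e-6, nA = 1e-3, uA = 1,
  ## dimensionless (fold change, ratios)
  none = 1
)

unit_kind <- function(unit) {
  switch(unit,
         M = , mM = , uM = , nM = , pM = "concentration",
         s = , ms = , min = , h = "time",
         mV = "voltage",
         pA = , nA = , uA = "current",
         none = "dimensionless",
         NA_character_)
}

#' Convert values to the canonical unit frame
#'
#' Canonical units are millimolar (concentration), seconds (time),
#' millivolts (membrane potential) and microamperes (injected current).
#'
#' @param x numeric values
#' @param unit one of `r paste(names(UNIT_TABLE), collapse=", ")`
#' @return values in canonical units
#' @export
to_canonical <- function(x, unit) {
  if (!(unit %in% names(UNIT_TABLE)))
    stop_expsim("unknown unit '%s' (supported: %s)", unit,
                paste(names(UNIT_TABLE), collapse = ", "))
  x * UNIT_TABLE[[unit]]
}

#' Convert values from the canonical frame back to a display unit
#' @inheritParams to_canonical
#' @export
from_canonical <- function(x, unit) {
  if (!(unit %in% names(UNIT_TABLE)))
    stop_expsim("unknown unit '%s'", unit)
  x / UNIT_TABLE[[unit]]
}
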