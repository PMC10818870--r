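#' Apparent total-tract digestibility from the AIA marker
#'
#' Computes `ATTD% = (1 - (Ad * Nf) / (Af * Nd)) * 100` from the
#' acid-insoluble-ash (AIA) marker concentration in diet (`Ad`, g/kg) and
#' feces (`Af`, g/kg) and the nutrient concentration in diet (`Nd`) and
#' feces (`Nf`).  Values can be negative when marker measurement error
#' makes `Nf * Ad > Nd * Af`; such records are kept (clamping would hide a
#' data problem) but flagged with a warning.
#'
#' @param records data.frame with columns `Ad`, `Af`, `Nd`, `Nf` (all
#'   g/kg); extra columns are carried through.
#' @return the input data.frame with an `attd_percent` column appended.
#' @examples
#' attd(data.frame(Ad = 10, Af = 20, Nd = 200, Nf = 100))$attd_percent  # 75
#' @export
attd <- function(records) {
  need <- c("Ad", "Af", "Nd", "Nf")
  if (!all(need %in% names(records)))
    stop("records need columns ", paste(need, collapse = ", "))
  with(records, {
    if (any(Ad <= 0) || any(Af <= 0) || any(Nd <= 0))
      stop("Ad, Af and Nd must be positive")
    if (any(Nf < 0)) stop("Nf must be non-negative")
  })
  out <- records
  out$attd_percent <- (1 - (records$Ad * records$Nf) /
                         (records$Af * records$Nd)) * 100
  if (any(out$attd_percent < 0))
    warning(sum(out$attd_percent < 0),
            " record(s) with negative ATTD; check marker concentrations")
  out
}
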