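# Range-energy relations for charged particles in unit-density water.

.range_table <- function(particle = c("electron", "alpha")) {
  particle <- match.arg(particle)
  if (is.null(.metadose_env$ranges)) {
    .metadose_env$ranges <- utils::read.csv(.extdata("range_energy_water.csv"),
                                            comment.char = "#",
                                            stringsAsFactors = FALSE)
  }
  t <- .metadose_env$ranges[.metadose_env$ranges$particle == particle, ]
  list(E = t$energy_keV, R = t$csda_range_cm)
}

#' CSDA range of an electron or alpha particle in water
#'
#' Log-log interpolation of the embedded range-energy table for liquid
#' water (density 1 g/cm^3). Below the lowest tabulated energy the range is
#' extrapolated with the first segment's log-log slope, so the range tends
#' to 0 as the energy tends to 0. At tabulated energies the tabulated value
#' is returned exactly.
#'
#' @param energy_keV Kinetic energy in keV (vectorised, all > 0).
#' @param particle `"electron"` or `"alpha"`.
#' @return CSDA range in cm.
#' @export
csda_range <- function(energy_keV, particle = c("electron", "alpha")) {
  if (any(!is.finite(energy_keV)) || any(energy_keV <= 0)) {
    stop("energy_keV must be positive", call. = FALSE)
  }
  t <- .range_table(particle)
  out <- exp(stats::approx(log(t$E), log(t$R), log(pmax(energy_keV, t$E[1])),
                           rule = 2)$y)
  lo <- energy_keV < t$E[1]
  if (any(lo)) {
    slope <- (log(t$R[2]) - log(t$R[1])) / (log(t$E[2]) - log(t$E[1]))
    out[lo] <- t$R[1] * (energy_keV[lo] / t$E[1])^slope
  }
  out
}

#' Kinetic energy remaining at a given residual CSDA range
#'
#' Inverse of [csda_range()]: the energy of a particle whose residual range
#' is `range_cm`. Used by the transport engine to score the energy a
#' particle still carries when it crosses the sphere surface.
#'
#' @param range_cm Residual range in cm (vectorised, >= 0); 0 maps to 0 keV.
#' @param particle `"electron"` or `"alpha"`.
#' @return Energy in keV.
#' @export
energy_from_range <- function(range_cm, particle = c("electron", "alpha")) {
  if (any(!is.finite(range_cm)) || any(range_cm < 0)) {
    stop("range_cm must be non-negative", call. = FALSE)
  }
  t <- .range_table(particle)
  out <- numeric(length(range_cm))
  hi <- range_cm >= t$R[1]
  if (any(hi)) {
    out[hi] <- exp(stats::approx(log(t$R), log(t$E), log(range_cm[hi]), rule = 2)$y)
  }
  lo <- range_cm > 0 & !hi
  if (any(lo)) {
    slope <- (log(t$E[2]) - log(t$E[1])) / (log(t$R[2]) - log(t$R[1]))
    out[lo] <- t$E[1] * (range_cm[lo] / t$R[1])^slope
  }
  out
}
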