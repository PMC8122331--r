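# Gompertzian tumor growth.

#' Volume of a sphere from its diameter
#'
#' @param diameter_mm Sphere diameter in mm.
#' @return Volume in cm^3 (equals mass in g at unit density).
#' @export
sphere_volume_cm3 <- function(diameter_mm) (4 / 3) * pi * (diameter_mm / 20)^3

#' Radius of a sphere from its volume
#'
#' @param volume_cm3 Volume in cm^3.
#' @return Radius in cm.
#' @export
sphere_radius_cm <- function(volume_cm3) (3 * volume_cm3 / (4 * pi))^(1 / 3)

#' Gompertz growth retardation factor
#'
#' `b = (SGR0 - SGRd) / ln(Vd / V0)`: the exponential decay rate of the
#' specific growth rate, determined from the initial specific growth rate
#' and the measured specific growth rate of a reference detectable tumor.
#' `SGRd = SGR0` gives `b = 0` (pure exponential growth, no retardation).
#'
#' @param SGR0 Initial specific growth rate (per day), at the single-cell
#'   stage.
#' @param SGRd Specific growth rate (per day) at the reference detectable
#'   volume.
#' @param Vd Reference detectable volume (g).
#' @param V0 Initial volume (g), a single cell.
#' @return Retardation factor b in 1/day.
#' @export
retardation_factor <- function(SGR0, SGRd, Vd, V0) {
  if (SGR0 < SGRd) stop("SGR0 must be >= SGRd", call. = FALSE)
  if (Vd <= V0 || V0 <= 0) stop("need Vd > V0 > 0", call. = FALSE)
  (SGR0 - SGRd) / log(Vd / V0)
}

#' Gompertz growth parameters
#'
#' Bundles the growth model: `V(t) = V0 exp[(SGR0/b)(1 - exp(-b t))]`, with
#' the retardation factor derived from the reference detectable tumor. The
#' defaults describe prostate cancer: a 1 ng initial cell, 7 %/day initial
#' growth, 0.773 %/day at a 20 mm tumor, which plateaus at about 65 cm^3
#' (50 mm diameter).
#'
#' @param V0 Initial mass (g).
#' @param SGR0 Initial specific growth rate (1/day).
#' @param SGRd Specific growth rate at the reference detectable size (1/day).
#' @param reference_diameter_mm Diameter (mm) of the tumor at which `SGRd`
#'   is measured.
#' @return Object of class `gompertz_params` with fields `V0`, `SGR0`,
#'   `SGRd`, `Vd`, `b`, and `plateau_g` (the asymptotic mass
#'   `V0 exp(SGR0/b)`).
#' @export
gompertz_params <- function(V0 = 1e-9, SGR0 = 0.07, SGRd = 0.00773,
                            reference_diameter_mm = 20) {
  Vd <- sphere_volume_cm3(reference_diameter_mm)
  b <- retardation_factor(SGR0, SGRd, Vd, V0)
  structure(list(V0 = V0, SGR0 = SGR0, SGRd = SGRd, Vd = Vd, b = b,
                 plateau_g = if (b > 0) V0 * exp(SGR0 / b) else Inf),
            class = "gompertz_params")
}

#' @export
print.gompertz_params <- function(x, ...) {
  cat(sprintf("<gompertz_params> V0 %.3g g, SGR0 %.3g/d, SGRd %.3g/d at %.4g g; b = %.4g/d, plateau %.4g g\n",
              x$V0, x$SGR0, x$SGRd, x$Vd, x$b, x$plateau_g))
  invisible(x)
}

#' Gompertz volume at a given age
#'
#' @param age_days Tumor age in days (>= 0, vectorised).
#' @param params A `gompertz_params` object.
#' @return Mass in g (volume in cm^3 at unit density).
#' @export
gompertz_volume <- function(age_days, params) {
  if (any(age_days < 0)) stop("age_days must be non-negative", call. = FALSE)
  if (params$b == 0) return(params$V0 * exp(params$SGR0 * age_days))
  params$V0 * exp((params$SGR0 / params$b) * (1 - exp(-params$b * age_days)))
}

#' Age at which a Gompertz tumor reaches a volume
#'
#' Closed-form inversion of [gompertz_volume()]. Volumes at or above the
#' plateau are unreachable and raise an error.
#'
#' @param volume_g Target mass in g (>= V0, < plateau).
#' @param params A `gompertz_params` object.
#' @return Age in days.
#' @export
gompertz_age <- function(volume_g, params) {
  if (any(volume_g < params$V0)) stop("volume below the initial cell mass", call. = FALSE)
  if (any(volume_g >= params$plateau_g)) {
    stop("volume at or beyond the plateau (", format(params$plateau_g), " g)", call. = FALSE)
  }
  if (params$b == 0) return(log(volume_g / params$V0) / params$SGR0)
  -log(1 - (params$b / params$SGR0) * log(volume_g / params$V0)) / params$b
}
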