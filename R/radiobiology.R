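# Activity concentration -> absorbed dose -> biologically effective dose ->
# tumor / metastatic control probability.

# Gy per (Bq/g * keV/decay): number of decays per gram over the full
# treatment, Teff/ln2 in seconds, times the keV-per-gram-to-Gy constant.
.dose_factor <- function(kinetics) {
  (kinetics$T_eff_h * 3600 / log(2)) * 1.6e-13
}

#' Tumor kinetic parameters
#'
#' @param T_eff_h Effective half-life of the radiopharmaceutical in the
#'   tumor, hours (default 51).
#' @param TNC Tumor-to-normal-tissue activity concentration ratio
#'   (default 100; 10 explores strong cross-irradiation).
#' @return Object of class `kinetic_params`.
#' @export
kinetic_params <- function(T_eff_h = 51, TNC = 100) {
  stopifnot(T_eff_h > 0, TNC >= 1)
  structure(list(T_eff_h = T_eff_h, TNC = TNC), class = "kinetic_params")
}

#' Radiobiological parameters
#'
#' @param alpha Linear radiosensitivity coefficient (1/Gy), default 0.147
#'   as calibrated from a 200 Gy BED curing a 50 mm tumor with probability
#'   0.99 (see [calibrate_alpha()]).
#' @param alpha_beta Alpha/beta ratio (Gy), default 1.5 for prostate cancer.
#' @param T_r_h Sublethal-damage repair half-life (hours), default 1.9.
#' @param clonogen_density Clonogenic cell density (cells/cm^3), default 1e9.
#' @param alpha_weight Relative weighting of alpha-particle absorbed dose
#'   (default 5; only affects alpha emitters).
#' @return Object of class `radbio_params`.
#' @export
radbio_params <- function(alpha = 0.147, alpha_beta = 1.5, T_r_h = 1.9,
                          clonogen_density = 1e9, alpha_weight = 5) {
  stopifnot(alpha > 0, alpha_beta > 0, T_r_h > 0, clonogen_density > 0,
            alpha_weight >= 1)
  structure(list(alpha = alpha, alpha_beta = alpha_beta, T_r_h = T_r_h,
                 clonogen_density = clonogen_density,
                 alpha_weight = alpha_weight),
            class = "radbio_params")
}

#' Absorbed dose to a spherical tumor
#'
#' Converts a tumor activity concentration into the absorbed dose of a
#' uniform-activity sphere: self-dose from the tumor's own concentration
#' through the radius-dependent absorbed fractions, plus equilibrium
#' cross-irradiation from the surrounding normal tissue at concentration
#' `C_T / TNC`:
#' `D = k [ C_N * E_total + (C_T - C_N) * sum_j E_j k_j phi_j(r) ]`
#' with `k = (T_eff / ln 2) * 1.6e-13` converting decays/g x keV to Gy.
#' Charged particles only; the alpha component is multiplied by
#' `weight_alpha`.
#'
#' @param C_T Tumor activity concentration in Bq/g (>= 0).
#' @param kinetics A `kinetic_params`.
#' @param record A `radionuclide_record`.
#' @param radius_cm Tumor radius (cm), vectorised; must lie in the grid hull.
#' @param grid A `phi_grid` covering the record.
#' @param weight_alpha Weight of the alpha dose component.
#' @return Absorbed dose in Gy (Gy-weighted when `weight_alpha > 1`).
#' @export
tumor_dose <- function(C_T, kinetics, record, radius_cm, grid, weight_alpha = 1) {
  stopifnot(inherits(kinetics, "kinetic_params"))
  if (any(C_T < 0)) stop("C_T must be non-negative", call. = FALSE)
  C_N <- C_T / kinetics$TNC
  e_self <- mean_absorbed_energy(record, radius_cm, grid, weight_alpha)
  e_tot <- total_charged_energy(record, weight_alpha)
  .dose_factor(kinetics) * (C_N * e_tot + (C_T - C_N) * e_self)
}

#' Biologically effective dose for protracted irradiation
#'
#' Linear-quadratic BED for a mono-exponentially decaying dose rate:
#' `BED = D (1 + D G / (alpha/beta))` with the dose-protraction factor
#' `G = T_r / (T_r + T_eff)` (repair half-life over repair plus effective
#' half-life). As `T_eff -> 0` this recovers the acute-exposure limit
#' `D (1 + D/(alpha/beta))`.
#'
#' `printed_formula = TRUE` evaluates the dimensionally inconsistent variant
#' `D (1 + G/(alpha/beta))` that omits the dose in the repair term, kept
#' only for comparison.
#'
#' @param D Absorbed dose in Gy (vectorised, >= 0).
#' @param kinetics A `kinetic_params`.
#' @param radbio A `radbio_params`.
#' @param printed_formula Use the no-dose-squared variant (comparison only).
#' @return BED in Gy.
#' @export
bed <- function(D, kinetics, radbio, printed_formula = FALSE) {
  if (any(D < 0)) stop("dose must be non-negative", call. = FALSE)
  G <- radbio$T_r_h / (radbio$T_r_h + kinetics$T_eff_h)
  if (printed_formula) return(D * (1 + G / radbio$alpha_beta))
  D * (1 + D * G / radbio$alpha_beta)
}

# clonogen number: nearest integer, at least 1 for any nonzero volume
.clonogens <- function(volume_cm3, radbio) {
  h <- round(radbio$clonogen_density * volume_cm3)
  ifelse(volume_cm3 > 0, pmax(h, 1), 0)
}

# log TCP, computed in log space so h ~ 1e10 does not underflow
.log_tcp <- function(BED, radbio, volume_cm3) {
  h <- .clonogens(volume_cm3, radbio)
  lt <- h * log1p(-exp(-radbio$alpha * BED))
  lt[h == 0] <- 0
  lt
}

#' Tumor control probability
#'
#' `TCP = (1 - exp(-alpha BED))^h` with `h` clonogens (density x volume,
#' rounded, at least one cell for any nonzero volume). Exponentiation is
#' performed in log space. A zero-volume tumor has no clonogens and
#' `TCP = 1`.
#'
#' @param BED Biologically effective dose in Gy (vectorised, >= 0).
#' @param radbio A `radbio_params`.
#' @param volume_cm3 Tumor volume(s) in cm^3.
#' @return Control probability in [0, 1].
#' @export
tcp <- function(BED, radbio, volume_cm3) {
  if (any(BED < 0)) stop("BED must be non-negative", call. = FALSE)
  exp(.log_tcp(BED, radbio, volume_cm3))
}

#' Calibrate the linear radiosensitivity from a reference cure point
#'
#' Solves the TCP model for alpha in closed form given that a reference
#' BED achieves a reference control probability in a sphere of the given
#' diameter: `alpha = -ln(1 - TCP_ref^(1/h)) / BED_ref`. With the defaults
#' (200 Gy, TCP 0.99, 50 mm, 1e9 cells/cm^3) this yields 0.147 /Gy.
#'
#' @param BED_ref Reference BED in Gy.
#' @param TCP_ref Reference control probability (0 < TCP_ref < 1).
#' @param diameter_mm Reference tumor diameter (mm).
#' @param radbio A `radbio_params` (supplies the clonogen density).
#' @return alpha in 1/Gy.
#' @export
calibrate_alpha <- function(BED_ref = 200, TCP_ref = 0.99, diameter_mm = 50,
                            radbio = radbio_params()) {
  stopifnot(BED_ref > 0, TCP_ref > 0, TCP_ref < 1)
  h <- .clonogens(sphere_volume_cm3(diameter_mm), radbio)
  # 1 - TCP^(1/h) = -expm1(log(TCP)/h), stable for huge h
  -log(-expm1(log(TCP_ref) / h)) / BED_ref
}

# per-tumor self-absorbed energy (keV/decay) for a set of volumes
.state_self_energy <- function(record, volumes_cm3, grid, weight_alpha) {
  mean_absorbed_energy(record, sphere_radius_cm(volumes_cm3), grid, weight_alpha)
}

# log MCP of a set of tumor volumes at concentration C_T, with the
# per-tumor self energies precomputed
.log_mcp_volumes <- function(C_T, volumes_cm3, e_self, e_tot, kinetics, radbio) {
  C_N <- C_T / kinetics$TNC
  D <- .dose_factor(kinetics) * (C_N * e_tot + (C_T - C_N) * e_self)
  sum(.log_tcp(bed(D, kinetics, radbio), radbio, volumes_cm3))
}

#' Metastatic control probability of a simulated patient
#'
#' Product over all tumors (primary included unless `include_primary =
#' FALSE`, e.g. after resection) of each tumor's control probability at its
#' own radius-dependent absorbed dose.
#'
#' @param state A `metastatic_state`.
#' @param C_T Tumor activity concentration (Bq/g).
#' @param kinetics A `kinetic_params`.
#' @param radbio A `radbio_params` (its `alpha_weight` is applied to alpha
#'   emissions).
#' @param record A `radionuclide_record`.
#' @param grid A `phi_grid` covering the record.
#' @param include_primary Include the primary tumor in the product.
#' @return Control probability in [0, 1].
#' @export
mcp <- function(state, C_T, kinetics, radbio, record, grid,
                include_primary = TRUE) {
  stopifnot(inherits(state, "metastatic_state"))
  v <- tumor_volumes(state, include_primary = include_primary)
  if (length(v) == 0L) stop("state has no tumors", call. = FALSE)
  e_self <- .state_self_energy(record, v, grid, radbio$alpha_weight)
  e_tot <- total_charged_energy(record, radbio$alpha_weight)
  exp(.log_mcp_volumes(C_T, v, e_self, e_tot, kinetics, radbio))
}
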