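# Shared fixtures: records and a lazily built, cached phi grid so unit test
# files do not re-simulate transport repeatedly.

.fixture_env <- new.env()

fixture_records <- function(names = list_radionuclides()) {
  lapply(names, load_radionuclide)
}

# moderate-resolution grid over all five nuclides, built once per session
fixture_grid <- function(histories = 4000) {
  key <- paste0("grid", histories)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- build_phi_grid(fixture_records(),
                                          histories = histories, seed = 99L)
  }
  .fixture_env[[key]]
}

# hand-built metastatic state: metastases with the given ages (days) at a
# given census time, default growth
manual_state <- function(ages_days, census_days = 1500,
                         growth = gompertz_params(),
                         config = dissemination_config()) {
  structure(list(census_time_days = census_days,
                 birth_days = census_days - ages_days,
                 detection_time_days = census_days,
                 growth = growth, config = config,
                 stop_at_detectable = NA_integer_, seed = NA_integer_),
            class = "metastatic_state")
}

# reference per-bin electron energies (keV/decay), as embedded in extdata
ref_bins <- rbind(
  `90Y`   = c(0, 1, 2, 7, 294, 630),
  `131I`  = c(1, 6, 13, 41, 129, 0),
  `177Lu` = c(2, 9, 16, 52, 67, 0),
  `161Tb` = c(9, 43, 16, 45, 87, 0),
  `225Ac` = c(6, 18, 24, 62, 504, 52)
)
ref_bin_edges <- c(0.01, 10, 50, 100, 200, 1000, 9000)

# closed-form required dose for a single spherical tumor: invert TCP for the
# required BED, the LQ quadratic for the dose, then scale concentration and
# dose through the absorbed-energy bookkeeping. Independent of the bisection
# solver.
closed_form_dreq <- function(volume_cm3, record, grid,
                             kinetics = kinetic_params(),
                             radbio = radbio_params(), target = 0.99) {
  w <- if (any(record$lines$particle_class == "alpha")) radbio$alpha_weight else 1
  h <- max(round(radbio$clonogen_density * volume_cm3), 1)
  bed_req <- -log(-expm1(log(target) / h)) / radbio$alpha
  Gab <- (radbio$T_r_h / (radbio$T_r_h + kinetics$T_eff_h)) / radbio$alpha_beta
  D <- (-1 + sqrt(1 + 4 * Gab * bed_req)) / (2 * Gab)
  e_tot <- total_charged_energy(record, w)
  e_self <- mean_absorbed_energy(record, sphere_radius_cm(volume_cm3), grid, w)
  e_per_ct <- e_tot / kinetics$TNC + (1 - 1 / kinetics$TNC) * e_self
  kfac <- kinetics$T_eff_h * 3600 / log(2) * 1.6e-13
  (D / (kfac * e_per_ct)) * kfac * e_tot
}
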