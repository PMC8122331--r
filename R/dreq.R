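# Required activity concentration and absorbed dose for a target
# metastatic control probability.

#' Primary-tumor-only state
#'
#' The baseline disease state before any metastasis is detectable: the
#' primary tumor alone, censused when it has grown to `plateau_fraction` of
#' its Gompertz plateau (about 65 cm^3 with the default growth parameters).
#'
#' @param growth A `gompertz_params`.
#' @param config A `dissemination_config` (carried for bookkeeping).
#' @param plateau_fraction Fraction of the plateau volume at census.
#' @return A `metastatic_state` with no metastases.
#' @export
primary_only_state <- function(growth = gompertz_params(),
                               config = dissemination_config(),
                               plateau_fraction = 0.99) {
  stopifnot(plateau_fraction > 0, plateau_fraction < 1)
  tc <- gompertz_age(plateau_fraction * growth$plateau_g, growth)
  structure(list(census_time_days = tc, birth_days = numeric(0),
                 detection_time_days = tc, growth = growth, config = config,
                 stop_at_detectable = 0L, seed = NA_integer_),
            class = "metastatic_state")
}

#' Solve the required concentration and dose for a target MCP
#'
#' Bisects on log10 of the tumor activity concentration until the patient's
#' metastatic control probability (see [mcp()]) hits `target_mcp`, then
#' converts the required concentration into the required absorbed dose under
#' complete local absorption of the charged-particle energy:
#' `D_req = (T_eff/ln 2) * 1.6e-13 * C_T_required * total_charged_energy`.
#' With an alpha weight above 1 the result is the weighted dose (Gy_w).
#'
#' @param state A `metastatic_state`.
#' @param record A `radionuclide_record`.
#' @param grid A `phi_grid` covering the record.
#' @param kinetics A `kinetic_params`.
#' @param radbio A `radbio_params`.
#' @param target_mcp Target control probability (default 0.99).
#' @param tol Convergence tolerance on |MCP - target| (default 1e-4).
#' @param conc_bounds Concentration bracket in Bq/g.
#' @param max_iter Maximum bisection iterations.
#' @param include_primary Include the primary tumor in the control product.
#' @return Object of class `dreq_result`: `nuclide`, `C_T_required` (Bq/g),
#'   `D_req_Gy`, `mcp_achieved`, `iterations`, `weight_alpha`,
#'   `replicate_seed`.
#' @export
solve_dreq <- function(state, record, grid, kinetics = kinetic_params(),
                       radbio = radbio_params(), target_mcp = 0.99,
                       tol = 1e-4, conc_bounds = c(1, 1e12), max_iter = 200L,
                       include_primary = TRUE) {
  stopifnot(inherits(state, "metastatic_state"), target_mcp > 0, target_mcp < 1)
  v <- tumor_volumes(state, include_primary = include_primary)
  if (length(v) == 0L) stop("state has no tumors", call. = FALSE)
  has_alpha <- any(record$lines$particle_class == "alpha")
  w <- if (has_alpha) radbio$alpha_weight else 1
  e_self <- .state_self_energy(record, v, grid, w)
  e_tot <- total_charged_energy(record, w)
  lmcp <- function(lc) .log_mcp_volumes(10^lc, v, e_self, e_tot, kinetics, radbio)
  lt <- log(target_mcp)
  lo <- log10(conc_bounds[1]); hi <- log10(conc_bounds[2])
  if (lmcp(lo) >= lt || lmcp(hi) < lt) {
    stop("target MCP ", target_mcp, " not bracketed by concentrations [",
         conc_bounds[1], ", ", conc_bounds[2], "] Bq/g (MCP range ",
         format(exp(lmcp(lo))), " - ", format(exp(lmcp(hi))), ")", call. = FALSE)
  }
  iter <- 0L
  repeat {
    iter <- iter + 1L
    mid <- (lo + hi) / 2
    val <- lmcp(mid)
    if (val < lt) lo <- mid else hi <- mid
    # converge on both the control probability and the concentration bracket,
    # so the result is invariant (to tolerance) under bracket changes
    if ((abs(exp(val) - target_mcp) < tol && (hi - lo) < 1e-7) ||
        iter >= max_iter) break
  }
  C_T <- 10^mid
  structure(list(nuclide = record$name,
                 C_T_required = C_T,
                 D_req_Gy = .dose_factor(kinetics) * C_T * e_tot,
                 mcp_achieved = exp(val),
                 iterations = iter,
                 weight_alpha = w,
                 replicate_seed = state$seed),
            class = "dreq_result")
}

#' @export
print.dreq_result <- function(x, ...) {
  cat(sprintf("<dreq_result> %s: C_T = %.4g Bq/g, D_req = %.4g Gy%s (MCP %.4f, %d iterations)\n",
              x$nuclide, x$C_T_required, x$D_req_Gy,
              if (x$weight_alpha > 1) sprintf("_%g", x$weight_alpha) else "",
              x$mcp_achieved, x$iterations))
  invisible(x)
}

#' Required dose over a simulated scenario
#'
#' Simulates `replicates` patients at one formation rate constant and
#' detectable-metastasis milestone, solves the required dose for each, and
#' summarizes. The default census (`"at_formation"`) snapshots each patient
#' at a metastasis-formation event, so the treated state carries the ongoing
#' dissemination's most recent single-cell metastasis.
#'
#' @param record A `radionuclide_record` (or nuclide name).
#' @param c Formation rate constant (%/day/g).
#' @param n_detectable Detectable-metastasis milestone (0 uses the
#'   primary-only state and needs no simulation).
#' @param replicates Number of simulated patients (>= 1).
#' @param seed Integer seed.
#' @param growth A `gompertz_params`.
#' @param kinetics,radbio Model parameters.
#' @param grid A `phi_grid`; built from the record if `NULL`.
#' @param census Census rule passed to [dissemination_config()].
#' @param dt_days,max_days Simulation stepping.
#' @return List with `nuclide`, `c`, `n_detectable`, `mean_D_req_Gy`,
#'   `median_D_req_Gy`, `p2.5`, `p97.5`, `replicates`, and the per-replicate
#'   `D_req_Gy` vector.
#' @export
scenario_dreq <- function(record, c = 0.16, n_detectable = 1,
                          replicates = 100, seed = 1L,
                          growth = gompertz_params(),
                          kinetics = kinetic_params(),
                          radbio = radbio_params(),
                          grid = NULL,
                          census = "at_formation",
                          dt_days = 1, max_days = 15000) {
  if (is.character(record)) record <- load_radionuclide(record)
  if (is.null(grid)) grid <- build_phi_grid(record, seed = seed)
  if (n_detectable == 0) {
    states <- list(primary_only_state(growth))
  } else {
    config <- dissemination_config(c = c, dt_days = dt_days,
                                   max_days = max_days, census = census)
    states <- simulate_cohort(replicates, growth, config, n_detectable, seed = seed)
  }
  d <- vapply(states, function(s) {
    solve_dreq(s, record, grid, kinetics, radbio)$D_req_Gy
  }, numeric(1))
  list(nuclide = record$name, c = c, n_detectable = n_detectable,
       mean_D_req_Gy = mean(d), median_D_req_Gy = stats::median(d),
       p2.5 = unname(stats::quantile(d, 0.025)),
       p97.5 = unname(stats::quantile(d, 0.975)),
       replicates = length(d), D_req_Gy = d)
}

#' Required-dose table across nuclides and metastatic scenarios
#'
#' Reproduces the study's summary table: for every nuclide and milestone,
#' the scenario mean required dose is computed at each formation rate
#' constant and reported as a [min, max] range over the constants. States
#' are simulated once per (c, milestone) pair and reused across nuclides.
#'
#' @param nuclides Character vector of nuclide names.
#' @param n_detectable Integer vector of milestones (0 allowed).
#' @param c_values Formation rate constants to range over.
#' @param replicates Patients per scenario.
#' @param seed Integer seed.
#' @param growth,kinetics,radbio Model parameters.
#' @param grid A `phi_grid` covering all nuclides; built if `NULL`.
#' @param census Census rule for the simulated states.
#' @param histories Histories per grid point when building the grid.
#' @return Data frame with one row per nuclide x milestone: `D_req_min_Gy`,
#'   `D_req_max_Gy` (over `c_values`) and per-c means.
#' @export
dreq_table <- function(nuclides = list_radionuclides(),
                       n_detectable = c(0, 1, 5, 10, 20),
                       c_values = c(0.16, 2.56),
                       replicates = 100, seed = 1L,
                       growth = gompertz_params(),
                       kinetics = kinetic_params(),
                       radbio = radbio_params(),
                       grid = NULL, census = "at_formation",
                       histories = 20000L) {
  if (length(nuclides) == 0L) stop("no nuclides given", call. = FALSE)
  records <- lapply(nuclides, load_radionuclide)
  if (is.null(grid)) grid <- build_phi_grid(records, histories = histories, seed = seed)
  rows <- list()
  for (nd in n_detectable) {
    # means[c_value, nuclide]
    means <- matrix(NA_real_, length(c_values), length(nuclides),
                    dimnames = list(NULL, nuclides))
    for (ci in seq_along(c_values)) {
      if (nd == 0) {
        states <- list(primary_only_state(growth))
      } else {
        config <- dissemination_config(c = c_values[ci], census = census)
        states <- simulate_cohort(replicates, growth, config, nd,
                                  seed = seed + 1000L * ci + nd)
      }
      for (ni in seq_along(records)) {
        means[ci, ni] <- mean(vapply(states, function(s) {
          solve_dreq(s, records[[ni]], grid, kinetics, radbio)$D_req_Gy
        }, numeric(1)))
      }
    }
    for (ni in seq_along(nuclides)) {
      row <- data.frame(nuclide = nuclides[ni], n_detectable = nd,
                        D_req_min_Gy = min(means[, ni]),
                        D_req_max_Gy = max(means[, ni]))
      for (ci in seq_along(c_values)) {
        row[[paste0("mean_c", c_values[ci])]] <- means[ci, ni]
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
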