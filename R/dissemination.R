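# Stochastic metastatic dissemination from a growing primary tumor.

#' Dissemination model configuration
#'
#' @param c Metastatic formation rate constant in %/day/g: every tumor of
#'   volume V grams seeds new metastases at rate `(c/100) * (V/1g)^exponent`
#'   per day. The study range is 0.16 (oligometastatic) to 2.56 (diffuse).
#' @param exponent Volume exponent of the formation rate (default 0.67,
#'   a surface-like scaling).
#' @param dt_days Time step of the simulation in days.
#' @param detection_diameter_mm Diameter above which a metastasis counts as
#'   detectable (default 7 mm, i.e. 0.1796 cm^3).
#' @param fusion_enabled If `TRUE`, each newly disseminated cell is discarded
#'   ("fuses" into established tumors) with probability
#'   `min(1, total tumor volume / fusion_bed_volume_cm3)`. Off by default;
#'   the cohort tables are matched without it.
#' @param fusion_bed_volume_cm3 Reference bed volume for the fusion
#'   probability.
#' @param max_days Simulation horizon; exceeding it before the stopping
#'   milestone raises an error carrying the partial state.
#' @param census When to take the snapshot of a simulated patient once the
#'   requested number of detectable metastases is reached:
#'   `"while_detectable"` (default) picks a time uniformly within the window
#'   during which exactly that many metastases are detectable (the state of
#'   a patient observed while presenting the milestone);
#'   `"at_detection"` censuses at the first step the count is reached;
#'   `"at_formation"` censuses at the first metastasis-formation event once
#'   the count is reached, so the state always carries a just-disseminated
#'   single-cell metastasis (used for dose-requirement scenarios, where
#'   dissemination is ongoing at treatment).
#' @return Object of class `dissemination_config`.
#' @export
dissemination_config <- function(c = 0.16, exponent = 0.67, dt_days = 1,
                                 detection_diameter_mm = 7,
                                 fusion_enabled = FALSE,
                                 fusion_bed_volume_cm3 = 1000,
                                 max_days = 15000,
                                 census = c("while_detectable", "at_detection",
                                            "at_formation")) {
  census <- match.arg(census)
  stopifnot(c >= 0, dt_days > 0, detection_diameter_mm > 0,
            fusion_bed_volume_cm3 > 0, max_days > dt_days)
  structure(list(c = c, exponent = exponent, dt_days = dt_days,
                 detection_diameter_mm = detection_diameter_mm,
                 fusion_enabled = fusion_enabled,
                 fusion_bed_volume_cm3 = fusion_bed_volume_cm3,
                 max_days = max_days, census = census),
            class = "dissemination_config")
}

#' Metastatic formation rate of a tumor
#'
#' `rate = (c/100) * (V / 1 g)^exponent` per day, with `c` in %/day/g.
#'
#' @param c Formation rate constant (%/day/g).
#' @param volume_g Tumor volume in g (vectorised, >= 0).
#' @param exponent Volume exponent (default 0.67).
#' @return Expected metastasis seedings per day.
#' @export
metastatic_formation_rate <- function(c, volume_g, exponent = 0.67) {
  stopifnot(c >= 0, all(volume_g >= 0))
  (c / 100) * volume_g^exponent
}

.detection_volume <- function(config) sphere_volume_cm3(config$detection_diameter_mm)

.new_state <- function(census_steps, birth_steps, detection_steps, growth,
                       config, stop_at_detectable, seed) {
  dt <- config$dt_days
  structure(list(census_time_days = census_steps * dt,
                 birth_days = birth_steps * dt,
                 detection_time_days = detection_steps * dt,
                 growth = growth, config = config,
                 stop_at_detectable = stop_at_detectable,
                 seed = seed),
            class = "metastatic_state")
}

#' Simulate one patient's metastatic dissemination
#'
#' Time-stepped simulation from a single primary cell at t = 0. At every
#' step each existing tumor (primary and metastases alike, all sharing the
#' same Gompertz growth law) seeds new single-cell metastases with a Poisson
#' count at its current formation rate; newborns begin growing and seeding
#' at the next step. The run stops once `stop_at_detectable` metastases
#' exceed the detection diameter and the state is censused according to
#' `config$census`. `stop_at_detectable = 0` returns the primary-only state,
#' censused when the primary has reached 99% of its plateau volume.
#'
#' @param growth A `gompertz_params` object.
#' @param config A `dissemination_config` object.
#' @param stop_at_detectable Number of detectable metastases defining the
#'   milestone (>= 0).
#' @param seed Integer seed for the patient's random stream.
#' @return Object of class `metastatic_state` with the census time, the
#'   metastases' birth times, and the parameters used. Tumor volumes derive
#'   from the closed-form growth law via [tumor_volumes()].
#' @export
simulate_patient <- function(growth, config = dissemination_config(),
                             stop_at_detectable = 1, seed = 1L) {
  stopifnot(inherits(growth, "gompertz_params"),
            inherits(config, "dissemination_config"),
            stop_at_detectable >= 0)
  if (stop_at_detectable == 0) {
    tc <- gompertz_age(0.99 * growth$plateau_g, growth) / config$dt_days
    return(.new_state(tc, numeric(0), tc, growth, config, 0L, seed))
  }
  set.seed(seed)
  dt <- config$dt_days
  nsteps <- ceiling(config$max_days / dt)
  vol <- gompertz_volume((0:nsteps) * dt, growth)       # volume at age k*dt
  v_exp <- vol^config$exponent
  vdet <- .detection_volume(config)
  det_idx <- which(vol >= vdet)[1] - 1L                 # age steps to detectability
  if (is.na(det_idx)) stop("detection volume unreachable within max_days", call. = FALSE)
  k <- (config$c / 100) * dt
  births <- integer(0)                                  # metastasis birth steps
  t_first <- NA_integer_
  nd <- stop_at_detectable
  for (t in seq_len(nsteps)) {
    rate <- k * (v_exp[t] + sum(v_exp[t - births]))     # tumors present at step start
    nnew <- stats::rpois(1L, rate)
    if (config$fusion_enabled && nnew > 0L) {
      p_fuse <- min(1, (vol[t] + sum(vol[t - births])) / config$fusion_bed_volume_cm3)
      nnew <- stats::rbinom(1L, nnew, 1 - p_fuse)
    }
    if (nnew > 0L) births <- c(births, rep.int(t, nnew))
    ndet <- sum(births <= t - det_idx)
    if (is.na(t_first) && ndet >= nd) t_first <- t
    if (!is.na(t_first)) {
      if (config$census == "at_detection") {
        return(.new_state(t_first, births[births <= t_first], t_first,
                          growth, config, nd, seed))
      }
      if (config$census == "at_formation" && nnew > 0L) {
        return(.new_state(t, births, t_first, growth, config, nd, seed))
      }
      if (config$census == "while_detectable" && ndet >= nd + 1L) {
        tc <- if (t - 1L > t_first) {
          t_first + sample.int(t - t_first, 1L) - 1L    # uniform on t_first..t-1
        } else t_first
        return(.new_state(tc, births[births <= tc], t_first,
                          growth, config, nd, seed))
      }
    }
  }
  partial <- .new_state(nsteps, births, t_first, growth, config, nd, seed)
  cond <- structure(class = c("metadose_horizon_error", "error", "condition"),
                    list(message = paste0("milestone of ", nd,
                                          " detectable metastases not reached within ",
                                          config$max_days, " days"),
                         call = sys.call(-1), state = partial))
  stop(cond)
}

#' Tumor volumes of a metastatic state at its census time
#'
#' @param state A `metastatic_state`.
#' @param include_primary Include the primary tumor (first element).
#' @return Numeric vector of volumes in cm^3; the primary first, then the
#'   metastases in order of formation.
#' @export
tumor_volumes <- function(state, include_primary = TRUE) {
  stopifnot(inherits(state, "metastatic_state"))
  v <- gompertz_volume(state$census_time_days - state$birth_days, state$growth)
  if (include_primary) {
    v <- c(gompertz_volume(state$census_time_days, state$growth), v)
  }
  v
}

#' Number of detectable metastases in a state
#'
#' @param state A `metastatic_state`.
#' @return Count of metastases at or above the detection diameter.
#' @export
n_detectable <- function(state) {
  sum(tumor_volumes(state, include_primary = FALSE) >= .detection_volume(state$config))
}

#' Total metastatic burden of a state
#'
#' @param state A `metastatic_state`.
#' @return Sum of metastasis volumes (cm^3), primary excluded.
#' @export
metastatic_burden <- function(state) {
  sum(tumor_volumes(state, include_primary = FALSE))
}

#' @export
print.metastatic_state <- function(x, ...) {
  cat(sprintf("<metastatic_state> census day %.0f: %d metastases (%d detectable), burden %.3g cm3; primary %.3g cm3\n",
              x$census_time_days, length(x$birth_days), n_detectable(x),
              metastatic_burden(x),
              gompertz_volume(x$census_time_days, x$growth)))
  invisible(x)
}

#' Simulate a cohort of patients
#'
#' @param n Number of replicates.
#' @param growth A `gompertz_params`.
#' @param config A `dissemination_config`.
#' @param stop_at_detectable Detectable-metastasis milestone.
#' @param seed Integer seed; per-replicate sub-seeds are drawn from it.
#' @return List of `metastatic_state` objects.
#' @export
simulate_cohort <- function(n, growth = gompertz_params(),
                            config = dissemination_config(),
                            stop_at_detectable = 1, seed = 1L) {
  stopifnot(n >= 1)
  set.seed(seed)
  seeds <- sample.int(1e8, n)
  lapply(seq_len(n), function(i) {
    simulate_patient(growth, config, stop_at_detectable, seed = seeds[i])
  })
}

#' Summarize a simulated cohort
#'
#' Per-scenario summary of a list of states sharing one configuration:
#' mean formation time (census time), the detectable-metastasis size summary
#' (mean over replicates of each replicate's median detectable size, with
#' 2.5-97.5 percentiles of the pooled detectable sizes), mean total number
#' of metastases of any size, and mean total metastatic burden. The primary
#' tumor is excluded from counts and burden.
#'
#' @param states List of at least two `metastatic_state` objects with
#'   identical configuration.
#' @return A one-row data frame of class `cohort_summary`.
#' @export
summarize_cohort <- function(states) {
  if (length(states) < 2L) stop("need at least two states", call. = FALSE)
  stopifnot(all(vapply(states, inherits, logical(1), "metastatic_state")))
  cfgs <- vapply(states, function(s) paste(s$config$c, s$stop_at_detectable), "")
  if (length(unique(cfgs)) != 1L) stop("states have differing configurations", call. = FALSE)
  vdet <- .detection_volume(states[[1]]$config)
  per <- lapply(states, function(s) {
    v <- tumor_volumes(s, include_primary = FALSE)
    dv <- v[v >= vdet]
    list(tc = s$census_time_days, n = length(v), burden = sum(v),
         med = if (length(dv)) stats::median(dv) else NA_real_, det = dv)
  })
  pooled <- unlist(lapply(per, `[[`, "det"))
  out <- data.frame(
    c = states[[1]]$config$c,
    n_detectable = states[[1]]$stop_at_detectable,
    replicates = length(states),
    formation_time_d = mean(vapply(per, `[[`, 0, "tc")),
    formation_time_median_d = stats::median(vapply(per, `[[`, 0, "tc")),
    median_size_cm3 = mean(vapply(per, `[[`, 0, "med"), na.rm = TRUE),
    size_p2.5_cm3 = if (length(pooled)) unname(stats::quantile(pooled, 0.025)) else NA_real_,
    size_p97.5_cm3 = if (length(pooled)) unname(stats::quantile(pooled, 0.975)) else NA_real_,
    n_metastases = mean(vapply(per, `[[`, 0, "n")),
    burden_cm3 = mean(vapply(per, `[[`, 0, "burden"))
  )
  class(out) <- c("cohort_summary", class(out))
  out
}
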