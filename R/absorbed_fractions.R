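# Absorbed energy fractions in uniform-activity unit-density spheres,
# computed with a straight-track continuous-slowing-down (CSDA) transport
# model: emission points uniform in the sphere, isotropic directions,
# energy deposited continuously along a straight track according to the
# residual-range relation. No secondary-particle or multiple-scattering
# transport; adequate for sphere self-absorption at the keV-MeV energies
# of therapeutic beta/CE/Auger and alpha emissions.

# distance from an interior point to the sphere surface along a direction:
# s = radial position, u = cosine between direction and outward radial.
.chord <- function(radius, s, u) -s * u + sqrt(radius^2 - s^2 * (1 - u^2))

#' Monte Carlo absorbed fraction for one emission line in a sphere
#'
#' Samples emission points uniformly inside a sphere of the given radius and
#' isotropic directions, tracks each particle along a straight line, and
#' scores the fraction of the emitted energy deposited before the track
#' leaves the sphere (the remainder is the energy the particle still carries
#' at the surface, from the residual-range relation).
#'
#' @param energy_keV Initial particle energy (keV, > 0).
#' @param particle `"electron"` or `"alpha"`.
#' @param radius_cm Sphere radius in cm (> 0).
#' @param histories Number of Monte Carlo histories (>= 1000).
#' @param seed Integer seed; fixed seed gives bit-identical results.
#' @param keep_histories If `TRUE`, attach the per-history deposited and
#'   escaped energies (keV) as attributes for energy-balance checks.
#' @return A list with `phi` (mean absorbed fraction), `se` (standard error
#'   of the mean), `histories`, and `seed`.
#' @export
simulate_phi <- function(energy_keV, particle = c("electron", "alpha"),
                         radius_cm, histories = 10000L, seed = 1L,
                         keep_histories = FALSE) {
  particle <- match.arg(particle)
  if (!is.finite(radius_cm) || radius_cm <= 0) stop("radius_cm must be positive", call. = FALSE)
  if (histories < 1000) stop("histories must be at least 1000", call. = FALSE)
  set.seed(seed)
  R <- csda_range(energy_keV, particle)
  s <- radius_cm * stats::runif(histories)^(1 / 3)
  u <- stats::runif(histories, -1, 1)
  d <- .chord(radius_cm, s, u)
  escaped <- energy_from_range(pmax(R - d, 0), particle)
  deposited <- energy_keV - escaped
  f <- deposited / energy_keV
  out <- list(phi = mean(f), se = stats::sd(f) / sqrt(histories),
              histories = as.integer(histories), seed = as.integer(seed))
  if (keep_histories) {
    attr(out, "deposited_keV") <- deposited
    attr(out, "escaped_keV") <- escaped
    attr(out, "emitted_keV") <- energy_keV
  }
  out
}

#' Deterministic chord-length oracle for the sphere absorbed fraction
#'
#' Independent check of [simulate_phi()]: integrates the same straight-track
#' CSDA model over the exact source-position and direction distribution with
#' 2-D Gauss-Legendre quadrature (radial position weighted by 3 v^2,
#' direction cosine uniform). Intended for validation; it shares no sampling
#' code with the Monte Carlo estimator.
#'
#' @param energy_keV Initial particle energy (keV, > 0).
#' @param particle `"electron"` or `"alpha"`.
#' @param radius_cm Sphere radius in cm (> 0).
#' @param nodes Quadrature nodes per dimension.
#' @return Absorbed fraction in [0, 1].
#' @export
chord_oracle_phi <- function(energy_keV, particle = c("electron", "alpha"),
                             radius_cm, nodes = 128L) {
  particle <- match.arg(particle)
  if (!is.finite(radius_cm) || radius_cm <= 0) stop("radius_cm must be positive", call. = FALSE)
  R <- csda_range(energy_keV, particle)
  gv <- pracma::gaussLegendre(nodes, 0, 1)    # radial fraction v, weight 3 v^2
  gu <- pracma::gaussLegendre(nodes, -1, 1)   # direction cosine, weight 1/2
  d <- .chord(radius_cm, outer(radius_cm * gv$x, rep(1, nodes)),
              outer(rep(1, nodes), gu$x))
  f <- 1 - energy_from_range(pmax(R - d, 0), particle) / energy_keV
  dim(f) <- dim(d)
  phi <- as.numeric(t(gv$w * 3 * gv$x^2) %*% f %*% (gu$w / 2))
  if (!is.finite(phi)) stop("chord oracle quadrature failed (non-finite result)", call. = FALSE)
  min(max(phi, 0), 1)
}

#' Precompute absorbed fractions on a radius grid
#'
#' Runs [simulate_phi()] for every charged line of one or more radionuclide
#' records over a log-spaced radius grid, so that downstream dose
#' computations interpolate instead of re-simulating. Lines shared between
#' nuclides (same particle class and energy) are simulated once.
#'
#' @param records A `radionuclide_record` or list of them.
#' @param radii_cm Radius grid (sorted, positive); default 48 log-spaced
#'   points from 1e-4 cm to 3 cm, covering single cells to the largest
#'   primary tumor.
#' @param histories Histories per (line, radius) point.
#' @param seed Integer base seed; each grid point uses a sub-seed derived
#'   from it, so the grid is reproducible bit-for-bit.
#' @return An object of class `phi_grid`: list with `lines` (particle,
#'   energy), `radii_cm`, `phi` (matrix radii x lines), `se`, `histories`,
#'   `seed`.
#' @export
build_phi_grid <- function(records,
                           radii_cm = exp(seq(log(1e-4), log(3), length.out = 48)),
                           histories = 20000L, seed = 1L) {
  if (inherits(records, "radionuclide_record")) records <- list(records)
  stopifnot(all(radii_cm > 0), !is.unsorted(radii_cm))
  lines <- unique(do.call(rbind, lapply(records, function(r) {
    l <- .charged_lines(r)
    data.frame(particle = l$particle_class, energy_keV = l$energy_keV)
  })))
  lines <- lines[order(lines$particle, lines$energy_keV), ]
  rownames(lines) <- NULL
  nr <- length(radii_cm); nl <- nrow(lines)
  phi <- se <- matrix(NA_real_, nr, nl)
  for (j in seq_len(nl)) {
    for (i in seq_len(nr)) {
      res <- simulate_phi(lines$energy_keV[j], lines$particle[j], radii_cm[i],
                          histories = histories,
                          seed = (seed + 7919L * j + 104729L * i) %% .Machine$integer.max)
      phi[i, j] <- res$phi
      se[i, j] <- res$se
    }
  }
  structure(list(lines = lines, radii_cm = radii_cm, phi = phi, se = se,
                 histories = as.integer(histories), seed = as.integer(seed)),
            class = "phi_grid")
}

#' @export
print.phi_grid <- function(x, ...) {
  cat("<phi_grid> ", nrow(x$lines), " lines x ", length(x$radii_cm),
      " radii [", format(min(x$radii_cm)), ", ", format(max(x$radii_cm)),
      "] cm, ", x$histories, " histories/point, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# interpolate phi at arbitrary radii (linear in log r) for given grid columns
.grid_phi_at <- function(grid, col, radius_cm) {
  if (any(radius_cm < min(grid$radii_cm) | radius_cm > max(grid$radii_cm))) {
    stop("radius outside the phi grid hull [", format(min(grid$radii_cm)), ", ",
         format(max(grid$radii_cm)), "] cm; rebuild the grid to cover it",
         call. = FALSE)
  }
  stats::approx(log(grid$radii_cm), grid$phi[, col], log(radius_cm))$y
}

# match a record's charged lines to grid columns (exact particle, energy
# within tolerance); error when a line is missing.
.grid_columns <- function(grid, lines) {
  vapply(seq_len(nrow(lines)), function(i) {
    j <- which(grid$lines$particle == lines$particle_class[i] &
                 abs(grid$lines$energy_keV - lines$energy_keV[i]) <
                   1e-9 * lines$energy_keV[i])
    if (length(j) != 1L) {
      stop("phi grid does not cover line ", lines$particle_class[i], " ",
           lines$energy_keV[i], " keV; rebuild the grid from this record",
           call. = FALSE)
    }
    j
  }, integer(1))
}

#' Mean absorbed energy per decay in a sphere
#'
#' Sum over the record's charged emission lines of energy x yield x absorbed
#' fraction at the given sphere radius, with the alpha component multiplied
#' by `weight_alpha`. Bounded above by [total_charged_energy()].
#'
#' @param record A `radionuclide_record`.
#' @param radius_cm Sphere radius (cm); vectorised. Must lie within the
#'   grid's radius hull (no silent extrapolation).
#' @param grid A `phi_grid` covering the record's lines.
#' @param weight_alpha Weight applied to the alpha energy component.
#' @return Absorbed energy in keV per decay (same length as `radius_cm`).
#' @export
mean_absorbed_energy <- function(record, radius_cm, grid, weight_alpha = 1) {
  stopifnot(inherits(record, "radionuclide_record"), inherits(grid, "phi_grid"))
  l <- .charged_lines(record, weight_alpha)
  cols <- .grid_columns(grid, l)
  acc <- numeric(length(radius_cm))
  for (i in seq_along(cols)) {
    acc <- acc + l$energy_keV[i] * l$yield_per_decay[i] * l$weight[i] *
      .grid_phi_at(grid, cols[i], radius_cm)
  }
  acc
}

#' Write / read a phi grid as CSV with a JSON metadata sidecar
#'
#' The CSV has columns `particle, energy_keV, radius_cm, phi, se`; the
#' sidecar `<path>.json` records histories and seed so a cached grid is
#' fully reproducible.
#'
#' @param grid A `phi_grid`.
#' @param path CSV path.
#' @return `write_phi_grid` returns `path` invisibly; `read_phi_grid`
#'   returns a `phi_grid`.
#' @export
write_phi_grid <- function(grid, path) {
  stopifnot(inherits(grid, "phi_grid"))
  df <- do.call(rbind, lapply(seq_len(nrow(grid$lines)), function(j) {
    data.frame(particle = grid$lines$particle[j],
               energy_keV = grid$lines$energy_keV[j],
               radius_cm = grid$radii_cm,
               phi = grid$phi[, j], se = grid$se[, j])
  }))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(histories = grid$histories, seed = grid$seed,
                            n_radii = length(grid$radii_cm),
                            n_lines = nrow(grid$lines)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_phi_grid
#' @export
read_phi_grid <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  lines <- unique(df[, c("particle", "energy_keV")])
  lines <- lines[order(lines$particle, lines$energy_keV), ]
  rownames(lines) <- NULL
  radii <- sort(unique(df$radius_cm))
  phi <- se <- matrix(NA_real_, length(radii), nrow(lines))
  for (j in seq_len(nrow(lines))) {
    sub <- df[df$particle == lines$particle[j] & df$energy_keV == lines$energy_keV[j], ]
    sub <- sub[order(sub$radius_cm), ]
    phi[, j] <- sub$phi
    se[, j] <- sub$se
  }
  structure(list(lines = lines, radii_cm = radii, phi = phi, se = se,
                 histories = as.integer(meta$histories),
                 seed = as.integer(meta$seed)),
            class = "phi_grid")
}
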