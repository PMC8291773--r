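#' Binding sites for the stochastic adsorption model
#'
#' A binding site is either a spherical receptor near the pore wall or a
#' region of the pore wall itself. The binding zone is the set of protein
#' center positions within the binding radius of the site; while the protein
#' is inside the zone, adsorption attempts occur as a Poisson process whose
#' rate follows from the bulk association rate constant k_a.
#'
#' @param kind `"spherical_receptor"` or `"wall_region"`.
#' @param center Receptor center, length-3 Cartesian (nm) — receptors only.
#' @param r_rec Receptor radius (nm) — receptors only.
#' @param r_b Binding radius (nm). For receptors: the protein-center to
#'   receptor-center threshold. For wall regions: the protein-surface to wall
#'   threshold (the default 0.2 nm is the standard choice for nonspecific
#'   wall adhesion).
#' @param z0,z1 Axial extent (nm) — wall regions only.
#' @param k_a Association rate constant (1/(M s)).
#' @param k_d Dissociation rate (1/s); must be positive.
#' @param delta Bond rupture length (nm); 0 disables force dependence.
#' @return A list of class `binding_site`.
#' @export
binding_site <- function(kind = c("spherical_receptor", "wall_region"),
                         center = NULL, r_rec = 0, r_b = 0.2,
                         z0 = NULL, z1 = NULL,
                         k_a, k_d, delta = 0) {
  kind <- match.arg(kind)
  stopifnot(r_b > 0, k_a >= 0, k_d >= 0, delta >= 0)
  if (kind == "spherical_receptor") {
    stopifnot(length(center) == 3)
  } else {
    stopifnot(is.numeric(z0), is.numeric(z1), z1 > z0)
  }
  structure(list(kind = kind, center = center, r_rec = r_rec, r_b = r_b,
                 z0 = z0, z1 = z1, k_a = k_a, k_d = k_d, delta = delta),
            class = "binding_site")
}

#' Adsorption rate inside the binding zone
#'
#' R_a = k_a * c_b, where c_b is the concentration of a single receptor in
#' the binding-zone volume: the spherical shell between center-to-center
#' distances (r_prot + r_rec) and r_b, so
#' c_b = (10^3 N_A V_b)^{-1} mol/L with V_b in m^3. Wall regions use
#' r_rec = 0 with the protein-surface-based binding radius converted to the
#' equivalent center-based shell.
#'
#' @param site A [binding_site()].
#' @param protein_radius Protein radius (nm).
#' @param constants [physical_constants()].
#' @return Adsorption rate R_a in 1/s.
#' @export
adsorption_rate <- function(site, protein_radius, constants = physical_constants()) {
  if (site$kind == "spherical_receptor") {
    r_inner <- protein_radius + site$r_rec
    r_outer <- site$r_b
  } else {
    r_inner <- protein_radius
    r_outer <- protein_radius + site$r_b
  }
  if (r_outer <= r_inner)
    stop("degenerate binding zone: binding radius does not exceed contact distance")
  V_b <- 4 / 3 * pi * (r_outer^3 - r_inner^3) * .nm^3
  c_b <- 1 / (1e3 * constants$N_A * V_b)   # mol/L
  site$k_a * c_b
}

#' Draw a stochastic binding duration
#'
#' Exponential with mean tau = k_d^{-1} exp(-|F| delta / kT): Bell's law,
#' with the magnitude of the PNPS force at the binding position shortening
#' the bond lifetime. With delta = 0 the mean reduces exactly to 1/k_d.
#'
#' @param site A [binding_site()] with `k_d > 0`.
#' @param F_mag Force magnitude (N), scalar or vector.
#' @param constants [physical_constants()].
#' @param n Number of draws per force value (recycled).
#' @return Duration(s) in seconds.
#' @export
binding_duration <- function(site, F_mag = 0, constants = physical_constants(),
                             n = length(F_mag)) {
  if (site$k_d <= 0) stop("k_d must be positive (k_d = 0 would bind permanently)")
  mu <- mean_binding_duration(site, F_mag, constants)
  stats::rexp(n, rate = 1 / mu)
}

mean_binding_duration <- function(site, F_mag, constants) {
  (1 / site$k_d) * exp(-abs(F_mag) * site$delta * .nm / constants$kT)
}

#' Draw binding events for one trajectory's attempt records
#'
#' For every BD step spent inside the binding zone the number of adsorptions
#' is Poisson with mean R_a dt; each adsorption gets an exponential duration
#' from [binding_duration()] evaluated with the force recorded at that step.
#'
#' @param records Attempt records: tibble with columns `t`, `F`, `J` (one row
#'   per in-zone BD step), as stored in `bd_trajectory$zone_records`.
#' @param site A [binding_site()].
#' @param dt BD time step (s).
#' @param protein_radius Protein radius (nm).
#' @param constants [physical_constants()].
#' @return Tibble of binding events: `t` (s), `tau` (s), `F` (N), `J` (A).
#' @export
draw_bindings <- function(records, site, dt, protein_radius,
                          constants = physical_constants()) {
  if (is.null(records) || nrow(records) == 0) {
    return(tibble::tibble(t = numeric(0), tau = numeric(0),
                          F = numeric(0), J = numeric(0)))
  }
  R_a <- adsorption_rate(site, protein_radius, constants)
  # Poisson thinning: total count over all records, then uniform assignment
  # (equivalent to independent Poisson draws per equal-length step)
  n_tot <- stats::rpois(1, R_a * dt * nrow(records))
  if (n_tot == 0) {
    return(tibble::tibble(t = numeric(0), tau = numeric(0),
                          F = numeric(0), J = numeric(0)))
  }
  idx <- sample.int(nrow(records), n_tot, replace = TRUE)
  tibble::tibble(
    t = records$t[idx],
    tau = binding_duration(site, records$F[idx], constants, n = n_tot),
    F = records$F[idx],
    J = records$J[idx]
  )
}

#' Assemble an event record from a trajectory and its binding draws
#'
#' The event duration tau_off is the free-motion duration plus the sum of all
#' binding durations; the normalized amplitude A/I0 is the time-weighted
#' average of (I0 - J)/I0 over free motion and over the binding intervals
#' (each weighted by its duration at the current of its binding position).
#' Binding never alters the trajectory geometry.
#'
#' @param trajectory A `bd_trajectory`.
#' @param bindings Tibble from [draw_bindings()] (or a list of them, one per
#'   site, which are concatenated).
#' @param I0 Open-pore current (A); defaults to the trajectory's grid value.
#' @return One-row tibble: `tau_off` (s), `amplitude` (A/I0), `n_bindings`,
#'   `outcome`, `bound`.
#' @export
assemble_event <- function(trajectory, bindings = NULL, I0 = trajectory$I0) {
  if (is.data.frame(bindings)) bindings <- list(bindings)
  bindings <- dplyr::bind_rows(bindings)
  t_free <- trajectory$duration
  A_free <- 1 - trajectory$mean_J / I0
  if (is.null(bindings) || nrow(bindings) == 0) {
    return(tibble::tibble(tau_off = t_free, amplitude = A_free,
                          n_bindings = 0L,
                          outcome = trajectory$termination, bound = FALSE))
  }
  tau_b <- sum(bindings$tau)
  A_b <- 1 - bindings$J / I0
  tau_off <- t_free + tau_b
  amplitude <- (t_free * A_free + sum(bindings$tau * A_b)) / tau_off
  tibble::tibble(tau_off = tau_off, amplitude = amplitude,
                 n_bindings = nrow(bindings),
                 outcome = trajectory$termination, bound = TRUE)
}

#' Resample events from a trajectory pool
#'
#' Implements the cheap event-multiplication variant used when binding is
#' rare: repeatedly pick a random trajectory from the pool (uniform, with
#' replacement) and draw fresh stochastic bindings for it, so each pick
#' yields a new event duration and amplitude while the spatial shapes come
#' from the fixed pool.
#'
#' @param pool A `bd_ensemble` (trajectories run with the sites' zones
#'   monitored).
#' @param sites List of [binding_site()] objects, aligned with the zone
#'   records of the pool's trajectories.
#' @param n_events Number of events to draw.
#' @param protein_radius Protein radius (nm).
#' @param seed RNG seed.
#' @param constants [physical_constants()].
#' @return A tibble of event records (one row per event) with the columns of
#'   [assemble_event()] plus `trajectory` and `seed`.
#' @export
resample_events <- function(pool, sites, n_events, protein_radius,
                            seed = 1, constants = physical_constants()) {
  stopifnot(length(pool$trajectories) >= 1, n_events >= 1)
  set.seed(seed)
  picks <- sample.int(length(pool$trajectories), n_events, replace = TRUE)
  out <- vector("list", n_events)
  for (e in seq_len(n_events)) {
    tr <- pool$trajectories[[picks[e]]]
    bl <- lapply(seq_along(sites), function(k) {
      draw_bindings(tr$zone_records[[k]], sites[[k]], tr$dt, protein_radius,
                    constants)
    })
    out[[e]] <- assemble_event(tr, bl)
  }
  res <- dplyr::bind_rows(out)
  res$trajectory <- picks
  res$seed <- seed
  res
}
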