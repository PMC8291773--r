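#' Solver options for the coupled PNPS iteration
#'
#' @param tol Relative residual / update tolerance for the damped fixed-point
#'   (Gummel-type) iteration between Poisson, Nernst-Planck and Stokes.
#' @param max_iter Maximum number of outer iterations.
#' @param relax Relaxation factor applied to the concentration update.
#' @param verbose Print per-iteration residuals.
#' @return A list of class `solver_options`.
#' @export
solver_options <- function(tol = 1e-6, max_iter = 40, relax = 0.7,
                           verbose = FALSE) {
  stopifnot(tol > 0, max_iter >= 1, relax > 0, relax <= 1)
  structure(list(tol = tol, max_iter = max_iter, relax = relax,
                 verbose = verbose), class = "solver_options")
}

#' Solve the coupled Poisson-Nernst-Planck-Stokes system
#'
#' Computes the steady electrokinetic state of a symmetric monovalent
#' electrolyte in an axisymmetric pore: electric potential phi, ion
#' concentrations c+ and c-, fluid velocity u and pressure p. The applied
#' voltage is split symmetrically across the two reservoir boundaries
#' (`voltage` is the potential of the lower/trans reservoir minus the
#' upper/cis one), bulk concentrations are imposed on both, walls carry
#' surface charge in the Poisson boundary condition and are no-slip for the
#' flow. The Poisson update uses a linearized Boltzmann response for
#' robustness; ion fluxes are discretized with Scharfetter-Gummel exponential
#' fitting (including advection), which keeps concentrations positive and
#' makes the current integral discretely conservative.
#'
#' @param mesh A [pore_mesh()].
#' @param constants [physical_constants()].
#' @param ion_diffusivity A `diffusivity_field` (built for the ion radius), a
#'   single diffusivity in m^2/s, or `NULL` for the Stokes-Einstein bulk value
#'   of a 0.11 nm ion.
#' @param voltage Applied voltage in mV (trans minus cis).
#' @param bulk_conc Bulk salt concentration in mol/L.
#' @param options [solver_options()].
#' @param ion_field_sees_protein If `TRUE` (default), the explicit protein
#'   surface counts as an additional wall when evaluating the ion-diffusivity
#'   field, so ion mobility in the protein-wall gap is hindered by both
#'   surfaces via the nearest-wall distance. Set `FALSE` to reuse a bare-pore
#'   ion field regardless of protein position.
#' @return An object of class `continuum_solution` with fields `phi` (V),
#'   `c_plus`, `c_minus` (mol/m^3), `u_r`, `u_z` (m/s, MAC faces), `p` (Pa),
#'   convergence diagnostics and metadata.
#' @export
solve_pnps <- function(mesh, constants = physical_constants(),
                       ion_diffusivity = NULL, voltage = -100,
                       bulk_conc = 1, options = solver_options(),
                       ion_field_sees_protein = TRUE) {
  nr <- mesh$nr; nz <- mesh$nz
  FL <- mesh$region == 0L
  V_appl <- voltage * 1e-3
  phi_bot <- V_appl / 2; phi_top <- -V_appl / 2
  c_bulk <- bulk_conc * 1e3                      # mol/m^3

  # ion diffusivity tensors at cell centers
  Dmat <- ion_diffusivity_matrices(mesh, constants, ion_diffusivity,
                                   ion_field_sees_protein)

  pois <- assemble_poisson(mesh, constants, phi_top, phi_bot)
  id_all <- matrix(seq_len(nr * nz), nr, nz)
  qkT <- constants$q / constants$kT

  phi <- matrix(0, nr, nz)
  # linear initial potential ramp across the domain
  phi <- matrix(rep(seq(phi_bot, phi_top, length.out = nz), each = nr), nr, nz)
  cp <- matrix(c_bulk, nr, nz); cm <- matrix(c_bulk, nr, nz)
  cp[!FL] <- 0; cm[!FL] <- 0
  u_r <- matrix(0, nr + 1, nz); u_z <- matrix(0, nr, nz + 1)
  p <- matrix(0, nr, nz)

  stokes_sys <- NULL
  res_hist <- numeric(0)
  J_prev <- NA_real_
  for (it in seq_len(options$max_iter)) {
    # --- Poisson with linearized ionic response (frozen quasi-Fermi) -------
    rhs <- pois$rhs0
    rhs[id_all[FL]] <- rhs[id_all[FL]] +
      constants$C_F * (cp[FL] - cm[FL]) * mesh$V[FL] * .nm^3
    resp <- numeric(nr * nz)
    resp[id_all[FL]] <- constants$C_F * qkT * (cp[FL] + cm[FL]) * mesh$V[FL] * .nm^3
    M <- pois$M + Matrix::Diagonal(nr * nz, resp)
    rhs <- rhs + resp * as.numeric(phi)
    phi_new <- matrix(as.numeric(Matrix::solve(M, rhs)), nr, nz)
    dphi <- max(abs(phi_new - phi))
    phi <- phi_new

    # --- Nernst-Planck for both species ------------------------------------
    npp <- assemble_np(mesh, constants, +1, Dmat, phi, u_r, u_z, c_bulk,
                       phi_top, phi_bot)
    cp_new <- cp
    cp_new[FL] <- as.numeric(Matrix::solve(npp$M, npp$rhs))
    npm <- assemble_np(mesh, constants, -1, Dmat, phi, u_r, u_z, c_bulk,
                       phi_top, phi_bot)
    cm_new <- cm
    cm_new[FL] <- as.numeric(Matrix::solve(npm$M, npm$rhs))
    dc <- max(abs(cp_new[FL] - cp[FL]), abs(cm_new[FL] - cm[FL])) / c_bulk
    w <- options$relax
    cp[FL] <- (1 - w) * cp[FL] + w * pmax(cp_new[FL], 0)
    cm[FL] <- (1 - w) * cm[FL] + w * pmax(cm_new[FL], 0)

    # --- Stokes with electric body force -----------------------------------
    if (is.null(stokes_sys)) {
      stokes_sys <- assemble_stokes(mesh, constants)
      stokes_sys$factor <- Matrix::lu(stokes_sys$M)
    }
    bf <- electric_body_force(mesh, constants, phi, cp, cm)
    sol_uv <- solve_stokes_system(stokes_sys, bf$f_r, bf$f_z)
    du <- max(abs(sol_uv$u_z - u_z))
    u_r <- sol_uv$u_r; u_z <- sol_uv$u_z; p <- sol_uv$p

    res <- max(dphi / max(abs(V_appl), 0.025), dc,
               du / max(max(abs(u_z)), 1e-12))
    res_hist <- c(res_hist, res)
    if (options$verbose)
      message(sprintf("  pnps iter %d: res %.3e", it, res))
    if (res < options$tol) break
  }
  sol <- structure(list(
    mesh = mesh, constants = constants, phi = phi, c_plus = cp, c_minus = cm,
    u_r = u_r, u_z = u_z, p = p,
    D_ion = Dmat,
    voltage = voltage, bulk_conc = bulk_conc,
    phi_top = phi_top, phi_bot = phi_bot, c_bulk = c_bulk,
    iterations = length(res_hist), residuals = res_hist,
    converged = length(res_hist) < options$max_iter ||
      utils::tail(res_hist, 1) < options$tol
  ), class = "continuum_solution")
  if (!sol$converged)
    warning(sprintf("PNPS iteration did not reach tol %.1e in %d iterations (last residual %.2e)",
                    options$tol, options$max_iter, utils::tail(res_hist, 1)))
  sol
}

ion_diffusivity_matrices <- function(mesh, constants, ion_diffusivity,
                                     ion_field_sees_protein = FALSE) {
  nr <- mesh$nr; nz <- mesh$nz
  if (is.null(ion_diffusivity)) ion_diffusivity <- bulk_diffusivity(constants, 0.11)
  if (is.numeric(ion_diffusivity) && length(ion_diffusivity) == 1) {
    return(list(D_rr = matrix(ion_diffusivity, nr, nz),
                D_zz = matrix(ion_diffusivity, nr, nz)))
  }
  stopifnot(inherits(ion_diffusivity, "diffusivity_field"))
  field <- ion_diffusivity
  if (ion_field_sees_protein && !is.null(mesh$protein) && is.null(field$protein)) {
    field$protein <- list(center = mesh$protein$center,
                          radius = mesh$protein$radius)
  }
  grid <- expand.grid(i = seq_len(nr), j = seq_len(nz))
  ev <- field_eval(field, mesh$r_c[grid$i], mesh$z_c[grid$j])
  list(D_rr = matrix(ev$D_rr, nr, nz), D_zz = matrix(ev$D_zz, nr, nz))
}

# electric body force -C_F (c+ - c-) grad(phi) interpolated to MAC faces
electric_body_force <- function(mesh, constants, phi, cp, cm) {
  nr <- mesh$nr; nz <- mesh$nz
  f_r <- matrix(0, nr + 1, nz); f_z <- matrix(0, nr, nz + 1)
  cd <- cp - cm
  for (i in 2:nr) {
    d <- (mesh$r_c[i] - mesh$r_c[i - 1]) * .nm
    f_r[i, ] <- -constants$C_F * (cd[i - 1, ] + cd[i, ]) / 2 *
      (phi[i, ] - phi[i - 1, ]) / d
  }
  for (j in 2:nz) {
    d <- (mesh$z_c[j] - mesh$z_c[j - 1]) * .nm
    f_z[, j] <- -constants$C_F * (cd[, j - 1] + cd[, j]) / 2 *
      (phi[, j] - phi[, j - 1]) / d
  }
  list(f_r = f_r, f_z = f_z)
}

#' Ionic current through a cross-section
#'
#' Integrates the z-component of q (j+ - j-) over the fluid cross-section at
#' `z_cross`, using the same Scharfetter-Gummel face fluxes as the solver so
#' that charge conservation holds discretely. Positive current flows in +z.
#'
#' @param solution A `continuum_solution`.
#' @param z_cross Axial position (nm); the nearest face row is used. Defaults
#'   to the channel midpoint.
#' @return Current in A.
#' @export
compute_current <- function(solution, z_cross = NULL) {
  mesh <- solution$mesh
  if (is.null(z_cross)) z_cross <- (mesh$spec$z_top + mesh$spec$z_bot) / 2
  if (z_cross < min(mesh$z_b) || z_cross > max(mesh$z_b))
    stop("z_cross outside the computational domain")
  jf <- which.min(abs(mesh$z_b - z_cross))
  fp <- np_face_flux_z(mesh, solution$constants, +1, solution$D_ion,
                       solution$phi, solution$u_z, solution$c_plus, jf,
                       solution$c_bulk, solution$phi_top, solution$phi_bot)
  fm <- np_face_flux_z(mesh, solution$constants, -1, solution$D_ion,
                       solution$phi, solution$u_z, solution$c_minus, jf,
                       solution$c_bulk, solution$phi_top, solution$phi_bot)
  solution$constants$C_F * sum(fp - fm)
}

#' Electric and hydrodynamic force on the explicit protein
#'
#' `F_el` is the volume integral of the protein charge density times the
#' electric field over the protein region; `F_drag` is the hydrodynamic force
#' obtained from a momentum balance over a control box of grid faces around
#' the protein (stress surface integral plus electric body-force volume
#' integral). For an on-axis protein both have only a z-component.
#'
#' @param solution A `continuum_solution` whose mesh contains a protein.
#' @return List with `F_el`, `F_drag`, `F_total` (N, z-components).
#' @export
compute_force <- function(solution) {
  mesh <- solution$mesh
  if (is.null(mesh$protein)) stop("mesh contains no protein region")
  constants <- solution$constants
  nr <- mesh$nr; nz <- mesh$nz
  # F_el: uniform volume charge density over the protein cells
  pc <- which(mesh$region == 3L, arr.ind = TRUE)
  F_el <- 0
  if (nrow(pc) && !is.null(mesh$protein$charge) && mesh$protein$charge != 0) {
    Vp <- mesh$V[pc] * .nm^3
    rho <- mesh$protein$charge * constants$q / sum(Vp)
    for (k in seq_len(nrow(pc))) {
      i <- pc[k, 1]; j <- pc[k, 2]
      jm <- max(j - 1, 1); jp <- min(j + 1, nz)
      Ez <- -(solution$phi[i, jp] - solution$phi[i, jm]) /
        ((mesh$z_c[jp] - mesh$z_c[jm]) * .nm)
      F_el <- F_el + rho * Ez * Vp[k]
    }
  }
  bf <- electric_body_force(mesh, constants, solution$phi,
                            solution$c_plus, solution$c_minus)
  # cell-centered f_z for the volume term
  f_z_cells <- (bf$f_z[, seq_len(nz)] + bf$f_z[, seq_len(nz) + 1]) / 2
  F_drag <- stokes_force_z(mesh, constants, solution$u_r, solution$u_z,
                           solution$p, f_z_cells = f_z_cells)
  list(F_el = c(0, 0, F_el), F_drag = c(0, 0, F_drag),
       F_total = c(0, 0, F_el + F_drag))
}

#' Stokes flow driven by a moving boundary
#'
#' Solves the Stokes equations with a prescribed rigid axial velocity on the
#' protein surface and no-slip walls (no electric force). Used for
#' low-Reynolds-number drag computations and as the independent cross-check of
#' the Stokeslet-based friction tensors.
#'
#' @param mesh A [pore_mesh()] containing a protein region.
#' @param constants [physical_constants()].
#' @param velocity Axial boundary velocity of the protein surface (m/s).
#' @return List with `u_r`, `u_z`, `p` fields and `F_drag` (N, z-component,
#'   force exerted by the fluid on the protein).
#' @export
solve_stokes <- function(mesh, constants = physical_constants(), velocity = 1) {
  if (is.null(mesh$protein)) stop("mesh contains no protein region")
  sys <- assemble_stokes(mesh, constants, protein_velocity = c(0, velocity))
  sol <- solve_stokes_system(sys)
  Fd <- stokes_force_z(mesh, constants, sol$u_r, sol$u_z, sol$p)
  list(u_r = sol$u_r, u_z = sol$u_z, p = sol$p, F_drag = Fd)
}

#' @exportS3Method base::print
print.continuum_solution <- function(x, ...) {
  J <- tryCatch(compute_current(x), error = function(e) NA)
  cat(sprintf(
    "continuum_solution: %s, %g mV, %g M; %d iterations (converged: %s)\n  mid-channel current %s pA\n",
    x$mesh$spec$name, x$voltage, x$bulk_conc, x$iterations, x$converged,
    format(J * 1e12, digits = 4)))
  invisible(x)
}

#' Tidy summary of a continuum solution
#'
#' @param x A `continuum_solution`.
#' @param ... Unused.
#' @return A one-row tibble with voltage, bulk concentration, mid-channel
#'   current (pA), iteration count and convergence flag.
#' @export
glance.continuum_solution <- function(x, ...) {
  tibble::tibble(
    pore = x$mesh$spec$name,
    voltage_mV = x$voltage,
    bulk_M = x$bulk_conc,
    current_pA = compute_current(x) * 1e12,
    iterations = x$iterations,
    converged = x$converged
  )
}
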