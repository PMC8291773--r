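#' Grid of physically possible protein positions
#'
#' Builds the meridional (r, z) grid of protein-center positions used to
#' sample the force and current fields: positions cover the channel and the
#' near-reservoir region and every position keeps the protein clear of walls
#' and membrane.
#'
#' @param spec A [pore_spec()].
#' @param protein_radius Protein radius (nm).
#' @param spacing Grid spacing inside the channel (nm); outside the channel
#'   twice this spacing is used.
#' @param z_margin How far beyond the channel ends to extend (nm); defaults to
#'   the reservoir extents.
#' @return A tibble with columns `r`, `z` (nm) and `in_channel`.
#' @export
make_grid <- function(spec, protein_radius, spacing = 1, z_margin = NULL) {
  stopifnot(spacing > 0)
  if (is.null(z_margin)) z_margin <- c(spec$reservoir$bottom, spec$reservoir$top)
  z_in <- seq(spec$z_bot, spec$z_top, by = spacing)
  pad <- protein_radius + 2   # keep stations clear of the reservoir boundary
  z_out <- c(seq(spec$z_bot - z_margin[1] + pad, spec$z_bot, by = 2 * spacing),
             seq(spec$z_top, spec$z_top + z_margin[2] - pad, by = 2 * spacing))
  zs <- sort(unique(c(z_in, z_out)))
  rmax <- spec$reservoir$radius - protein_radius
  pts <- do.call(rbind, lapply(zs, function(z) {
    in_ch <- z >= spec$z_bot & z <= spec$z_top
    h <- if (in_ch) spacing else 2 * spacing
    data.frame(r = seq(0, rmax, by = h), z = z)
  }))
  wd <- wall_distance(spec, pts)
  keep <- wd$distance >= protein_radius
  out <- tibble::tibble(r = pts$r[keep], z = pts$z[keep])
  out$in_channel <- out$z >= spec$z_bot & out$z <= spec$z_top
  if (!any(out$in_channel & out$r == 0))
    stop("no admissible in-channel positions: protein larger than the channel")
  out
}

#' Sample the force and current fields over a position grid
#'
#' Runs the continuum solver over the position grid and assembles a
#' `force_current_grid`: the open-pore current I0 from a protein-free solve,
#' explicit-protein PNPS solves (force from the charge and stress integrals,
#' current from the cross-section flux) at on-axis stations, and point-particle
#' entries elsewhere (F_el = Q E(x), F_drag = gamma(x) u(x) from the
#' protein-free fields and the protein diffusivity field). The sampled values
#' are postprocessed into rectangular interpolation tables for the
#' Brownian-dynamics integrator.
#'
#' @param spec A [pore_spec()].
#' @param protein List `radius` (nm), `charge` (units of q).
#' @param voltage Applied voltage (mV, trans minus cis).
#' @param bulk_conc Bulk concentration (mol/L).
#' @param ion_field Ion `diffusivity_field` (or `NULL` for bulk).
#' @param protein_field Protein `diffusivity_field` (combined r,z model is the
#'   reference choice); used for point-particle drag and carried along for BD.
#' @param spacing Explicit-station spacing along the axis (nm).
#' @param resolution Mesh resolution list for the PNPS solves.
#' @param options [solver_options()].
#' @param table_dr,table_dz Resolution of the rectangular BD tables (nm).
#' @param mode `"blend"` (default): explicit-protein solves at on-axis
#'   stations blended with the point-particle closure; `"point_particle"`:
#'   skip the explicit solves entirely and use the closure everywhere (the
#'   choice for wide pores whose blockades are negligible, where the explicit
#'   stress integrals are dominated by staircase noise).
#' @param verbose Print progress.
#' @return An object of class `force_current_grid`.
#' @export
sample_forcefield <- function(spec, protein, voltage, bulk_conc = 1,
                              ion_field = NULL, protein_field = NULL,
                              spacing = 2,
                              resolution = list(fine = 0.25, coarse = 1.5),
                              options = solver_options(tol = 1e-5, max_iter = 60),
                              table_dr = 0.25, table_dz = 0.5,
                              mode = c("blend", "point_particle"),
                              verbose = FALSE) {
  mode <- match.arg(mode)
  constants <- physical_constants()
  a <- protein$radius; Q <- protein$charge
  if (is.null(protein_field))
    protein_field <- diffusivity_field(spec, a, "r_dependent", constants)

  # --- protein-free reference solution ------------------------------------
  mesh0 <- pore_mesh(spec, resolution)
  sol0 <- solve_pnps(mesh0, constants, ion_field, voltage, bulk_conc, options)
  I0 <- compute_current(sol0)

  # --- explicit on-axis stations ------------------------------------------
  z_stations <- if (mode == "point_particle") numeric(0) else
    make_grid(spec, a, spacing = spacing)
  if (is.data.frame(z_stations))
    z_stations <- sort(unique(z_stations$z[z_stations$r == 0]))
  exp_rows <- list()
  for (z0 in z_stations) {
    ok <- tryCatch({
      mp <- pore_mesh(spec, resolution, protein = list(center = c(0, z0),
                                                       radius = a, charge = Q))
      sp <- solve_pnps(mp, constants, ion_field, voltage, bulk_conc, options)
      Fp <- compute_force(sp)
      Jp <- compute_current(sp, z_cross = NULL)
      exp_rows[[length(exp_rows) + 1]] <- tibble::tibble(
        r = 0, z = z0, F_r = 0, F_z = Fp$F_total[3], J = Jp, mode = "explicit")
      TRUE
    }, error = function(e) {
      warning(sprintf("explicit solve failed at z = %g nm: %s", z0,
                      conditionMessage(e)))
      FALSE
    })
    if (verbose && ok) message(sprintf("  explicit station z = %g done", z0))
  }
  exp_tab <- dplyr::bind_rows(exp_rows)
  if (length(z_stations) && nrow(exp_tab) < 0.9 * length(z_stations))
    stop("more than 10% of explicit grid positions failed to converge")

  # --- interpolation tables -------------------------------------------------
  rg <- seq(0, spec$reservoir$radius - 1e-6, by = table_dr)
  zg <- seq(min(mesh0$z_b) + 1e-6, max(mesh0$z_b) - 1e-6, by = table_dz)
  grid <- expand.grid(r = rg, z = zg)
  ev <- field_eval(protein_field, grid$r, grid$z)
  nr <- length(rg); nz <- length(zg)
  fpar <- matrix(pmax(ev$f_par, 1e-3), nr, nz)
  fperp <- matrix(pmax(ev$f_perp, 1e-3), nr, nz)
  n_r <- matrix(ev$n_r, nr, nz); n_z <- matrix(ev$n_z, nr, nz)

  # point-particle force from the protein-free fields
  pp <- point_particle_force(sol0, grid$r, grid$z, Q, protein_field, constants)
  F_r <- matrix(pp$F_r, nr, nz)
  F_z <- matrix(pp$F_z, nr, nz)
  if (nrow(exp_tab) >= 2) {
    # blend the explicit axial force into the channel interior
    fz_exp <- stats::approx(exp_tab$z, exp_tab$F_z, xout = zg, rule = 2)$y
    fz_pp0 <- stats::approx(zg, F_z[1, ], xout = zg, rule = 2)$y
    Rz <- profile_radius(spec, zg)
    for (j in seq_len(nz)) {
      w <- if (is.finite(Rz[j])) pmax(0, 1 - rg / Rz[j]) else rep(0, nr)
      F_z[, j] <- F_z[, j] + w * (fz_exp[j] - fz_pp0[j])
    }
    # currents: on-axis explicit blockade profile, extended across the lumen
    J_exp <- stats::approx(exp_tab$z, exp_tab$J, xout = zg, rule = 2)$y
    J <- matrix(rep(J_exp, each = nr), nr, nz)
  } else {
    J <- matrix(I0, nr, nz)
  }

  structure(list(
    spec = spec, protein = protein, voltage = voltage, bulk_conc = bulk_conc,
    I0 = I0, table = exp_tab,
    tables = list(r = rg, z = zg, Fr = F_r, Fz = F_z, J = J,
                  fpar = fpar, fperp = fperp, n_r = n_r, n_z = n_z,
                  D0 = protein_field$D0),
    protein_field_model = protein_field$model,
    spec_hash = rlang::hash(spec),
    modes = c(explicit_stations = nrow(exp_tab))
  ), class = "force_current_grid")
}

# Point-particle force closure on the protein-free fields. The protein drifts
# with the local electrophoretic slip plus the fluid velocity, so the
# equivalent BD force is F = gamma(x) (mu_ep E(x) + u(x)), with gamma from the
# protein diffusivity field and mu_ep = eps eps0 zeta / eta the thin-double-
# layer (Smoluchowski) mobility; zeta follows from the net charge spread over
# the sphere surface via the Grahame equation. At 1 M the double layer is far
# thinner than the protein, so the screened mobility — not the bare QE force —
# sets the electrophoretic drift.
point_particle_force <- function(sol0, r, z, Q, protein_field, constants) {
  mesh <- sol0$mesh
  dphidr <- interp_cell_gradient(mesh, sol0$phi, r, z, "r")
  dphidz <- interp_cell_gradient(mesh, sol0$phi, r, z, "z")
  ur <- interp_mac(mesh, sol0$u_r, r, z, "r")
  uz <- interp_mac(mesh, sol0$u_z, r, z, "z")
  ev <- field_eval(protein_field, r, z)
  g_rr <- constants$kT / pmax(ev$D_rr, 1e-16)
  g_zz <- constants$kT / pmax(ev$D_zz, 1e-16)
  a_m <- protein_field$a * .nm
  sigma_p <- Q * constants$q / (4 * pi * a_m^2)
  n0 <- sol0$bulk_conc * 1e3 * constants$N_A
  eps_w <- constants$eps_r[["water"]] * constants$eps0
  sigma_c <- sqrt(8 * eps_w * constants$kT * n0)
  zeta <- (2 * constants$kT / constants$q) * asinh(sigma_p / sigma_c)
  mu_ep <- eps_w * zeta / constants$eta
  # E = -grad(phi); slip velocity = mu_ep E + u
  list(F_r = g_rr * (mu_ep * (-dphidr) + ur),
       F_z = g_zz * (mu_ep * (-dphidz) + uz))
}

# bilinear sample of a cell-centered field's gradient component (SI per m)
interp_cell_gradient <- function(mesh, phi, r, z, dir) {
  n <- length(r)
  out <- numeric(n)
  for (k in seq_len(n)) {
    i <- findInterval(r[k], mesh$r_c, all.inside = TRUE)
    j <- findInterval(z[k], mesh$z_c, all.inside = TRUE)
    if (dir == "r") {
      ip <- min(i + 1, mesh$nr)
      d <- (mesh$r_c[ip] - mesh$r_c[i]) * .nm
      out[k] <- if (d > 0) (phi[ip, j] - phi[i, j]) / d else 0
    } else {
      jp <- min(j + 1, mesh$nz)
      d <- (mesh$z_c[jp] - mesh$z_c[j]) * .nm
      out[k] <- if (d > 0) (phi[i, jp] - phi[i, j]) / d else 0
    }
  }
  out
}

# nearest-face sample of a MAC velocity component
interp_mac <- function(mesh, u, r, z, dir) {
  n <- length(r)
  out <- numeric(n)
  for (k in seq_len(n)) {
    if (dir == "r") {
      i <- findInterval(r[k], mesh$r_b, all.inside = TRUE)
      j <- findInterval(z[k], mesh$z_c, all.inside = TRUE)
      out[k] <- u[i, j]
    } else {
      i <- findInterval(r[k], mesh$r_c, all.inside = TRUE)
      j <- findInterval(z[k], mesh$z_b, all.inside = TRUE)
      out[k] <- u[i, j]
    }
  }
  out
}

#' Interpolate force and current at arbitrary positions
#'
#' Bilinear interpolation in the grid's rectangular tables; exact at table
#' nodes, continuous in between, clamped to the nearest boundary value outside
#' the covered rectangle.
#'
#' @param grid A `force_current_grid`.
#' @param r,z Positions (nm).
#' @return A tibble with `r`, `z`, `F_r`, `F_z` (N), `J` (A).
#' @export
interpolate_forcefield <- function(grid, r, z) {
  tb <- grid$tables
  n <- max(length(r), length(z))
  r <- rep_len(pmin(pmax(r, tb$r[1]), max(tb$r)), n)
  z <- rep_len(pmin(pmax(z, tb$z[1]), max(tb$z)), n)
  bil <- function(M) {
    out <- numeric(n)
    for (k in seq_len(n)) {
      i <- findInterval(r[k], tb$r, all.inside = TRUE)
      j <- findInterval(z[k], tb$z, all.inside = TRUE)
      wr <- (r[k] - tb$r[i]) / (tb$r[i + 1] - tb$r[i])
      wz <- (z[k] - tb$z[j]) / (tb$z[j + 1] - tb$z[j])
      out[k] <- M[i, j] * (1 - wr) * (1 - wz) + M[i + 1, j] * wr * (1 - wz) +
        M[i, j + 1] * (1 - wr) * wz + M[i + 1, j + 1] * wr * wz
    }
    out
  }
  tibble::tibble(r = r, z = z, F_r = bil(tb$Fr), F_z = bil(tb$Fz), J = bil(tb$J))
}

#' @exportS3Method base::print
print.force_current_grid <- function(x, ...) {
  cat(sprintf(
    "force_current_grid: %s at %g mV, %g M; I0 = %.1f pA; %d explicit stations; tables %d x %d\n",
    x$spec$name, x$voltage, x$bulk_conc, x$I0 * 1e12, nrow(x$table),
    length(x$tables$r), length(x$tables$z)))
  invisible(x)
}

#' Export a force grid as a tibble
#'
#' @param grid A `force_current_grid`.
#' @return The explicit-station table with I0 attached as an attribute.
#' @export
forcefield_table <- function(grid) {
  out <- grid$table
  attr(out, "I0") <- grid$I0
  out
}
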