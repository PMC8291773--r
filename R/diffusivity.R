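#' Stokes-Einstein bulk diffusivity
#'
#' D0 = kT / (6 pi eta a) for a sphere of hydrodynamic radius `a`.
#' The hydrodynamic radius of both K+ and Cl- ions is taken as 0.11 nm, chosen
#' so that this formula matches measured bulk ion diffusivities.
#'
#' @param constants [physical_constants()].
#' @param radius Particle radius in nm.
#' @return Diffusivity in m^2/s.
#' @export
bulk_diffusivity <- function(constants, radius) {
  if (any(radius <= 0)) stop("radius must be positive")
  constants$kT / (6 * pi * constants$eta * radius * .nm)
}

#' Hindered-diffusion factors near an infinite plane wall
#'
#' Closed-form approximations for the mobility of a sphere of radius `a` whose
#' center is at distance `h` from a plane wall: the Faxen series for motion
#' parallel to the wall and a Pade approximant in the surface-to-wall gap for
#' perpendicular motion. Both factors are clamped to `[floor, 1]`; the floor
#' (default 1e-3) guards the lubrication limit where the approximations break
#' down as the gap closes.
#'
#' @param a Sphere radius (nm).
#' @param h Center-to-wall distance (nm); values below `a` are treated as
#'   contact.
#' @param floor Lower clamp for both factors.
#' @return List with numeric vectors `f_parallel` and `f_perpendicular`.
#' @export
plane_wall_factors <- function(a, h, floor = 1e-3) {
  stopifnot(a > 0)
  h <- pmax(h, a)
  s <- a / h
  f_par <- 1 - (9 / 16) * s + (1 / 8) * s^3 - (45 / 256) * s^4 - (1 / 16) * s^5
  g <- h - a
  f_perp <- (6 * g^2 + 2 * a * g) / (6 * g^2 + 9 * a * g + 2 * a^2)
  list(
    f_parallel = pmin(pmax(f_par, floor), 1),
    f_perpendicular = pmin(pmax(f_perp, floor), 1)
  )
}

#' Position-dependent diffusivity fields
#'
#' Builds a `diffusivity_field` for a particle of radius `a` in the pore
#' described by `spec`. Four models are supported:
#' \describe{
#'   \item{`bulk_constant`}{`D0 * I` everywhere.}
#'   \item{`z_dependent`}{the numerical low-Reynolds-number hydrodynamics
#'     (LRNH) tensor computed on the channel centerline, extended radially.}
#'   \item{`r_dependent`}{plane-wall factors of the distance to the nearest
#'     wall, oriented along the nearest-wall normal.}
#'   \item{`combined_rz`}{the `r_dependent` tensor rescaled per z so that its
#'     centerline value equals the centerline LRNH tensor; the reference model
#'     for production runs.}
#'   \item{`lrnh_numeric`}{full LRNH evaluation (three Stokes solves) at every
#'     query point; accurate but expensive, used for validation.}
#' }
#'
#' @param spec A [pore_spec()].
#' @param a Particle radius (nm).
#' @param model Model id (see above).
#' @param constants [physical_constants()].
#' @param protein Optional explicit protein (list `center`, `radius`) treated
#'   as an additional wall for ion fields.
#' @param centerline Optional precomputed centerline table (tibble with
#'   columns `z`, `f_axial`, `f_transverse`) to reuse across fields.
#' @param n_stations Number of centerline LRNH stations (default 12) when the
#'   centerline has to be computed.
#' @param lrnh_options Options passed to [lrnh_tensor()] for centerline or
#'   `lrnh_numeric` evaluations.
#' @return An object of class `diffusivity_field`.
#' @export
diffusivity_field <- function(spec, a, model = c("combined_rz", "bulk_constant",
                                                 "z_dependent", "r_dependent",
                                                 "lrnh_numeric"),
                              constants = physical_constants(),
                              protein = NULL, centerline = NULL,
                              n_stations = 12, lrnh_options = list()) {
  model <- match.arg(model)
  D0 <- bulk_diffusivity(constants, a)
  field <- list(spec = spec, a = a, model = model, D0 = D0,
                constants = constants, protein = protein,
                lrnh_options = lrnh_options)
  if (model %in% c("z_dependent", "combined_rz")) {
    if (is.null(centerline)) {
      centerline <- lrnh_centerline(spec, a, constants, n_stations = n_stations,
                                    options = lrnh_options)
    }
    field$centerline <- centerline
    field$cl_axial <- stats::splinefun(centerline$z, centerline$f_axial,
                                       method = "monoH.FC")
    field$cl_trans <- stats::splinefun(centerline$z, centerline$f_transverse,
                                       method = "monoH.FC")
    field$cl_range <- range(centerline$z)
  }
  class(field) <- "diffusivity_field"
  field
}

#' @exportS3Method base::print
print.diffusivity_field <- function(x, ...) {
  cat(sprintf("diffusivity_field: model %s, a = %g nm, D0 = %.4g m^2/s (%s)\n",
              x$model, x$a, x$D0, x$spec$name))
  invisible(x)
}

# centerline factor lookup, clamped to the sampled range (-> 1 far outside)
cl_factors <- function(field, z) {
  z0 <- pmax(pmin(z, field$cl_range[2]), field$cl_range[1])
  list(axial = pmin(pmax(field$cl_axial(z0), 1e-3), 1),
       trans = pmin(pmax(field$cl_trans(z0), 1e-3), 1))
}

#' Evaluate a diffusivity field in the meridional plane
#'
#' Returns wall-frame factors and the diagonal (r, z, theta) tensor components
#' at points (r, z). The tensor eigenframe is aligned with the nearest-wall
#' normal (perpendicular factor) and its tangent plane (parallel factor).
#'
#' @param field A `diffusivity_field`.
#' @param r,z Coordinates (nm).
#' @return A list with `f_par`, `f_perp` (wall-frame factors), `n_r`, `n_z`
#'   (nearest-wall normal), and tensor components `D_rr`, `D_zz`, `D_tt`
#'   (m^2/s) under the diagonal-in-(r,z,theta) approximation.
#' @export
field_eval <- function(field, r, z) {
  n <- max(length(r), length(z))
  r <- rep_len(r, n); z <- rep_len(z, n)
  D0 <- field$D0
  if (field$model == "bulk_constant") {
    one <- rep(1, n)
    return(list(f_par = one, f_perp = one, n_r = one, n_z = rep(0, n),
                D_rr = rep(D0, n), D_zz = rep(D0, n), D_tt = rep(D0, n)))
  }
  wd <- wall_distance(field$spec, data.frame(r = r, z = z),
                      protein = field$protein)
  h <- pmax(wd$distance, 0)
  nr_ <- wd$normal[, 1]; nz_ <- wd$normal[, 2]
  if (field$model == "z_dependent") {
    cf <- cl_factors(field, z)
    # centerline tensor extended radially: axial factor along z,
    # transverse factor along r and theta
    return(list(f_par = cf$axial, f_perp = cf$trans, n_r = rep(1, n), n_z = rep(0, n),
                D_rr = D0 * cf$trans, D_zz = D0 * cf$axial, D_tt = D0 * cf$trans))
  }
  # wall_distance gives the distance from the particle center (the query
  # point) to the wall surface, which is the center-to-wall distance h
  pw <- plane_wall_factors(field$a, h)
  f_par <- pw$f_parallel; f_perp <- pw$f_perpendicular
  if (field$model == "lrnh_numeric") {
    f_par <- numeric(n); f_perp <- numeric(n)
    for (k in seq_len(n)) {
      Dk <- lrnh_tensor(field$spec, field$a, c(r[k], z[k]),
                        constants = field$constants,
                        options = field$lrnh_options)$D
      # wall frame: normal in the meridional plane
      nv <- c(nr_[k], 0, nz_[k])
      f_perp[k] <- as.numeric(t(nv) %*% Dk %*% nv) / D0
      tv <- c(-nz_[k], 0, nr_[k])
      f_par[k] <- as.numeric(t(tv) %*% Dk %*% tv) / D0
    }
  } else if (field$model == "combined_rz") {
    cf <- cl_factors(field, z)
    rc <- profile_radius(field$spec, z)
    h_cl <- ifelse(is.finite(rc), rc, Inf)
    pw_cl <- plane_wall_factors(field$a, pmin(h_cl, 1e6))
    f_par <- f_par * pmin(cf$axial / pw_cl$f_parallel, 1.2)
    f_perp <- f_perp * pmin(cf$trans / pw_cl$f_perpendicular, 1.2)
  }
  f_par <- pmin(pmax(f_par, 1e-3), 1)
  f_perp <- pmin(pmax(f_perp, 1e-3), 1)
  # extra hindrance from an explicit protein surface is already included via
  # wall_distance(protein = ...) choosing the nearest surface
  D_rr <- D0 * (f_perp * nr_^2 + f_par * (1 - nr_^2))
  D_zz <- D0 * (f_perp * nz_^2 + f_par * (1 - nz_^2))
  D_tt <- D0 * f_par
  list(f_par = f_par, f_perp = f_perp, n_r = nr_, n_z = nz_,
       D_rr = D_rr, D_zz = D_zz, D_tt = D_tt)
}

#' Full 3x3 diffusion tensor at a 3-D position
#'
#' @param field A `diffusivity_field`.
#' @param x Numeric length-3 Cartesian position (nm), z along the pore axis.
#' @return 3x3 diffusion tensor (m^2/s), symmetric positive semidefinite.
#' @export
field_tensor <- function(field, x) {
  r <- sqrt(x[1]^2 + x[2]^2)
  ev <- field_eval(field, r, x[3])
  if (r < 1e-12) {
    nvec <- c(ev$n_r, 0, ev$n_z)
  } else {
    nvec <- c(ev$n_r * x[1] / r, ev$n_r * x[2] / r, ev$n_z)
  }
  D0f <- field$D0 * ev$f_par
  D <- diag(rep(D0f, 3)) +
    (field$D0 * ev$f_perp - D0f) * (nvec %o% nvec)
  (D + t(D)) / 2
}

#' Average relative diffusivity over the channel
#'
#' Computes the weighted channel average of D_zz / D0, the quantity usually
#' compared against molecular-dynamics estimates of in-pore ion diffusivity.
#'
#' @param field A `diffusivity_field`.
#' @param mesh A [pore_mesh()] of the same spec.
#' @param weight Either a matrix of nonnegative weights on mesh cells (e.g. a
#'   simulated K+ concentration field) or `NULL` for a uniform weight.
#' @return Dimensionless average in (0, 1].
#' @export
channel_average <- function(field, mesh, weight = NULL) {
  inch <- outer(seq_len(mesh$nr), seq_len(mesh$nz), function(i, j) {
    mesh$z_c[j] >= mesh$spec$z_bot & mesh$z_c[j] <= mesh$spec$z_top
  }) & mesh$region == 0L
  if (is.null(weight)) weight <- matrix(1, mesh$nr, mesh$nz)
  w <- weight[inch] * mesh$V[inch]
  if (sum(w) <= 0) stop("zero total weight over the channel region")
  grid <- which(inch, arr.ind = TRUE)
  ev <- field_eval(field, mesh$r_c[grid[, 1]], mesh$z_c[grid[, 2]])
  sum((ev$D_zz / field$D0) * w) / sum(w)
}

#' Tabulate a diffusivity field profile
#'
#' Convenience export reproducing centerline (r = 0) or cross-section
#' (fixed z) relative-diffusivity profiles.
#'
#' @param field A `diffusivity_field`.
#' @param along `"z"` (centerline) or `"r"` (cross-section).
#' @param at Fixed coordinate of the other axis (nm).
#' @param values Coordinates to evaluate at (nm).
#' @return A tibble with the coordinates and relative factors.
#' @export
field_profile <- function(field, along = c("z", "r"), at = 0, values) {
  along <- match.arg(along)
  if (along == "z") {
    ev <- field_eval(field, at, values)
    tibble::tibble(z = values, r = at,
                   rel_parallel = ev$f_par, rel_perpendicular = ev$f_perp,
                   rel_zz = ev$D_zz / field$D0)
  } else {
    ev <- field_eval(field, values, at)
    tibble::tibble(r = values, z = at,
                   rel_parallel = ev$f_par, rel_perpendicular = ev$f_perp,
                   rel_zz = ev$D_zz / field$D0)
  }
}
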