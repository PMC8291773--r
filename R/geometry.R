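#' Axisymmetric pore specifications
#'
#' A `pore_spec` describes an axisymmetric computational domain: a channel whose
#' wall radius is a piecewise-linear function of the axial coordinate z, a solid
#' wall of finite thickness, an optional membrane annulus, and a cylindrical
#' electrolyte reservoir on both sides. The coordinate convention is cylindrical
#' (r, z) with z = 0 at the upper (cis) channel entry and z increasing upward,
#' so the channel occupies z in [-L, 0]. All lengths are in nm and surface
#' charges in elementary charges per nm^2.
#'
#' @param name Identifier for the spec.
#' @param profile Data frame with columns `z` and `r` (nm): channel wall radius
#'   versus axial position, piecewise linear, covering z in `[-channel_length, 0]`.
#' @param channel_length Channel length L (nm).
#' @param wall List: `thickness` (nm, radial thickness of the solid wall),
#'   `charge` (q/nm^2 on the inner channel wall), `outer_charge` (q/nm^2 on the
#'   outer and horizontal wall faces; defaults to `charge`), `material`.
#' @param membrane `NULL` or list `z0`, `z1` (nm), `charge` (q/nm^2),
#'   `material`; an annulus spanning from the outer wall radius to the domain
#'   boundary.
#' @param reservoir List `top`, `bottom` (nm of fluid beyond the channel ends)
#'   and `radius` (nm, domain radius).
#' @param cross_section List `shape` (`"circular"` or `"square-equivalent"`)
#'   and `width` (nm): metadata recording how the nominal cross-section was
#'   mapped to the axisymmetric radius.
#' @param extras Free-form list for preset metadata (e.g. receptor placement).
#' @return An object of class `pore_spec`.
#' @export
pore_spec <- function(name, profile, channel_length, wall, membrane = NULL,
                      reservoir, cross_section = list(shape = "circular", width = NA),
                      extras = list()) {
  profile <- as.data.frame(profile)[, c("z", "r")]
  profile <- profile[order(profile$z), ]
  stopifnot(all(profile$r > 0), channel_length > 0,
            nrow(profile) >= 2, reservoir$radius > max(profile$r))
  if (is.null(wall$outer_charge)) wall$outer_charge <- wall$charge
  spec <- list(
    name = name, profile = profile, channel_length = channel_length,
    z_top = 0, z_bot = -channel_length,
    wall = wall, membrane = membrane, reservoir = reservoir,
    cross_section = cross_section, extras = extras
  )
  class(spec) <- "pore_spec"
  invisible(validate_pore_spec(spec))
  spec
}

validate_pore_spec <- function(spec) {
  if (!is.null(spec$membrane)) {
    m <- spec$membrane
    stopifnot(m$z1 > m$z0)
    if (m$z1 > spec$z_top + spec$reservoir$top ||
        m$z0 < spec$z_bot - spec$reservoir$bottom)
      stop("membrane lies outside the computational domain")
  }
  spec
}

#' @exportS3Method base::print
print.pore_spec <- function(x, ...) {
  cat(sprintf(
    "pore_spec '%s': channel L = %g nm, radius %g-%g nm, wall %g nm thick,\n  reservoir r = %g nm, z in [%g, %g] nm, cross-section %s (width %g nm)\n",
    x$name, x$channel_length, min(x$profile$r), max(x$profile$r),
    x$wall$thickness, x$reservoir$radius,
    x$z_bot - x$reservoir$bottom, x$z_top + x$reservoir$top,
    x$cross_section$shape, x$cross_section$width))
  invisible(x)
}

#' Built-in pore presets
#'
#' Returns a `pore_spec` populated with the geometry and surface-charge
#' parameters of one of three reference pores: the alpha-hemolysin protein pore
#' (parameterized axisymmetric profile, radii 0.5-2.8 nm over a 10 nm channel),
#' a conical SAM-coated silicon nitride solid-state pore (40 degree aperture,
#' 20 nm tip diameter), and a DNA origami pore (46 nm channel, nominally
#' 6 x 6 nm^2 lumen, 6 nm DNA walls carrying -0.74 q/nm^2). The DNA pore's
#' square lumen and box reservoir are mapped to equal-area circles in this
#' axisymmetric representation; pass `shape = "circular"` with a `width` to get
#' a circular lumen of that diameter instead.
#'
#' @param name One of `"alpha_hemolysin"`, `"solid_state"`, `"dna_origami"`.
#' @param overrides Named list of overrides. Recognised fields: `width`,
#'   `shape`, `wall_thickness`, `wall_charge`, `outer_wall_charge`,
#'   `channel_length`, `reservoir_top`, `reservoir_bottom`, `reservoir_radius`,
#'   `tip_diameter` (solid-state only).
#' @return A `pore_spec`.
#' @export
#' @examples
#' build_preset("dna_origami")
#' build_preset("dna_origami", list(shape = "circular", width = 4.9))
build_preset <- function(name, overrides = list()) {
  allowed <- c("width", "shape", "wall_thickness", "wall_charge",
               "outer_wall_charge", "channel_length", "reservoir_top",
               "reservoir_bottom", "reservoir_radius", "tip_diameter")
  bad <- setdiff(names(overrides), allowed)
  if (length(bad)) stop("unknown override field(s): ", paste(bad, collapse = ", "))
  ov <- function(field, default) {
    if (!is.null(overrides[[field]])) overrides[[field]] else default
  }

  if (name == "dna_origami") {
    width <- ov("width", 6)
    shape <- ov("shape", "square-equivalent")
    L <- ov("channel_length", 46)
    R <- if (shape == "circular") width / 2 else width / sqrt(pi)
    # box reservoir 20 x 20 x 70 nm^3 mapped to the equal-area cylinder
    res_R <- ov("reservoir_radius", 20 / sqrt(pi))
    pore_spec(
      name = "dna_origami",
      profile = data.frame(z = c(-L, 0), r = c(R, R)),
      channel_length = L,
      wall = list(thickness = ov("wall_thickness", 6),
                  charge = ov("wall_charge", -0.74),
                  outer_charge = ov("outer_wall_charge", -0.74),
                  material = "dna"),
      membrane = list(z0 = -L, z1 = -L + 2.2, charge = 0, material = "lipid"),
      reservoir = list(top = ov("reservoir_top", 12),
                       bottom = ov("reservoir_bottom", 12),
                       radius = res_R),
      cross_section = list(shape = shape, width = width)
    )
  } else if (name == "solid_state") {
    # conical channel with 40 degree aperture (20 degree half-angle) through a
    # 50 nm membrane stack; tip (smallest diameter) at the lower end
    L <- ov("channel_length", 50)
    tip_r <- ov("tip_diameter", 20) / 2
    top_r <- tip_r + L * tan(20 * pi / 180)
    sam <- -0.078 / 0.1602   # C/m^2 expressed in q/nm^2
    sin_c <- -0.022 / 0.1602
    pore_spec(
      name = "solid_state",
      profile = data.frame(z = c(-L, 0), r = c(tip_r, top_r)),
      channel_length = L,
      wall = list(thickness = ov("wall_thickness", 1e4),
                  charge = ov("wall_charge", sam),
                  outer_charge = ov("outer_wall_charge", sin_c),
                  material = "sin"),
      membrane = NULL,
      reservoir = list(top = ov("reservoir_top", 50),
                       bottom = ov("reservoir_bottom", 50),
                       radius = ov("reservoir_radius", 70)),
      cross_section = list(shape = "circular", width = 2 * tip_r),
      extras = list(receptor = list(height_fraction = 0.95, wall_offset = 2.75),
                    full_scale_reservoir = list(top = 95, bottom = 95, radius = 120))
    )
  } else if (name == "alpha_hemolysin") {
    # parameterized axisymmetric stand-in for the atomistic geometry: a wide
    # vestibule narrowing to a 0.5 nm constriction, then a ~0.9 nm beta barrel
    L <- ov("channel_length", 10)
    prof <- data.frame(
      z = c(-10, -6.5, -5.2, -4.6, -3.5, -1.5, 0),
      r = c(0.9, 0.9, 0.7, 0.5, 1.3, 2.3, 2.8)
    )
    if (L != 10) prof$z <- prof$z * L / 10
    pore_spec(
      name = "alpha_hemolysin",
      profile = prof,
      channel_length = L,
      wall = list(thickness = ov("wall_thickness", 2.5),
                  charge = ov("wall_charge", 0),
                  outer_charge = ov("outer_wall_charge", 0),
                  material = "protein"),
      membrane = list(z0 = -7.6 - 1.1, z1 = -7.6 + 1.1, charge = 0,
                      material = "lipid"),
      reservoir = list(top = ov("reservoir_top", 6),
                       bottom = ov("reservoir_bottom", 6),
                       radius = ov("reservoir_radius", 10)),
      cross_section = list(shape = "circular", width = 2 * 2.8)
    )
  } else {
    stop("unknown preset '", name, "'; available: alpha_hemolysin, solid_state, dna_origami")
  }
}

#' Channel wall radius at axial position z
#'
#' Piecewise-linear interpolation of the channel profile; returns `Inf` outside
#' the channel's z-range (no wall there).
#' @param spec A `pore_spec`.
#' @param z Axial positions (nm).
#' @return Radii (nm).
#' @export
profile_radius <- function(spec, z) {
  r <- rep(Inf, length(z))
  inside <- z >= spec$z_bot & z <= spec$z_top
  if (any(inside)) {
    r[inside] <- stats::approx(spec$profile$z, spec$profile$r, xout = z[inside],
                               rule = 2)$y
  }
  r
}

wall_outer_radius <- function(spec, z) {
  pmin(profile_radius(spec, z) + spec$wall$thickness, spec$reservoir$radius)
}

#' Point-in-solid test
#'
#' @param spec A `pore_spec`.
#' @param r,z Coordinates (nm), recycled to common length.
#' @return Character vector: `"fluid"`, `"wall"` or `"membrane"`.
#' @export
region_at <- function(spec, r, z) {
  n <- max(length(r), length(z))
  r <- rep_len(r, n); z <- rep_len(z, n)
  out <- rep("fluid", n)
  inner <- profile_radius(spec, z)
  outer <- wall_outer_radius(spec, z)
  in_wall <- is.finite(inner) & r > inner & r < outer
  out[in_wall] <- "wall"
  if (!is.null(spec$membrane)) {
    m <- spec$membrane
    # the membrane annulus spans from the outer wall radius (or, beyond the
    # channel's z-range, from the lumen radius at the nearest channel end) out
    # to the domain boundary
    z_cl <- pmax(pmin(z, spec$z_top), spec$z_bot)
    lim <- ifelse(is.finite(inner), outer, profile_radius(spec, z_cl))
    in_mem <- z > m$z0 & z < m$z1 & r >= lim & out != "wall"
    out[in_mem] <- "membrane"
  }
  out
}

# Meridional fluid-solid interface as a set of line segments (nm).
# Used for exact wall distances, BD reflection and surface-charge bookkeeping.
wall_segments <- function(spec) {
  segs <- list()
  add <- function(r0, z0, r1, z1, primitive, charge) {
    segs[[length(segs) + 1]] <<- data.frame(
      r0 = r0, z0 = z0, r1 = r1, z1 = z1,
      primitive = primitive, charge = charge
    )
  }
  R_dom <- spec$reservoir$radius
  prof <- spec$profile
  # inner channel wall (piecewise linear profile), charged
  for (i in seq_len(nrow(prof) - 1)) {
    add(prof$r[i], prof$z[i], prof$r[i + 1], prof$z[i + 1],
        "wall_inner", spec$wall$charge)
  }
  out_top <- wall_outer_radius(spec, spec$z_top)
  out_bot <- wall_outer_radius(spec, spec$z_bot)
  r_top <- prof$r[nrow(prof)]
  r_bot <- prof$r[1]
  # top rim of the wall
  if (out_top > r_top) add(r_top, spec$z_top, out_top, spec$z_top,
                           "wall_rim_top", spec$wall$outer_charge)
  # bottom rim
  if (out_bot > r_bot) add(r_bot, spec$z_bot, out_bot, spec$z_bot,
                           "wall_rim_bot", spec$wall$outer_charge)
  # outer wall faces (vertical), split around the membrane if it attaches
  if (out_top < R_dom) {
    mz <- if (!is.null(spec$membrane)) c(spec$membrane$z0, spec$membrane$z1) else NULL
    zs <- sort(unique(c(spec$z_bot, spec$z_top, mz)))
    zs <- zs[zs >= spec$z_bot & zs <= spec$z_top]
    for (i in seq_len(length(zs) - 1)) {
      zm <- (zs[i] + zs[i + 1]) / 2
      covered <- !is.null(spec$membrane) && zm > spec$membrane$z0 && zm < spec$membrane$z1
      if (!covered) {
        ro <- wall_outer_radius(spec, zm)
        add(ro, zs[i], ro, zs[i + 1], "wall_outer", spec$wall$outer_charge)
      }
    }
  }
  if (!is.null(spec$membrane)) {
    m <- spec$membrane
    rin <- function(z) {
      if (z >= spec$z_bot && z <= spec$z_top) wall_outer_radius(spec, z)
      else profile_radius(spec, max(min(z, spec$z_top), spec$z_bot))
    }
    r0 <- min(rin(m$z0), R_dom)
    r1 <- min(rin(m$z1), R_dom)
    if (r1 < R_dom) add(r1, m$z1, R_dom, m$z1, "membrane_top", m$charge)
    if (r0 < R_dom) add(r0, m$z0, R_dom, m$z0, "membrane_bot", m$charge)
    # inner face of the membrane annulus where it extends beyond the wall z-range
    if (m$z0 < spec$z_bot) add(r0, m$z0, r0, min(m$z1, spec$z_bot), "membrane_inner", m$charge)
    if (m$z1 > spec$z_top) add(r1, max(m$z0, spec$z_top), r1, m$z1, "membrane_inner", m$charge)
  }
  do.call(rbind, segs)
}

#' Distance to the nearest wall
#'
#' Exact minimum distance from points in the fluid domain to the axisymmetric
#' solid surfaces (channel wall, membrane), together with the unit normal of
#' the nearest wall pointing into the fluid. For a surface of revolution the
#' nearest point lies in the meridional plane through the query point, so the
#' 2-D segment distance in (r, z) is exact.
#'
#' @param spec A `pore_spec`.
#' @param points Matrix or data frame with columns `r`, `z` (nm).
#' @param protein Optional list `center = c(r, z)`, `radius` (nm): include a
#'   protein sphere as an additional wall (used for ion-diffusivity fields with
#'   an explicit protein).
#' @return A list with `distance` (nm, negative inside a solid) and `normal`
#'   (n x 2 matrix of unit normals in (r, z)).
#' @export
wall_distance <- function(spec, points, protein = NULL) {
  pts <- as.matrix(as.data.frame(points)[, c("r", "z")])
  segs <- wall_segments(spec)
  d <- rep(Inf, nrow(pts))
  nr <- numeric(nrow(pts)); nz <- numeric(nrow(pts))
  for (i in seq_len(nrow(segs))) {
    a <- c(segs$r0[i], segs$z0[i]); b <- c(segs$r1[i], segs$z1[i])
    ab <- b - a
    len2 <- sum(ab^2)
    t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
    t <- pmin(pmax(t, 0), 1)
    px <- a[1] + t * ab[1]; pz <- a[2] + t * ab[2]
    di <- sqrt((pts[, 1] - px)^2 + (pts[, 2] - pz)^2)
    upd <- di < d
    if (any(upd)) {
      d[upd] <- di[upd]
      nr[upd] <- (pts[upd, 1] - px[upd])
      nz[upd] <- (pts[upd, 2] - pz[upd])
    }
  }
  if (!is.null(protein)) {
    dc <- sqrt((pts[, 1] - protein$center[1])^2 + (pts[, 2] - protein$center[2])^2)
    di <- dc - protein$radius
    upd <- di < d
    if (any(upd)) {
      d[upd] <- di[upd]
      nr[upd] <- pts[upd, 1] - protein$center[1]
      nz[upd] <- pts[upd, 2] - protein$center[2]
    }
  }
  # sign: negative inside solids
  reg <- region_at(spec, pts[, 1], pts[, 2])
  inside_solid <- reg != "fluid"
  if (!is.null(protein)) {
    inside_solid <- inside_solid |
      (sqrt((pts[, 1] - protein$center[1])^2 + (pts[, 2] - protein$center[2])^2) < protein$radius)
  }
  d[inside_solid] <- -d[inside_solid]
  nn <- sqrt(nr^2 + nz^2)
  nn[nn == 0] <- 1
  list(distance = d, normal = cbind(r = nr / nn, z = nz / nn))
}

#' Read or write a pore specification as YAML
#'
#' Lengths carry the nm unit convention documented in [pore_spec()].
#' @param spec A `pore_spec`.
#' @param path File path.
#' @return `write_pore_spec` returns `path` invisibly; `read_pore_spec`
#'   returns a `pore_spec`.
#' @export
write_pore_spec <- function(spec, path) {
  x <- unclass(spec)
  x$profile <- as.list(x$profile)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pore_spec
#' @export
read_pore_spec <- function(path) {
  x <- yaml::read_yaml(path)
  pore_spec(
    name = x$name,
    profile = data.frame(z = x$profile$z, r = x$profile$r),
    channel_length = x$channel_length,
    wall = x$wall, membrane = x$membrane, reservoir = x$reservoir,
    cross_section = x$cross_section,
    extras = if (is.null(x$extras)) list() else x$extras
  )
}
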