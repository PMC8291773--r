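#' Structured axisymmetric mesh for the continuum solvers
#'
#' Discretizes the (r, z) meridional plane of a [pore_spec()] into a
#' tensor-product finite-volume grid. Cell edges snap to geometric features
#' (channel ends, profile kinks, membrane faces, the protein extent), spacing
#' is graded from `fine` near the channel and protein to `coarse` in the
#' reservoir, and every face stores the fraction of its area open to fluid so
#' that curved walls are represented sub-cell accurately. An optional spherical
#' protein centered on the axis is carved out as its own region.
#'
#' @param spec A [pore_spec()].
#' @param resolution List with `fine` (nm, target edge length near walls and
#'   channel, default 0.25), `coarse` (nm, reservoir, default 2) and optional
#'   `gap` (nm, extra-fine spacing near the protein; default adapts to the
#'   protein-wall gap).
#' @param protein Optional list `center = c(r = 0, z = z0)`, `radius` (nm),
#'   `charge` (net charge in units of q). Only on-axis proteins preserve
#'   axisymmetry and are accepted here.
#' @return An object of class `pore_mesh`.
#' @export
pore_mesh <- function(spec, resolution = list(fine = 0.25, coarse = 2),
                      protein = NULL) {
  fine <- resolution$fine %||% 0.25
  coarse <- resolution$coarse %||% 2
  stopifnot(fine > 0, coarse >= fine)
  R_dom <- spec$reservoir$radius
  z_lo <- spec$z_bot - spec$reservoir$bottom
  z_hi <- spec$z_top + spec$reservoir$top

  if (!is.null(protein)) {
    if (length(protein$center) != 2) protein$center <- c(0, protein$center)
    if (abs(protein$center[1]) > 1e-9)
      stop("explicit protein meshes require an on-axis protein (r = 0)")
    wd <- wall_distance(spec, data.frame(r = protein$center[1], z = protein$center[2]))
    if (wd$distance < protein$radius)
      stop("protein overlaps a solid region; position is not physically possible")
  }

  prof_r <- unique(spec$profile$r)
  r_snap <- sort(unique(pmin(c(0, prof_r, wall_outer_radius(spec, spec$profile$z), R_dom), R_dom)))
  z_snap <- c(z_lo, spec$z_bot, spec$profile$z, spec$z_top, z_hi)
  if (!is.null(spec$membrane)) z_snap <- c(z_snap, spec$membrane$z0, spec$membrane$z1)

  r_windows <- data.frame(lo = 0, hi = min(max(prof_r) + 0.5, R_dom), h = fine)
  z_windows <- data.frame(lo = spec$z_bot - 1.5, hi = spec$z_top + 1.5, h = fine)

  # electric-double-layer band: resolve the charged channel wall radially so
  # electroosmosis converges (only meaningful where the wall radius is locally
  # constant; graded walls fall back to `fine`)
  edl <- resolution$edl %||% 0.08
  if (edl < fine) {
    for (rw in unique(spec$profile$r)) {
      r_windows <- rbind(r_windows,
                         data.frame(lo = max(0, rw - 4 * edl),
                                    hi = min(rw + 2 * edl, R_dom), h = edl))
    }
  }

  if (!is.null(protein)) {
    a <- protein$radius; zc <- protein$center[2]
    z_snap <- c(z_snap, zc - a, zc, zc + a)
    r_snap <- c(r_snap, a)
    gap <- profile_radius(spec, zc) - a
    hgap <- resolution$gap %||% max(min(fine, gap / 3), 0.04)
    r_windows <- rbind(r_windows,
                       data.frame(lo = max(0, a - 1),
                                  hi = min(a + min(gap, 1.5) + 0.3, R_dom), h = hgap))
    z_windows <- rbind(z_windows,
                       data.frame(lo = zc - a - 0.8, hi = zc + a + 0.8, h = hgap * 2))
  }

  r_b <- graded_breaks(0, R_dom, r_snap, r_windows, coarse)
  z_b <- graded_breaks(z_lo, z_hi, z_snap, z_windows, coarse)
  nr <- length(r_b) - 1; nz <- length(z_b) - 1
  r_c <- (r_b[-1] + r_b[-length(r_b)]) / 2
  z_c <- (z_b[-1] + z_b[-length(z_b)]) / 2
  dr <- diff(r_b); dz <- diff(z_b)

  grid <- expand.grid(i = seq_len(nr), j = seq_len(nz))
  reg <- region_at(spec, r_c[grid$i], z_c[grid$j])
  code <- match(reg, c("fluid", "wall", "membrane")) - 1L
  if (!is.null(protein)) {
    dprot <- sqrt((r_c[grid$i] - protein$center[1])^2 + (z_c[grid$j] - protein$center[2])^2)
    code[dprot < protein$radius] <- 3L
  }
  region <- matrix(code, nr, nz)

  in_fluid_pt <- function(r, z) {
    ok <- region_at(spec, r, z) == "fluid"
    if (!is.null(protein)) {
      ok <- ok & (sqrt((r - protein$center[1])^2 + (z - protein$center[2])^2) >=
                    protein$radius)
    }
    ok
  }

  # fraction of each face open to fluid (5-point sampling; z-faces sampled
  # uniformly in r^2 so the unweighted mean is area-correct)
  ns <- 5
  open_r <- matrix(0, nr + 1, nz)
  tq <- (seq_len(ns) - 0.5) / ns
  for (i in 2:nr) {   # i = 1 is the axis (zero area), i = nr+1 the outer wall
    zs <- outer(dz, tq) + z_b[seq_len(nz)]
    fl <- matrix(in_fluid_pt(rep(r_b[i], length(zs)), as.vector(zs)), nz, ns)
    open_r[i, ] <- rowMeans(fl)
  }
  open_z <- matrix(0, nr, nz + 1)
  for (j in seq_len(nz + 1)) {
    r2 <- outer(r_b[seq_len(nr)]^2, rep(1, ns)) +
      outer(r_b[-1]^2 - r_b[seq_len(nr)]^2, tq)
    rs <- sqrt(r2)
    fl <- matrix(in_fluid_pt(as.vector(rs), rep(z_b[j], length(rs))), nr, ns)
    open_z[, j] <- rowMeans(fl)
  }

  V <- outer(pi * (r_b[-1]^2 - r_b[-length(r_b)]^2), dz)
  A_r <- outer(2 * pi * r_b, dz)           # (nr+1) x nz
  A_z <- matrix(pi * (r_b[-1]^2 - r_b[-length(r_b)]^2), nr, nz + 1)

  mesh <- list(
    spec = spec, protein = protein,
    r_b = r_b, z_b = z_b, r_c = r_c, z_c = z_c, dr = dr, dz = dz,
    nr = nr, nz = nz, region = region,
    open_r = open_r, open_z = open_z, V = V, A_r = A_r, A_z = A_z
  )
  class(mesh) <- "pore_mesh"
  mesh$surface <- mesh_surface_charges(mesh)
  mesh
}

# piecewise-uniform breaks between snap points, with local target spacing
# taken from the finest window covering each sub-interval
graded_breaks <- function(lo, hi, snap, windows, h_default) {
  snap <- c(snap, windows$lo, windows$hi)
  snap <- sort(unique(c(lo, hi, snap[snap > lo & snap < hi])))
  snap <- snap[c(TRUE, diff(snap) > 1e-9)]
  out <- lo
  for (k in seq_len(length(snap) - 1)) {
    a <- snap[k]; b <- snap[k + 1]
    mid <- (a + b) / 2
    h <- h_default
    cov <- windows$lo <= mid & windows$hi >= mid
    if (any(cov)) h <- min(h, min(windows$h[cov]))
    n <- max(1L, ceiling((b - a) / h))
    out <- c(out, a + (b - a) * seq_len(n) / n)
  }
  out
}

# assign surface-charge densities to fluid|solid faces; staircase areas are
# rescaled per wall segment so the total charge matches the analytic
# surface-of-revolution area
mesh_surface_charges <- function(mesh) {
  spec <- mesh$spec
  segs <- wall_segments(spec)
  nr <- mesh$nr; nz <- mesh$nz
  reg <- mesh$region
  faces <- list()
  # r-faces between laterally adjacent cells
  for (i in 2:nr) {
    fl_l <- reg[i - 1, ] == 0L; fl_r <- reg[i, ] == 0L
    sol_l <- reg[i - 1, ] %in% c(1L, 2L); sol_r <- reg[i, ] %in% c(1L, 2L)
    hit <- (fl_l & sol_r) | (fl_r & sol_l)
    if (any(hit)) {
      j <- which(hit)
      faces[[length(faces) + 1]] <- data.frame(
        type = "r", i = i, j = j, r = mesh$r_b[i], z = mesh$z_c[j],
        area = mesh$A_r[i, j]
      )
    }
  }
  for (j in 2:nz) {
    fl_b <- reg[, j - 1] == 0L; fl_t <- reg[, j] == 0L
    sol_b <- reg[, j - 1] %in% c(1L, 2L); sol_t <- reg[, j] %in% c(1L, 2L)
    hit <- (fl_b & sol_t) | (fl_t & sol_b)
    if (any(hit)) {
      i <- which(hit)
      faces[[length(faces) + 1]] <- data.frame(
        type = "z", i = i, j = j, r = mesh$r_c[i], z = mesh$z_b[j],
        area = mesh$A_z[i, j]
      )
    }
  }
  if (!length(faces)) {
    return(data.frame(type = character(), i = integer(), j = integer(),
                      r = numeric(), z = numeric(), area = numeric(),
                      sigma = numeric()))
  }
  fc <- do.call(rbind, faces)
  # nearest wall segment decides the charge density
  seg_id <- integer(nrow(fc)); seg_d <- rep(Inf, nrow(fc))
  for (s in seq_len(nrow(segs))) {
    a <- c(segs$r0[s], segs$z0[s]); b <- c(segs$r1[s], segs$z1[s])
    ab <- b - a; len2 <- max(sum(ab^2), 1e-300)
    t <- ((fc$r - a[1]) * ab[1] + (fc$z - a[2]) * ab[2]) / len2
    t <- pmin(pmax(t, 0), 1)
    di <- sqrt((fc$r - (a[1] + t * ab[1]))^2 + (fc$z - (a[2] + t * ab[2]))^2)
    upd <- di < seg_d
    seg_d[upd] <- di[upd]; seg_id[upd] <- s
  }
  fc$segment <- seg_id
  fc$sigma <- segs$charge[seg_id] * 0.1602  # q/nm^2 -> C/m^2
  # area rescaling per segment: analytic lateral area of revolution
  seg_area <- 2 * pi * (segs$r0 + segs$r1) / 2 *
    sqrt((segs$r1 - segs$r0)^2 + (segs$z1 - segs$z0)^2)
  stair <- tapply(fc$area, fc$segment, sum)
  scale <- rep(1, nrow(segs))
  scale[as.integer(names(stair))] <- seg_area[as.integer(names(stair))] / as.numeric(stair)
  scale[!is.finite(scale)] <- 1
  fc$area_scale <- scale[fc$segment]
  fc
}

#' Total fluid volume of a mesh
#'
#' @param mesh A `pore_mesh`.
#' @return Volume in nm^3 (full 2*pi revolution).
#' @export
mesh_fluid_volume <- function(mesh) {
  sum(mesh$V[mesh$region == 0L])
}

#' @exportS3Method base::print
print.pore_mesh <- function(x, ...) {
  cat(sprintf("pore_mesh: %d x %d cells (%d fluid), r <= %g nm, z in [%g, %g] nm%s\n",
              x$nr, x$nz, sum(x$region == 0L), max(x$r_b), min(x$z_b), max(x$z_b),
              if (!is.null(x$protein))
                sprintf(", protein a = %g nm at z = %g", x$protein$radius,
                        x$protein$center[2]) else ""))
  invisible(x)
}

#' Export mesh cell data for inspection
#'
#' Returns a tibble of cell centers with region labels and volumes, suitable
#' for plotting or writing to CSV as a light-weight interchange format.
#' @param mesh A `pore_mesh`.
#' @return A tibble with columns `r`, `z`, `region`, `volume`.
#' @export
mesh_table <- function(mesh) {
  grid <- expand.grid(i = seq_len(mesh$nr), j = seq_len(mesh$nz))
  tibble::tibble(
    r = mesh$r_c[grid$i], z = mesh$z_c[grid$j],
    region = c("fluid", "wall", "membrane", "protein")[mesh$region[cbind(grid$i, grid$j)] + 1L],
    volume = mesh$V[cbind(grid$i, grid$j)]
  )
}
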