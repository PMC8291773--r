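# Low-Reynolds-number hydrodynamics: position-dependent friction and diffusion
# tensors from Stokes-flow solves around a rigid sphere, via the method of
# regularized Stokeslets. The sphere surface is discretized with a Fibonacci
# spiral of point forces; the resistance problem (three unit translations) is
# solved by collocation and the friction tensor gamma assembled from the total
# force; D = kT * gamma^{-1} (Einstein relation). Plane walls are handled
# exactly with the classical image system (no wall discretization); general
# axisymmetric channel walls are discretized into rings of collocation points.

# quasi-uniform points on a unit sphere
fibonacci_sphere <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# regularized Stokeslet kernel (blob), without the 1/(8 pi eta) prefactor:
# S_ij = delta_ij (r^2 + 2 eps^2) / (r^2 + eps^2)^{3/2} + r_i r_j / (r^2+eps^2)^{3/2}
# x: n x 3 field points, y: m x 3 source points -> 3n x 3m matrix
stokeslet_block <- function(x, y, eps) {
  n <- nrow(x); m <- nrow(y)
  out <- matrix(0, 3 * n, 3 * m)
  dx <- outer(x[, 1], y[, 1], "-")
  dy <- outer(x[, 2], y[, 2], "-")
  dz <- outer(x[, 3], y[, 3], "-")
  r2 <- dx^2 + dy^2 + dz^2
  # eps may vary per source point (length-m vector)
  e2 <- matrix(rep(eps^2, length.out = m), n, m, byrow = TRUE)
  de <- (r2 + e2)^(3 / 2)
  diag_term <- (r2 + 2 * e2) / de
  d <- list(dx, dy, dz)
  for (i in 1:3) for (j in 1:3) {
    blk <- d[[i]] * d[[j]] / de
    if (i == j) blk <- blk + diag_term
    out[seq_len(n) + (i - 1) * n, seq_len(m) + (j - 1) * m] <- blk
  }
  out
}

# singular Blake image system for a plane wall at z = 0 (fluid in z > 0):
# returns the image contribution (to be added to the free-space kernel) for
# sources y (all with y3 > 0) evaluated at x. Without the 1/(8 pi eta) factor.
blake_image_block <- function(x, y) {
  n <- nrow(x); m <- nrow(y)
  out <- matrix(0, 3 * n, 3 * m)
  hmat <- matrix(y[, 3], n, m, byrow = TRUE)
  Rx <- outer(x[, 1], y[, 1], "-")
  Ry <- outer(x[, 2], y[, 2], "-")
  Rz <- outer(x[, 3], -y[, 3], "-")   # x3 + h
  R2 <- Rx^2 + Ry^2 + Rz^2
  R1 <- sqrt(R2)
  R3 <- R1 * R2
  R5 <- R3 * R2
  Rv <- list(Rx, Ry, Rz)
  # minus the image Stokeslet
  for (i in 1:3) for (j in 1:3) {
    blk <- -(Rv[[i]] * Rv[[j]] / R3)
    if (i == j) blk <- blk - 1 / R1
    out[seq_len(n) + (i - 1) * n, seq_len(m) + (j - 1) * m] <- blk
  }
  # dipole/doublet correction: G_ij += 2 h s_j dA_i/dR_j, with
  # A_i(R) = h R_i / R^3 - delta_i3 / R - R_i R_3 / R^3, s = (+1, +1, -1)
  for (i in 1:3) for (j in 1:3) {
    dij <- as.numeric(i == j)
    di3 <- as.numeric(i == 3)
    dj3 <- as.numeric(j == 3)
    dAdR <- hmat * (dij / R3 - 3 * Rv[[i]] * Rv[[j]] / R5) +
      di3 * Rv[[j]] / R3 -
      (dij * Rz + dj3 * Rv[[i]]) / R3 +
      3 * Rv[[i]] * Rz * Rv[[j]] / R5
    sj <- if (j == 3) -1 else 1
    idx_i <- seq_len(n) + (i - 1) * n
    idx_j <- seq_len(m) + (j - 1) * m
    out[idx_i, idx_j] <- out[idx_i, idx_j] + 2 * hmat * sj * dAdR
  }
  out
}

# collocation points on axisymmetric channel walls near the sphere
wall_rings <- function(spec, center_rz, cutoff, spacing_min, spacing_grow = 0.35) {
  segs <- wall_segments(spec)
  pts <- list()
  for (s in seq_len(nrow(segs))) {
    a <- c(segs$r0[s], segs$z0[s]); b <- c(segs$r1[s], segs$z1[s])
    len <- sqrt(sum((b - a)^2))
    if (len < 1e-9) next
    # adaptive meridional subdivision: step grows with distance to the sphere
    tcur <- 0; tmid <- numeric(0)
    dirv <- (b - a) / len
    while (tcur < len) {
      p <- a + tcur * dirv
      d0 <- sqrt(sum((p - center_rz)^2))
      step <- max(spacing_min, spacing_grow * d0)
      tmid <- c(tmid, if (tcur + step / 2 > len) (tcur + len) / 2 else tcur + step / 2)
      tcur <- tcur + step
    }
    rr <- a[1] + tmid * dirv[1]
    zz <- a[2] + tmid * dirv[2]
    d <- sqrt((rr - center_rz[1])^2 + (zz - center_rz[2])^2)
    keep <- d < cutoff
    if (!any(keep)) next
    rr <- rr[keep]; zz <- zz[keep]; d <- d[keep]
    ds <- pmax(spacing_min, spacing_grow * d)
    for (k in seq_along(rr)) {
      if (rr[k] < 1e-9) next
      mring <- max(6L, ceiling(2 * pi * rr[k] / ds[k]))
      th <- 2 * pi * (seq_len(mring) - 0.5) / mring
      p <- cbind(rr[k] * cos(th), rr[k] * sin(th), zz[k])
      attr(p, "eps") <- rep(0.5 * ds[k], mring)
      pts[[length(pts) + 1]] <- p
    }
  }
  if (!length(pts)) {
    out <- matrix(numeric(0), 0, 3)
    attr(out, "eps") <- numeric(0)
    out
  } else {
    out <- do.call(rbind, pts)
    eps <- unlist(lapply(pts, attr, "eps"))
    # drop near-duplicate collocation points (segment corners meet)
    keep <- rep(TRUE, nrow(out))
    if (nrow(out) > 1) {
      dmin <- 0.3 * spacing_min
      dd <- as.matrix(stats::dist(out))
      dd[upper.tri(dd, diag = TRUE)] <- Inf
      keep <- apply(dd, 1, min) > dmin
    }
    out <- out[keep, , drop = FALSE]
    attr(out, "eps") <- eps[keep]
    out
  }
}

#' LRNH diffusion tensor of a sphere at a position
#'
#' Solves the Stokes resistance problem for a rigid sphere of radius `a`
#' centered at `x` with the method of regularized Stokeslets: three solves
#' with unit boundary velocities along x, y, z give the 3x3 friction tensor
#' gamma (force per velocity), and the diffusion tensor follows from the
#' Einstein relation D = kT gamma^{-1}. Nearby channel walls are included as
#' no-slip collocation rings; a plane wall can instead be treated exactly with
#' the classical image system (`wall = "plane"`).
#'
#' @param spec A [pore_spec()], or `NULL` for an unbounded fluid.
#' @param a Sphere radius (nm).
#' @param x Position: length-2 `(r, z)` (nm, meridional plane) or length-3
#'   Cartesian.
#' @param constants [physical_constants()].
#' @param wall `"auto"` (channel walls from `spec`), `"none"`, or `"plane"`
#'   (single plane wall; give `wall_z` and `wall_side`).
#' @param wall_z Plane-wall position (nm) when `wall = "plane"`.
#' @param wall_side `+1` if the fluid is above the wall, `-1` below.
#' @param options List: `n_sphere` (surface points, default 600),
#'   `eps_factor` (regularization over point spacing, default 0.45),
#'   `cutoff` (wall inclusion radius in sphere radii, default 8),
#'   `wall_spacing` (minimum wall collocation spacing, nm).
#' @return List with `D` (3x3, m^2/s), `gamma` (3x3, kg/s), `n_points`.
#' @export
lrnh_tensor <- function(spec, a, x, constants = physical_constants(),
                        wall = "auto", wall_z = 0, wall_side = +1,
                        options = list()) {
  n_sph <- options$n_sphere %||% 600
  eps_f <- options$eps_factor %||% 0.45
  cutoff <- options$cutoff %||% 8
  if (length(x) == 2) x <- c(x[1], 0, x[2])
  center <- x
  sp <- fibonacci_sphere(n_sph) * a
  spacing <- sqrt(4 * pi * a^2 / n_sph)
  eps <- eps_f * spacing
  pts <- sweep(sp, 2, center, "+")

  use_plane <- identical(wall, "plane")
  wallpts <- matrix(numeric(0), 0, 3)
  if (identical(wall, "auto") && !is.null(spec)) {
    wd <- wall_distance(spec, data.frame(r = sqrt(x[1]^2 + x[2]^2), z = x[3]))
    if (wd$distance < a) stop("sphere intersects a wall")
    wspace <- options$wall_spacing %||% max(min(spacing, (wd$distance - a) / 2), 0.05)
    # wall coverage must scale with the confinement size, not the particle:
    # the flow disturbance in a channel decays on the scale of the local
    # wall distance, so cover several of those
    reach <- wd$distance + max(cutoff * a, 5 * wd$distance)
    wallpts <- wall_rings(spec, c(sqrt(x[1]^2 + x[2]^2), x[3]),
                          cutoff = reach, spacing_min = wspace)
  }
  if (use_plane) {
    # transform so the wall is z = 0 with fluid above
    shift <- function(p) {
      q <- p
      q[, 3] <- (p[, 3] - wall_z) * wall_side
      q
    }
    ppts <- shift(pts)
    if (min(ppts[, 3]) <= 0) stop("sphere intersects the plane wall")
    K <- stokeslet_block(ppts, ppts, eps) + blake_image_block(ppts, ppts)
  } else if (nrow(wallpts)) {
    allpts <- rbind(pts, wallpts)
    # wall blobs are sized to their local spacing so the collocated wall acts
    # as a closed surface rather than a string of isolated beads
    eps_all <- c(rep(eps, n_sph), attr(wallpts, "eps"))
    K <- stokeslet_block(allpts, allpts, eps_all)
  } else {
    K <- stokeslet_block(pts, pts, eps)
  }
  n_all <- if (use_plane || nrow(wallpts) == 0) n_sph else n_sph + nrow(wallpts)
  # rhs: unit translation on the sphere points, zero on wall points
  U <- matrix(0, 3 * n_all, 3)
  for (dir in 1:3) {
    U[seq_len(n_sph) + (dir - 1) * n_all, dir] <- 1
  }
  Fsol <- solve(K, U * (8 * pi * constants$eta))
  gamma <- matrix(0, 3, 3)
  for (dir in 1:3) {
    f <- Fsol[, dir]
    Ftot <- c(sum(f[seq_len(n_sph)]),
              sum(f[seq_len(n_sph) + n_all]),
              sum(f[seq_len(n_sph) + 2 * n_all]))
    gamma[, dir] <- Ftot
  }
  gamma <- (gamma + t(gamma)) / 2 * .nm  # units: forces per (m/s) with nm grid
  if (use_plane && wall_side < 0) {
    # mirror transform flips the z axis; gamma transforms with M = diag(1,1,-1)
    M <- diag(c(1, 1, -1))
    gamma <- M %*% gamma %*% M
  }
  D <- constants$kT * solve(gamma)
  D <- (D + t(D)) / 2
  list(D = D, gamma = gamma, n_points = n_all)
}

#' Centerline LRNH factors along a channel
#'
#' Computes relative axial and transverse diffusivities of a sphere on the
#' pore axis at `n_stations` z-stations spanning the channel plus one radius
#' of reservoir on each side. Used to normalize the combined r,z-dependent
#' diffusivity model.
#'
#' @param spec A [pore_spec()].
#' @param a Particle radius (nm).
#' @param constants [physical_constants()].
#' @param n_stations Number of z-stations.
#' @param options Passed to [lrnh_tensor()].
#' @return A tibble with columns `z`, `f_axial`, `f_transverse`.
#' @export
lrnh_centerline <- function(spec, a, constants = physical_constants(),
                            n_stations = 12, options = list()) {
  D0 <- bulk_diffusivity(constants, a)
  pad <- min(4 * a, spec$reservoir$top * 0.8)
  zs <- seq(spec$z_bot - pad, spec$z_top + pad, length.out = n_stations)
  # keep only stations where the sphere fits
  ok <- wall_distance(spec, data.frame(r = 0, z = zs))$distance > a * 1.02
  zs <- zs[ok]
  f_ax <- numeric(length(zs)); f_tr <- numeric(length(zs))
  for (k in seq_along(zs)) {
    D <- lrnh_tensor(spec, a, c(0, zs[k]), constants, options = options)$D
    f_ax[k] <- D[3, 3] / D0
    f_tr[k] <- (D[1, 1] + D[2, 2]) / 2 / D0
  }
  tibble::tibble(z = zs, f_axial = pmin(f_ax, 1), f_transverse = pmin(f_tr, 1))
}
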