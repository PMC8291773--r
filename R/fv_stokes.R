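# Staggered (MAC) finite-volume Stokes solver on the axisymmetric mesh.
# u_r lives on r-faces, u_z on z-faces, p at cell centers. Solid faces are
# no-slip (optionally a prescribed rigid-body velocity on the protein surface);
# the top/bottom reservoir boundaries are open (zero outside pressure, zero
# outside velocity gradient); the lateral boundary is free-slip with no
# penetration. The viscous operator and incompressibility constraint are
# assembled once into a saddle-point system and factorized; repeated solves
# with new body forces reuse the factorization.

assemble_stokes <- function(mesh, constants, protein_velocity = c(0, 0)) {
  nr <- mesh$nr; nz <- mesh$nz
  FL <- mesh$region == 0L
  eta <- constants$eta
  rb <- mesh$r_b * .nm; zb <- mesh$z_b * .nm
  rc <- mesh$r_c * .nm; zc <- mesh$z_c * .nm
  drv <- mesh$dr * .nm; dzv <- mesh$dz * .nm

  # unknown numbering -------------------------------------------------------
  ur_id <- matrix(0L, nr + 1, nz)      # active u_r unknowns
  for (i in 2:nr) ur_id[i, FL[i - 1, ] & FL[i, ]] <- 1L
  uz_id <- matrix(0L, nr, nz + 1)
  for (j in 2:nz) uz_id[FL[, j - 1] & FL[, j], j] <- 1L
  uz_id[FL[, 1], 1] <- 1L              # open bottom boundary faces
  uz_id[FL[, nz], nz + 1] <- 1L        # open top boundary faces
  n_ur <- sum(ur_id); n_uz <- sum(uz_id)
  ur_id[ur_id == 1L] <- seq_len(n_ur)
  uz_id[uz_id == 1L] <- n_ur + seq_len(n_uz)
  p_id <- matrix(0L, nr, nz)
  p_id[FL] <- n_ur + n_uz + seq_len(sum(FL))
  ntot <- n_ur + n_uz + sum(FL)

  # boundary values: protein surface may translate axially with speed vz
  vz_bc <- protein_velocity[2]
  prot_mask <- mesh$region == 3L
  uz_bcval <- function(i, j) {
    # value of an inactive u_z face: protein-adjacent faces move with vz
    j0 <- max(j - 1, 1); j1 <- min(j, nz)
    if (vz_bc != 0 && (prot_mask[i, j0] || prot_mask[i, j1])) vz_bc else 0
  }

  cap <- 16L * ntot + 64L
  trip_i <- integer(cap); trip_j <- integer(cap); trip_x <- numeric(cap)
  ntrip <- 0L
  rhs <- numeric(ntot)
  add <- function(row, col, val) {
    keep <- col > 0 & val != 0
    nk <- sum(keep)
    if (nk == 0L) return(invisible())
    idx <- ntrip + seq_len(nk)
    trip_i[idx] <<- row[keep]; trip_j[idx] <<- col[keep]
    trip_x[idx] <<- val[keep]
    ntrip <<- ntrip + nk
  }
  add_rhs <- function(row, val) rhs[row] <<- rhs[row] + val

  # r-momentum --------------------------------------------------------------
  for (i in 2:nr) {
    for (j in seq_len(nz)) {
      row <- ur_id[i, j]
      if (row == 0L) next
      hP <- rc[i] - rc[i - 1]
      # radial part: d/dr[(1/r) d(r u)/dr], via cell-centered divergences
      # Dc(i)   over cell i (faces i, i+1), Dc(i-1) over cell i-1
      # face i+1 term
      c_ip <- if (i + 1 <= nr + 1) ur_id[i + 1, j] else 0L
      c_im <- if (i - 1 >= 1) ur_id[i - 1, j] else 0L
      co_self <- 0
      # Dc(i) = (rb[i+1]*u(i+1) - rb[i]*u(i)) / (rc[i]*dr[i])
      # Dc(i-1) = (rb[i]*u(i) - rb[i-1]*u(i-1)) / (rc[i-1]*dr[i-1])
      # T1 = (Dc(i) - Dc(i-1)) / hP
      aDc_i_ip <- rb[i + 1] / (rc[i] * drv[i])
      aDc_i_self <- -rb[i] / (rc[i] * drv[i])
      aDc_m_self <- rb[i] / (rc[i - 1] * drv[i - 1])
      aDc_m_im <- if (i - 1 >= 2) -rb[i - 1] / (rc[i - 1] * drv[i - 1]) else 0
      add(row, c_ip, eta * aDc_i_ip / hP)
      co_self <- co_self + eta * (aDc_i_self - aDc_m_self) / hP
      add(row, c_im, eta * (-aDc_m_im) / hP)
      # u(i+1)/u(i-1) faces that are inactive are walls (u = 0): no rhs term
      # axial second derivative
      hN <- if (j < nz) zc[j + 1] - zc[j] else NA
      hS <- if (j > 1) zc[j] - zc[j - 1] else NA
      hc <- dzv[j]
      if (j < nz) {
        cN <- ur_id[i, j + 1]
        add(row, cN, eta / (hN * hc))
        co_self <- co_self - eta / (hN * hc)
      }
      if (j > 1) {
        cS <- ur_id[i, j - 1]
        add(row, cS, eta / (hS * hc))
        co_self <- co_self - eta / (hS * hc)
      }
      add(row, row, co_self)
      # pressure gradient
      pP <- p_id[i - 1, j]; pN <- p_id[i, j]
      add(row, pN, -1 / hP)
      add(row, pP, 1 / hP)
    }
  }

  # z-momentum --------------------------------------------------------------
  for (j in seq_len(nz + 1)) {
    for (i in seq_len(nr)) {
      row <- uz_id[i, j]
      if (row == 0L) next
      boundary_bot <- j == 1
      boundary_top <- j == nz + 1
      co_self <- 0
      # radial Laplacian (1/r) d/dr (r du/dr)
      if (i < nr) {
        hE <- rc[i + 1] - rc[i]
        cE <- uz_id[i + 1, j]
        g <- eta * rb[i + 1] / (rc[i] * drv[i] * hE)
        add(row, cE, g)
        co_self <- co_self - g
        if (cE == 0L) add_rhs(row, -g * uz_bcval(i + 1, j))
      } # i == nr: free-slip outer boundary, drop flux
      if (i > 1) {
        hW <- rc[i] - rc[i - 1]
        cW <- uz_id[i - 1, j]
        g <- eta * rb[i] / (rc[i] * drv[i] * hW)
        add(row, cW, g)
        co_self <- co_self - g
        if (cW == 0L) add_rhs(row, -g * uz_bcval(i - 1, j))
      } # i == 1: axis, rb = 0, flux vanishes
      # axial second derivative
      if (!boundary_bot && !boundary_top) {
        hc <- (dzv[j - 1] + dzv[j]) / 2
        cN <- uz_id[i, j + 1]
        gN <- eta / (dzv[j] * hc)
        add(row, cN, gN); co_self <- co_self - gN
        if (cN == 0L) add_rhs(row, -gN * uz_bcval(i, j + 1))
        cS <- uz_id[i, j - 1]
        gS <- eta / (dzv[j - 1] * hc)
        add(row, cS, gS); co_self <- co_self - gS
        if (cS == 0L) add_rhs(row, -gS * uz_bcval(i, j - 1))
        pS <- p_id[i, j - 1]; pN <- p_id[i, j]
        hP <- zc[j] - zc[j - 1]
        add(row, pN, -1 / hP); add(row, pS, 1 / hP)
      } else if (boundary_bot) {
        hc <- dzv[1]
        cN <- uz_id[i, 2]
        gN <- eta / (dzv[1] * hc)
        add(row, cN, gN); co_self <- co_self - gN
        if (cN == 0L) add_rhs(row, -gN * uz_bcval(i, 2))
        # outside: zero velocity gradient, outside pressure 0
        pN <- p_id[i, 1]
        add(row, pN, -1 / hc)  # -(p_in - 0)/h
      } else {
        hc <- dzv[nz]
        cS <- uz_id[i, nz]
        gS <- eta / (dzv[nz] * hc)
        add(row, cS, gS); co_self <- co_self - gS
        if (cS == 0L) add_rhs(row, -gS * uz_bcval(i, nz))
        pS <- p_id[i, nz]
        add(row, pS, 1 / hc)   # -(0 - p_in)/h
      }
      add(row, row, co_self)
    }
  }

  # continuity ---------------------------------------------------------------
  for (j in seq_len(nz)) {
    for (i in seq_len(nr)) {
      row <- p_id[i, j]
      if (row == 0L) next
      V <- mesh$V[i, j] * .nm^3
      aW <- mesh$A_r[i, j] * .nm^2;  aE <- mesh$A_r[i + 1, j] * .nm^2
      aS <- mesh$A_z[i, j] * .nm^2;  aN <- mesh$A_z[i, j + 1] * .nm^2
      cE <- ur_id[i + 1, j]; cW <- ur_id[i, j]
      cN <- uz_id[i, j + 1]; cS <- uz_id[i, j]
      add(row, cE, aE / V); add(row, cW, -aW / V)
      add(row, cN, aN / V); add(row, cS, -aS / V)
      if (cN == 0L) add_rhs(row, -aN / V * uz_bcval(i, j + 1))
      if (cS == 0L) add_rhs(row, aS / V * uz_bcval(i, j))
    }
  }

  trip_i <- trip_i[seq_len(ntrip)]; trip_j <- trip_j[seq_len(ntrip)]
  trip_x <- trip_x[seq_len(ntrip)]
  M <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                            dims = c(ntot, ntot))
  # fluid cells isolated by staircase slivers have empty continuity rows and
  # an undetermined pressure: pin them
  pin_scale <- max(abs(trip_x))   # keep pinned rows on the matrix scale
  empty <- which(Matrix::diag(M) == 0 & Matrix::rowSums(abs(M)) == 0)
  if (length(empty)) {
    M <- M + Matrix::sparseMatrix(i = empty, j = empty,
                                  x = rep(pin_scale, length(empty)),
                                  dims = dim(M))
    rhs[empty] <- 0
  }
  # fluid components with no open boundary face (enclosed pockets, or the
  # whole domain when it is closed) have pressure defined only up to a
  # constant: pin one pressure unknown per such component
  comp <- matrix(0L, nr, nz)
  ncomp <- 0L
  for (j0 in seq_len(nz)) for (i0 in seq_len(nr)) {
    if (!FL[i0, j0] || comp[i0, j0] > 0L) next
    ncomp <- ncomp + 1L
    stack_i <- integer(nr * nz); stack_j <- integer(nr * nz)
    top <- 1L; stack_i[1] <- i0; stack_j[1] <- j0
    comp[i0, j0] <- ncomp
    while (top > 0L) {
      ci <- stack_i[top]; cj <- stack_j[top]; top <- top - 1L
      push <- function(pi, pj) {
        if (FL[pi, pj] && comp[pi, pj] == 0L) {
          comp[pi, pj] <<- ncomp
          top <<- top + 1L
          stack_i[top] <<- pi; stack_j[top] <<- pj
        }
      }
      if (ci > 1 && ur_id[ci, cj] > 0) push(ci - 1L, cj)
      if (ci < nr && ur_id[ci + 1, cj] > 0) push(ci + 1L, cj)
      if (cj > 1 && uz_id[ci, cj] > 0) push(ci, cj - 1L)
      if (cj < nz && uz_id[ci, cj + 1] > 0) push(ci, cj + 1L)
    }
  }
  open_comp <- unique(c(comp[, 1][uz_id[, 1] > 0], comp[, nz][uz_id[, nz + 1] > 0]))
  for (k in seq_len(ncomp)) {
    if (k %in% open_comp) next
    cells <- which(comp == k)
    prow <- p_id[cells[1]]
    M[prow, ] <- 0
    M[prow, prow] <- pin_scale
    rhs[prow] <- 0
  }
  # row equilibration: momentum rows are O(eta/d^2) ~ 1e17 while continuity
  # rows are O(1/d) ~ 1e10; scale every row to unit max magnitude so the
  # factorization is well conditioned
  rmax <- Matrix::rowSums(abs(M))
  rmax[rmax == 0] <- 1
  Ms <- Matrix::Diagonal(ntot, 1 / rmax) %*% M
  list(M = Ms, rhs_bc = rhs / rmax, row_scale = rmax,
       ur_id = ur_id, uz_id = uz_id, p_id = p_id,
       ntot = ntot, n_ur = n_ur, n_uz = n_uz, vz_bc = vz_bc)
}

# Solve the Stokes system for a given body force (f_r, f_z at faces, N/m^3).
# `sys` from assemble_stokes (with factor cached on first use).
solve_stokes_system <- function(sys, f_r = NULL, f_z = NULL) {
  rhs <- sys$rhs_bc
  if (!is.null(f_r)) {
    act <- sys$ur_id > 0
    rows <- sys$ur_id[act]
    rhs[rows] <- rhs[rows] - f_r[act] / sys$row_scale[rows]
  }
  if (!is.null(f_z)) {
    act <- sys$uz_id > 0
    rows <- sys$uz_id[act]
    rhs[rows] <- rhs[rows] - f_z[act] / sys$row_scale[rows]
  }
  if (is.null(sys$factor)) sys$factor <- Matrix::lu(sys$M)
  x <- as.numeric(Matrix::solve(sys$factor, rhs))
  nrw <- nrow(sys$ur_id); nzw <- ncol(sys$ur_id)
  u_r <- matrix(0, nrw, nzw)
  u_r[sys$ur_id > 0] <- x[sys$ur_id[sys$ur_id > 0]]
  u_z <- matrix(0, nrow(sys$uz_id), ncol(sys$uz_id))
  u_z[sys$uz_id > 0] <- x[sys$uz_id[sys$uz_id > 0]]
  # inactive protein faces carry the boundary velocity for post-processing
  p <- matrix(0, nrow(sys$p_id), ncol(sys$p_id))
  p[sys$p_id > 0] <- x[sys$p_id[sys$p_id > 0]]
  list(u_r = u_r, u_z = u_z, p = p, sys = sys)
}

# Axial hydrodynamic force on the protein by momentum balance over a control
# box of grid faces enclosing it: F_z = surface integral of the stress plus
# the body-force integral inside the box (minus the protein volume).
stokes_force_z <- function(mesh, constants, u_r, u_z, p, f_z_cells = NULL,
                           box = NULL) {
  stopifnot(!is.null(mesh$protein))
  eta <- constants$eta
  a <- mesh$protein$radius; zc0 <- mesh$protein$center[2]
  rb <- mesh$r_b; zb <- mesh$z_b
  if (is.null(box)) {
    gap <- profile_radius(mesh$spec, zc0) - a
    r_target <- a + max(min(gap / 2, 1), gap * 0.4)
    i_box <- which.min(abs(rb - min(r_target, max(rb) * 0.9)))
    below <- which(zb <= zc0 - a - min(1, a / 2))
    above <- which(zb >= zc0 + a + min(1, a / 2))
    j_lo <- if (length(below)) max(below) else 2L
    j_hi <- if (length(above)) min(above) else length(zb) - 1L
  } else {
    i_box <- box$i; j_lo <- box$j_lo; j_hi <- box$j_hi
  }
  i_box <- max(i_box, 2L)
  nm <- .nm
  Fz <- 0
  # top and bottom disks: sigma_zz = -p + 2 eta du_z/dz
  for (jj in c(j_hi, j_lo)) {
    sgn <- if (jj == j_hi) 1 else -1
    for (i in seq_len(i_box - 1)) {
      A <- mesh$A_z[i, jj] * nm^2
      # du_z/dz centered at the face from the two neighbouring faces
      jm <- max(jj - 1, 1); jp <- min(jj + 1, ncol(u_z))
      dz_gap <- (mesh$z_b[jp] - mesh$z_b[jm]) * nm
      duz <- if (dz_gap > 0) (u_z[i, jp] - u_z[i, jm]) / dz_gap else 0
      pf <- mean(c(p[i, min(jj, ncol(p))], p[i, max(jj - 1, 1)]))
      Fz <- Fz + sgn * A * (-pf + 2 * eta * duz)
    }
  }
  # side cylinder at r = rb[i_box]: sigma_rz = eta (du_r/dz + du_z/dr)
  for (j in j_lo:(j_hi - 1)) {
    A <- mesh$A_r[i_box, j] * nm^2
    duzdr <- (u_z[i_box, j] - u_z[i_box - 1, j] +
                u_z[i_box, j + 1] - u_z[i_box - 1, j + 1]) / 2 /
      ((mesh$r_c[i_box] - mesh$r_c[i_box - 1]) * nm)
    jm <- max(j - 1, 1); jp <- min(j + 1, ncol(u_r))
    dz_gap <- (mesh$z_c[jp] - mesh$z_c[jm]) * nm
    durdz <- if (dz_gap > 0) (u_r[i_box, jp] - u_r[i_box, jm]) / dz_gap else 0
    Fz <- Fz + A * eta * (durdz + duzdr)
  }
  # body force inside the box (fluid cells only)
  if (!is.null(f_z_cells)) {
    for (j in j_lo:(j_hi - 1)) {
      for (i in seq_len(i_box - 1)) {
        if (mesh$region[i, j] == 0L)
          Fz <- Fz + f_z_cells[i, j] * mesh$V[i, j] * nm^3
      }
    }
  }
  Fz
}
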