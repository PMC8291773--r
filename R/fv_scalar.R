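# Finite-volume operators for the scalar fields (electric potential and ion
# concentrations) on the structured axisymmetric mesh. All assembly is in SI
# units; mesh coordinates are nm and converted here.

# Bernoulli function B(x) = x / (exp(x) - 1), numerically safe
bernoulli_fn <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-10
  out[small] <- 1 - x[small] / 2
  big <- x > 500
  out[big] <- 0
  neg_big <- x < -500
  out[neg_big] <- -x[neg_big]
  rest <- !small & !big & !neg_big
  out[rest] <- x[rest] / expm1(x[rest])
  out
}

# cell permittivities from region codes
cell_permittivity <- function(mesh, constants) {
  mats <- c("water", mesh$spec$wall$material,
            if (!is.null(mesh$spec$membrane)) mesh$spec$membrane$material else "lipid",
            "protein")
  eps_r <- constants$eps_r[mats]
  matrix(constants$eps0 * eps_r[mesh$region + 1L], mesh$nr, mesh$nz)
}

# Poisson operator over ALL cells (dielectric solids included).
# Returns triplets for the permittivity Laplacian, the Dirichlet boundary
# augmentation, and the fixed part of the right-hand side (surface and protein
# charges). Ionic space charge is added per Gummel iteration.
assemble_poisson <- function(mesh, constants, phi_top, phi_bot) {
  nr <- mesh$nr; nz <- mesh$nz
  eps <- cell_permittivity(mesh, constants)
  id <- matrix(seq_len(nr * nz), nr, nz)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  diag_acc <- numeric(nr * nz)
  add_pair <- function(P, N, g) {
    ii <<- c(ii, P, N, P, N); jj <<- c(jj, P, N, N, P)
    xx <<- c(xx, g, g, -g, -g)
  }
  # r-faces
  for (i in 2:nr) {
    P <- id[i - 1, ]; N <- id[i, ]
    dP <- (mesh$r_b[i] - mesh$r_c[i - 1]) * .nm
    dN <- (mesh$r_c[i] - mesh$r_b[i]) * .nm
    eps_f <- (dP + dN) / (dP / eps[i - 1, ] + dN / eps[i, ])
    g <- eps_f * mesh$A_r[i, ] * .nm^2 / (dP + dN)
    add_pair(P, N, g)
  }
  # z-faces
  for (j in 2:nz) {
    P <- id[, j - 1]; N <- id[, j]
    dP <- (mesh$z_b[j] - mesh$z_c[j - 1]) * .nm
    dN <- (mesh$z_c[j] - mesh$z_b[j]) * .nm
    eps_f <- (dP + dN) / (dP / eps[, j - 1] + dN / eps[, j])
    g <- eps_f * mesh$A_z[, j] * .nm^2 / (dP + dN)
    add_pair(P, N, g)
  }
  # Dirichlet ghosts top/bottom
  rhs0 <- numeric(nr * nz)
  gb <- eps[, 1] * mesh$A_z[, 1] * .nm^2 / (mesh$dz[1] / 2 * .nm)
  ii <- c(ii, id[, 1]); jj <- c(jj, id[, 1]); xx <- c(xx, gb)
  rhs0[id[, 1]] <- rhs0[id[, 1]] + gb * phi_bot
  gt <- eps[, nz] * mesh$A_z[, nz + 1] * .nm^2 / (mesh$dz[nz] / 2 * .nm)
  ii <- c(ii, id[, nz]); jj <- c(jj, id[, nz]); xx <- c(xx, gt)
  rhs0[id[, nz]] <- rhs0[id[, nz]] + gt * phi_top

  # surface charges (C/m^2), area-corrected, split between adjacent cells
  sc <- mesh$surface
  if (nrow(sc)) {
    for (k in seq_len(nrow(sc))) {
      if (sc$type[k] == "r") {
        cells <- c(id[sc$i[k] - 1, sc$j[k]], id[sc$i[k], sc$j[k]])
        A <- mesh$A_r[sc$i[k], sc$j[k]]
      } else {
        cells <- c(id[sc$i[k], sc$j[k] - 1], id[sc$i[k], sc$j[k]])
        A <- mesh$A_z[sc$i[k], sc$j[k]]
      }
      qs <- sc$sigma[k] * sc$area_scale[k] * A * .nm^2
      rhs0[cells] <- rhs0[cells] + qs / 2
    }
  }
  # protein volume charge, normalised to the exact net charge
  if (!is.null(mesh$protein) && !is.null(mesh$protein$charge) &&
      mesh$protein$charge != 0) {
    pc <- which(mesh$region == 3L)
    if (length(pc)) {
      Vp <- mesh$V[pc] * .nm^3
      rhs0[pc] <- rhs0[pc] + mesh$protein$charge * constants$q * Vp / sum(Vp)
    }
  }
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nr * nz, nr * nz))
  list(M = M, rhs0 = rhs0, eps = eps)
}

# Nernst-Planck assembly for one ion species with Scharfetter-Gummel fluxes.
# sgn = +1 (cation) or -1 (anion). D is a list with matrices D_rr, D_zz
# (m^2/s at cell centers). phi in V; u_r, u_z MAC velocities in m/s.
# Returns the sparse matrix and rhs for the steady-state conservation system
# over fluid cells (Dirichlet c_bulk at top/bottom reservoir boundaries).
assemble_np <- function(mesh, constants, sgn, D, phi, u_r, u_z, c_bulk_si,
                        phi_top, phi_bot) {
  nr <- mesh$nr; nz <- mesh$nz
  FL <- mesh$region == 0L
  id <- matrix(NA_integer_, nr, nz)
  id[FL] <- seq_len(sum(FL))
  nun <- sum(FL)
  qkT <- constants$q / constants$kT
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  rhs <- numeric(nun)

  face_terms <- function(P, N, A_open, D_f, d, dphi, uf) {
    # flux P->N = aP*cP - aN*cN
    w <- sgn * qkT * D_f * (-dphi) / d + uf   # dphi = phi_N - phi_P
    Pe <- w * d / D_f
    g <- A_open * D_f / d
    list(aP = g * bernoulli_fn(-Pe), aN = g * bernoulli_fn(Pe))
  }

  for (i in 2:nr) {
    ok <- FL[i - 1, ] & FL[i, ] & mesh$open_r[i, ] > 0
    if (!any(ok)) next
    j <- which(ok)
    P <- id[i - 1, j]; N <- id[i, j]
    d <- (mesh$r_c[i] - mesh$r_c[i - 1]) * .nm
    D_f <- 2 / (1 / D$D_rr[i - 1, j] + 1 / D$D_rr[i, j])
    A_open <- mesh$A_r[i, j] * mesh$open_r[i, j] * .nm^2
    ft <- face_terms(P, N, A_open, D_f, d, phi[i, j] - phi[i - 1, j], u_r[i, j])
    ii <- c(ii, P, P, N, N); jj <- c(jj, P, N, P, N)
    xx <- c(xx, ft$aP, -ft$aN, -ft$aP, ft$aN)
  }
  for (j in 2:nz) {
    ok <- FL[, j - 1] & FL[, j] & mesh$open_z[, j] > 0
    if (!any(ok)) next
    i <- which(ok)
    P <- id[i, j - 1]; N <- id[i, j]
    d <- (mesh$z_c[j] - mesh$z_c[j - 1]) * .nm
    D_f <- 2 / (1 / D$D_zz[i, j - 1] + 1 / D$D_zz[i, j])
    A_open <- mesh$A_z[i, j] * mesh$open_z[i, j] * .nm^2
    ft <- face_terms(P, N, A_open, D_f, d, phi[i, j] - phi[i, j - 1], u_z[i, j])
    ii <- c(ii, P, P, N, N); jj <- c(jj, P, N, P, N)
    xx <- c(xx, ft$aP, -ft$aN, -ft$aP, ft$aN)
  }
  # Dirichlet reservoirs: bottom (j = 1) and top (j = nz)
  for (side in c("bot", "top")) {
    j <- if (side == "bot") 1L else nz
    jm <- if (side == "bot") 1L else nz + 1L
    phb <- if (side == "bot") phi_bot else phi_top
    i <- which(FL[, j])
    if (!length(i)) next
    P <- id[i, j]
    d <- mesh$dz[j] / 2 * .nm
    D_f <- D$D_zz[i, j]
    A_open <- mesh$A_z[i, jm] * .nm^2
    # ghost outside: dphi measured P -> ghost
    dphi <- phb - phi[i, j]
    uf <- u_z[i, jm] * (if (side == "bot") -1 else 1)  # outward component
    ft <- face_terms(P, NA, A_open, D_f, d, dphi, uf)
    ii <- c(ii, P); jj <- c(jj, P); xx <- c(xx, ft$aP)
    rhs[P] <- rhs[P] + ft$aN * c_bulk_si
  }
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nun, nun))
  # staircase slivers can isolate a fluid cell from all neighbours; pin such
  # cells to the bulk concentration so the system stays nonsingular
  iso <- which(Matrix::diag(M) == 0)
  if (length(iso)) {
    M <- M + Matrix::sparseMatrix(i = iso, j = iso, x = rep(1, length(iso)),
                                  dims = dim(M))
    rhs[iso] <- c_bulk_si
  }
  list(M = M, rhs = rhs, id = id)
}

# z-directed molar fluxes (mol/s, positive up) of one species through the row
# of z-faces at break index jf, recomputed with the same SG scheme used in the
# solve so that the current integral is discretely conservative.
np_face_flux_z <- function(mesh, constants, sgn, D, phi, u_z, conc, jf,
                           c_bulk_si, phi_top, phi_bot) {
  nr <- mesh$nr; nz <- mesh$nz
  FL <- mesh$region == 0L
  qkT <- constants$q / constants$kT
  flux <- numeric(nr)
  for (i in seq_len(nr)) {
    if (jf >= 2 && jf <= nz) {
      if (!(FL[i, jf - 1] && FL[i, jf]) || mesh$open_z[i, jf] == 0) next
      d <- (mesh$z_c[jf] - mesh$z_c[jf - 1]) * .nm
      D_f <- 2 / (1 / D$D_zz[i, jf - 1] + 1 / D$D_zz[i, jf])
      A_open <- mesh$A_z[i, jf] * mesh$open_z[i, jf] * .nm^2
      dphi <- phi[i, jf] - phi[i, jf - 1]
      w <- sgn * qkT * D_f * (-dphi) / d + u_z[i, jf]
      Pe <- w * d / D_f
      g <- A_open * D_f / d
      flux[i] <- g * (bernoulli_fn(-Pe) * conc[i, jf - 1] -
                        bernoulli_fn(Pe) * conc[i, jf])
    } else if (jf == 1 && FL[i, 1]) {
      d <- mesh$dz[1] / 2 * .nm
      D_f <- D$D_zz[i, 1]
      A_open <- mesh$A_z[i, 1] * .nm^2
      dphi <- phi[i, 1] - phi_bot
      w <- sgn * qkT * D_f * (-dphi) / d + u_z[i, 1]
      Pe <- w * d / D_f
      g <- A_open * D_f / d
      flux[i] <- g * (bernoulli_fn(-Pe) * c_bulk_si - bernoulli_fn(Pe) * conc[i, 1])
    } else if (jf == nz + 1 && FL[i, nz]) {
      d <- mesh$dz[nz] / 2 * .nm
      D_f <- D$D_zz[i, nz]
      A_open <- mesh$A_z[i, nz + 1] * .nm^2
      dphi <- phi_top - phi[i, nz]
      w <- sgn * qkT * D_f * (-dphi) / d + u_z[i, nz + 1]
      Pe <- w * d / D_f
      g <- A_open * D_f / d
      flux[i] <- g * (bernoulli_fn(-Pe) * conc[i, nz] - bernoulli_fn(Pe) * c_bulk_si)
    }
  }
  flux
}
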