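co <- physical_constants()

test_that("zero voltage gives a quiescent, electroneutral solution", {
  fx <- make_fixture("toy_cylinder")
  m <- pore_mesh(fx$spec, list(fine = 0.5, coarse = 2.5))
  s0 <- solve_pnps(m, co, NULL, 0, 1, solver_options(max_iter = 8))
  expect_equal(compute_current(s0), 0, tolerance = 1e-18)
  expect_equal(max(abs(s0$u_z)), 0, tolerance = 1e-20)
  fl <- m$region == 0L
  expect_equal(max(abs(s0$c_plus[fl] - 1000)), 0, tolerance = 1e-6)
})

test_that("toy-cylinder conductance matches the Ohmic + access-resistance oracle", {
  fx <- make_fixture("toy_cylinder")
  s1 <- toy_solution(100)
  J <- compute_current(s1)
  expect_rel(J, fx$conductance_oracle(co), 0.05)
})

test_that("current is conserved across cross-sections", {
  s1 <- toy_solution(100)
  J_ref <- compute_current(s1, -10)
  for (zc in c(-18, -2, 8, 20)) {
    expect_rel(compute_current(s1, zc), J_ref, 0.01)
  }
  expect_error(compute_current(s1, 1e4), "outside")
})

test_that("reversing the voltage flips the current", {
  s1 <- toy_solution(100)
  s2 <- toy_solution(-100)
  expect_rel(compute_current(s2), -compute_current(s1), 0.01)
})

test_that("concentrations stay nonnegative with charged walls", {
  spec <- pore_spec("charged_cyl",
                    profile = data.frame(z = c(-20, 0), r = c(5, 5)),
                    channel_length = 20,
                    wall = list(thickness = 1e4, charge = -0.5, material = "sin"),
                    membrane = NULL,
                    reservoir = list(top = 15, bottom = 15, radius = 20))
  m <- pore_mesh(spec, list(fine = 0.4, coarse = 2))
  s <- solve_pnps(m, co, NULL, 100, 0.2, solver_options(tol = 1e-5, max_iter = 50))
  fl <- m$region == 0L
  expect_true(all(s$c_plus[fl] >= 0))
  expect_true(all(s$c_minus[fl] >= 0))
  # counterions are enriched over coions near a negative wall
  iw <- max(which(m$r_c < 5))
  jm <- which.min(abs(m$z_c + 10))
  expect_gt(s$c_plus[iw, jm], s$c_minus[iw, jm])
})

test_that("forces vanish for an uncharged protein in an unbiased pore", {
  m <- protein_box_mesh()
  s <- solve_pnps(m, co, NULL, 0, 1, solver_options(max_iter = 6))
  Fc <- compute_force(s)
  expect_equal(Fc$F_el[3], 0, tolerance = 1e-25)
  expect_lt(abs(Fc$F_drag[3]), 1e-18)
})

test_that("electric force approaches QE in the weak-screening limit", {
  spec <- pore_spec("lowsalt_box",
                    profile = data.frame(z = c(-40, 0), r = c(15, 15)),
                    channel_length = 40,
                    wall = list(thickness = 1e4, charge = 0, material = "sin"),
                    membrane = NULL,
                    reservoir = list(top = 2, bottom = 2, radius = 16))
  m <- pore_mesh(spec, list(fine = 1, coarse = 2, gap = 0.3),
                 protein = list(center = c(0, -20), radius = 2, charge = 10))
  # 1e-5 M: Debye length ~ 100 nm >> domain, screening negligible
  s <- solve_pnps(m, co, NULL, 100, 1e-5, solver_options(tol = 1e-5, max_iter = 30))
  Fc <- compute_force(s)
  # oracle: the volume-charge force samples the macroscopic field inside the
  # low-permittivity sphere, which in a uniform external field E0 is
  # 3 eps_w/(2 eps_w + eps_p) E0 (dielectric cavity factor), so
  # F_el = Q E0 * 3 eps_w/(2 eps_w + eps_p)
  m0 <- pore_mesh(spec, list(fine = 1, coarse = 2))
  s0 <- solve_pnps(m0, co, NULL, 100, 1e-5, solver_options(tol = 1e-5, max_iter = 20))
  j0 <- which.min(abs(m0$z_c + 20))
  E_z <- -(s0$phi[1, j0 + 2] - s0$phi[1, j0 - 2]) /
    ((m0$z_c[j0 + 2] - m0$z_c[j0 - 2]) * 1e-9)
  cavity <- 3 * co$eps_r[["water"]] / (2 * co$eps_r[["water"]] + co$eps_r[["protein"]])
  expect_rel(Fc$F_el[3], 10 * co$q * E_z * cavity, 0.2)
  expect_gt(Fc$F_el[3] * E_z, 0)   # force along the field for positive charge
})
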