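co <- physical_constants()

test_that("image system cancels the velocity on the wall plane", {
  set.seed(1)
  y <- cbind(runif(3, -1, 1), runif(3, -1, 1), runif(3, 0.5, 2))
  xw <- cbind(runif(6, -4, 4), runif(6, -4, 4), 0)
  K <- poresim:::stokeslet_block(xw, y, 1e-8) + poresim:::blake_image_block(xw, y)
  expect_lt(max(abs(K)), 1e-10)
})

test_that("free-sphere friction recovers Stokes' law", {
  res <- lrnh_tensor(NULL, 1, c(0, 0, 0), co, wall = "none",
                     options = list(n_sphere = 600))
  exact <- 6 * pi * co$eta * 1e-9
  expect_rel(res$gamma[1, 1], exact, 0.02)
  expect_rel(res$gamma[3, 3], exact, 0.02)
  expect_lt(max(abs(res$gamma[row(res$gamma) != col(res$gamma)])), exact * 1e-4)
  # Einstein relation closes the loop
  expect_rel(res$D[1, 1], co$kT / exact, 0.02)
})

test_that("plane-wall numerical factors match the closed forms within 5%", {
  fx <- make_fixture("plane_wall")
  a <- 1
  D0 <- bulk_diffusivity(co, a)
  for (hr in fx$h_over_a) {
    res <- lrnh_tensor(NULL, a, c(0, 0, hr * a), co, wall = "plane",
                       wall_z = 0, wall_side = +1,
                       options = list(n_sphere = 700))
    pw <- plane_wall_factors(a, hr * a)
    f_par_num <- res$D[1, 1] / D0
    f_perp_num <- res$D[3, 3] / D0
    expect_rel(f_par_num, pw$f_parallel, 0.05)
    expect_rel(f_perp_num, pw$f_perpendicular, 0.05)
    # perpendicular motion is always hindered more strongly
    expect_lt(f_perp_num, f_par_num)
  }
})

test_that("channel confinement matches the axial cylinder series for small spheres", {
  dna <- build_preset("dna_origami")
  R <- max(dna$profile$r)
  res <- lrnh_tensor(dna, 0.11, c(0, -23), co, options = list(n_sphere = 400))
  D0 <- bulk_diffusivity(co, 0.11)
  lam <- 0.11 / R
  bohlin <- 1 - 2.10444 * lam + 2.08877 * lam^3   # infinite-cylinder series
  expect_rel(res$D[3, 3] / D0, bohlin, 0.03)
  # transverse hindered at least as strongly as axial
  expect_lte((res$D[1, 1] + res$D[2, 2]) / 2, res$D[3, 3] * 1.02)
})

test_that("FV Stokes drag agrees with the Stokeslet route", {
  m <- protein_box_mesh()
  st <- solve_stokes(m, co, velocity = 1)
  exact <- -6 * pi * co$eta * 2e-9
  # staircase FV drag converges from below; tolerance documented in vignette
  expect_gt(st$F_drag / exact, 0.75)
  expect_lt(st$F_drag / exact, 1.1)
  # v = 0 gives a quiescent fluid
  st0 <- solve_stokes(m, co, velocity = 0)
  expect_equal(max(abs(st0$u_z)), 0, tolerance = 1e-20)
})
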