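co <- physical_constants()

test_that("bulk diffusivity follows Stokes-Einstein", {
  # kT/(6 pi eta a) at 293 K for the 0.11 nm hydrodynamic ion radius
  expect_rel(bulk_diffusivity(co, 0.11), 1.9509e-9, 1e-4)
  # doubling the radius halves D0
  expect_rel(bulk_diffusivity(co, 0.22), bulk_diffusivity(co, 0.11) / 2, 1e-12)
  # trypsin-sized sphere
  expect_rel(bulk_diffusivity(co, 2.078),
             co$kT / (6 * pi * co$eta * 2.078e-9), 1e-12)
  expect_error(bulk_diffusivity(co, -1), "positive")
})

test_that("plane-wall factors have the right limits and ordering", {
  pw <- plane_wall_factors(1, 1e6)
  expect_equal(pw$f_parallel, 1, tolerance = 1e-5)
  expect_equal(pw$f_perpendicular, 1, tolerance = 1e-5)

  h <- seq(1.01, 10, length.out = 200)
  pw <- plane_wall_factors(1, h)
  expect_true(all(pw$f_perpendicular < pw$f_parallel))
  expect_true(all(diff(pw$f_parallel) >= 0))
  expect_true(all(diff(pw$f_perpendicular) >= 0))
  expect_true(all(pw$f_parallel > 0 & pw$f_parallel <= 1))
})

test_that("diffusivity field models obey their defining relations", {
  dna <- build_preset("dna_origami")
  # reuse one centerline table across models
  cl <- cached("cl_ion_dna", function() {
    lrnh_centerline(dna, 0.11, co, n_stations = 5,
                    options = list(n_sphere = 200))
  })
  f_r <- diffusivity_field(dna, 0.11, "r_dependent", co)
  f_z <- diffusivity_field(dna, 0.11, "z_dependent", co, centerline = cl)
  f_c <- diffusivity_field(dna, 0.11, "combined_rz", co, centerline = cl)
  f_b <- diffusivity_field(dna, 0.11, "bulk_constant", co)

  zs <- seq(-40, -6, length.out = 9)
  # combined equals z-dependent on the centerline by construction
  ec <- field_eval(f_c, rep(0, 9), zs)
  ez <- field_eval(f_z, rep(0, 9), zs)
  expect_equal(ec$D_zz, ez$D_zz, tolerance = 1e-6)
  # r-only model overestimates: combined <= r_dependent inside the channel
  set.seed(3)
  rr <- runif(60, 0, 3.3); zz <- runif(60, -44, -2)
  er <- field_eval(f_r, rr, zz)
  ec2 <- field_eval(f_c, rr, zz)
  expect_true(all(ec2$D_zz <= er$D_zz * (1 + 1e-9)))
  expect_true(all(ec2$D_rr <= er$D_rr * (1 + 1e-9)))
  # bulk model is D0 everywhere
  eb <- field_eval(f_b, rr, zz)
  expect_true(all(eb$D_zz == f_b$D0))
})

test_that("tensors are symmetric positive semidefinite and reach D0 far away", {
  dna <- build_preset("dna_origami")
  f_r <- diffusivity_field(dna, 0.11, "r_dependent", co)
  set.seed(4)
  for (k in 1:50) {
    x <- c(runif(1, -3, 3), runif(1, -3, 3), runif(1, -50, 5))
    if (wall_distance(dna, data.frame(r = sqrt(x[1]^2 + x[2]^2), z = x[3]))$distance <= 0)
      next
    D <- field_tensor(f_r, x)
    expect_equal(D, t(D), tolerance = 1e-12)
    expect_true(all(eigen(D, only.values = TRUE)$values > -1e-20))
    expect_true(max(eigen(D, only.values = TRUE)$values) <= f_r$D0 * (1 + 1e-9))
  }
  # reservoir point far from any wall (> 20 radii)
  far <- field_tensor(f_r, c(0, 0, 10))
  expect_rel(far[1, 1], f_r$D0, 0.05)
})

test_that("channel averaging weights D_zz/D0 correctly", {
  fx <- make_fixture("toy_cylinder")
  m <- pore_mesh(fx$spec, list(fine = 0.5, coarse = 2.5))
  f_b <- diffusivity_field(fx$spec, 0.11, "bulk_constant", co)
  expect_equal(channel_average(f_b, m), 1.0, tolerance = 1e-12)
  f_r <- diffusivity_field(fx$spec, 0.11, "r_dependent", co)
  avg <- channel_average(f_r, m)
  expect_true(avg > 0 && avg < 1)
  # weight concentrated at the wall pulls the average toward the wall factor
  w <- matrix(0, m$nr, m$nz)
  iw <- max(which(m$r_c < 5))
  w[iw, m$z_c[1:m$nz] > -20 & m$z_c[1:m$nz] < 0] <- 1
  w <- matrix(w[, seq_len(m$nz)], m$nr, m$nz)
  avg_wall <- channel_average(f_r, m, weight = w)
  expect_lt(avg_wall, avg)
  expect_error(channel_average(f_r, m, weight = matrix(0, m$nr, m$nz)),
               "zero total weight")
})
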