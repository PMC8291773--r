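test_that("presets carry the published pore parameters", {
  dna <- build_preset("dna_origami")
  expect_equal(dna$channel_length, 46)
  expect_equal(dna$wall$thickness, 6)
  expect_equal(dna$cross_section$width, 6)
  expect_equal(dna$wall$charge, -0.74)
  expect_equal(dna$membrane$material, "lipid")
  # box reservoir 20 x 20 mapped to the equal-area cylinder
  expect_equal(dna$reservoir$radius, 20 / sqrt(pi), tolerance = 1e-12)

  ss <- build_preset("solid_state")
  expect_equal(min(ss$profile$r), 10)            # 20 nm tip diameter
  slope <- diff(ss$profile$r) / diff(ss$profile$z)
  expect_equal(slope, tan(20 * pi / 180), tolerance = 1e-12)  # 40 deg aperture
  expect_equal(ss$wall$outer_charge * 0.1602, -0.022, tolerance = 1e-3)

  ah <- build_preset("alpha_hemolysin")
  expect_equal(ah$channel_length, 10)
  expect_equal(range(ah$profile$r), c(0.5, 2.8))
  expect_equal((ah$membrane$z0 + ah$membrane$z1) / 2, -7.6)
  expect_equal(ah$membrane$z1 - ah$membrane$z0, 2.2, tolerance = 1e-12)
})

test_that("preset overrides are applied and unknown fields rejected", {
  d49 <- build_preset("dna_origami", list(shape = "circular", width = 4.9))
  expect_equal(unique(d49$profile$r), 4.9 / 2)
  expect_equal(d49$cross_section$shape, "circular")
  expect_error(build_preset("dna_origami", list(bogus = 1)), "unknown override")
  expect_error(build_preset("no_such_pore"), "unknown preset")
})

test_that("wall_distance is exact on cylinders and matches brute force on cones", {
  fx <- make_fixture("toy_cylinder")
  onaxis <- wall_distance(fx$spec, data.frame(r = 0, z = -10))
  expect_equal(onaxis$distance, 5)
  expect_equal(unname(onaxis$normal[1, ]), c(-1, 0))
  atwall <- wall_distance(fx$spec, data.frame(r = 5, z = -10))
  expect_equal(atwall$distance, 0, tolerance = 1e-12)

  # conical pore: compare to brute-force nearest-point search over densely
  # sampled wall points
  ss <- build_preset("solid_state")
  segs <- wall_segments(ss)
  dense <- do.call(rbind, lapply(seq_len(nrow(segs)), function(k) {
    t <- seq(0, 1, length.out = 4000)
    cbind(segs$r0[k] + t * (segs$r1[k] - segs$r0[k]),
          segs$z0[k] + t * (segs$z1[k] - segs$z0[k]))
  }))
  set.seed(1)
  pts <- data.frame(r = runif(12, 0, 9), z = runif(12, -48, -2))
  wd <- wall_distance(ss, pts)
  for (k in seq_len(nrow(pts))) {
    brute <- min(sqrt((dense[, 1] - pts$r[k])^2 + (dense[, 2] - pts$z[k])^2))
    expect_equal(wd$distance[k], brute, tolerance = 1e-3)
  }
})

test_that("wall_distance is 1-Lipschitz", {
  dna <- build_preset("dna_origami")
  set.seed(2)
  p1 <- data.frame(r = runif(40, 0, 3), z = runif(40, -46, 0))
  p2 <- data.frame(r = p1$r + rnorm(40, 0, 0.5), z = p1$z + rnorm(40, 0, 0.5))
  p2$r <- pmax(p2$r, 0)
  d1 <- wall_distance(dna, p1)$distance
  d2 <- wall_distance(dna, p2)$distance
  step <- sqrt((p1$r - p2$r)^2 + (p1$z - p2$z)^2)
  expect_true(all(abs(d1 - d2) <= step + 1e-9))
})

test_that("meshing is deterministic and volume-consistent", {
  fx <- make_fixture("toy_cylinder")
  m1 <- pore_mesh(fx$spec, list(fine = 0.5, coarse = 2.5))
  m2 <- pore_mesh(fx$spec, list(fine = 0.5, coarse = 2.5))
  expect_identical(m1$r_b, m2$r_b)
  expect_identical(m1$region, m2$region)

  vol <- mesh_fluid_volume(m1)
  analytic <- pi * 5^2 * 20 + 2 * pi * 30^2 * 25
  expect_rel(vol, analytic, 0.01)

  # refinement converges toward the analytic volume
  m3 <- pore_mesh(fx$spec, list(fine = 0.25, coarse = 1.25))
  expect_lte(abs(mesh_fluid_volume(m3) - analytic),
             abs(vol - analytic) + 1e-9)
})

test_that("protein meshes carve a tagged cavity and reject overlaps", {
  dna <- build_preset("dna_origami")
  m <- pore_mesh(dna, list(fine = 0.3, coarse = 1.5),
                 protein = list(center = c(0, -23), radius = 2.078, charge = 5))
  expect_gt(sum(m$region == 3L), 0)
  vol_prot <- sum(m$V[m$region == 3L])
  expect_rel(vol_prot, 4 / 3 * pi * 2.078^3, 0.15)
  expect_error(
    pore_mesh(dna, list(fine = 0.3, coarse = 1.5),
              protein = list(center = c(0, -23), radius = 3.5, charge = 0)),
    "not physically possible")
})

test_that("pore specs round-trip through YAML", {
  dna <- build_preset("dna_origami", list(width = 4.9, shape = "circular"))
  path <- tempfile(fileext = ".yaml")
  write_pore_spec(dna, path)
  back <- read_pore_spec(path)
  expect_equal(back$profile, dna$profile, tolerance = 1e-6)
  expect_equal(back$wall$charge, dna$wall$charge)
  expect_equal(back$reservoir$radius, dna$reservoir$radius, tolerance = 1e-6)
})
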