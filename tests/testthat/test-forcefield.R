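co <- physical_constants()

test_that("position grids respect the overlap constraint", {
  dna <- build_preset("dna_origami")
  g <- make_grid(dna, protein_radius = 2.078, spacing = 1)
  expect_gt(nrow(g), 50)
  wd <- wall_distance(dna, g)
  expect_true(all(wd$distance >= 2.078 - 1e-9))
  # a channel narrower than the protein has no admissible in-channel position
  narrow <- build_preset("dna_origami", list(shape = "circular", width = 3.5))
  expect_error(make_grid(narrow, protein_radius = 2.078, spacing = 1),
               "no admissible")
  # grid size grows roughly linearly with channel length
  long <- build_preset("dna_origami", list(channel_length = 92))
  g2 <- make_grid(long, protein_radius = 2.078, spacing = 1)
  n_in <- sum(g$in_channel); n_in2 <- sum(g2$in_channel)
  expect_gt(n_in2 / n_in, 1.6)
  expect_lt(n_in2 / n_in, 2.4)
})

test_that("interpolation is exact at nodes and bounded between them", {
  gridb <- make_fixture("harmonic_box", k_spring = 1e-5, D0 = 1e-10,
                        radius = 10, half_length = 10, protein_radius = 0.5)
  tb <- gridb$tables
  # node exactness
  out <- interpolate_forcefield(gridb, tb$r[3], tb$z[5])
  expect_equal(out$F_z, tb$Fz[3, 5], tolerance = 1e-15)
  # midpoint of two nodes = arithmetic mean
  mid <- interpolate_forcefield(gridb, (tb$r[3] + tb$r[4]) / 2, tb$z[5])
  expect_equal(mid$F_z, (tb$Fz[3, 5] + tb$Fz[4, 5]) / 2, tolerance = 1e-15)
  # random queries never overshoot the neighbouring node range
  set.seed(8)
  for (k in 1:30) {
    rq <- runif(1, 0, max(tb$r)); zq <- runif(1, min(tb$z), max(tb$z))
    i <- findInterval(rq, tb$r); j <- findInterval(zq, tb$z)
    v <- interpolate_forcefield(gridb, rq, zq)$F_z
    nb <- tb$Fz[i:min(i + 1, length(tb$r)), j:min(j + 1, length(tb$z))]
    expect_gte(v, min(nb) - 1e-18)
    expect_lte(v, max(nb) + 1e-18)
  }
})

test_that("an unbiased pore produces a null force and current table", {
  fx <- make_fixture("toy_cylinder")
  # uncharged probe: with charge the protein's own double layer exerts a
  # small configuration-dependent force even without bias
  grid <- suppressWarnings(sample_forcefield(fx$spec, list(radius = 2, charge = 0),
                            voltage = 0, bulk_conc = 1,
                            spacing = 10,
                            resolution = list(fine = 0.6, coarse = 3),
                            options = solver_options(tol = 1e-4, max_iter = 30),
                            table_dr = 1, table_dz = 2))
  expect_equal(grid$I0, 0, tolerance = 1e-16)
  expect_lt(max(abs(grid$table$F_z)), 1e-14)
  expect_lt(max(abs(grid$table$J)), 1e-15)
  expect_lt(max(abs(grid$tables$Fr)), 1e-13)
})
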