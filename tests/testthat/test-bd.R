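co <- physical_constants()

free_box <- function(D0 = 1e-10) {
  make_fixture("harmonic_box", k_spring = 0, D0 = D0, radius = 500,
               half_length = 500, protein_radius = 0.5)
}

no_term <- function(max_steps) {
  structure(list(z_translocate = -1e30, escape_box = c(1e30, 1e30, 1e30),
                 max_steps = as.integer(max_steps)),
            class = "termination_rule")
}

test_that("free diffusion reproduces the Einstein MSD", {
  gridb <- free_box()
  dt <- 1e-9
  set.seed(101)
  n <- 4000
  # many short trajectories: displacement over 25 steps each
  msd <- replicate(n, {
    tr <- run_trajectory(gridb, no_term(25), dt, c(0, 0, 0), store_stride = 0)
    sum(tr$final^2)
  })
  expected <- 6 * 1e-10 * dt * 25 / 1e-18
  expect_rel(mean(msd), expected, 0.05)
})

test_that("constant force produces the Einstein drift", {
  # harmonic spring evaluated at fixed offset acts as a constant force
  gridb <- make_fixture("harmonic_box", k_spring = 2e-5, D0 = 1e-10,
                        radius = 300, half_length = 300, protein_radius = 0.5)
  dt <- 1e-9
  set.seed(102)
  drifts <- replicate(20000, {
    x1 <- bd_step(gridb, c(0, 0, 50), dt)
    x1[3] - 50
  })
  Fz <- -2e-5 * 50e-9
  expected <- dt * 1e-10 * Fz / co$kT / 1e-9
  se <- stats::sd(drifts) / sqrt(length(drifts))
  expect_lt(abs(mean(drifts) - expected), 3 * se)
})

test_that("spatially varying diffusivity keeps a uniform stationary density", {
  gridb <- make_fixture("harmonic_box", k_spring = 0, D0 = 1e-9, radius = 10,
                        half_length = 10, protein_radius = 0.5)
  nzg <- length(gridb$tables$z)
  nrg <- length(gridb$tables$r)
  fac <- matrix(rep(0.3 + 0.7 * (gridb$tables$z + 10) / 20, each = nrg),
                nrg, nzg)
  gridb$tables$fpar <- fac
  gridb$tables$fperp <- fac
  set.seed(103)
  tr <- run_trajectory(gridb, no_term(3e6), 2e-11, c(0, 0, 0),
                       store_stride = 5)
  z <- tr$positions$z
  z <- z[abs(z) < 8]
  # thinned samples (spacing ~ box relaxation time) so the chi-square test
  # sees approximately independent draws
  z <- z[seq(1, length(z), by = 500)]
  h <- table(cut(z, breaks = seq(-8, 8, 4)))
  chi <- stats::chisq.test(h)
  expect_gt(chi$p.value, 0.01)
})

test_that("a harmonic trap reaches the Boltzmann distribution", {
  k_spring <- 2e-5
  gridb <- make_fixture("harmonic_box", k_spring = k_spring, D0 = 1e-9,
                        radius = 60, half_length = 60, protein_radius = 0.5)
  set.seed(104)
  tr <- run_trajectory(gridb, no_term(6e5), 1e-9, c(0, 0, 0), store_stride = 20)
  z <- tr$positions$z
  sd_th <- sqrt(co$kT / k_spring) / 1e-9
  expect_rel(stats::sd(z), sd_th, 0.06)
  # chi-square against the Gaussian in quintile bins, on thinned samples
  zs <- z[seq(1, length(z), by = 30)]
  qs <- stats::qnorm(seq(0.2, 0.8, 0.2)) * sd_th
  h <- table(cut(zs, breaks = c(-Inf, qs, Inf)))
  chi <- stats::chisq.test(h)
  expect_gt(chi$p.value, 0.01)
})

test_that("hard-wall reflection never penetrates the wall", {
  gridb <- make_fixture("harmonic_box", k_spring = 0, D0 = 1e-9, radius = 4,
                        half_length = 4, protein_radius = 0.5)
  set.seed(105)
  tr <- run_trajectory(gridb, no_term(2e5), 5e-11, c(0, 0, 0), store_stride = 1)
  r <- sqrt(tr$positions$x^2 + tr$positions$y^2)
  expect_true(all(r <= 4 - 0.5 + 1e-6))
  expect_true(all(abs(tr$positions$z) <= 4 - 0.5 + 1e-6))
})

test_that("trajectories are bitwise reproducible under a fixed seed", {
  gridb <- free_box()
  set.seed(42)
  t1 <- run_trajectory(gridb, no_term(500), 1e-9, c(0, 0, 0), store_stride = 1)
  set.seed(42)
  t2 <- run_trajectory(gridb, no_term(500), 1e-9, c(0, 0, 0), store_stride = 1)
  expect_identical(t1$positions, t2$positions)
  expect_identical(t1$final, t2$final)
})

test_that("termination rules fire correctly", {
  gridb <- free_box(D0 = 1e-9)
  # escape: start just below the box top with a tiny box
  rule <- structure(list(z_translocate = -1e30, escape_box = c(2, 2, 1),
                         max_steps = 100000L), class = "termination_rule")
  set.seed(106)
  tr <- run_trajectory(gridb, rule, 1e-9, c(0, 0, 0.5))
  expect_equal(tr$termination, "escaped")
  # translocation plane just below the start
  rule2 <- structure(list(z_translocate = -0.5, escape_box = c(1e30, 1e30, 1e30),
                          max_steps = 100000L), class = "termination_rule")
  set.seed(107)
  tr2 <- run_trajectory(gridb, rule2, 1e-9, c(0, 0, 0))
  expect_equal(tr2$termination, "translocated")
  # step cap
  rule3 <- no_term(10)
  set.seed(108)
  tr3 <- run_trajectory(gridb, rule3, 1e-9, c(0, 0, 0))
  expect_equal(tr3$termination, "max_steps")
  expect_equal(tr3$n_steps, 10)
})

test_that("binding-zone records are collected with force and current", {
  gridb <- free_box(D0 = 1e-10)
  site <- binding_site("spherical_receptor", center = c(0, 0, 0), r_rec = 0.5,
                       r_b = 300, k_a = 1e5, k_d = 1)
  set.seed(109)
  tr <- run_trajectory(gridb, no_term(1000), 1e-9, c(0, 0, 0),
                       binding_sites = list(site))
  rec <- tr$zone_records[[1]]
  expect_equal(nrow(rec), 1000)  # always inside this huge zone
  expect_true(all(c("t", "F", "J") %in% names(rec)))
})
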