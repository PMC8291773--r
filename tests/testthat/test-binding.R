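co <- physical_constants()

receptor_site <- function(k_a = 1.5e5, k_d = 25e-3, delta = 0) {
  binding_site("spherical_receptor", center = c(0, 0, 0), r_rec = 0,
               r_b = 5.75, k_a = k_a, k_d = k_d, delta = delta)
}

test_that("adsorption rate matches the shell-volume relation", {
  # hand-evaluated oracle: V_b = 4/3 pi (5.75^3 - 3^3) nm^3,
  # c_b = 1/(1e3 N_A V_b) M, R_a = k_a c_b = 364.62 /s
  site <- receptor_site()
  expect_rel(adsorption_rate(site, 3, co), 364.62, 1e-3)
  # k_a = 0 gives no adsorption
  expect_equal(adsorption_rate(receptor_site(k_a = 0), 3, co), 0)
  # doubling the zone volume halves the rate
  s1 <- receptor_site()
  V1 <- 4 / 3 * pi * (s1$r_b^3 - 3^3)
  r_b2 <- (2 * V1 * 3 / (4 * pi) + 3^3)^(1 / 3)
  s2 <- binding_site("spherical_receptor", center = c(0, 0, 0), r_rec = 0,
                     r_b = r_b2, k_a = 1.5e5, k_d = 25e-3)
  expect_rel(adsorption_rate(s2, 3, co), adsorption_rate(s1, 3, co) / 2, 1e-6)
  # degenerate zone rejected
  expect_error(adsorption_rate(binding_site("spherical_receptor",
                                            center = c(0, 0, 0), r_rec = 2,
                                            r_b = 3, k_a = 1, k_d = 1), 3, co),
               "degenerate")
})

test_that("binding durations are exponential with the Bell mean", {
  site <- receptor_site(k_d = 25e-3)
  set.seed(11)
  tau <- binding_duration(site, 0, co, n = 1e5)
  expect_rel(mean(tau), 40, 0.01)       # 1/k_d = 40 s
  # KS test against the exponential distribution
  ks <- stats::ks.test(tau, "pexp", rate = 25e-3)
  expect_gt(ks$p.value, 0.01)
  # delta = 0 makes the force irrelevant
  site_d <- receptor_site(delta = 0.55)
  set.seed(12)
  t_f0 <- binding_duration(site_d, 0, co, n = 2e4)
  expect_rel(mean(t_f0), 40, 0.03)
  # increasing |F| strictly decreases the mean when delta > 0
  mus <- vapply(c(0, 2e-12, 5e-12, 1e-11), function(f) {
    poresim:::mean_binding_duration(site_d, f, co)
  }, 0)
  expect_true(all(diff(mus) < 0))
  expect_error(binding_duration(receptor_site(k_d = 0), 0, co, n = 1),
               "k_d")
})

test_that("Poisson attempt statistics follow the closed forms", {
  site <- receptor_site()
  R_a <- adsorption_rate(site, 3, co)
  dt <- 1e-9
  n_steps <- 2000
  rec <- tibble::tibble(t = seq_len(n_steps) * dt, F = 0, J = 0)
  set.seed(13)
  counts <- replicate(3000, nrow(draw_bindings(rec, site, dt, 3, co)))
  lam <- R_a * dt * n_steps
  se <- sqrt(lam / 3000)
  expect_lt(abs(mean(counts) - lam), 3 * se)
  # P(at least one binding) = 1 - exp(-R_a T_a)
  p_hat <- mean(counts >= 1)
  p_th <- 1 - exp(-lam)
  expect_lt(abs(p_hat - p_th), 3 * sqrt(p_th * (1 - p_th) / 3000))
  # empty attempt list -> no events
  expect_equal(nrow(draw_bindings(rec[0, ], site, dt, 3, co)), 0)
})

test_that("binding probability is invariant under time-step splitting", {
  site <- receptor_site(k_a = 1e7)
  R_a <- adsorption_rate(site, 3, co)
  T_a <- 2e-6
  set.seed(14)
  rec1 <- tibble::tibble(t = c(0, 1e-6), F = 0, J = 0)          # 2 coarse steps
  rec2 <- tibble::tibble(t = seq(0, T_a, length.out = 20), F = 0, J = 0)
  p1 <- mean(replicate(4000, nrow(draw_bindings(rec1, site, 1e-6, 3, co)) >= 1))
  p2 <- mean(replicate(4000, nrow(draw_bindings(rec2, site, 1e-7, 3, co)) >= 1))
  expect_lt(abs(p1 - p2), 3 * sqrt(0.25 / 4000) * 2)
})

test_that("events assemble with time-weighted amplitudes", {
  traj <- structure(list(duration = 1e-6, mean_J = 0.9e-10, I0 = 1e-10,
                         termination = "translocated"),
                    class = "bd_trajectory")
  # no bindings: tau_off equals the trajectory duration
  ev0 <- assemble_event(traj, NULL)
  expect_equal(ev0$tau_off, 1e-6)
  expect_equal(ev0$amplitude, 0.1, tolerance = 1e-12)
  expect_false(ev0$bound)
  # hand-computed two-interval weighted average
  b <- tibble::tibble(t = 0, tau = 3e-6, F = 0, J = 0.5e-10)
  ev1 <- assemble_event(traj, b)
  expect_equal(ev1$tau_off, 4e-6)
  expect_equal(ev1$amplitude, (1e-6 * 0.1 + 3e-6 * 0.5) / 4e-6,
               tolerance = 1e-12)
  # a binding much longer than the free motion dominates the amplitude
  b2 <- tibble::tibble(t = 0, tau = 10, F = 0, J = 0.4e-10)
  ev2 <- assemble_event(traj, b2)
  expect_equal(ev2$amplitude, 0.6, tolerance = 1e-4)
})

test_that("resampling reuses trajectory shapes with fresh binding draws", {
  gridb <- make_fixture("harmonic_box", k_spring = 0, D0 = 1e-10, radius = 300,
                        half_length = 300, protein_radius = 0.5)
  rule <- structure(list(z_translocate = -1e30, escape_box = c(1e30, 1e30, 1e30),
                         max_steps = 500L), class = "termination_rule")
  site <- binding_site("spherical_receptor", center = c(0, 0, 0), r_rec = 0.5,
                       r_b = 200, k_a = 5e8, k_d = 1e3)
  pool <- run_trajectories(gridb, rule, 1e-9, c(0, 0, 0), n = 4, seed = 7,
                           binding_sites = list(site))
  ev <- resample_events(pool, list(site), 600, 0.5, seed = 21)
  expect_equal(nrow(ev), 600)
  # binding fraction agrees with the analytic per-trajectory expectation
  R_a <- adsorption_rate(site, 0.5, co)
  T_a <- vapply(pool$trajectories,
                function(t) nrow(t$zone_records[[1]]) * 1e-9, 0)
  p_th <- mean(1 - exp(-R_a * T_a))
  p_hat <- mean(ev$bound)
  expect_lt(abs(p_hat - p_th), 4 * sqrt(p_th * (1 - p_th) / 600) + 0.01)
  # with k_a = 0 every resampled event reduces to its base trajectory
  site0 <- binding_site("spherical_receptor", center = c(0, 0, 0), r_rec = 0.5,
                        r_b = 200, k_a = 0, k_d = 1e3)
  ev0 <- resample_events(pool, list(site0), 50, 0.5, seed = 22)
  expect_true(all(!ev0$bound))
  expect_true(all(ev0$tau_off %in% vapply(pool$trajectories, `[[`, 0, "duration")))
})

test_that("binding never alters the trajectory geometry", {
  gridb <- make_fixture("harmonic_box", k_spring = 0, D0 = 1e-10, radius = 50,
                        half_length = 50, protein_radius = 0.5)
  rule <- structure(list(z_translocate = -1e30, escape_box = c(1e30, 1e30, 1e30),
                         max_steps = 300L), class = "termination_rule")
  site <- binding_site("spherical_receptor", center = c(0, 0, 0), r_rec = 0.5,
                       r_b = 40, k_a = 1e9, k_d = 10)
  set.seed(31)
  t_with <- run_trajectory(gridb, rule, 1e-9, c(0, 0, 0), store_stride = 1,
                           binding_sites = list(site))
  set.seed(31)
  t_without <- run_trajectory(gridb, rule, 1e-9, c(0, 0, 0), store_stride = 1)
  expect_identical(t_with$positions, t_without$positions)
})
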