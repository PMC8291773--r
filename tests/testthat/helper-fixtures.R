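# shared fixtures, computed once per test run and cached in this environment
.cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (is.null(.cache[[key]])) .cache[[key]] <- fn()
  .cache[[key]]
}

toy_solution <- function(voltage = 100) {
  cached(paste0("toy", voltage), function() {
    fx <- make_fixture("toy_cylinder")
    m <- pore_mesh(fx$spec, list(fine = 0.5, coarse = 2.5))
    solve_pnps(m, physical_constants(), NULL, voltage, 1,
               solver_options(tol = 1e-6, max_iter = 40))
  })
}

# small sealed cylinder with a protein cavity, for explicit-protein machinery
protein_box_mesh <- function() {
  cached("protein_box", function() {
    spec <- pore_spec("drag_box",
                      profile = data.frame(z = c(-60, 0), r = c(30, 30)),
                      channel_length = 60,
                      wall = list(thickness = 1e4, charge = 0, material = "sin"),
                      membrane = NULL,
                      reservoir = list(top = 2, bottom = 2, radius = 31))
    pore_mesh(spec, list(fine = 1, coarse = 3, gap = 0.18),
              protein = list(center = c(0, -30), radius = 2, charge = 0))
  })
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}
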