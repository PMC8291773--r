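#' Run configuration
#'
#' Collects everything needed for an end-to-end simulation: pore preset and
#' overrides, drive conditions, protein, diffusivity model, BD and binding
#' settings, and the global seed. Configurations round-trip through YAML.
#'
#' @param pore Preset name (see [build_preset()]).
#' @param overrides Preset overrides.
#' @param voltage Applied voltage (mV, trans minus cis).
#' @param bulk_conc Bulk concentration (mol/L).
#' @param diffusivity_model Ion/protein diffusivity model id.
#' @param protein List `radius` (nm), `charge` (q).
#' @param dt BD time step (s).
#' @param n_trajectories Trajectories to integrate.
#' @param n_events Events to draw (resampling variant used when larger than
#'   `n_trajectories`).
#' @param binding_sites List of [binding_site()] objects.
#' @param grid_spacing Explicit force-grid station spacing (nm).
#' @param resolution Mesh resolution list.
#' @param forcefield_mode `"blend"` or `"point_particle"` (see
#'   [sample_forcefield()]); `NULL` picks per pore.
#' @param seed Global seed.
#' @param out_dir Output directory (`NULL` = no artifacts written).
#' @return A list of class `run_config`.
#' @export
run_config <- function(pore = "dna_origami", overrides = list(),
                       voltage = -80, bulk_conc = 1,
                       diffusivity_model = "combined_rz",
                       protein = list(radius = 2.078, charge = 5),
                       dt = 0.2e-9, n_trajectories = 100, n_events = NULL,
                       binding_sites = list(), grid_spacing = 2,
                       resolution = list(fine = 0.25, coarse = 1.5),
                       forcefield_mode = NULL,
                       seed = 1, out_dir = NULL) {
  if (is.null(forcefield_mode)) {
    # wide pores with negligible blockade use the point-particle closure;
    # narrow pores get explicit on-axis blockade solves
    forcefield_mode <- if (pore == "solid_state") "point_particle" else "blend"
  }
  structure(list(pore = pore, overrides = overrides, voltage = voltage,
                 bulk_conc = bulk_conc, diffusivity_model = diffusivity_model,
                 protein = protein, dt = dt,
                 n_trajectories = n_trajectories,
                 n_events = n_events %||% n_trajectories,
                 binding_sites = binding_sites, grid_spacing = grid_spacing,
                 resolution = resolution, forcefield_mode = forcefield_mode,
                 seed = seed, out_dir = out_dir),
            class = "run_config")
}

#' Execute the full simulation pipeline
#'
#' Runs the end-to-end chain: build the pore, precompute diffusivity fields,
#' sample the force/current grid, integrate BD trajectories, draw stochastic
#' binding events (resampling the trajectory pool when more events than
#' trajectories are requested), and fit the event statistics. Stage results
#' are checkpointed to `out_dir` (keyed by the configuration hash) so reruns
#' with an identical configuration and seed reuse finished stages and produce
#' identical outputs.
#'
#' @param config A [run_config()].
#' @param verbose Print stage progress.
#' @return A list of class `pipeline_result` with `grid`, `ensemble`,
#'   `events`, `fits` and the configuration.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  t_start <- Sys.time()
  constants <- physical_constants()
  cfg_hash <- rlang::hash(config[setdiff(names(config), "out_dir")])
  ckpt <- function(name) {
    if (is.null(config$out_dir)) return(NULL)
    file.path(config$out_dir, sprintf("%s-%s.rds", name, cfg_hash))
  }
  load_or <- function(name, fn) {
    path <- ckpt(name)
    if (!is.null(path) && file.exists(path)) {
      if (verbose) message("stage ", name, ": reusing checkpoint")
      return(readRDS(path))
    }
    t0 <- Sys.time()
    val <- fn()
    if (verbose)
      message(sprintf("stage %s: %.1f s", name,
                      as.numeric(Sys.time() - t0, units = "secs")))
    if (!is.null(path)) {
      dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
      saveRDS(val, path)
    }
    val
  }

  spec <- build_preset(config$pore, config$overrides)
  grid <- load_or("forcefield", function() {
    ion_field <- if (config$diffusivity_model == "bulk_constant") NULL else {
      diffusivity_field(spec, 0.11, config$diffusivity_model, constants,
                        n_stations = 6, lrnh_options = list(n_sphere = 300))
    }
    protein_field <- diffusivity_field(
      spec, config$protein$radius,
      if (config$diffusivity_model == "bulk_constant") "bulk_constant"
      else config$diffusivity_model,
      constants, n_stations = 6, lrnh_options = list(n_sphere = 400))
    sample_forcefield(spec, config$protein, config$voltage, config$bulk_conc,
                      ion_field = ion_field, protein_field = protein_field,
                      spacing = config$grid_spacing,
                      resolution = config$resolution,
                      mode = config$forcefield_mode %||% "blend")
  })

  rule <- termination_rule(spec)
  start_fn <- pipeline_start_rule(spec, config$protein$radius)
  ensemble <- load_or("trajectories", function() {
    run_trajectories(grid, rule, config$dt, start_fn,
                     n = config$n_trajectories, seed = config$seed,
                     binding_sites = config$binding_sites)
  })

  events <- load_or("events", function() {
    if (length(config$binding_sites) == 0) {
      ev <- ensemble$events
      tibble::tibble(tau_off = ev$duration, amplitude = ev$amplitude,
                     n_bindings = 0L, outcome = ev$termination,
                     bound = FALSE, trajectory = ev$trajectory,
                     seed = config$seed)
    } else {
      resample_events(ensemble, config$binding_sites, config$n_events,
                      config$protein$radius, seed = config$seed + 10000L)
    }
  })

  fits <- list()
  if (nrow(events) >= 10) {
    fits$exponential <- tryCatch(fit_exponential(events), error = function(e) NULL)
    if (any(events$bound)) {
      fits$double_exponential <- tryCatch(
        fit_double_exponential(events, seed = config$seed),
        error = function(e) NULL)
    }
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(events,
                     file.path(config$out_dir, sprintf("events-%s.csv", cfg_hash)),
                     row.names = FALSE)
    meta <- list(config_hash = cfg_hash, seed = config$seed,
                 package_version = as.character(utils::packageVersion("poresim")),
                 I0_pA = grid$I0 * 1e12)
    jsonlite::write_json(meta,
                         file.path(config$out_dir, sprintf("meta-%s.json", cfg_hash)),
                         auto_unbox = TRUE)
  }
  if (verbose)
    message(sprintf("pipeline finished in %.1f s",
                    as.numeric(Sys.time() - t_start, units = "secs")))
  structure(list(config = config, spec = spec, grid = grid,
                 ensemble = ensemble, events = events, fits = fits,
                 config_hash = cfg_hash),
            class = "pipeline_result")
}

# start rule per the study conditions: DNA pore starts centered at the upper
# entry; the solid-state pore starts at random positions on the disc of the
# larger (upper) entrance
pipeline_start_rule <- function(spec, protein_radius) {
  if (spec$name == "solid_state") {
    R_entry <- profile_radius(spec, spec$z_top) - protein_radius - 0.2
    function(k) {
      th <- stats::runif(1, 0, 2 * pi)
      rr <- sqrt(stats::runif(1)) * R_entry
      c(rr * cos(th), rr * sin(th), spec$z_top + protein_radius + 0.2)
    }
  } else {
    c(0, 0, spec$z_top + protein_radius + 0.05)
  }
}

#' @exportS3Method base::print
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: %s, %d trajectories, %d events (%.2f%% bound)\n",
              x$spec$name, nrow(x$ensemble$events), nrow(x$events),
              100 * mean(x$events$bound)))
  invisible(x)
}

#' Built-in test fixtures
#'
#' Small geometries with analytic reference solutions, used throughout the
#' test suite:
#' \describe{
#'   \item{`toy_cylinder`}{a sealed cylindrical channel (R = 5 nm, L = 20 nm)
#'     with the Ohmic + access-resistance conductance oracle attached.}
#'   \item{`plane_wall`}{parameters for plane-wall hindered-diffusion
#'     validation.}
#'   \item{`harmonic_box`}{a closed cylindrical box with a harmonic axial
#'     force field and constant diffusivity; the stationary Boltzmann
#'     distribution is known.}
#' }
#'
#' @param name Fixture name.
#' @param ... Fixture-specific settings (`harmonic_box`: `k_spring` (N/m),
#'   `D0` (m^2/s), `radius`, `half_length` (nm)).
#' @return A fixture object (see details above).
#' @export
make_fixture <- function(name = c("toy_cylinder", "plane_wall", "harmonic_box"),
                         ...) {
  name <- match.arg(name)
  args <- list(...)
  if (name == "toy_cylinder") {
    spec <- pore_spec("toy_cylinder",
                      profile = data.frame(z = c(-20, 0), r = c(5, 5)),
                      channel_length = 20,
                      wall = list(thickness = 1e4, charge = 0, material = "sin"),
                      membrane = NULL,
                      reservoir = list(top = 25, bottom = 25, radius = 30))
    oracle <- function(constants, bulk_conc = 1, voltage_mV = 100,
                       D = bulk_diffusivity(constants, 0.11)) {
      sigma <- constants$q^2 * (bulk_conc * 1e3 * constants$N_A) * 2 * D /
        constants$kT
      Rch <- 20 * .nm / (sigma * pi * (5 * .nm)^2)
      Racc <- 2 / (4 * sigma * 5 * .nm)
      voltage_mV * 1e-3 / (Rch + Racc)
    }
    list(spec = spec, conductance_oracle = oracle)
  } else if (name == "plane_wall") {
    list(wall = "plane", wall_z = 0, wall_side = +1,
         h_over_a = c(1.2, 1.5, 2, 3, 5, 10))
  } else {
    k_spring <- args$k_spring %||% 2e-5      # N/m, soft harmonic trap
    D0 <- args$D0 %||% 1e-10
    R <- args$radius %||% 6
    H <- args$half_length %||% 8
    a_prot <- args$protein_radius %||% 0.5
    ng <- 41
    rg <- seq(0, R, length.out = ng)
    zg <- seq(-H, H, length.out = 2 * ng - 1)
    Fz <- -k_spring * outer(rep(1, ng), zg) * .nm     # F_z = -k z
    Fr <- -k_spring * outer(rg, rep(1, 2 * ng - 1)) * .nm
    one <- matrix(1, ng, 2 * ng - 1)
    tables <- list(r = rg, z = zg, Fr = Fr, Fz = Fz, J = one * 0,
                   fpar = one, fperp = one, n_r = one, n_z = one * 0, D0 = D0)
    # closed box: cylinder wall plus end caps
    segs <- rbind(c(R, -H, R, H), c(0, -H, R, -H), c(0, H, R, H))
    structure(list(spec = NULL, protein = list(radius = a_prot, charge = 0),
                   I0 = 1e-12, tables = tables, wall_segments = segs,
                   k_spring = k_spring, D0 = D0,
                   table = tibble::tibble(), voltage = 0, bulk_conc = 0),
              class = "force_current_grid")
  }
}
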