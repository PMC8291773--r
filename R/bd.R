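#' Termination rule for Brownian-dynamics trajectories
#'
#' A trajectory ends when the protein center crosses the translocation plane
#' at the lower end of the nanopore, leaves the escape box above the upper
#' entry, or exhausts `max_steps`.
#'
#' @param spec A [pore_spec()] (sets the default translocation plane at the
#'   lower channel end).
#' @param z_translocate Translocation plane (nm).
#' @param escape_box Numeric length-3: half-width in x, half-width in y (nm)
#'   and the top of the box above the upper entry (nm). The default is the
#'   10 x 10 x 12 nm^3 box anchored on the upper channel entry.
#' @param max_steps Step cap.
#' @return A list of class `termination_rule`.
#' @export
termination_rule <- function(spec, z_translocate = spec$z_bot,
                             escape_box = c(5, 5, spec$z_top + 12),
                             max_steps = 2e6) {
  structure(list(z_translocate = z_translocate, escape_box = escape_box,
                 max_steps = as.integer(max_steps)), class = "termination_rule")
}

bd_wall_segments <- function(spec) {
  segs <- wall_segments(spec)
  as.matrix(segs[, c("r0", "z0", "r1", "z1")])
}

grid_segments <- function(grid) {
  if (!is.null(grid$wall_segments)) grid$wall_segments
  else bd_wall_segments(grid$spec)
}

# minimum meridional distance from (r, z) to a segment matrix
seg_distance_rz <- function(segs, r, z) {
  best <- Inf
  for (s in seq_len(nrow(segs))) {
    a <- segs[s, 1:2]; b <- segs[s, 3:4]
    ab <- b - a; len2 <- max(sum(ab^2), 1e-300)
    t <- min(max(((r - a[1]) * ab[1] + (z - a[2]) * ab[2]) / len2, 0), 1)
    d <- sqrt((r - a[1] - t * ab[1])^2 + (z - a[2] - t * ab[2])^2)
    best <- min(best, d)
  }
  best
}

#' Run one Brownian-dynamics trajectory
#'
#' Integrates the discretized overdamped Langevin equation over the
#' interpolated force and diffusivity fields, with the spurious-drift term
#' div(D), anisotropic noise via the closed-form tensor square root, and
#' hard-wall reflection (steps crossing the protein-inflated wall surface are
#' shortened to stop just before contact). Uses R's RNG: seed with
#' [set.seed()] for bitwise reproducibility.
#'
#' @param grid A [sample_forcefield()] result.
#' @param rule A [termination_rule()].
#' @param dt Time step (s).
#' @param start Start position, length-3 Cartesian (nm) or length-2 (r, z).
#' @param binding_sites List of [binding_site()] objects whose binding zones
#'   are monitored during integration (per-step time, force and current
#'   records are stored for the adsorption model).
#' @param store_stride Store every n-th position (0 = none).
#' @param constants [physical_constants()].
#' @return An object of class `bd_trajectory`: `duration` (s), `termination`
#'   (`"translocated"`, `"escaped"` or `"max_steps"`), `mean_J` (A),
#'   `positions` (tibble, strided), and `zone_records` (one tibble per binding
#'   site with columns `t`, `F`, `J`).
#' @export
run_trajectory <- function(grid, rule, dt, start,
                           binding_sites = list(), store_stride = 0,
                           constants = physical_constants()) {
  if (length(start) == 2) start <- c(start[1], 0, start[2])
  segs <- grid_segments(grid)
  if (seg_distance_rz(segs, sqrt(start[1]^2 + start[2]^2), start[3]) <
      grid$protein$radius)
    stop("start position is not admissible (protein overlaps a wall)")
  zones <- lapply(binding_sites, function(s) {
    if (s$kind == "spherical_receptor") {
      list(type = "sphere", center = s$center, r_b = s$r_b)
    } else {
      list(type = "wall", z0 = s$z0, z1 = s$z1, r_b = s$r_b)
    }
  })
  res <- cpp_bd_trajectory(grid$tables, segs,
                           grid$protein$radius, as.numeric(start),
                           dt, constants$kT, rule$max_steps,
                           rule$z_translocate, rule$escape_box,
                           zones, as.integer(store_stride))
  structure(list(
    duration = res$duration, n_steps = res$n_steps,
    termination = c("max_steps", "translocated", "escaped")[res$status + 1L],
    mean_J = res$mean_J, final = res$final, dt = dt,
    positions = tibble::as_tibble(res$positions),
    zone_records = lapply(res$zones, tibble::as_tibble),
    I0 = grid$I0
  ), class = "bd_trajectory")
}

#' Run an ensemble of trajectories
#'
#' Each trajectory is integrated with its own RNG stream derived from
#' `seed + index`, so ensembles are reproducible and individual trajectories
#' can be regenerated in isolation.
#'
#' @inheritParams run_trajectory
#' @param n Number of trajectories.
#' @param start Either a fixed start position or a function `(k)` returning
#'   one (used e.g. to start on a random disc at the channel entrance).
#' @param seed Global seed.
#' @return A list of class `bd_ensemble` with `trajectories` and a summary
#'   tibble `events` (duration, termination, mean blockade).
#' @export
run_trajectories <- function(grid, rule, dt, start, n, seed = 1,
                             binding_sites = list(), store_stride = 0,
                             constants = physical_constants()) {
  trajs <- vector("list", n)
  for (k in seq_len(n)) {
    set.seed(seed + k)
    st <- if (is.function(start)) start(k) else start
    trajs[[k]] <- run_trajectory(grid, rule, dt, st, binding_sites,
                                 store_stride, constants)
  }
  events <- tibble::tibble(
    trajectory = seq_len(n),
    duration = vapply(trajs, `[[`, 0, "duration"),
    termination = vapply(trajs, `[[`, "", "termination"),
    mean_J = vapply(trajs, `[[`, 0, "mean_J"),
    amplitude = 1 - vapply(trajs, `[[`, 0, "mean_J") / grid$I0
  )
  structure(list(trajectories = trajs, events = events, seed = seed, dt = dt,
                 I0 = grid$I0),
            class = "bd_ensemble")
}

#' Current trace of a trajectory
#'
#' Evaluates J(x) along the stored positions. Requires the trajectory to have
#' been run with `store_stride = 1` for a full-resolution trace.
#'
#' @param trajectory A `bd_trajectory`.
#' @param grid The `force_current_grid` it was run on.
#' @return A tibble with `time` (ns) and `current` (pA).
#' @export
current_trace <- function(trajectory, grid) {
  pos <- trajectory$positions
  if (!nrow(pos)) stop("trajectory stored no positions; rerun with store_stride = 1")
  r <- sqrt(pos$x^2 + pos$y^2)
  J <- interpolate_forcefield(grid, r, pos$z)$J
  stride <- max(1, round(trajectory$n_steps / nrow(pos)))
  tibble::tibble(time = (seq_len(nrow(pos)) - 1) * trajectory$dt * stride * 1e9,
                 current = J * 1e12)
}

#' Single BD step (exposed for verification)
#'
#' @param grid A `force_current_grid`.
#' @param x Position (nm, Cartesian).
#' @param dt Time step (s).
#' @param constants [physical_constants()].
#' @return The next position (nm).
#' @export
bd_step <- function(grid, x, dt, constants = physical_constants()) {
  cpp_bd_step(grid$tables, grid_segments(grid),
              grid$protein$radius, as.numeric(x), dt, constants$kT)
}

#' @exportS3Method base::print
print.bd_trajectory <- function(x, ...) {
  cat(sprintf("bd_trajectory: %s after %.3g us (%g steps), mean blockade %.1f%%\n",
              x$termination, x$duration * 1e6, x$n_steps,
              100 * (1 - x$mean_J / x$I0)))
  invisible(x)
}

#' @exportS3Method base::print
print.bd_ensemble <- function(x, ...) {
  tab <- table(x$events$termination)
  cat("bd_ensemble:", nrow(x$events), "trajectories (",
      paste(names(tab), tab, collapse = ", "), ")\n")
  invisible(x)
}
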