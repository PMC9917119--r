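# pulling_dynamics module: overdamped Langevin dynamics with a moving
# virtual spring.

#' Pulling protocol
#'
#' Describes how a system is pulled.  In `vertical` geometry the spring is
#' attached to the C-alpha of the C-terminal residue and retracted along +z;
#' in `lateral` geometry tension is applied in the membrane plane (+x) while
#' a second, fixed spring anchors the N-terminal residue.  The `stiff` mode
#' is AFM-like (default spring constant 0.05 kBT/A^2, about 21 pN/nm at
#' 300 K); `soft` emulates a magnetic-tweezers spring whose force stays
#' nearly constant after a rupture; `force_clamp` applies a constant force.
#'
#' @param geometry `"vertical"` or `"lateral"`.
#' @param mode `"stiff"`, `"soft"` or `"force_clamp"`.
#' @param k spring constant, kBT/A^2; defaults 0.05 (stiff) or 0.002 (soft).
#' @param velocity cantilever retraction velocity, Angstrom per time step.
#' @param initial_offset pre-tension: the cantilever starts this far beyond
#'   the attachment point (Angstrom), so the spring is loaded to
#'   `k * initial_offset` at step zero.  Skips the quiescent loading phase
#'   when only the rupture region is of interest.
#' @param clamp_force constant force for `force_clamp`, kBT/A.
#' @param anchor_residue residue (1-based) held by the fixed spring in
#'   lateral mode; default 1.  `NULL` for no anchor (vertical).
#' @param anchor_k fixed-spring constant, kBT/A^2 (defaults to `k`).
#' @param restrain_helices add harmonic restraints on the native helical
#'   donor-acceptor distances so the TM helices cannot unfold.
#' @param restraint_k restraint spring constant, kBT/A^2.
#' @param temperature reduced temperature (kBT units; 0.85 maps to ~300 K).
#' @param dt integration time step (reduced units).
#' @param friction friction coefficient (1/time step).
#' @param n_steps number of integration steps (> 0).
#' @param frame_interval steps between saved frames (>= 1).
#' @param seed integer seed; a trajectory is a pure function of
#'   (system, params, protocol, seed).
#' @param max_disp instability guard: any site moving further than this in
#'   one step aborts with an error naming the step, Angstrom.
#' @return an `mp_protocol` list.
#' @export
pulling_protocol <- function(geometry = c("vertical", "lateral"),
                             mode = c("stiff", "soft", "force_clamp"),
                             k = NULL, velocity = 0.001, initial_offset = 0,
                             clamp_force = 0,
                             anchor_residue = NULL, anchor_k = NULL,
                             restrain_helices = FALSE, restraint_k = 10,
                             temperature = 0.85, dt = 0.015, friction = 1,
                             n_steps = 100000L, frame_interval = 100L,
                             seed = 1L, max_disp = 2) {
  geometry <- match.arg(geometry)
  mode <- match.arg(mode)
  if (is.null(k)) k <- switch(mode, stiff = 0.05, soft = 0.002,
                              force_clamp = 0)
  if (k < 0) stop("invalid argument: spring constant must be >= 0")
  if (n_steps < 1) stop("invalid argument: n_steps must be >= 1 (zero-length run)")
  if (frame_interval < 1) stop("invalid argument: frame_interval must be >= 1")
  if (geometry == "lateral" && is.null(anchor_residue)) anchor_residue <- 1L
  structure(list(geometry = geometry, mode = mode, k = k,
                 velocity = velocity, initial_offset = initial_offset,
                 clamp_force = clamp_force,
                 anchor_residue = anchor_residue, anchor_k = anchor_k,
                 restrain_helices = restrain_helices,
                 restraint_k = restraint_k,
                 temperature = temperature, dt = dt, friction = friction,
                 n_steps = as.integer(n_steps),
                 frame_interval = as.integer(frame_interval),
                 seed = as.integer(seed), max_disp = max_disp),
            class = "mp_protocol")
}

# restraint matrix (0-based N residue, O residue, current distance) for the
# native helical H-bonds of a topology on a conformation
helix_restraint_matrix <- function(topo, conf) {
  hb <- topo$native_hbonds
  if (!nrow(hb)) return(matrix(0, 0, 3))
  sites <- cpp_derived_sites(conf_cpp(conf))
  d0 <- sqrt(rowSums((conf$N[hb$donor, , drop = FALSE] -
                        sites$O[hb$acceptor, , drop = FALSE])^2))
  cbind(hb$donor - 1, hb$acceptor - 1, d0)
}

#' Run a pulling simulation
#'
#' Integrates overdamped Langevin dynamics (Euler-Maruyama) while the
#' cantilever advances `velocity` Angstrom per step along the pulling axis
#' (or holds a constant force in `force_clamp` mode).  Frames are saved every
#' `frame_interval` steps with the spring state and the full energy
#' breakdown.  Extension is the displacement of the attachment C-alpha along
#' the pulling axis from its initial position; in lateral mode the anchored
#' end's displacement is subtracted.
#'
#' @param system list with `topology` and `conformation`, as returned by the
#'   builders.
#' @param protocol an [pulling_protocol()].
#' @param params an [energy_params()].
#' @param membrane a [membrane_model()]; default from the topology.
#' @return an `mp_trajectory`.
#' @examples
#' \donttest{
#' sys <- build_tm_bundle(bundle_spec(n_helices = 2, residues_per_helix = 12))
#' tr <- run_pulling(sys, pulling_protocol(n_steps = 2000, velocity = 0.01))
#' tr
#' }
#' @export
run_pulling <- function(system, protocol = pulling_protocol(),
                        params = energy_params(), membrane = NULL) {
  topo <- system$topology
  conf <- system$conformation
  membrane <- default_membrane(topo, membrane)
  n <- nrow(topo$residues)
  axis <- if (protocol$geometry == "vertical") c(0, 0, 1) else c(1, 0, 0)
  anchor <- if (is.null(protocol$anchor_residue)) -1L
            else as.integer(protocol$anchor_residue - 1)
  if (protocol$geometry == "lateral" && anchor < 0)
    stop("invalid argument: lateral pulling requires an anchor residue")
  restr <- NULL
  if (isTRUE(protocol$restrain_helices))
    restr <- helix_restraint_matrix(topo, conf)
  prot <- list(mode = protocol$mode, k = protocol$k,
               velocity = protocol$velocity,
               initial_offset = protocol$initial_offset,
               clamp_force = protocol$clamp_force,
               axis = axis, attach = n - 1L,
               anchor_residue = anchor,
               anchor_k = if (is.null(protocol$anchor_k)) protocol$k
                          else protocol$anchor_k,
               temperature = protocol$temperature, dt = protocol$dt,
               friction = protocol$friction, n_steps = protocol$n_steps,
               frame_interval = protocol$frame_interval,
               seed = protocol$seed, max_disp = protocol$max_disp,
               restraints = restr, restraint_k = protocol$restraint_k)
  out <- cpp_run_pulling(conf_cpp(conf), topo_cpp(topo),
                         pack_params(params, membrane), prot)
  structure(list(steps = out$steps, coords = out$coords, x = out$x,
                 force = out$force, spring_energy = out$spring_energy,
                 extension = out$extension, breakdown = out$breakdown,
                 topology = topo, protocol = protocol, params = params,
                 membrane = membrane, seed = protocol$seed),
            class = "mp_trajectory")
}

#' Single Langevin step
#'
#' One Euler-Maruyama update `dr = (dt / friction) F + sqrt(2 kBT dt /
#' friction) eta` applied to every backbone coordinate, with `eta` standard
#' normal from a seeded generator.
#'
#' @param conf an `mp_conformation`.
#' @param forces n x 9 force matrix as from [compute_forces()].
#' @param dt time step (> 0).
#' @param friction friction coefficient.
#' @param temperature reduced temperature (kBT).
#' @param seed integer seed for the noise.
#' @return the updated `mp_conformation`.
#' @export
step_langevin <- function(conf, forces, dt, friction = 1, temperature = 0.85,
                          seed = 1L) {
  if (dt <= 0) stop("invalid argument: dt must be > 0")
  m <- cpp_step_langevin(conf_cpp(conf), t(unclass(forces)), dt, friction,
                         temperature, as.integer(seed))
  conf_from_cpp(m)
}

#' Convert forces from reduced units to piconewton
#'
#' A force of 1 kBT/Angstrom corresponds to `kB * T / 1e-10 m` newton; at
#' 300 K that is 41.42 pN.  The simulation's reduced temperature plays no
#' role here: the mapping fixes the physical temperature.
#'
#' @param force force in kBT/Angstrom (vectorized).
#' @param temperature_K physical temperature in kelvin (> 0).
#' @return force in pN.
#' @examples
#' map_force_units(1)            # 41.42 pN
#' map_force_units(0.05) * 10    # 0.05 kBT/A^2 as pN/nm: about 21
#' @export
map_force_units <- function(force, temperature_K = 300) {
  if (any(temperature_K <= 0)) stop("invalid argument: temperature_K must be > 0")
  kB <- 1.380649e-23
  force * kB * temperature_K / 1e-10 * 1e12
}

#' Single-bead integrator diagnostics
#'
#' Runs the package's Langevin update rule on one coordinate in a harmonic
#' well (`U = k x^2 / 2`) or a tilted double well
#' (`U = h (x^2 - 1)^2 + t x`), for validating equipartition and Boltzmann
#' sampling of the integrator.
#'
#' @param potential `"harmonic"` or `"double_well"`.
#' @param k harmonic spring constant (kBT/A^2).
#' @param h double-well barrier scale (kBT).
#' @param tilt linear tilt `t` (kBT/A); sets the energy difference between
#'   the two wells.
#' @param n_steps,dt,friction,temperature,seed integrator settings.
#' @param thin keep every `thin`-th position.
#' @param x0 starting position.
#' @return numeric vector of sampled positions.
#' @export
simulate_bead <- function(potential = c("harmonic", "double_well"), k = 1,
                          h = 2, tilt = 0, n_steps = 1e6, dt = 0.01,
                          friction = 1, temperature = 0.85, seed = 1L,
                          thin = 10L, x0 = 0) {
  potential <- match.arg(potential)
  type <- if (potential == "harmonic") 0L else 1L
  p1 <- if (potential == "harmonic") k else h
  p2 <- if (potential == "harmonic") 0 else tilt
  cpp_bead_sim(type, p1, p2, n_steps, dt, friction, temperature,
               as.integer(seed), as.integer(thin), x0)
}
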