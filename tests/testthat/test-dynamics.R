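# integrator and pulling machinery

test_that("force units map correctly to piconewton", {
  expect_equal(map_force_units(1, 300), 41.42, tolerance = 0.01)
  expect_equal(map_force_units(0), 0)
  # kappa = 0.05 kBT/A^2 is about 21 pN/nm at 300 K
  k_pN_per_nm <- map_force_units(0.05, 300) * 10
  expect_equal(round(k_pN_per_nm), 21)
  expect_error(map_force_units(1, -5), "invalid argument")
})

test_that("a displaced bead on a spring feels Hooke's law", {
  h <- build_ideal_helix(4)
  topo <- helix_topology(4)
  # pull spring along z with target 7 A above the attachment CA
  target <- h$CA[4, 3] + 7
  springs <- list(list(kind = "pull", residue = 4, axis = c(0, 0, 1),
                       k = 0.05, target = target))
  p0 <- energy_params(lambda_hb = 0, lambda_pp = 0, lambda_memb = 0,
                      k_bond = 0, k_angle = 0, k_tors_phi = 0,
                      k_tors_psi = 0, k_tors_omega = 0, eps_rep = 0)
  F <- compute_forces(h, topo, p0, springs = springs)
  expect_equal(unname(F[4, "CA.z"]), 0.05 * 7, tolerance = 1e-9)
  expect_equal(attr(F, "spring_energy"), 0.5 * 0.05 * 49, tolerance = 1e-9)
  # no other site feels the spring
  expect_equal(max(abs(F[1:3, ])), 0)
})

test_that("zero force at zero temperature leaves the conformation unchanged", {
  h <- build_ideal_helix(6)
  F0 <- matrix(0, 6, 9)
  out <- step_langevin(h, F0, dt = 0.01, temperature = 0, seed = 5)
  expect_equal(out$CA, h$CA, tolerance = 1e-14)
})

test_that("oversized steps abort with an instability error", {
  h <- build_ideal_helix(6)
  F <- matrix(0, 6, 9)
  F[3, 4] <- 1e5
  expect_error(step_langevin(h, F, dt = 0.01, seed = 1), "2.00 A")
})

test_that("harmonic-well positional variance satisfies equipartition", {
  k <- 1; temp <- 0.85
  x <- simulate_bead("harmonic", k = k, n_steps = 1e6, dt = 0.01,
                     temperature = temp, seed = 42, thin = 10)
  expect_equal(var(x), temp / k, tolerance = 0.05)
  expect_lt(abs(mean(x)), 0.05)
})

test_that("double-well occupancy matches the Boltzmann ratio", {
  h <- 2; tilt <- 0.2; temp <- 0.85
  U <- function(x) h * (x^2 - 1)^2 + tilt * x
  # independent oracle: energy difference between the two minima
  lo <- optimize(U, c(-2, 0))
  hi <- optimize(U, c(0, 2))
  dE <- hi$objective - lo$objective
  # split occupancy at the barrier top, not at zero (the tilt shifts it)
  top <- optimize(U, c(lo$minimum, hi$minimum), maximum = TRUE)$maximum
  x <- simulate_bead("double_well", h = h, tilt = tilt, n_steps = 4e7,
                     dt = 0.005, temperature = temp, seed = 7, thin = 40)
  ratio <- mean(x > top) / mean(x < top)
  expect_equal(ratio, exp(-dE / temp), tolerance = 0.1)
})

test_that("trajectories are reproducible and frames follow the interval", {
  sys <- build_single_helix_probe("", residues_per_helix = 8,
                                  membrane_thickness = 12, relax_iter = 50)
  prot <- pulling_protocol(n_steps = 1000, frame_interval = 100, seed = 3)
  t1 <- run_pulling(sys, prot)
  t2 <- run_pulling(sys, prot)
  expect_identical(t1$coords, t2$coords)
  expect_identical(t1$force, t2$force)
  expect_equal(t1$steps, as.integer(seq(0, 1000, by = 100)))

  t3 <- run_pulling(sys, pulling_protocol(n_steps = 1000,
                                          frame_interval = 100, seed = 4))
  expect_false(identical(t1$coords, t3$coords))
})

test_that("a soft spring at zero velocity holds extension near zero", {
  # lateral geometry: extension is the relative displacement of the two
  # spring attachment points along the pulling axis; at zero velocity it
  # fluctuates about zero (the helix breathes and tilts, so individual
  # excursions are a few Angstrom, but there is no systematic drift)
  sys <- build_single_helix_probe("", residues_per_helix = 14,
                                  membrane_thickness = 21)
  tr <- run_pulling(sys, pulling_protocol(geometry = "lateral",
                                          mode = "soft", velocity = 0,
                                          n_steps = 1e5, seed = 2))
  expect_lt(abs(mean(tr$extension)), 2)
})

test_that("a force clamp applies a constant force and extends the chain", {
  sys <- build_single_helix_probe("", residues_per_helix = 10,
                                  membrane_thickness = 15, relax_iter = 50)
  tr <- run_pulling(sys, pulling_protocol(mode = "force_clamp",
                                          clamp_force = 1.5,
                                          n_steps = 5000,
                                          frame_interval = 100, seed = 9))
  expect_true(all(tr$force == 1.5))
  expect_true(all(is.na(tr$x)))
  # 1.5 kBT/A pulls the attachment upward
  expect_gt(tail(tr$extension, 1), 2)
})

test_that("protocol validation rejects degenerate settings", {
  expect_error(pulling_protocol(n_steps = 0), "zero-length")
  expect_error(pulling_protocol(frame_interval = 0), "invalid argument")
  expect_error(pulling_protocol(k = -1), "invalid argument")
})
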