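#' Energy parameters
#'
#' Collects the strength scale factors and term parameters of the potential.
#' The three `lambda_*` factors scale whole energy groups and are the handles
#' used in perturbation experiments (e.g. doubling the H-bond term is
#' `lambda_hb = 2`); well depths are per-interaction energies in kBT.
#'
#' @param lambda_hb,lambda_pp,lambda_memb dimensionless scale factors (>= 0)
#'   for the H-bond, protein-protein (contacts + burial) and membrane terms.
#' @param eps_hb H-bond well depth, kBT.
#' @param eps_contact native-contact well depth, kBT.
#' @param eps_burial C-beta desolvation strength, kBT.
#' @param eps_burial_bb backbone desolvation strength, kBT.
#' @param nonnative_hb_scale well-depth factor for non-native H-bonds
#'   (Go-type bias; native pairs use the full `eps_hb`).
#' @param eps_unsat penalty for an unsatisfied backbone polar group buried in
#'   the membrane core, kBT.
#' @param hb_core_bonus dimensionless strengthening of satisfied H-bonds in
#'   the membrane core (fraction of `eps_hb`).
#' @param hb_geometry numeric length-2: H...O distance cutoff (Angstrom) and
#'   N-H...O angle cutoff (degrees) of the H-bond detector.  The switching
#'   function reaches zero at these values and saturates at 1 well inside
#'   them (0.8 Angstrom / 25 degrees inside).
#' @param contact_cutoff C-beta contact distance cutoff, Angstrom.
#' @param contact_well_width half-width of the native-contact well, Angstrom.
#' @param excluded_volume_diameter C-beta soft-core diameter, Angstrom.  The
#'   excluded-volume repulsion is never scaled by any lambda.
#' @param excluded_volume_diameter_ca C-alpha soft-core diameter, Angstrom.
#' @param eps_rep repulsion strength at full overlap scale, kBT.
#' @param burial_r_on,burial_r_off inner/outer knots of the smooth
#'   neighbour-count switch, Angstrom.
#' @param include_linker_membrane logical; when `FALSE`, residues with role
#'   `linker` or `tail` are excluded from the membrane energy (the
#'   linker-membrane perturbation experiment).
#' @param k_bond,k_angle backbone bond/angle spring constants (kBT/A^2, kBT).
#' @param k_tors_phi,k_tors_psi,k_tors_omega backbone torsion bias strengths,
#'   kBT.  phi/psi are biased weakly toward the helical basin; omega strongly
#'   toward trans.
#' @return An object of class `mp_energy_params` (a named list).
#' @seealso [membrane_model()], [total_energy()]
#' @export
energy_params <- function(lambda_hb = 1, lambda_pp = 1, lambda_memb = 1,
                          eps_hb = 3, eps_contact = 1.0, eps_burial = 0.5,
                          eps_burial_bb = 0.25, nonnative_hb_scale = 0.45,
                          eps_unsat = 2.5,
                          hb_core_bonus = 0.3,
                          hb_geometry = c(3.0, 120),
                          contact_cutoff = 8.0, contact_well_width = 2.0,
                          excluded_volume_diameter = 4.0,
                          excluded_volume_diameter_ca = 3.6,
                          eps_rep = 10,
                          burial_r_on = 6.5, burial_r_off = 9.5,
                          include_linker_membrane = TRUE,
                          k_bond = 30, k_angle = 25,
                          k_tors_phi = 3, k_tors_psi = 3,
                          k_tors_omega = 3) {
  stopifnot(lambda_hb >= 0, lambda_pp >= 0, lambda_memb >= 0,
            eps_hb >= 0, eps_contact >= 0, eps_burial >= 0,
            length(hb_geometry) == 2, hb_geometry[1] > 0,
            hb_geometry[2] > 0, hb_geometry[2] < 180)
  p <- list(lambda_hb = lambda_hb, lambda_pp = lambda_pp,
            lambda_memb = lambda_memb,
            eps_hb = eps_hb, eps_contact = eps_contact,
            eps_burial = eps_burial, eps_burial_bb = eps_burial_bb,
            nonnative_hb_scale = nonnative_hb_scale,
            eps_unsat = eps_unsat, hb_core_bonus = hb_core_bonus,
            hb_geometry = hb_geometry,
            contact_cutoff = contact_cutoff,
            contact_well_width = contact_well_width,
            excluded_volume_diameter = excluded_volume_diameter,
            excluded_volume_diameter_ca = excluded_volume_diameter_ca,
            eps_rep = eps_rep,
            burial_r_on = burial_r_on, burial_r_off = burial_r_off,
            include_linker_membrane = include_linker_membrane,
            k_bond = k_bond, k_angle = k_angle,
            k_tors_phi = k_tors_phi, k_tors_psi = k_tors_psi,
            k_tors_omega = k_tors_omega)
  class(p) <- "mp_energy_params"
  p
}

#' Implicit membrane model
#'
#' The bilayer is a smooth slab: every residue feels its transfer free energy
#' `dG_transfer` weighted by the depth profile
#' `f(z) = 1 / (1 + exp((|z| - thickness/2) / width))`, attenuated by a
#' shielding factor that grows with the number of protein neighbours (a
#' lipid-facing residue feels the full transfer energy, a fully shielded one
#' none).  Backbone polar groups inside the slab pay `eps_unsat` when their
#' H-bond is unsatisfied and receive a bonus when it is satisfied.
#'
#' @param thickness membrane thickness, Angstrom (> 0).
#' @param width interface width of the sigmoidal depth profile, Angstrom.
#' @param n_sat neighbour count at which burial/shielding saturates.
#' @param sat_ref H-bond strength sum treated as full satisfaction.
#' @param shield_max ceiling of the shielding factor: even a fully
#'   coordinated residue keeps `1 - shield_max` of its lipid exposure.
#' @return An object of class `mp_membrane` (a named list).
#' @export
membrane_model <- function(thickness = 31.8, width = 3, n_sat = 10,
                           sat_ref = 0.8, shield_max = 0.6) {
  stopifnot(thickness > 0, width > 0, n_sat >= 1)
  m <- list(thickness = thickness, width = width, n_sat = n_sat,
            sat_ref = sat_ref, shield_max = shield_max)
  class(m) <- "mp_membrane"
  m
}

# flatten params + membrane into the list the C++ layer expects
pack_params <- function(params, membrane, restraints = NULL, restraint_k = 10) {
  angle_deg <- params$hb_geometry[2]
  list(lambda_hb = params$lambda_hb, lambda_pp = params$lambda_pp,
       lambda_memb = params$lambda_memb,
       eps_hb = params$eps_hb, eps_contact = params$eps_contact,
       eps_burial = params$eps_burial, eps_burial_bb = params$eps_burial_bb,
       nonnative_hb_scale = params$nonnative_hb_scale,
       eps_unsat = params$eps_unsat, hb_core_bonus = params$hb_core_bonus,
       hb_dist_cutoff = params$hb_geometry[1],
       hb_dist_inner = params$hb_geometry[1] - 0.8,
       hb_cos_lo = -cos(angle_deg * pi / 180),
       hb_cos_hi = -cos(pmin(angle_deg + 35, 160) * pi / 180),
       contact_cutoff = params$contact_cutoff,
       contact_well_width = params$contact_well_width,
       excluded_volume_diameter = params$excluded_volume_diameter,
       excluded_volume_diameter_ca = params$excluded_volume_diameter_ca,
       eps_rep = params$eps_rep,
       burial_r_on = params$burial_r_on, burial_r_off = params$burial_r_off,
       n_sat = membrane$n_sat, sat_ref = membrane$sat_ref,
       shield_max = membrane$shield_max,
       membrane_thickness = membrane$thickness,
       membrane_width = membrane$width,
       include_linker_membrane = params$include_linker_membrane,
       k_bond = params$k_bond, k_angle = params$k_angle,
       k_tors_phi = params$k_tors_phi, k_tors_psi = params$k_tors_psi,
       k_tors_omega = params$k_tors_omega,
       restraints = restraints, restraint_k = restraint_k)
}

#' @export
print.mp_energy_params <- function(x, ...) {
  cat("Energy parameters (kBT units)\n")
  cat(sprintf("  lambda: hb %.2f  pp %.2f  memb %.2f\n",
              x$lambda_hb, x$lambda_pp, x$lambda_memb))
  cat(sprintf("  eps: hb %.2f  contact %.2f  burial %.2f  unsat %.2f\n",
              x$eps_hb, x$eps_contact, x$eps_burial, x$eps_unsat))
  cat(sprintf("  hb geometry: d < %.1f A, angle > %.0f deg\n",
              x$hb_geometry[1], x$hb_geometry[2]))
  cat(sprintf("  linker-membrane coupling: %s\n",
              if (x$include_linker_membrane) "on" else "off"))
  invisible(x)
}

#' @export
print.mp_membrane <- function(x, ...) {
  cat(sprintf("Implicit membrane: thickness %.1f A, interface width %.1f A, n_sat %g\n",
              x$thickness, x$width, x$n_sat))
  invisible(x)
}
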