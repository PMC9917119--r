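# energetics module: R surface over the compiled potential.

# common argument pattern: conformation, topology, params, membrane.
# The membrane defaults to the topology's thickness.
default_membrane <- function(topo, membrane) {
  if (is.null(membrane)) membrane_model(topo$membrane_thickness) else membrane
}

#' Total potential energy breakdown
#'
#' Evaluates every term of the potential and returns the per-term breakdown:
#' `hb` (directional backbone H-bonds), `sc_sc` (native side-chain contact
#' wells), `cb_burial`/`bb_burial` (multibody desolvation of side-chain and
#' backbone sites), `cb_membrane` (transfer free energy in the bilayer,
#' shielding-attenuated), `hb_membrane` (membrane modulation of backbone
#' polar groups), `bonded` (bond/angle springs and torsion bias, plus any
#' helix restraints) and `excluded_volume` (soft-core repulsion).  `bonded`
#' and `excluded_volume` are never scaled by any lambda.
#'
#' @param conf an `mp_conformation`.
#' @param topo the matching `mp_topology`.
#' @param params an [energy_params()].
#' @param membrane a [membrane_model()]; default uses the topology thickness.
#' @return named numeric of class `mp_energy_breakdown`, kBT.
#' @examples
#' sys <- build_tm_bundle(bundle_spec(n_helices = 2, residues_per_helix = 12))
#' total_energy(sys$conformation, sys$topology)
#' @export
total_energy <- function(conf, topo, params = energy_params(),
                         membrane = NULL) {
  membrane <- default_membrane(topo, membrane)
  e <- cpp_energy(conf_cpp(conf), topo_cpp(topo),
                  pack_params(params, membrane))
  structure(e$breakdown, class = "mp_energy_breakdown")
}

#' @export
print.mp_energy_breakdown <- function(x, ...) {
  cat("Energy breakdown (kBT):\n")
  v <- unclass(x)
  for (nm in names(v)) cat(sprintf("  %-16s %10.3f\n", nm, v[[nm]]))
  invisible(x)
}

energy_details <- function(conf, topo, params, membrane) {
  membrane <- default_membrane(topo, membrane)
  cpp_energy(conf_cpp(conf), topo_cpp(topo),
             pack_params(params, membrane), details = TRUE)
}

#' Hydrogen-bond energy
#'
#' Sums `-lambda_hb * eps_hb * s(geometry)` over all donor-acceptor pairs
#' passing the geometric criterion (H...O distance below the cutoff and
#' N-H...O angle above the angle cutoff), where `s` is a smooth switching
#' function equal to 1 at ideal geometry.  Detection is not restricted to
#' native pairs, so non-native H-bonds formed during unfolding count too.
#'
#' @inheritParams total_energy
#' @return list with `energy` (kBT) and `bonds`, a data.frame with 1-based
#'   `donor`, `acceptor`, geometry and per-bond energy.
#' @export
hbond_energy <- function(conf, topo, params = energy_params(),
                         membrane = NULL) {
  d <- energy_details(conf, topo, params, membrane)
  hb <- as.data.frame(d$hbonds)
  if (nrow(hb)) {
    hb$donor <- hb$donor + 1
    hb$acceptor <- hb$acceptor + 1
  }
  list(energy = unname(d$breakdown["hb"]), bonds = hb)
}

#' Side-chain contact energy
#'
#' Native inter-helix C-beta pairs contribute a smooth attractive well
#' centred at their native distance, scaled by `lambda_pp * eps_contact`;
#' all residue pairs additionally feel a soft excluded-volume repulsion that
#' is never lambda-scaled.
#'
#' @inheritParams total_energy
#' @return list with `energy` (native wells + repulsion, kBT),
#'   `native_energy`, `repulsion_energy` and per-pair data.frame `pairs`.
#' @export
contact_energy <- function(conf, topo, params = energy_params(),
                           membrane = NULL) {
  d <- energy_details(conf, topo, params, membrane)
  cm <- as.data.frame(d$contacts)
  if (nrow(cm)) { cm$i <- cm$i + 1; cm$j <- cm$j + 1 }
  list(energy = unname(d$breakdown["sc_sc"] + d$breakdown["excluded_volume"]),
       native_energy = unname(d$breakdown["sc_sc"]),
       repulsion_energy = unname(d$breakdown["excluded_volume"]),
       pairs = cm)
}

#' Burial (desolvation) energy
#'
#' Each residue contributes a smooth, saturating function of its neighbour
#' count (computed separately for the C-beta and backbone sites), scaled by
#' `lambda_pp`: burial is favourable for hydrophobic residues and
#' unfavourable for polar ones, saturating at `n_sat` neighbours.
#'
#' @inheritParams total_energy
#' @return list with `energy` and per-residue data.frame `residues`
#'   (`n_cb`, `n_bb` smooth neighbour counts and both components).
#' @export
burial_energy <- function(conf, topo, params = energy_params(),
                          membrane = NULL) {
  d <- energy_details(conf, topo, params, membrane)
  list(energy = unname(d$breakdown["cb_burial"] + d$breakdown["bb_burial"]),
       cb_burial = unname(d$breakdown["cb_burial"]),
       bb_burial = unname(d$breakdown["bb_burial"]),
       residues = as.data.frame(d$burial))
}

#' Implicit membrane energy
#'
#' `cb_membrane` applies each residue's transfer free energy through the
#' sigmoidal depth profile, attenuated by protein shielding; `hb_membrane`
#' penalizes unsatisfied backbone polar groups inside the slab and rewards
#' satisfied ones.  Residues with role `linker` or `tail` contribute nothing
#' when `include_linker_membrane` is `FALSE`.
#'
#' @inheritParams total_energy
#' @return list with `energy`, `cb_membrane`, `hb_membrane` and per-residue
#'   data.frame `residues`.
#' @export
membrane_energy <- function(conf, topo, params = energy_params(),
                            membrane = NULL) {
  d <- energy_details(conf, topo, params, membrane)
  list(energy = unname(d$breakdown["cb_membrane"] + d$breakdown["hb_membrane"]),
       cb_membrane = unname(d$breakdown["cb_membrane"]),
       hb_membrane = unname(d$breakdown["hb_membrane"]),
       residues = as.data.frame(d$membrane))
}

#' Forces on every backbone site
#'
#' Returns `-grad(total energy + spring energies)` evaluated analytically;
#' gradients through the derived H/O/C-beta sites are chain-ruled onto the
#' backbone.  Springs act only at their attachment C-alpha.
#'
#' @inheritParams total_energy
#' @param springs list of spring descriptions as built by [run_pulling()]
#'   internals; each is a list with `kind` (`"pull"`, `"anchor"` or
#'   `"clamp"`), `residue` (1-based), and `axis`/`k`/`target`/`point`/`force`
#'   as appropriate.
#' @return n x 9 matrix of force components (columns `N.x ... C.z`, kBT/A),
#'   with the energy breakdown in attribute `"breakdown"`.
#' @export
compute_forces <- function(conf, topo, params = energy_params(),
                           membrane = NULL, springs = list()) {
  membrane <- default_membrane(topo, membrane)
  sp <- lapply(springs, function(s) {
    s$residue <- as.integer(s$residue - 1)
    s
  })
  out <- cpp_forces(conf_cpp(conf), topo_cpp(topo),
                    pack_params(params, membrane), sp)
  f <- t(out$forces)
  colnames(f) <- c("N.x", "N.y", "N.z", "CA.x", "CA.y", "CA.z",
                   "C.x", "C.y", "C.z")
  attr(f, "breakdown") <- out$breakdown
  attr(f, "spring_energy") <- out$spring_energy
  f
}

#' Relax a conformation to a local energy minimum
#'
#' Adaptive gradient descent on the full potential; used by the builders to
#' remove construction strain before native contacts are measured.
#'
#' @inheritParams total_energy
#' @param max_iter maximum iterations.
#' @return list with `conformation`, `energy` and `iterations`.
#' @export
minimize_energy <- function(conf, topo, params = energy_params(),
                            membrane = NULL, max_iter = 500) {
  membrane <- default_membrane(topo, membrane)
  fit <- cpp_minimize(conf_cpp(conf), topo_cpp(topo),
                      pack_params(params, membrane), max_iter = max_iter)
  list(conformation = conf_from_cpp(fit$coords), energy = fit$energy,
       iterations = fit$iterations)
}
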