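# shared fixtures, built in code

# single-helix topology over an existing conformation (all TM leucines)
helix_topology <- function(n, thickness = 31.8) {
  res <- data.frame(index = seq_len(n), aa = "L", role = "tm", helix = 1L,
                    charge = 0, dG_transfer = -2, stringsAsFactors = FALSE)
  hel <- data.frame(start = 1L, end = as.integer(n), orientation = "up",
                    stringsAsFactors = FALSE)
  don <- if (n >= 5) 5:n else integer()
  structure(list(residues = res, helices = hel,
                 native_contacts = data.frame(i = integer(), j = integer(),
                                              d0 = numeric()),
                 native_hbonds = data.frame(donor = don, acceptor = don - 4,
                                            helix = rep(1L, length(don))),
                 membrane_thickness = thickness),
            class = "mp_topology")
}

# small two-helix bundle, memoized (used by several energy tests)
test_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- build_tm_bundle(bundle_spec(n_helices = 2,
                                            residues_per_helix = 12,
                                            linker_lengths = 3, tail = "GG",
                                            membrane_thickness = 18))
    cache
  }
})

# an extended (non-helical) chain conformation
extended_chain <- function(n) {
  env <- asNamespace("mempull")
  get("nerf_chain", env)(rep(-135, n), rep(135, n))
}

# assemble a trajectory object from a list of conformations (for testing the
# per-frame analysis operators on constructed frames)
fake_trajectory <- function(confs, topo, force = NULL, spring_energy = NULL,
                            params = energy_params(), membrane = NULL,
                            frame_interval = 100) {
  nf <- length(confs)
  n <- nrow(topo$residues)
  coords <- array(0, c(9, n, nf))
  for (f in seq_len(nf)) coords[, , f] <- t(cbind(confs[[f]]$N, confs[[f]]$CA,
                                                  confs[[f]]$C))
  if (is.null(force)) force <- rep(0, nf)
  if (is.null(spring_energy)) spring_energy <- rep(0, nf)
  if (is.null(membrane)) membrane <- membrane_model(topo$membrane_thickness)
  protocol <- pulling_protocol(n_steps = frame_interval * max(nf - 1, 1),
                               frame_interval = frame_interval)
  structure(list(steps = (seq_len(nf) - 1L) * frame_interval,
                 coords = coords, x = force / max(protocol$k, 1e-9),
                 force = force, spring_energy = spring_energy,
                 extension = seq_len(nf) - 1,
                 breakdown = matrix(0, nf, 9,
                                    dimnames = list(NULL,
                                      c("hb", "sc_sc", "cb_burial",
                                        "bb_burial", "cb_membrane",
                                        "hb_membrane", "bonded",
                                        "excluded_volume", "total"))),
                 topology = topo, protocol = protocol, params = params,
                 membrane = membrane, seed = 1L),
            class = "mp_trajectory")
}

# random small perturbation of a conformation
perturb_conf <- function(conf, sd = 0.15) {
  for (m in c("N", "CA", "C"))
    conf[[m]] <- conf[[m]] + matrix(rnorm(length(conf[[m]]), 0, sd), ncol = 3)
  conf
}
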