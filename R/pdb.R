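# PDB input/output, via bio3d.  Structures are assumed already oriented with
# the membrane normal along z and the midplane at z = 0 (as from a
# PPM-style placement); the membrane thickness is always user-supplied.

#' Write a conformation as a PDB file
#'
#' Writes ATOM records for N, CA, C plus the derived O and CB sites
#' (occupancy 1.00, B-factor 0.00).  The derived amide H is not written.
#'
#' @param conf an `mp_conformation`.
#' @param topo optional `mp_topology` supplying residue names; glycine-free
#'   default is ALA when absent.
#' @param path output file.
#' @return invisibly `path`.
#' @export
write_pdb <- function(conf, topo = NULL, path) {
  n <- n_residues(conf)
  sites <- cpp_derived_sites(conf_cpp(conf))
  aa1 <- if (!is.null(topo)) topo$residues$aa else rep("A", n)
  resid3 <- vapply(aa1, function(a) {
    r <- bio3d::aa123(a)
    if (is.na(r)) "ALA" else r
  }, character(1))
  xyz <- c(); elety <- c(); resno <- c(); resid <- c()
  for (i in seq_len(n)) {
    atoms <- list(N = conf$N[i, ], CA = conf$CA[i, ], C = conf$C[i, ])
    if (sites$has_O[i]) atoms$O <- sites$O[i, ]
    atoms$CB <- sites$CB[i, ]
    for (nm in names(atoms)) {
      xyz <- c(xyz, atoms[[nm]])
      elety <- c(elety, nm)
      resno <- c(resno, i)
      resid <- c(resid, resid3[i])
    }
  }
  na <- length(elety)
  bio3d::write.pdb(file = path, xyz = xyz, resno = resno, resid = resid,
                   elety = elety, chain = rep("A", na), o = rep(1, na),
                   b = rep(0, na))
  invisible(path)
}

#' Load a single-chain PDB structure
#'
#' Reads backbone N/CA/C atoms of a single chain, rebuilds C-beta and the
#' other derived sites from the backbone (missing side-chain atoms are
#' tolerated), annotates helices from the H-bond pattern of the input
#' conformation (a residue is helical if it participates in an i -> i-4
#' H-bond; runs of at least `min_run` residues become helices), and measures
#' the native contact and H-bond lists.
#'
#' @param path PDB file.
#' @param membrane_thickness bilayer thickness, Angstrom (from a PPM-style
#'   placement of the structure).
#' @param params energy parameters used for H-bond detection and the contact
#'   cutoff.
#' @param min_run minimum helical run length.
#' @return list with `topology` and `conformation`.
#' @export
load_pdb <- function(path, membrane_thickness, params = energy_params(),
                     min_run = 5) {
  if (membrane_thickness <= 0)
    stop("invalid argument: membrane_thickness must be > 0")
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  chains <- unique(at$chain)
  if (length(chains) > 1)
    stop("unsupported input: multiple chains (",
         paste(chains, collapse = ", "), ")")
  resno <- unique(at$resno)
  n <- length(resno)
  N <- CA <- C <- matrix(NA_real_, n, 3)
  aa <- character(n)
  for (k in seq_len(n)) {
    rows <- at[at$resno == resno[k], , drop = FALSE]
    aa3 <- rows$resid[1]
    a1 <- bio3d::aa321(aa3)
    aa[k] <- if (is.na(a1)) "A" else a1
    for (nm in c("N", "CA", "C")) {
      r <- rows[rows$elety == nm, , drop = FALSE]
      if (nrow(r) == 0)
        stop("parse error: missing backbone atom ", nm,
             " for residue ", resno[k])
      m <- switch(nm, N = "N", CA = "CA", C = "C")
      coords <- as.numeric(r[1, c("x", "y", "z")])
      if (nm == "N") N[k, ] <- coords
      if (nm == "CA") CA[k, ] <- coords
      if (nm == "C") C[k, ] <- coords
    }
  }
  conf <- new_conformation(N, CA, C)

  # helix annotation from the i -> i-4 H-bond pattern
  res0 <- residue_table(aa, rep("linker", n), rep(NA_integer_, n))
  topo0 <- new_topology(res0,
                        data.frame(start = integer(), end = integer(),
                                   orientation = character()),
                        data.frame(i = integer(), j = integer(),
                                   d0 = numeric()),
                        data.frame(donor = integer(), acceptor = integer(),
                                   helix = integer()),
                        membrane_thickness)
  membrane <- membrane_model(membrane_thickness)
  hb <- cpp_hbond_list(conf_cpp(conf), topo_cpp(topo0),
                       pack_params(params, membrane))
  helical <- rep(FALSE, n)
  if (nrow(hb)) {
    hb4 <- hb[hb[, "donor"] - hb[, "acceptor"] == 4 & hb[, "s"] >= 0.5, ,
              drop = FALSE]
    helical[hb4[, "donor"] + 1] <- TRUE
    helical[hb4[, "acceptor"] + 1] <- TRUE
  }
  r <- rle(helical)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_run
  hstart <- starts[keep]; hend <- ends[keep]
  nh <- length(hstart)
  helix_id <- rep(NA_integer_, n)
  orient <- character(nh)
  for (k in seq_len(nh)) {
    helix_id[hstart[k]:hend[k]] <- k
    orient[k] <- if (CA[hend[k], 3] >= CA[hstart[k], 3]) "up" else "down"
  }
  role <- rep("linker", n)
  role[!is.na(helix_id)] <- "tm"
  if (nh > 0) {
    if (hstart[1] > 1) role[1:(hstart[1] - 1)] <- "tail"
    if (hend[nh] < n) role[(hend[nh] + 1):n] <- "tail"
  }
  res <- residue_table(aa, role, helix_id)
  helices <- data.frame(start = hstart, end = hend, orientation = orient,
                        stringsAsFactors = FALSE)
  topo <- new_topology(res, helices,
                       measure_native_contacts(conf, helix_id,
                                               params$contact_cutoff),
                       native_hbond_table(helices), membrane_thickness)
  list(topology = topo, conformation = conf)
}
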