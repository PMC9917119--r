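# systems module: molecular data model and synthetic system builders.
#
# A conformation stores backbone N/CA/C coordinates (n x 3 matrices, Angstrom)
# in the membrane frame (midplane z = 0, normal +z).  A topology stores the
# residue table, helix annotations, native contact/H-bond lists and the
# membrane thickness.  Residue indices are 1-based and helix ranges are closed
# intervals, the native R convention.

# ideal backbone internal coordinates (Engh-Huber-like values)
.bb <- list(r_n_ca = 1.458, r_ca_c = 1.525, r_c_n = 1.329,
            a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
            phi_helix = -60, psi_helix = -47,
            phi_ext = -135, psi_ext = 135)

# default per-residue membrane transfer free energies (kBT) and charges by
# one-letter code; editable via the `hydrophobicity` argument of the builders
aa_defaults <- function() {
  dG <- c(A = -4, C = -4, F = -4, I = -4, L = -4, M = -4, V = -4, W = -4,
          G = 0.5, H = 0.5, N = 0.5, P = 0.5, Q = 0.5, S = 0.5, T = 0.5,
          Y = 0.5,
          D = 4, E = 4, K = 4, R = 4)
  charge <- c(D = -1, E = -1, K = 1, R = 1)
  list(dG = dG, charge = charge)
}

new_conformation <- function(N, CA, C) {
  stopifnot(is.matrix(N), is.matrix(CA), is.matrix(C),
            ncol(N) == 3, nrow(N) == nrow(CA), nrow(N) == nrow(C))
  dimnames(N) <- dimnames(CA) <- dimnames(C) <- NULL
  structure(list(N = N, CA = CA, C = C), class = "mp_conformation")
}

n_residues <- function(conf) nrow(conf$N)

# n x 9 coordinate matrix (rows = residues)
conf_matrix <- function(conf) cbind(conf$N, conf$CA, conf$C)

matrix_conf <- function(m) {
  new_conformation(m[, 1:3, drop = FALSE], m[, 4:6, drop = FALSE],
                   m[, 7:9, drop = FALSE])
}

# the C++ layer works on the flat residue-major layout, i.e. a 9 x n matrix
# (column-major), so the boundary transposes
conf_cpp <- function(conf) t(conf_matrix(conf))
conf_from_cpp <- function(m9) matrix_conf(t(m9))

#' Derived sites of a conformation
#'
#' Amide H, carbonyl O and the side-chain bead C-beta are pure functions of
#' the backbone: H sits on N opposite the bisector of N->CA and N->C(i-1)
#' (undefined for the first residue), O on C opposite the bisector of C->CA
#' and C->N(i+1) (undefined for the last residue), and C-beta is placed from
#' N/CA/C by the standard ideal-geometry reconstruction.
#'
#' @param conf an `mp_conformation`.
#' @return list with matrices `H`, `O`, `CB` (NA rows where undefined) and
#'   logical vectors `has_H`, `has_O`.
#' @export
derived_sites <- function(conf) {
  cpp_derived_sites(conf_cpp(conf))
}

#' Validate a conformation
#'
#' Checks that all coordinates are finite and that bonded N-CA, CA-C and
#' C-N(next) distances are within 10 percent of their ideal values.
#'
#' @param conf an `mp_conformation`.
#' @return invisibly `TRUE`; stops with a message otherwise.
#' @export
validate_conformation <- function(conf) {
  m <- conf_matrix(conf)
  if (!all(is.finite(m))) stop("conformation has non-finite coordinates")
  n <- n_residues(conf)
  d1 <- sqrt(rowSums((conf$CA - conf$N)^2))
  d2 <- sqrt(rowSums((conf$C - conf$CA)^2))
  ok1 <- abs(d1 - .bb$r_n_ca) <= 0.1 * .bb$r_n_ca
  ok2 <- abs(d2 - .bb$r_ca_c) <= 0.1 * .bb$r_ca_c
  if (!all(ok1, ok2))
    stop("backbone bond lengths deviate more than 10% from ideal at residue ",
         which(!(ok1 & ok2))[1])
  if (n > 1) {
    d3 <- sqrt(rowSums((conf$N[-1, , drop = FALSE] -
                          conf$C[-n, , drop = FALSE])^2))
    ok3 <- abs(d3 - .bb$r_c_n) <= 0.1 * .bb$r_c_n
    if (!all(ok3))
      stop("peptide bond length deviates more than 10% from ideal at residue ",
           which(!ok3)[1])
  }
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# NeRF chain building
# ---------------------------------------------------------------------------

# place atom D given A, B, C and internal coordinates (r, angle at C in
# degrees, torsion A-B-C-D in degrees)
nerf_place <- function(A, B, C, r, angle, torsion) {
  th <- angle * pi / 180
  chi <- torsion * pi / 180
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- r * c(-cos(th), sin(th) * cos(chi), sin(th) * sin(chi))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

# backbone chain from per-residue (phi, psi); omega fixed trans
nerf_chain <- function(phi, psi) {
  n <- length(phi)
  N <- CA <- C <- matrix(0, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(.bb$r_n_ca, 0, 0)
  th <- .bb$a_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + .bb$r_ca_c * c(-cos(th), sin(th), 0)
  for (i in seq_len(n - 1)) {
    N[i + 1, ] <- nerf_place(N[i, ], CA[i, ], C[i, ],
                             .bb$r_c_n, .bb$a_ca_c_n, psi[i])
    CA[i + 1, ] <- nerf_place(CA[i, ], C[i, ], N[i + 1, ],
                              .bb$r_n_ca, .bb$a_c_n_ca, 180)
    C[i + 1, ] <- nerf_place(C[i, ], N[i + 1, ], CA[i + 1, ],
                             .bb$r_ca_c, .bb$a_n_ca_c, phi[i + 1])
  }
  new_conformation(N, CA, C)
}

# extend an existing conformation by n_new residues with given (phi, psi)
nerf_extend <- function(conf, n_new, phi, psi) {
  if (n_new == 0) return(conf)
  n <- n_residues(conf)
  N <- rbind(conf$N, matrix(0, n_new, 3))
  CA <- rbind(conf$CA, matrix(0, n_new, 3))
  C <- rbind(conf$C, matrix(0, n_new, 3))
  for (k in seq_len(n_new)) {
    i <- n + k - 1
    N[i + 1, ] <- nerf_place(N[i, ], CA[i, ], C[i, ],
                             .bb$r_c_n, .bb$a_ca_c_n, psi)
    CA[i + 1, ] <- nerf_place(CA[i, ], C[i, ], N[i + 1, ],
                              .bb$r_n_ca, .bb$a_c_n_ca, 180)
    C[i + 1, ] <- nerf_place(C[i, ], N[i + 1, ], CA[i + 1, ],
                             .bb$r_ca_c, .bb$a_n_ca_c, phi)
  }
  new_conformation(N, CA, C)
}

# rotation matrix taking unit vector a to unit vector b
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (abs(c_ + 1) < 1e-12) {  # opposite: rotate pi about any perpendicular
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- p - sum(p * a) * a
    v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

transform_conf <- function(conf, R = diag(3), shift = c(0, 0, 0)) {
  tr <- function(m) sweep(m %*% t(R), 2, -shift)
  new_conformation(tr(conf$N), tr(conf$CA), tr(conf$C))
}

#' Build an ideal alpha-helix
#'
#' Constructs an ideal alpha-helical backbone (rise about 1.5 Angstrom per
#' residue, 100 degrees per turn) whose axis is aligned with `axis` and whose
#' C-alpha centroid sits at `origin`.  Residues run N to C along `axis`.
#'
#' @param n_res number of residues (>= 4).
#' @param axis direction of the helix axis (any non-zero length-3 vector).
#' @param origin C-alpha centroid position.
#' @return an `mp_conformation`.
#' @examples
#' h <- build_ideal_helix(11)
#' diff(range(h$CA[, 3]))  # about 15 Angstrom
#' @export
build_ideal_helix <- function(n_res, axis = c(0, 0, 1), origin = c(0, 0, 0)) {
  if (n_res < 4) stop("invalid argument: n_res must be >= 4")
  conf <- nerf_chain(rep(.bb$phi_helix, n_res), rep(.bb$psi_helix, n_res))
  # helix axis: leading principal component of CA, oriented N -> C
  ca <- conf$CA
  cen <- colMeans(ca)
  sv <- svd(sweep(ca, 2, cen))
  ax <- sv$v[, 1]
  if (sum(ax * (ca[n_res, ] - ca[1, ])) < 0) ax <- -ax
  R <- rotation_between(ax, axis)
  conf <- transform_conf(conf, R, shift = -as.vector(R %*% cen))
  transform_conf(conf, diag(3), shift = origin)
}

# ---------------------------------------------------------------------------
# bundle specification and builders
# ---------------------------------------------------------------------------

#' Specify a synthetic transmembrane bundle
#'
#' Parameterizes an idealized N-helix up-down bundle: helices on a regular
#' lateral grid spanning the membrane, consecutive helices antiparallel and
#' joined by surface linkers, an optional tail at the pulled (C-terminal)
#' end.  The pulled terminus is always on the +z side, so the C-terminal
#' helix points up and orientations alternate backwards from it.
#'
#' @param n_helices number of transmembrane helices (>= 1).
#' @param residues_per_helix residues in each helix.
#' @param linker_lengths integer vector (length `n_helices - 1`) of linker
#'   lengths; a scalar is recycled.
#' @param linker_charges `NULL` or a data.frame with columns `linker`
#'   (1-based linker index), `offset` (1-based position within the linker)
#'   and `charge` (+1 or -1); charged positions become Lys/Asp.
#' @param tail one-letter residue string appended after the last helix at the
#'   pulled terminus (default five glycines); `""` for no tail.
#' @param helix_aa,linker_aa one-letter codes used for helix core and linker
#'   residues.
#' @param cap_aa,cap_length each helix carries `cap_length` residues of
#'   `cap_aa` at both ends (default two lysines).  The polar/charged caps
#'   anchor the helix termini at the two membrane surfaces, as the charged
#'   flanks of natural transmembrane helices do; without them an idealized
#'   all-hydrophobic helix prefers to lie flat in the bilayer midplane.
#' @param membrane_thickness bilayer thickness, Angstrom.
#' @param spacing lateral grid spacing between helix axes, Angstrom.
#' @param hydrophobicity optional named numeric vector overriding the default
#'   per-residue transfer free energies (kBT, negative = hydrophobic).
#' @return a `mp_bundle_spec` list.
#' @seealso [build_tm_bundle()], [br_bundle_spec()], [glpg_bundle_spec()]
#' @export
bundle_spec <- function(n_helices = 4, residues_per_helix = 20,
                        linker_lengths = 4, linker_charges = NULL,
                        tail = "GGGGG", helix_aa = "L", linker_aa = "G",
                        cap_aa = "K", cap_length = 2,
                        membrane_thickness = 31.8, spacing = 10,
                        hydrophobicity = NULL) {
  if (n_helices < 1) stop("invalid argument: n_helices must be >= 1")
  if (2 * cap_length >= residues_per_helix)
    stop("invalid argument: caps longer than the helix")
  if (length(linker_lengths) == 1)
    linker_lengths <- rep(linker_lengths, max(n_helices - 1, 0))
  if (length(linker_lengths) != max(n_helices - 1, 0))
    stop("invalid argument: linker_lengths must have n_helices - 1 entries")
  if (any(linker_lengths < 0)) stop("invalid argument: linker lengths must be >= 0")
  if (!is.null(linker_charges)) {
    stopifnot(is.data.frame(linker_charges),
              all(c("linker", "offset", "charge") %in% names(linker_charges)))
    if (any(linker_charges$linker > n_helices - 1) ||
        any(linker_charges$offset > linker_lengths[linker_charges$linker]))
      stop("invalid argument: linker_charges outside linker ranges")
  }
  if (membrane_thickness <= 0) stop("invalid argument: membrane_thickness must be > 0")
  structure(list(n_helices = n_helices,
                 residues_per_helix = residues_per_helix,
                 linker_lengths = linker_lengths,
                 linker_charges = linker_charges,
                 tail = tail, helix_aa = helix_aa, linker_aa = linker_aa,
                 cap_aa = cap_aa, cap_length = cap_length,
                 membrane_thickness = membrane_thickness, spacing = spacing,
                 hydrophobicity = hydrophobicity),
            class = "mp_bundle_spec")
}

#' Bacteriorhodopsin-like bundle preset
#'
#' Seven transmembrane helices with five positive charges distributed among
#' the linkers and the membrane thickness of a bR-type bundle (31.8 A).
#' @param residues_per_helix residues per helix.
#' @return a `mp_bundle_spec`.
#' @export
br_bundle_spec <- function(residues_per_helix = 20) {
  bundle_spec(n_helices = 7, residues_per_helix = residues_per_helix,
              linker_lengths = 4,
              linker_charges = data.frame(linker = 1:5, offset = 2,
                                          charge = 1),
              membrane_thickness = 31.8)
}

#' GlpG-like bundle preset
#'
#' Six transmembrane helices at the membrane thickness of a GlpG-type bundle
#' (28.6 A); used for lateral pulling experiments.
#' @param residues_per_helix residues per helix.
#' @return a `mp_bundle_spec`.
#' @export
glpg_bundle_spec <- function(residues_per_helix = 20) {
  bundle_spec(n_helices = 6, residues_per_helix = residues_per_helix,
              linker_lengths = 4, membrane_thickness = 28.6)
}

# serpentine grid positions for n helices, spacing s: two rows for n >= 4
grid_positions <- function(n, s) {
  rows <- if (n >= 4) 2 else 1
  cols <- ceiling(n / rows)
  pos <- matrix(0, n, 2)
  for (k in seq_len(n)) {
    r <- (k - 1) %/% cols
    cidx <- (k - 1) %% cols
    if (r %% 2 == 1) cidx <- cols - 1 - cidx  # serpentine
    pos[k, ] <- c(cidx * s, r * s)
  }
  pos
}

# quadratic Bezier utilities for linker placement
bezier_points <- function(p0, p1, p2, t) {
  outer((1 - t)^2, p0) + outer(2 * t * (1 - t), p1) + outer(t^2, p2)
}

bezier_arclength <- function(p0, p1, p2, n = 200) {
  pts <- bezier_points(p0, p1, p2, seq(0, 1, length.out = n))
  sum(sqrt(rowSums(diff(pts)^2)))
}

# place n_atoms points along a Bezier arc at given cumulative fractions
bezier_at_fractions <- function(p0, p1, p2, fr, n = 400) {
  t <- seq(0, 1, length.out = n)
  pts <- bezier_points(p0, p1, p2, t)
  cl <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  cl <- cl / cl[length(cl)]
  ti <- approx(cl, t, xout = fr, rule = 2)$y
  bezier_points(p0, p1, p2, ti)
}

# build linker backbone atoms between attachment atoms a0 (C of previous
# residue) and a1 (N of next residue); returns L x 9 matrix (may be 0-row).
# CA sites ride on a Bezier arc bulging away from the membrane; N and C are
# offset perpendicular to the local tangent so that backbone angles come out
# near tetrahedral instead of collinear (collinear angles make the derived
# carbonyl-O direction ill-defined).
build_linker <- function(a0, a1, L, z_side) {
  if (L == 0) return(matrix(0, 0, 9))
  along <- 1.23; perp <- 0.85                   # local in-residue geometry
  arc_step <- c(along, along, .bb$r_c_n)        # N->CA, CA->C, C->N(next)
  arc_pos <- c(1.02, rep(arc_step, L))          # from a0 (a C atom; the
  arc_pos <- cumsum(arc_pos)[seq_len(3 * L + 1)]  # junction atoms carry a
  # shorter arc gap because only one of the two is offset off-curve
  arc_pos[3 * L + 1] <- arc_pos[3 * L] + 1.02
  target <- arc_pos[3 * L + 1]                  # arc length C(prev) -> N(next)
  dvec <- a1 - a0
  D <- sqrt(sum(dvec^2))
  mid <- (a0 + a1) / 2
  f <- function(h) bezier_arclength(a0, mid + c(0, 0, z_side * h), a1) - target
  h <- if (target <= D) 0 else uniroot(f, c(0, 60))$root
  ctrl <- mid + c(0, 0, z_side * h)
  fr <- arc_pos / target
  fr <- pmin(fr[-length(fr)], 1)                # interior atoms (3L of them)
  ats <- bezier_at_fractions(a0, ctrl, a1, fr)
  # local tangents for the perpendicular offsets
  eps <- 0.01
  ats2 <- bezier_at_fractions(a0, ctrl, a1, pmin(fr + eps, 1))
  tans <- ats2 - ats
  tans <- tans / pmax(sqrt(rowSums(tans^2)), 1e-9)
  out <- matrix(0, L, 9)
  for (k in seq_len(L)) {
    for (atom in 1:3) {                          # N, CA, C
      row <- 3 * (k - 1) + atom
      t <- tans[row, ]
      w <- c(0, 0, z_side)
      nrm <- w - sum(w * t) * t
      if (sum(nrm^2) < 1e-6) nrm <- c(1, 0, 0) - sum(c(1, 0, 0) * t) * t
      nrm <- nrm / sqrt(sum(nrm^2))
      off <- if (atom == 2) 0 else perp          # N and C off-curve, CA on it
      out[k, (3 * atom - 2):(3 * atom)] <- ats[row, ] + off * nrm
    }
  }
  out
}

# assemble residue bookkeeping for a bundle/probe
residue_table <- function(aa, role, helix, hydro_override = NULL) {
  tab <- aa_defaults()
  dG <- unname(tab$dG[aa])
  dG[is.na(dG)] <- 0.5
  if (!is.null(hydro_override)) {
    idx <- aa %in% names(hydro_override)
    dG[idx] <- unname(hydro_override[aa[idx]])
  }
  # TM helix residues use the hydrophobic default unless explicitly charged
  charge <- unname(ifelse(aa %in% names(tab$charge), tab$charge[aa], 0))
  data.frame(index = seq_along(aa), aa = aa, role = role, helix = helix,
             charge = charge, dG_transfer = dG, stringsAsFactors = FALSE)
}

new_topology <- function(residues, helices, native_contacts, native_hbonds,
                         membrane_thickness) {
  structure(list(residues = residues, helices = helices,
                 native_contacts = native_contacts,
                 native_hbonds = native_hbonds,
                 membrane_thickness = membrane_thickness),
            class = "mp_topology")
}

# topology list for the C++ layer (0-based indices)
topo_cpp <- function(topo) {
  res <- topo$residues
  role_code <- match(res$role, c("tm", "linker", "tail")) - 1L
  helix <- res$helix
  helix[is.na(helix)] <- 0L
  helix <- as.integer(helix) - 1L
  helix[is.na(res$helix)] <- -1L
  nc <- topo$native_contacts
  cm <- if (is.null(nc) || nrow(nc) == 0) matrix(0, 0, 3) else
    cbind(nc$i - 1, nc$j - 1, nc$d0)
  hb <- topo$native_hbonds
  hm <- if (is.null(hb) || nrow(hb) == 0)
    matrix(0L, 0, 2) else cbind(as.integer(hb$donor - 1),
                                as.integer(hb$acceptor - 1))
  list(n = nrow(res), role = as.integer(role_code), helix = helix,
       dG = res$dG_transfer, contacts = cm, hbonds = hm)
}

helices_cpp <- function(topo) {
  h <- topo$helices
  cbind(as.integer(h$start - 1L), as.integer(h$end - 1L))
}

#' @export
print.mp_topology <- function(x, ...) {
  cat(sprintf("System topology: %d residues, %d helices, thickness %.1f A\n",
              nrow(x$residues), nrow(x$helices), x$membrane_thickness))
  cat(sprintf("  native contacts: %d, native H-bonds: %d\n",
              nrow(x$native_contacts), nrow(x$native_hbonds)))
  for (k in seq_len(nrow(x$helices)))
    cat(sprintf("  helix %d: residues %d-%d (%s)\n", k, x$helices$start[k],
                x$helices$end[k], x$helices$orientation[k]))
  invisible(x)
}

#' @export
print.mp_conformation <- function(x, ...) {
  cat(sprintf("Conformation: %d residues (N/CA/C backbone sites)\n",
              n_residues(x)))
  invisible(x)
}

# native inter-helix CB contacts measured on a conformation
measure_native_contacts <- function(conf, helix_id, cutoff) {
  cb <- cpp_derived_sites(conf_cpp(conf))$CB
  n <- nrow(cb)
  idx <- which(!is.na(helix_id))
  out <- list()
  for (a in seq_along(idx)) {
    i <- idx[a]
    for (b in seq_along(idx)) {
      j <- idx[b]
      if (j <= i || helix_id[i] == helix_id[j]) next
      d <- sqrt(sum((cb[i, ] - cb[j, ])^2))
      if (d <= cutoff) out[[length(out) + 1]] <- c(i, j, d)
    }
  }
  if (!length(out))
    return(data.frame(i = integer(), j = integer(), d0 = numeric()))
  m <- do.call(rbind, out)
  data.frame(i = m[, 1], j = m[, 2], d0 = m[, 3])
}

native_hbond_table <- function(helices) {
  out <- list()
  for (k in seq_len(nrow(helices))) {
    a <- helices$start[k]; b <- helices$end[k]
    if (b - a + 1 >= 5) {
      don <- (a + 4):b
      out[[k]] <- data.frame(donor = don, acceptor = don - 4, helix = k)
    }
  }
  if (!length(out))
    return(data.frame(donor = integer(), acceptor = integer(),
                      helix = integer()))
  do.call(rbind, out)
}

#' Build a synthetic transmembrane bundle
#'
#' Places ideal helices on a regular lateral grid spanning the membrane with
#' alternating up/down orientation, joins them with surface linkers, appends
#' the tail, relaxes the assembly to a local energy minimum, and measures the
#' native contact and H-bond lists on the relaxed structure.
#'
#' @param spec a [bundle_spec()].
#' @param params,membrane energy model used for the relaxation; defaults are
#'   [energy_params()] and a membrane at the bundle's stated thickness.
#' @param relax_iter minimization iterations (0 to skip relaxation).
#' @return list with elements `topology` (`mp_topology`) and `conformation`
#'   (`mp_conformation`).
#' @examples
#' sys <- build_tm_bundle(bundle_spec(n_helices = 2, residues_per_helix = 12))
#' sys$topology
#' @export
build_tm_bundle <- function(spec, params = energy_params(),
                            membrane = membrane_model(spec$membrane_thickness),
                            relax_iter = 400) {
  stopifnot(inherits(spec, "mp_bundle_spec"))
  nh <- spec$n_helices
  npr <- spec$residues_per_helix
  pos <- grid_positions(nh, spec$spacing)
  # C-terminal helix points up; alternate backwards from it
  orient <- ifelse((nh - seq_len(nh)) %% 2 == 0, "up", "down")
  helix_confs <- lapply(seq_len(nh), function(k) {
    ax <- if (orient[k] == "up") c(0, 0, 1) else c(0, 0, -1)
    build_ideal_helix(npr, axis = ax, origin = c(pos[k, 1], pos[k, 2], 0))
  })
  tail_seq <- if (nzchar(spec$tail)) strsplit(spec$tail, "")[[1]] else character()

  # assemble chain: helix 1, linker 1, helix 2, ..., tail
  aa <- character(); role <- character(); helix_id <- integer()
  coords <- matrix(0, 0, 9)
  hstart <- integer(nh); hend <- integer(nh)
  for (k in seq_len(nh)) {
    hstart[k] <- nrow(coords) + 1L
    coords <- rbind(coords, conf_matrix(helix_confs[[k]]))
    hend[k] <- nrow(coords)
    cl <- spec$cap_length
    haa <- c(rep(spec$cap_aa, cl), rep(spec$helix_aa, npr - 2 * cl),
             rep(spec$cap_aa, cl))
    aa <- c(aa, haa)
    role <- c(role, rep("tm", npr))
    helix_id <- c(helix_id, rep(k, npr))
    if (k < nh) {
      L <- spec$linker_lengths[k]
      laa <- rep(spec$linker_aa, L)
      if (!is.null(spec$linker_charges)) {
        lc <- spec$linker_charges[spec$linker_charges$linker == k, , drop = FALSE]
        if (nrow(lc))
          laa[lc$offset] <- ifelse(lc$charge > 0, "K", "D")
      }
      a0 <- coords[nrow(coords), 7:9]                 # C of last helix residue
      a1 <- helix_confs[[k + 1]]$N[1, ]               # N of next helix start
      z_side <- if (a0[3] + a1[3] > 0) 1 else -1
      lk <- build_linker(a0, a1, L, z_side)
      coords <- rbind(coords, lk)
      aa <- c(aa, laa)
      role <- c(role, rep("linker", L))
      helix_id <- c(helix_id, rep(NA_integer_, L))
    }
  }
  conf <- matrix_conf(coords)
  if (length(tail_seq)) {
    conf <- nerf_extend(conf, length(tail_seq), .bb$phi_ext, .bb$psi_ext)
    aa <- c(aa, tail_seq)
    role <- c(role, rep("tail", length(tail_seq)))
    helix_id <- c(helix_id, rep(NA_integer_, length(tail_seq)))
  }

  res <- residue_table(aa, role, helix_id, spec$hydrophobicity)
  helices <- data.frame(start = hstart, end = hend, orientation = orient)
  topo <- new_topology(res, helices,
                       data.frame(i = integer(), j = integer(), d0 = numeric()),
                       native_hbond_table(helices),
                       spec$membrane_thickness)
  if (relax_iter > 0) {
    pk <- pack_params(params, membrane)
    fit <- cpp_minimize(conf_cpp(conf), topo_cpp(topo), pk,
                        max_iter = relax_iter)
    conf <- conf_from_cpp(fit$coords)
  }
  topo$native_contacts <- measure_native_contacts(conf, res$helix,
                                                  params$contact_cutoff)
  list(topology = topo, conformation = conf)
}

#' Build a single-helix probe
#'
#' One transmembrane helix centred in the bilayer with a tail extended on the
#' pulled (+z) side, outside the membrane slab.  The preset tails are the
#' neutral `(Gly)5` and the +3e `(Arg)3(Gly)2`.
#'
#' @param tail `"G5"`, `"R3G2"`, or a custom one-letter string (may be `""`).
#' @param residues_per_helix helix length.
#' @param membrane_thickness bilayer thickness, Angstrom.
#' @param helix_aa,cap_aa,cap_length helix composition as in [bundle_spec()].
#' @param hydrophobicity optional named dG override, as in [bundle_spec()].
#' @param params,membrane energy model for relaxation.
#' @param relax_iter minimization iterations.
#' @return list with `topology` and `conformation`.
#' @export
build_single_helix_probe <- function(tail = c("G5", "R3G2"),
                                     residues_per_helix = 20,
                                     membrane_thickness = 31.8,
                                     helix_aa = "L", cap_aa = "K",
                                     cap_length = 2, hydrophobicity = NULL,
                                     params = energy_params(),
                                     membrane = membrane_model(membrane_thickness),
                                     relax_iter = 200) {
  if (length(tail) > 1) tail <- tail[1]
  tail_seq <- switch(tail,
                     G5 = rep("G", 5),
                     R3G2 = c("R", "R", "R", "G", "G"),
                     if (nzchar(tail)) strsplit(tail, "")[[1]] else character())
  npr <- residues_per_helix
  conf <- build_ideal_helix(npr, axis = c(0, 0, 1), origin = c(0, 0, 0))
  if (length(tail_seq))
    conf <- nerf_extend(conf, length(tail_seq), .bb$phi_ext, .bb$psi_ext)
  haa <- c(rep(cap_aa, cap_length), rep(helix_aa, npr - 2 * cap_length),
           rep(cap_aa, cap_length))
  aa <- c(haa, tail_seq)
  role <- c(rep("tm", npr), rep("tail", length(tail_seq)))
  helix_id <- c(rep(1L, npr), rep(NA_integer_, length(tail_seq)))
  res <- residue_table(aa, role, helix_id, hydrophobicity)
  helices <- data.frame(start = 1L, end = npr, orientation = "up")
  topo <- new_topology(res, helices,
                       data.frame(i = integer(), j = integer(), d0 = numeric()),
                       native_hbond_table(helices), membrane_thickness)
  if (relax_iter > 0) {
    pk <- pack_params(params, membrane)
    fit <- cpp_minimize(conf_cpp(conf), topo_cpp(topo), pk,
                        max_iter = relax_iter)
    conf <- conf_from_cpp(fit$coords)
  }
  list(topology = topo, conformation = conf)
}
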