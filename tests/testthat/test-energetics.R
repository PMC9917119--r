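# energy terms: values, scaling, symmetries, gradients

test_that("H-bond energy counts the helical ladder and scales with lambda", {
  n <- 12
  h <- build_ideal_helix(n)
  topo <- helix_topology(n)
  p1 <- energy_params()
  hb1 <- hbond_energy(h, topo, p1)
  expect_equal(nrow(hb1$bonds), 8)
  expect_equal(hb1$energy, -8 * p1$eps_hb, tolerance = 0.05)

  p_half <- energy_params(lambda_hb = 0.5)
  hb_half <- hbond_energy(h, topo, p_half)
  expect_equal(hb_half$energy, hb1$energy / 2, tolerance = 1e-12)

  ext <- extended_chain(10)
  hb0 <- hbond_energy(ext, helix_topology(10))
  expect_equal(nrow(hb0$bonds), 0)
  expect_equal(hb0$energy, 0)
})

test_that("contact wells sit at their native minima and have finite range", {
  sys <- test_bundle()
  p <- energy_params()
  ce <- contact_energy(sys$conformation, sys$topology, p)
  nn <- nrow(sys$topology$native_contacts)
  expect_equal(ce$native_energy, -p$lambda_pp * p$eps_contact * nn,
               tolerance = 1e-9)
  # translate helix 2 far away laterally: its wells empty out
  conf2 <- sys$conformation
  h2 <- with(sys$topology$helices, start[2]:end[2])
  for (m in c("N", "CA", "C")) conf2[[m]][h2, 1] <- conf2[[m]][h2, 1] + 100
  ce2 <- contact_energy(conf2, sys$topology, p)
  expect_equal(ce2$native_energy, 0, tolerance = 1e-9)
})

test_that("excluded volume repulsion is never lambda-scaled", {
  # two residues with CB at half the soft-core diameter
  h <- build_ideal_helix(6)
  conf <- h
  # move residue 5 on top of residue 1 laterally
  shift <- conf$CA[1, ] - conf$CA[5, ] + c(2, 0, 0)
  for (m in c("N", "CA", "C")) conf[[m]][5:6, ] <-
    sweep(conf[[m]][5:6, , drop = FALSE], 2, -shift)
  p0 <- energy_params(lambda_hb = 0, lambda_pp = 0, lambda_memb = 0)
  ce <- contact_energy(conf, helix_topology(6), p0)
  expect_gt(ce$repulsion_energy, 0)
})

test_that("burial saturates smoothly and matches brute-force counting", {
  p <- energy_params()
  m <- membrane_model(31.8)
  # isolated residue: no neighbours, no burial
  h1 <- build_ideal_helix(4)
  topo1 <- structure(list(
    residues = data.frame(index = 1:4, aa = "L", role = "tm", helix = 1L,
                          charge = 0, dG_transfer = -2),
    helices = data.frame(start = 1L, end = 4L, orientation = "up"),
    native_contacts = data.frame(i = integer(), j = integer(), d0 = numeric()),
    native_hbonds = data.frame(donor = integer(), acceptor = integer(),
                               helix = integer()),
    membrane_thickness = 31.8), class = "mp_topology")
  be <- burial_energy(h1, topo1, p, m)
  # a 4-residue fragment has few in-range neighbours (|i-j| >= 2 only)
  expect_true(all(be$residues$n_cb < m$n_sat))

  # brute-force oracle on a small bundle: recompute the smooth neighbour
  # counts with an O(n^2) scan in R
  sys <- test_bundle()
  bd <- burial_energy(sys$conformation, sys$topology, p, m)
  cb <- derived_sites(sys$conformation)$CB
  n <- nrow(cb)
  sstep <- function(t) ifelse(t <= 0, 0, ifelse(t >= 1, 1, t^2 * (3 - 2 * t)))
  swd <- function(d) sstep((p$burial_r_off - d) / (p$burial_r_off - p$burial_r_on))
  ncb <- numeric(n)
  for (i in 1:n) for (j in 1:n)
    if (abs(i - j) >= 2)
      ncb[i] <- ncb[i] + swd(sqrt(sum((cb[i, ] - cb[j, ])^2)))
  expect_equal(bd$residues$n_cb, ncb, tolerance = 1e-9)
  # saturated residues contribute exactly the saturated value
  sat <- which(ncb >= m$n_sat)
  if (length(sat)) {
    sgn <- sign(sys$topology$residues$dG_transfer[sat])
    expect_equal(bd$residues$e_cb_burial[sat],
                 p$lambda_pp * p$eps_burial * sgn, tolerance = 1e-9)
  }
})

test_that("membrane energy follows the depth profile and role exclusion", {
  p <- energy_params()
  n <- 12
  h <- build_ideal_helix(n, axis = c(1, 0, 0))    # lies along x at z = 0
  topo <- helix_topology(n)
  m_thin <- membrane_model(31.8, width = 0.5)     # near-step profile
  me <- membrane_energy(h, topo, p, m_thin)
  # fully exposed hydrophobic residues near z = 0: about dG each
  expect_equal(me$residues$fz, rep(1, n), tolerance = 1e-3)
  # shift far outside the slab (10 interface widths): contribution vanishes
  h_out <- h
  for (mm in c("N", "CA", "C")) h_out[[mm]][, 3] <- h_out[[mm]][, 3] + 31.8 / 2 + 10
  me_out <- membrane_energy(h_out, topo, p, m_thin)
  expect_equal(me_out$cb_membrane, 0, tolerance = 1e-3)

  # linker/tail residues drop out when include_linker_membrane = FALSE
  topo_l <- topo
  topo_l$residues$role <- "linker"
  topo_l$helices <- topo_l$helices[0, ]
  topo_l$native_hbonds <- topo_l$native_hbonds[0, ]
  p_off <- energy_params(include_linker_membrane = FALSE)
  me_off <- membrane_energy(h, topo_l, p_off, m_thin)
  expect_equal(me_off$energy, 0, tolerance = 1e-12)
})

test_that("the breakdown sums to the total and is exactly linear in lambda", {
  sys <- test_bundle()
  conf <- sys$conformation
  topo <- sys$topology
  m <- membrane_model(topo$membrane_thickness)

  e1 <- total_energy(conf, topo, energy_params(), m)
  expect_equal(unname(e1["total"]),
               sum(e1[setdiff(names(e1), "total")]), tolerance = 1e-9)

  # E(lambda_hb = 2) - E(lambda_hb = 1) equals the lambda = 1 hb component
  e2 <- total_energy(conf, topo, energy_params(lambda_hb = 2), m)
  expect_equal(unname(e2["total"] - e1["total"]), unname(e1["hb"]),
               tolerance = 1e-9)

  # each scaled component is proportional to its lambda
  for (lam in c(0.25, 0.75, 2)) {
    eh <- total_energy(conf, topo, energy_params(lambda_hb = lam), m)
    expect_equal(unname(eh["hb"]), lam * unname(e1["hb"]), tolerance = 1e-9)
    ep <- total_energy(conf, topo, energy_params(lambda_pp = lam), m)
    expect_equal(unname(ep["sc_sc"]), lam * unname(e1["sc_sc"]),
                 tolerance = 1e-9)
    em <- total_energy(conf, topo, energy_params(lambda_memb = lam), m)
    expect_equal(unname(em["cb_membrane"]), lam * unname(e1["cb_membrane"]),
                 tolerance = 1e-9)
    expect_equal(unname(em["hb_membrane"]), lam * unname(e1["hb_membrane"]),
                 tolerance = 1e-9)
  }

  # all lambdas zero: only bonded + excluded volume remain
  e0 <- total_energy(conf, topo,
                     energy_params(lambda_hb = 0, lambda_pp = 0,
                                   lambda_memb = 0), m)
  expect_equal(unname(e0["total"]),
               unname(e0["bonded"] + e0["excluded_volume"]), tolerance = 1e-9)
})

test_that("energies are invariant under xy-translation and z-mirror", {
  sys <- test_bundle()
  topo <- sys$topology
  m <- membrane_model(topo$membrane_thickness)
  conf <- sys$conformation
  e0 <- total_energy(conf, topo, membrane = m)

  shift_conf <- function(conf, d) {
    for (mm in c("N", "CA", "C")) conf[[mm]] <- sweep(conf[[mm]], 2, -d)
    conf
  }
  e_xy <- total_energy(shift_conf(conf, c(13.7, -4.2, 0)), topo, membrane = m)
  expect_equal(unclass(e_xy), unclass(e0), tolerance = 1e-9)

  # z-translation changes only the membrane terms
  e_z <- total_energy(shift_conf(conf, c(0, 0, 4)), topo, membrane = m)
  for (term in c("hb", "sc_sc", "cb_burial", "bb_burial", "bonded",
                 "excluded_volume"))
    expect_equal(unname(e_z[term]), unname(e0[term]), tolerance = 1e-9)
  expect_false(isTRUE(all.equal(unname(e_z["cb_membrane"]),
                                unname(e0["cb_membrane"]))))

  # flipping the protein upside-down (proper rotation by pi about x, which
  # maps z to -z) leaves every term unchanged: the slab is symmetric.  A
  # bare z-reflection is not used because it inverts chirality.
  conf_m <- conf
  for (mm in c("N", "CA", "C")) {
    conf_m[[mm]][, 2] <- -conf_m[[mm]][, 2]
    conf_m[[mm]][, 3] <- -conf_m[[mm]][, 3]
  }
  e_m <- total_energy(conf_m, topo, membrane = m)
  expect_equal(unclass(e_m), unclass(e0), tolerance = 1e-9)
})

test_that("analytic forces match central finite differences", {
  set.seed(11)
  sys <- test_bundle()
  topo <- sys$topology
  m <- membrane_model(topo$membrane_thickness)
  p <- energy_params()
  conf <- perturb_conf(sys$conformation, 0.15)
  F <- compute_forces(conf, topo, p, m)
  E <- function(cf) unname(total_energy(cf, topo, p, m)["total"])
  h <- 1e-5
  n <- nrow(conf$N)
  idx <- expand.grid(i = seq_len(n), s = 1:3, c = 1:3)
  idx <- idx[sample(nrow(idx), 60), ]
  for (r in seq_len(nrow(idx))) {
    i <- idx$i[r]; s <- idx$s[r]; cc <- idx$c[r]
    site <- c("N", "CA", "C")[s]
    cp <- conf; cm <- conf
    cp[[site]][i, cc] <- cp[[site]][i, cc] + h
    cm[[site]][i, cc] <- cm[[site]][i, cc] - h
    fd <- -(E(cp) - E(cm)) / (2 * h)
    an <- F[i, (s - 1) * 3 + cc]
    expect_lt(abs(fd - an) / max(abs(fd), abs(an), 1e-4), 1e-4)
  }
})

test_that("the built bundle is a local energy minimum", {
  set.seed(21)
  sys <- test_bundle()
  topo <- sys$topology
  m <- membrane_model(topo$membrane_thickness)
  e0 <- unname(total_energy(sys$conformation, topo, membrane = m)["total"])
  worse <- 0
  for (k in 1:100) {
    cf <- sys$conformation
    for (mm in c("N", "CA", "C")) {
      d <- matrix(rnorm(length(cf[[mm]])), ncol = 3)
      d <- d / sqrt(rowSums(d^2)) * 0.5
      cf[[mm]] <- cf[[mm]] + d
    }
    if (unname(total_energy(cf, topo, membrane = m)["total"]) > e0)
      worse <- worse + 1
  }
  expect_equal(worse, 100)
})
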