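# system builders: ideal helices, bundles, probes, derived sites, PDB I/O

test_that("ideal helix has the canonical rise and H-bond ladder", {
  h <- build_ideal_helix(11, axis = c(0, 0, 1))
  expect_lt(abs((h$CA[11, 3] - h$CA[1, 3]) - 15.0), 0.5)

  h12 <- build_ideal_helix(12)
  topo <- helix_topology(12)
  hb <- hbond_energy(h12, topo)
  expect_equal(nrow(hb$bonds), 8)
  expect_true(all(hb$bonds$donor - hb$bonds$acceptor == 4))

  # mirror symmetry: building along -z negates the NH projection
  up <- build_ideal_helix(12, axis = c(0, 0, 1))
  dn <- build_ideal_helix(12, axis = c(0, 0, -1))
  nh_z <- function(conf) {
    s <- derived_sites(conf)
    v <- conf$N[-1, ] - s$H[-1, ]
    mean(v[, 3] / sqrt(rowSums(v^2)))
  }
  expect_equal(nh_z(up), -nh_z(dn), tolerance = 1e-6)
  expect_gt(nh_z(up), 0.85)

  expect_error(build_ideal_helix(3), "invalid argument")
})

test_that("helix H-bond count is n - 4 across lengths", {
  for (n in c(5, 9, 17, 33, 50)) {
    h <- build_ideal_helix(n)
    hb <- hbond_energy(h, helix_topology(n))
    native <- hb$bonds[hb$bonds$donor - hb$bonds$acceptor == 4, ]
    expect_equal(nrow(native), n - 4)
    expect_true(all(native$s > 0.99))
  }
})

test_that("bundles alternate orientation ending up at the pulled side", {
  spec7 <- bundle_spec(n_helices = 7, residues_per_helix = 12,
                       linker_lengths = 3, tail = "")
  sys <- build_tm_bundle(spec7, relax_iter = 0)
  expect_identical(sys$topology$helices$orientation,
                   c("up", "down", "up", "down", "up", "down", "up"))
  # 4 helices: C-terminal helix still points up
  sys4 <- test_bundle()
  orients <- sys4$topology$helices$orientation
  expect_identical(orients[length(orients)], "up")
})

test_that("native contacts are inter-helix, symmetric-free and clash-free", {
  sys <- test_bundle()
  topo <- sys$topology
  nc <- topo$native_contacts
  expect_gt(nrow(nc), 0)
  expect_true(all(nc$i < nc$j))                       # no duplicates/self
  hx <- topo$residues$helix
  expect_true(all(hx[nc$i] != hx[nc$j]))              # inter-helix only
  expect_true(all(!is.na(hx[nc$i])))
  # clash-free: no CB pair below the excluded-volume diameter
  cb <- derived_sites(sys$conformation)$CB
  d <- as.matrix(dist(cb))
  diag(d) <- Inf
  n <- nrow(cb)
  near_diag <- abs(row(d) - col(d)) < 2
  expect_gt(min(d[!near_diag]), energy_params()$excluded_volume_diameter)
})

test_that("bR-like preset distributes five positive linker charges", {
  spec <- br_bundle_spec()
  sys <- build_tm_bundle(spec, relax_iter = 0)
  res <- sys$topology$residues
  linker_charge <- sum(abs(res$charge[res$role == "linker"]))
  expect_equal(linker_charge, 5)
  expect_equal(sys$topology$membrane_thickness, 31.8)
  expect_equal(nrow(sys$topology$helices), 7)
  # TM CA inside the slab at construction
  tm <- res$role == "tm"
  expect_true(all(abs(sys$conformation$CA[tm, 3]) <= 31.8 / 2 + 1))
})

test_that("single-helix probes carry the specified tail charge", {
  charged <- build_single_helix_probe("R3G2", residues_per_helix = 12,
                                      membrane_thickness = 18, relax_iter = 0)
  res <- charged$topology$residues
  expect_equal(sum(res$charge[res$role == "tail"]), 3)
  expect_equal(sum(res$role == "tail"), 5)

  neutral <- build_single_helix_probe("G5", residues_per_helix = 12,
                                      membrane_thickness = 18, relax_iter = 0)
  expect_equal(sum(neutral$topology$residues$charge[
    neutral$topology$residues$role == "tail"]), 0)

  bare <- build_single_helix_probe("", residues_per_helix = 12,
                                   membrane_thickness = 18, relax_iter = 0)
  expect_equal(nrow(bare$topology$residues), 12)
  # tail extends on the +z (pulled) side
  expect_gt(tail(charged$conformation$CA[, 3], 1), 0)
})

test_that("derived sites are deterministic pure functions of the backbone", {
  h <- build_ideal_helix(10)
  s1 <- derived_sites(h)
  s2 <- derived_sites(h)
  expect_identical(s1, s2)
  expect_true(all(is.na(s1$H[1, ])))
  expect_true(all(is.na(s1$O[10, ])))
  expect_false(anyNA(s1$CB))
  # CB sits about 1.5 A from CA
  d <- sqrt(rowSums((s1$CB - h$CA)^2))
  expect_true(all(abs(d - 1.53) < 0.1))
})

test_that("conformation validation flags broken bonds", {
  h <- build_ideal_helix(8)
  expect_true(validate_conformation(h))
  h$CA[4, ] <- h$CA[4, ] + c(3, 0, 0)
  expect_error(validate_conformation(h), "residue")
})

test_that("PDB write and reload round-trips coordinates and helices", {
  h <- build_ideal_helix(12, axis = c(0, 0, 1))
  topo <- helix_topology(12)
  path <- tempfile(fileext = ".pdb")
  write_pdb(h, topo, path)
  loaded <- load_pdb(path, membrane_thickness = 31.8)
  expect_equal(nrow(loaded$topology$residues), 12)
  expect_lt(max(abs(loaded$conformation$CA - h$CA)), 1e-3 + 1e-8)
  expect_lt(max(abs(loaded$conformation$N - h$N)), 1e-3 + 1e-8)
  # one helix annotation covering most residues
  expect_equal(nrow(loaded$topology$helices), 1)
  hh <- loaded$topology$helices
  expect_gte(hh$end[1] - hh$start[1] + 1, 8)
  expect_identical(hh$orientation[1], "up")
})

test_that("PDB loader reports missing backbone atoms and extra chains", {
  h <- build_ideal_helix(5)
  path <- tempfile(fileext = ".pdb")
  write_pdb(h, helix_topology(5), path)
  # drop the CA of residue 3
  lines <- readLines(path)
  keep <- !(grepl("^ATOM", lines) & grepl(" CA ", lines) &
              substr(lines, 23, 26) == "   3")
  broken <- tempfile(fileext = ".pdb")
  writeLines(lines[keep], broken)
  expect_error(load_pdb(broken, 31.8), "residue 3")

  # duplicate the chain under a different id
  dup <- lines[grepl("^ATOM", lines)]
  dup <- sub("^(.{21})A", "\\1B", dup)
  two <- tempfile(fileext = ".pdb")
  writeLines(c(lines[grepl("^ATOM", lines)], dup, "END"), two)
  expect_error(suppressWarnings(load_pdb(two, 31.8)), "chain")
})
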