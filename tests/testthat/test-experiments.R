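# configuration-driven experiment runner

small_config <- function(out_seed = 1) {
  list(system = list(n_helices = 1, residues_per_helix = 8,
                     linker_lengths = numeric(0), tail = "",
                     membrane_thickness = 12),
       protocol = list(n_steps = 600, frame_interval = 100,
                       velocity = 0.01),
       replicas = 2, base_seed = out_seed)
}

test_that("configs validate and reject unknown keys", {
  cfg <- experiment_config(small_config())
  expect_s3_class(cfg, "mp_experiment_config")
  expect_equal(cfg$replicas, 2)

  bad <- small_config(); bad$bogus <- 1
  expect_error(experiment_config(bad), "bogus")
  bad2 <- small_config(); bad2$sweep <- list(nonsense = 1)
  expect_error(experiment_config(bad2), "sweep")
  bad3 <- small_config()
  bad3$sweep <- list(term_scaling = list(term = "zz", factors = 1))
  expect_error(experiment_config(bad3), "term")
  expect_error(experiment_config(list(protocol = list())), "system")
})

test_that("configs round-trip through YAML", {
  cfg <- small_config()
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path)
  parsed <- experiment_config(path)
  expect_equal(parsed$protocol$n_steps, 600)
  expect_equal(parsed$system$residues_per_helix, 8)
})

test_that("an experiment writes one run per replica with distinct seeds", {
  out <- tempfile("exp")
  res <- run_experiment(small_config(), out)
  files <- list.files(out, recursive = TRUE)
  expect_equal(sum(grepl("trajectory.csv", files)), 2)
  expect_equal(sum(grepl("manifest.json", files)), 2)
  seeds <- vapply(list.files(out, pattern = "manifest.json", recursive = TRUE,
                             full.names = TRUE),
                  function(f) jsonlite::read_json(f)$seed, numeric(1))
  expect_equal(sort(unname(seeds)), c(1, 2))

  # re-running the same config reproduces byte-identical trajectories
  out2 <- tempfile("exp")
  run_experiment(small_config(), out2)
  t1 <- readLines(file.path(out, "baseline", "rep_001", "trajectory.csv"))
  t2 <- readLines(file.path(out2, "baseline", "rep_001", "trajectory.csv"))
  expect_identical(t1, t2)
})

test_that("a term-scaling sweep produces one directory per factor", {
  cfg <- small_config()
  cfg$sweep <- list(term_scaling = list(term = "hb", factors = c(0.5, 1, 2)))
  out <- tempfile("sweep")
  run_experiment(cfg, out)
  dirs <- list.dirs(out, recursive = FALSE)
  expect_equal(sort(basename(dirs)), c("hb_x0.5", "hb_x1", "hb_x2"))
})

test_that("summaries tabulate per-condition rupture statistics", {
  # hand-written events tree: one condition, three replicas
  out <- tempfile("sum")
  dir.create(file.path(out, "demo"), recursive = TRUE)
  evs <- list(list(peak_force = 1), list(peak_force = 2),
              list(peak_force = 3))
  jsonlite::write_json(evs, file.path(out, "demo", "events.json"),
                       auto_unbox = TRUE, digits = NA)
  tab <- summarize_experiment(out)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$mean_force, 2)
  expect_equal(tab$sem, 0.577, tolerance = 1e-3)
  expect_equal(tab$n, 3)

  # empty tree: empty table with a warning
  expect_warning(tab0 <- summarize_experiment(tempfile("none")), "no analyses")
  expect_equal(nrow(tab0), 0)
})

test_that("trajectory snapshots round-trip through the PDB writer", {
  sys <- build_single_helix_probe("", residues_per_helix = 8,
                                  membrane_thickness = 12, relax_iter = 50)
  tr <- run_pulling(sys, pulling_protocol(n_steps = 300, frame_interval = 100,
                                          seed = 1))
  dir <- tempfile("snaps")
  paths <- write_trajectory_snapshots(tr, dir, every = 2)
  files <- list.files(dir, pattern = "\\.pdb$")
  expect_equal(length(files), 2)
  back <- load_pdb(file.path(dir, files[1]), membrane_thickness = 12)
  expect_equal(nrow(back$topology$residues), 8)
})

test_that("a velocity sweep produces one directory per velocity", {
  cfg <- small_config()
  cfg$sweep <- list(velocities = c(0.005, 0.02))
  cfg$replicas <- 1
  out <- tempfile("vel")
  run_experiment(cfg, out)
  expect_equal(sort(basename(list.dirs(out, recursive = FALSE))),
               c("velocity_0.005", "velocity_0.02"))
})

test_that("trajectory CSV carries the spring state and energy breakdown", {
  sys <- build_single_helix_probe("", residues_per_helix = 8,
                                  membrane_thickness = 12, relax_iter = 50)
  tr <- run_pulling(sys, pulling_protocol(n_steps = 500, frame_interval = 100,
                                          seed = 1))
  path <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  df <- read.csv(path)
  expect_true(all(c("step", "extension_A", "force_kT_per_A", "force_pN_300K",
                    "spring_energy_kT", "hb", "sc_sc", "cb_burial",
                    "bb_burial", "cb_membrane", "hb_membrane", "bonded",
                    "excluded_volume", "total") %in% names(df)))
  expect_equal(nrow(df), 6)
  expect_equal(df$force_pN_300K, map_force_units(df$force_kT_per_A),
               tolerance = 1e-6)
  # spring force and energy are consistent with the stored displacement
  expect_equal(df$spring_energy_kT, 0.5 * tr$protocol$k * tr$x^2,
               tolerance = 1e-9)
})
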