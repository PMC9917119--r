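# experiments_io module: configuration-driven experiment runner reproducing
# the perturbation grid (term scalings, restraints, linker exclusion,
# thickness sweep, pulling geometries, velocity series) over seeded replicas.

#' Experiment configuration
#'
#' Builds (and validates) an experiment configuration from a list or a YAML
#' file.  A configuration names a system, a pulling protocol, base energy
#' parameters and at most one sweep axis; each sweep point is run for
#' `replicas` seeds, replica i using seed `base_seed + i - 1` so that sweep
#' conditions are seed-paired.
#'
#' Recognised sweep axes (at most one):
#' \describe{
#'   \item{`term_scaling`}{list with `term` (`"hb"`, `"pp"` or `"memb"`) and
#'     `factors` (numeric vector of lambda values).}
#'   \item{`thickness_offsets`}{numeric vector of membrane-thickness offsets
#'     in Angstrom (e.g. `c(-8, -4, 0, 4, 8)`).}
#'   \item{`velocities`}{numeric vector of pulling velocities for a
#'     Bell-Evans series.}
#'   \item{`restrain`}{logical vector, e.g. `c(FALSE, TRUE)`.}
#'   \item{`linker_membrane`}{logical vector toggling
#'     `include_linker_membrane`.}
#' }
#'
#' @param config named list, or path to a YAML file with the same fields:
#'   `system` (either `preset` = `"br"`/`"glpg"` or `bundle_spec` fields, or
#'   `pdb` = path plus `membrane_thickness`), `protocol` (fields of
#'   [pulling_protocol()]), `params` (overrides for [energy_params()]),
#'   `sweep`, `replicas` (default 28), `base_seed` (default 1).
#' @return a validated `mp_experiment_config`.
#' @export
experiment_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config error: configuration must be a list or YAML file")
  bad <- setdiff(names(config),
                 c("system", "protocol", "params", "sweep", "replicas",
                   "base_seed", "name"))
  if (length(bad))
    stop("config error: unknown keys: ", paste(bad, collapse = ", "))
  if (is.null(config$system)) stop("config error: missing 'system'")
  config$replicas <- if (is.null(config$replicas)) 28L else as.integer(config$replicas)
  config$base_seed <- if (is.null(config$base_seed)) 1L else as.integer(config$base_seed)
  if (config$replicas < 1) stop("config error: replicas must be >= 1")
  if (!is.null(config$sweep)) {
    axes <- intersect(names(config$sweep),
                      c("term_scaling", "thickness_offsets", "velocities",
                        "restrain", "linker_membrane"))
    unknown <- setdiff(names(config$sweep), axes)
    if (length(unknown))
      stop("config error: unknown sweep axes: ", paste(unknown, collapse = ", "))
    if (length(axes) > 1)
      stop("config error: at most one sweep axis per experiment")
    if (identical(axes, "term_scaling")) {
      ts <- config$sweep$term_scaling
      if (is.null(ts$term) || !ts$term %in% c("hb", "pp", "memb"))
        stop("config error: term_scaling$term must be hb, pp or memb")
      if (is.null(ts$factors)) stop("config error: term_scaling$factors missing")
    }
  }
  structure(config, class = "mp_experiment_config")
}

# condition list (label + parameter deltas) implied by the sweep axis
sweep_conditions <- function(config) {
  sw <- config$sweep
  if (is.null(sw) || !length(sw))
    return(list(list(label = "baseline")))
  if (!is.null(sw$term_scaling)) {
    ts <- sw$term_scaling
    return(lapply(ts$factors, function(f)
      list(label = sprintf("%s_x%g", ts$term, f), term = ts$term, factor = f)))
  }
  if (!is.null(sw$thickness_offsets))
    return(lapply(sw$thickness_offsets, function(o)
      list(label = sprintf("thickness_%+g", o), thickness_offset = o)))
  if (!is.null(sw$velocities))
    return(lapply(sw$velocities, function(v)
      list(label = sprintf("velocity_%g", v), velocity = v)))
  if (!is.null(sw$restrain))
    return(lapply(sw$restrain, function(r)
      list(label = if (r) "restrained" else "unrestrained", restrain = r)))
  if (!is.null(sw$linker_membrane))
    return(lapply(sw$linker_membrane, function(l)
      list(label = if (l) "linker_membrane_on" else "linker_membrane_off",
           linker_membrane = l)))
  list(list(label = "baseline"))
}

build_system_from_config <- function(config) {
  sysc <- config$system
  if (!is.null(sysc$pdb))
    return(load_pdb(sysc$pdb, sysc$membrane_thickness))
  if (!is.null(sysc$preset)) {
    spec <- switch(sysc$preset,
                   br = br_bundle_spec(),
                   glpg = glpg_bundle_spec(),
                   stop("config error: unknown preset '", sysc$preset, "'"))
  } else {
    args <- sysc[intersect(names(sysc), names(formals(bundle_spec)))]
    spec <- do.call(bundle_spec, args)
  }
  build_tm_bundle(spec)
}

config_protocol <- function(config, overrides = list()) {
  args <- config$protocol
  if (is.null(args)) args <- list()
  args <- modifyList(args, overrides)
  do.call(pulling_protocol, args)
}

config_params <- function(config, cond = list()) {
  args <- if (is.null(config$params)) list() else config$params
  if (!is.null(cond$term)) {
    lam <- paste0("lambda_", cond$term)
    args[[lam]] <- cond$factor
  }
  if (!is.null(cond$linker_membrane))
    args$include_linker_membrane <- cond$linker_membrane
  do.call(energy_params, args)
}

# deterministic content hash (polynomial rolling hash over the serialized
# object; stays within exact double-precision integer range)
config_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  h <- 5381
  for (b in as.integer(raw)) h <- (h * 33 + b) %% 4294967291
  sprintf("%08x", as.integer(h %% 2147483647))
}

run_manifest <- function(config, cond, seed) {
  list(config_hash = config_hash(unclass(config)),
       condition = cond$label, seed = seed,
       package_version = as.character(utils::packageVersion("mempull")),
       generated = "mempull::run_experiment")
}

#' Run an experiment grid
#'
#' For every sweep condition and replica, runs a pulling simulation and
#' writes `trajectory.csv` plus `manifest.json` into
#' `out_dir/<condition>/rep_<i>/`; per-condition rupture analyses are
#' written to `out_dir/<condition>/events.json`.  Outputs are a pure
#' function of the configuration (given `base_seed`).
#'
#' @param config an [experiment_config()] (or list/YAML path coercible to
#'   one).
#' @param out_dir output directory, created if needed.
#' @param keep_trajectories return the trajectory objects as well (memory
#'   permitting).
#' @param fec_args arguments passed to [extract_fec()].
#' @param rupture_args arguments passed to [detect_ruptures()].
#' @return invisibly, a list with `conditions`, per-condition event tables
#'   and (optionally) trajectories.
#' @export
run_experiment <- function(config, out_dir, keep_trajectories = FALSE,
                           fec_args = list(), rupture_args = list()) {
  config <- experiment_config(if (inherits(config, "mp_experiment_config"))
    unclass(config) else config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  conds <- sweep_conditions(config)
  system0 <- build_system_from_config(config)
  results <- list()
  for (cond in conds) {
    cdir <- file.path(out_dir, cond$label)
    dir.create(cdir, showWarnings = FALSE, recursive = TRUE)
    params <- config_params(config, cond)
    membrane <- membrane_model(system0$topology$membrane_thickness +
                                 (cond$thickness_offset %||% 0))
    proto_over <- list()
    if (!is.null(cond$velocity)) proto_over$velocity <- cond$velocity
    if (!is.null(cond$restrain)) proto_over$restrain_helices <- cond$restrain
    events <- list(); trajs <- list()
    for (r in seq_len(config$replicas)) {
      seed <- config$base_seed + r - 1L
      protocol <- config_protocol(config, c(proto_over, list(seed = seed)))
      rdir <- file.path(cdir, sprintf("rep_%03d", r))
      dir.create(rdir, showWarnings = FALSE)
      tr <- run_pulling(system0, protocol, params, membrane)
      write_trajectory_csv(tr, file.path(rdir, "trajectory.csv"))
      jsonlite::write_json(run_manifest(config, cond, seed),
                           file.path(rdir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA)
      fec <- do.call(extract_fec, c(list(tr), fec_args))
      ev <- do.call(detect_ruptures, c(list(fec), rupture_args))
      events[[r]] <- ev
      if (keep_trajectories) trajs[[r]] <- tr
    }
    jsonlite::write_json(
      lapply(events, function(e) as.list(as.data.frame(e))),
      file.path(cdir, "events.json"), digits = NA)
    results[[cond$label]] <- list(condition = cond, events = events,
                                  trajectories = if (keep_trajectories) trajs)
  }
  invisible(list(conditions = conds, results = results, out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarize an experiment output tree
#'
#' Reads the per-condition `events.json` files under `out_dir` and tabulates
#' event-indexed mean and SEM rupture forces per condition.
#'
#' @param out_dir directory written by [run_experiment()].
#' @param max_events tabulate at most this many events.
#' @return data.frame with one row per condition x event: `condition`,
#'   `event`, `mean_force`, `sem`, `n`, `n_total`.  Empty (with a warning)
#'   if the tree holds no analyses.
#' @export
summarize_experiment <- function(out_dir, max_events = 6) {
  files <- list.files(out_dir, pattern = "^events\\.json$", recursive = TRUE,
                      full.names = TRUE)
  if (!length(files)) {
    warning("no analyses found under ", out_dir)
    return(data.frame(condition = character(), event = integer(),
                      mean_force = numeric(), sem = numeric(),
                      n = integer(), n_total = integer()))
  }
  rows <- list()
  for (f in files) {
    cond <- basename(dirname(f))
    evs <- jsonlite::read_json(f, simplifyVector = FALSE)
    forces <- lapply(evs, function(e)
      if (length(e$peak_force)) as.numeric(unlist(e$peak_force)) else numeric(0))
    for (k in seq_len(max_events)) {
      have <- vapply(forces, function(v) length(v) >= k, logical(1))
      if (sum(have) < 2) break
      v <- vapply(forces[have], `[`, numeric(1), k)
      rows[[length(rows) + 1]] <-
        data.frame(condition = cond, event = k, mean_force = mean(v),
                   sem = sd(v) / sqrt(length(v)), n = length(v),
                   n_total = length(forces))
    }
  }
  if (!length(rows)) {
    warning("analyses found but no event present in >= 2 replicas")
    return(data.frame(condition = character(), event = integer(),
                      mean_force = numeric(), sem = numeric(),
                      n = integer(), n_total = integer()))
  }
  do.call(rbind, rows)
}
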