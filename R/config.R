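## Scenario configuration: validated construction, YAML round-trip with
## default filling, architecture instantiation, and the two headline
## comparison experiments (modification panel, suppression panel).

config_defaults <- list(
  architecture = list(
    type = "split_drive_Y",
    drive = list(cleavage = 0.99, hdr = 1, resistance = 1e-6,
                 inframe = 1/3, deposition = 0),
    shred = list(efficiency = 0.95, resistance = 1e-6),
    fitness = list(cost_cas9 = 0.1, cost_effector = 0.05, cost_B = 0.1,
                   floor = 0.05),
    somatic_cost = 0.5
  ),
  lifecycle = list(fecundity = 32, t_egg = 1L, t_larva = 14L, t_pupa = 1L,
                   mu_adult = 0.123, rm = 1.096, n_eq = 10000),
  releases = list(),
  migration = list(m = 0.01, n_patches = 2L),
  run = list(horizon = 365L, reps = 1L, seed = 1L, stochastic = TRUE)
)

release_defaults <- list(patch = 1L, size = 0, n_releases = 12L,
                         interval = 7L, start = 1L)

fill_defaults <- function(x, defaults, path = character()) {
  filled <- character()
  for (nm in names(defaults)) {
    key <- paste(c(path, nm), collapse = ".")
    if (is.null(x[[nm]])) {
      x[[nm]] <- defaults[[nm]]
      filled <- c(filled, key)
    } else if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])) &&
               is.list(x[[nm]])) {
      sub <- fill_defaults(x[[nm]], defaults[[nm]], c(path, nm))
      x[[nm]] <- sub$x
      filled <- c(filled, sub$filled)
    }
  }
  list(x = x, filled = filled)
}

check_num <- function(cfg, key, lo = -Inf, hi = Inf) {
  v <- cfg
  for (k in strsplit(key, ".", fixed = TRUE)[[1]]) v <- v[[k]]
  if (is.null(v) || !is.numeric(v) || length(v) != 1L || is.na(v) ||
      v < lo || v > hi)
    stop("config key '", key, "' must be a number in [", lo, ", ", hi, "]",
         call. = FALSE)
  invisible(v)
}

#' Validated simulation configuration
#'
#' Assembles and validates a full scenario configuration (architecture,
#' lifecycle, releases, migration, run control). Missing keys are filled with
#' package defaults; which keys were defaulted is recorded in the
#' `"defaults_filled"` attribute so the provenance of every value is explicit.
#'
#' @param architecture,lifecycle,releases,migration,run Named lists; see
#'   [make_sim_fixture()] for a fully populated example.
#' @return A `sim_config`.
#' @export
sim_config <- function(architecture = list(), lifecycle = list(),
                       releases = list(), migration = list(), run = list()) {
  cfg <- list(architecture = architecture, lifecycle = lifecycle,
              releases = releases, migration = migration, run = run)
  res <- fill_defaults(cfg, config_defaults)
  cfg <- res$x
  filled <- res$filled
  cfg$releases <- lapply(seq_along(cfg$releases), function(i) {
    sub <- fill_defaults(cfg$releases[[i]], release_defaults,
                         c("releases", as.character(i)))
    filled <<- c(filled, sub$filled)
    sub$x
  })
  if (!cfg$architecture$type %in% arch_types)
    stop("config key 'architecture.type' must be one of: ",
         paste(arch_types, collapse = ", "), call. = FALSE)
  for (k in c("architecture.drive.cleavage", "architecture.drive.hdr",
              "architecture.drive.resistance", "architecture.drive.inframe",
              "architecture.drive.deposition", "architecture.shred.efficiency",
              "architecture.shred.resistance", "architecture.fitness.cost_cas9",
              "architecture.fitness.cost_effector",
              "architecture.fitness.cost_B", "architecture.somatic_cost"))
    check_num(cfg, k, 0, 1)
  if (!is.null(cfg$architecture$shred$fertility_cost))
    check_num(cfg, "architecture.shred.fertility_cost", 0, 1)
  check_num(cfg, "architecture.fitness.floor", 1e-9, 1)
  check_num(cfg, "lifecycle.fecundity", 1e-9, Inf)
  for (k in c("lifecycle.t_egg", "lifecycle.t_larva", "lifecycle.t_pupa"))
    check_num(cfg, k, 1, 1000)
  check_num(cfg, "lifecycle.rm", 1 + 1e-9, 10)
  check_num(cfg, "lifecycle.mu_adult", 1e-9, 0.999)
  check_num(cfg, "lifecycle.n_eq", 0, Inf)
  check_num(cfg, "migration.m", 0, 1)
  check_num(cfg, "migration.n_patches", 1, 100)
  check_num(cfg, "run.horizon", 0, Inf)
  check_num(cfg, "run.reps", 1, Inf)
  for (i in seq_along(cfg$releases)) {
    rel <- cfg$releases[[i]]
    if (rel$size < 0) stop("config key 'releases.", i, ".size' must be >= 0",
                           call. = FALSE)
  }
  structure(cfg, class = "sim_config", defaults_filled = filled)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$architecture$type, "; N_eq=", x$lifecycle$n_eq,
      " x ", x$migration$n_patches, " patches; ",
      length(x$releases), " release schedule(s); horizon ", x$run$horizon,
      " d; ", x$run$reps, " rep(s)\n", sep = "")
  df <- attr(x, "defaults_filled")
  if (length(df)) cat("  defaulted keys: ", length(df), "\n", sep = "")
  invisible(x)
}

#' Save / load a configuration as YAML
#'
#' `save_config()` writes the configuration (without attributes);
#' `load_config()` reads it back, fills defaults, validates, and records which
#' keys were defaulted. Round-tripping a config reproduces it exactly.
#'
#' @param config A `sim_config`.
#' @param path File path.
#' @return `load_config()` returns a `sim_config`.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(unclass(config), path, precision = 16L)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("malformed config file: ", path)
  do.call(sim_config, raw[intersect(names(raw),
                                    c("architecture", "lifecycle", "releases",
                                      "migration", "run"))])
}

#' Stable hash of a configuration
#'
#' @param config A `sim_config`.
#' @return Character hash (used in run manifests).
#' @export
config_hash <- function(config) {
  ## canonicalize numeric storage modes so a YAML round trip (which may read
  ## whole numbers back as integers) hashes identically
  canon <- rapply(unclass(config),
                  function(x) if (is.numeric(x)) as.numeric(x) else x,
                  how = "replace")
  attributes(canon) <- list(names = names(canon))  # provenance flags excluded
  rlang::hash(canon)
}

#' Instantiate the drive architecture described by a config
#'
#' @param config A `sim_config`.
#' @return A `drive_architecture`.
#' @export
build_architecture <- function(config) {
  a <- config$architecture
  fit <- do.call(fitness_params, a$fitness)
  switch(a$type,
    split_drive_Y = split_drive_architecture("Y", do.call(drive_params, a$drive), fit),
    split_drive_X = split_drive_architecture("X", do.call(drive_params, a$drive), fit),
    split_drive_autosomal = split_drive_architecture("autosomal",
                                                     do.call(drive_params, a$drive), fit),
    x_shredder_Y = x_shredder_architecture("Y", do.call(shredder_params, a$shred), fit),
    x_shredder_autosomal = x_shredder_architecture("autosomal",
                                                   do.call(shredder_params, a$shred), fit),
    homing_suppression = homing_suppression_architecture(do.call(drive_params, a$drive), fit,
                                                         somatic_cost = a$somatic_cost),
    stop("unknown architecture type: ", a$type))
}

#' Run a configured scenario
#'
#' Builds the architecture, the life-history and the release/migration
#' settings from a validated config and runs the simulation. The returned
#' trajectory set carries a run manifest (config hash, seed, package version,
#' timestamp) sufficient to reproduce the run bit-for-bit.
#'
#' @param config A `sim_config`.
#' @return A `trajectory_set` with attribute `"manifest"`.
#' @export
run_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  arch <- build_architecture(config)
  lh <- do.call(life_history_params, config$lifecycle)
  mig <- if (config$migration$n_patches > 1)
    migration_matrix(config$migration$m, config$migration$n_patches, lh$t_gen)
  else NULL
  rels <- lapply(config$releases, function(r)
    release_schedule(patch = r$patch, genotype = arch$release_label,
                     size = r$size, n_releases = r$n_releases,
                     interval = r$interval, start = r$start))
  traj <- simulate_drive(arch, lh, releases = rels, migration = mig,
                         horizon = config$run$horizon, reps = config$run$reps,
                         seed = config$run$seed,
                         stochastic = config$run$stochastic,
                         n_patches = config$migration$n_patches)
  attr(traj, "manifest") <- list(
    config_hash = config_hash(config),
    seed = config$run$seed,
    package_version = as.character(utils::packageVersion("drivesim")),
    timestamp = format(Sys.time(), tz = "UTC"))
  traj
}

#' Run the headline architecture comparisons
#'
#' Panel `"a"` (population modification): the three split drives (Y-, X- and
#' autosomally linked Cas9), reporting the window of protection in the release
#' patch and the maximum effector carrier frequency in the neighboring patch.
#' Panel `"b"` (population suppression): Y-linked X-shredder, autosomal homing
#' suppression drive and autosomal X-shredder, reporting elimination
#' probability and time for the first two and the rebound time of the
#' self-limiting autosomal shredder.
#'
#' @param panel `"a"` or `"b"`.
#' @param reps Stochastic repetitions per architecture (>= 1).
#' @param scale Joint population/release scale (1 = full scale).
#' @param seed Master seed.
#' @param horizon Optional horizon override (days).
#' @param keep_trajectories Keep the full trajectory sets (memory-heavy at
#'   full scale).
#' @return List with `panel`, `summary` (data.frame) and `reports` (per
#'   architecture `metric_report`s), plus `trajectories` if kept.
#' @export
run_figure_experiment <- function(panel = c("a", "b"), reps = 100L, scale = 1,
                                  seed = 1L, horizon = NULL,
                                  keep_trajectories = FALSE) {
  panel <- match.arg(panel)
  if (!is.numeric(reps) || reps < 1) stop("reps must be >= 1")
  archs <- if (panel == "a") {
    c("split_drive_Y", "split_drive_autosomal", "split_drive_X")
  } else {
    c("x_shredder_Y", "homing_suppression", "x_shredder_autosomal")
  }
  set.seed(seed)
  arch_seeds <- sample.int(.Machine$integer.max - 1L, length(archs))
  reports <- list(); trajs <- list(); rows <- list()
  for (i in seq_along(archs)) {
    cfg <- make_sim_fixture(archs[i], scale = scale, horizon = horizon,
                            reps = reps, seed = arch_seeds[i])
    traj <- run_config(cfg)
    rep_ <- metric_report(traj)
    reports[[archs[i]]] <- rep_
    if (keep_trajectories) trajs[[archs[i]]] <- traj
    rows[[i]] <- data.frame(
      architecture = archs[i],
      wop_days = rep_$wop[[1]]$days,
      max_carrier_neighbor = if (traj$n_patches > 1) rep_$max_carrier_frequency[2] else NA_real_,
      elimination_probability = if (!is.null(rep_$elimination)) rep_$elimination$probability else NA_real_,
      elimination_weeks = if (!is.null(rep_$elimination)) rep_$elimination$mean_weeks else NA_real_,
      rebound_weeks = rep_$rebound$weeks,
      stringsAsFactors = FALSE)
  }
  out <- list(panel = panel, summary = do.call(rbind, rows), reports = reports,
              scale = scale, reps = reps, seed = seed)
  if (keep_trajectories) out$trajectories <- trajs
  out
}
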