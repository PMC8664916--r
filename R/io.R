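## Plain-text export of tensors and trajectories.

#' Export an inheritance cube to CSV
#'
#' Writes `legend.csv` (genotype index: id, sex, label), `tensor.csv` (long
#' format: mother, father, offspring labels and probability, zero entries
#' omitted) and `scaling.csv` (per-cross fecundity scaling) into a directory.
#'
#' @param cube An `inheritance_cube`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
export_cube <- function(cube, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cube$gset$legend, file.path(dir, "legend.csv"),
                   row.names = FALSE)
  dn <- dimnames(cube$tau)
  idx <- which(cube$tau > 0, arr.ind = TRUE)
  long <- data.frame(mother = dn[[1]][idx[, 1]], father = dn[[2]][idx[, 2]],
                     offspring = dn[[3]][idx[, 3]],
                     probability = cube$tau[idx], stringsAsFactors = FALSE)
  long <- long[order(long$mother, long$father, long$offspring), ]
  utils::write.csv(long, file.path(dir, "tensor.csv"), row.names = FALSE)
  sc <- as.data.frame(as.table(cube$scaling), stringsAsFactors = FALSE)
  names(sc) <- c("mother", "father", "scaling")
  utils::write.csv(sc, file.path(dir, "scaling.csv"), row.names = FALSE)
  invisible(dir)
}

#' Write a trajectory set to CSV with a JSON run manifest
#'
#' Emits `trajectory.csv` in long format (rep, day, patch, sex, genotype,
#' count) and `manifest.json` (seed, architecture, horizon, repetitions,
#' package version; plus the config hash when the trajectory came from
#' [run_config()]).
#'
#' @param traj A `trajectory_set`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_trajectory <- function(traj, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(trajectory_long(traj), file.path(dir, "trajectory.csv"),
                   row.names = FALSE)
  man <- attr(traj, "manifest")
  meta <- list(arch = traj$arch_name, seed = traj$seed, reps = traj$reps,
               horizon = traj$horizon, n_patches = traj$n_patches,
               stochastic = traj$stochastic,
               final_release_day = traj$final_release_day,
               package_version = as.character(utils::packageVersion("drivesim")))
  if (!is.null(man)) meta <- c(meta, man[setdiff(names(man), names(meta))])
  jsonlite::write_json(meta, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
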