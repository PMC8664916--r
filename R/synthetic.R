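## Synthetic data generators: cross counts with the Tables-style
## data-generating process, miniature simulation fixtures, and the bundled
## default scenario configurations.

#' Simulate observed F1 counts for a sexing cross
#'
#' Emulates the data-generating process of the cross experiments: a
#' multinomial draw of `n` zygotes over the pre-viability Mendelian class
#' distribution, followed by independent binomial survival at probability
#' `1 - penetrance` in each lethal class.
#'
#' @param cross A `cross_design`.
#' @param n Total zygotes (>= 0).
#' @param penetrance Lethality penetrance (0-1).
#' @param seed Optional RNG seed for reproducibility.
#' @return Integer vector of surviving counts, named by class, in
#'   `enumerate_f1(cross)` order.
#' @export
simulate_cross_counts <- function(cross, n, penetrance = 1.0, seed = NULL) {
  stopifnot(n >= 0)
  if (!is.null(seed)) set.seed(seed)
  cls <- enumerate_f1(cross, penetrance = 0)    # pre-viability layout
  if (n == 0) return(stats::setNames(integer(nrow(cls)), cls$class))
  zygotes <- as.integer(stats::rmultinom(1, n, cls$pre_prob))
  surv <- zygotes
  for (i in which(cls$lethal)) {
    surv[i] <- stats::rbinom(1, zygotes[i], 1 - penetrance)
  }
  stats::setNames(surv, cls$class)
}

arch_types <- c("split_drive_Y", "split_drive_X", "split_drive_autosomal",
                "x_shredder_Y", "x_shredder_autosomal", "homing_suppression")

#' Build a simulation scenario configuration, optionally scaled down
#'
#' Returns the standard two-patch release scenario (equilibrium size 10,000
#' adults per patch, 12 weekly releases of 10,000 drive males into patch 1,
#' 1% per-generation migration) for one drive architecture, with population
#' and release sizes jointly scaled by `scale` so that the release ratio
#' (one release equals the adult population) is preserved in miniature test
#' fixtures.
#'
#' @param arch_type One of `"split_drive_Y"`, `"split_drive_X"`,
#'   `"split_drive_autosomal"`, `"x_shredder_Y"`, `"x_shredder_autosomal"`,
#'   `"homing_suppression"`.
#' @param scale Joint scale factor for `n_eq` and release size (> 0).
#' @param horizon Days to simulate.
#' @param reps Stochastic repetitions.
#' @param seed Master seed.
#' @param stochastic Logical.
#' @return A `sim_config` (see [sim_config()]).
#' @export
make_sim_fixture <- function(arch_type = arch_types, scale = 1,
                             horizon = NULL, reps = 100L, seed = 1L,
                             stochastic = TRUE) {
  arch_type <- match.arg(arch_type)
  stopifnot(scale > 0)
  if (is.null(horizon)) {
    horizon <- if (grepl("^split_drive", arch_type)) 1460L else 730L
  }
  suppression <- !grepl("^split_drive", arch_type)
  architecture <- list(type = arch_type)
  if (grepl("^split_drive", arch_type)) {
    architecture$drive <- list(cleavage = 0.99, hdr = 0.95, resistance = 0.001,
                               inframe = 1/3, deposition = 0.5)
    architecture$fitness <- list(cost_cas9 = 0.15, cost_effector = 0.05,
                                 cost_B = 0.10, floor = 0.05)
  } else if (grepl("^x_shredder", arch_type)) {
    architecture$shred <- list(efficiency = 1.0, resistance = 1e-6,
                               fertility_cost = 0.05)
    architecture$fitness <- list(cost_cas9 = 0.025, cost_effector = 0,
                                 cost_B = 0.10, floor = 0.05)
  } else {
    architecture$drive <- list(cleavage = 0.99, hdr = 1, resistance = 1e-6,
                               inframe = 1/3, deposition = 0)
    architecture$fitness <- list(cost_cas9 = 0.025, cost_effector = 0,
                                 cost_B = 0.10, floor = 0.05)
    architecture$somatic_cost <- 0.5
  }
  sim_config(
    architecture = architecture,
    lifecycle = list(fecundity = 32, t_egg = 1L, t_larva = 14L, t_pupa = 1L,
                     mu_adult = 0.123, rm = 1.096, n_eq = round(10000 * scale)),
    releases = list(list(patch = 1L, size = round(10000 * scale),
                         n_releases = 12L, interval = 7L, start = 1L)),
    migration = list(m = 0.01, n_patches = 2L),
    run = list(horizon = as.integer(horizon), reps = as.integer(reps),
               seed = as.integer(seed), stochastic = stochastic)
  )
}

#' Bundled scenario configurations for all six drive architectures
#'
#' The three population-modification split drives (Y-, X- and autosomally
#' linked Cas9 with an autosomal gRNA/effector) and the three suppression
#' systems (Y-linked X-shredder, autosomal X-shredder, autosomal homing drive
#' targeting a female-fertility gene), each in the standard full-scale
#' two-patch release scenario. Suppression systems carry the printed
#' high-cleavage (0.99) / low-resistance (1e-6) parameterization; split-drive
#' efficiency and all fitness costs are documented stand-in values (see the
#' package vignette).
#'
#' @param scale Joint population/release scale factor (1 = full scale).
#' @param reps Stochastic repetitions.
#' @param seed Master seed.
#' @return Named list of six `sim_config` objects.
#' @export
default_configs <- function(scale = 1, reps = 100L, seed = 1L) {
  out <- lapply(arch_types, make_sim_fixture, scale = scale, reps = reps,
                seed = seed)
  names(out) <- arch_types
  out
}
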