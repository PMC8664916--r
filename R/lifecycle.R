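#' Life-history parameters for the stage-structured daily model
#'
#' Parameterizes the egg/larva/pupa/adult daily-timestep model with
#' overlapping generations. The density parameter `alpha` of the larval
#' survival factor `(alpha/(alpha + L))^(1/t_larva)` is solved in closed form
#' so that the all-wild-type population has a stationary adult count of
#' `n_eq`: daily adult replacement fixes the required egg-to-adult survival,
#' which fixes the equilibrium larval daily survival and hence `alpha`.
#'
#' The density-independent juvenile mortality is, by default, derived from the
#' low-density daily population growth rate `rm`: the expected lifetime female
#' offspring of a female at low density is `rm^t_gen`, which fixes the shared
#' daily aquatic mortality across the egg, larval and pupal stages. This ties
#' the strength of density compensation — how hard the population is to
#' suppress — to a single measurable quantity. Individual stage mortalities
#' can be overridden.
#'
#' @param fecundity Eggs per adult female per day.
#' @param t_egg,t_larva,t_pupa Stage durations in days (integers >= 1).
#' @param mu_adult Daily adult mortality (1/day).
#' @param rm Daily low-density population growth rate (> 1); default 1.096,
#'   the standard malaria-vector value for this class of models.
#' @param mu_egg,mu_larva,mu_pupa Optional overrides for the daily
#'   density-independent juvenile mortalities (1/day); larval density
#'   mortality comes on top of `mu_larva`.
#' @param n_eq Equilibrium adult population size (females + males).
#' @return A `life_history` list including derived fields: `alpha`,
#'   per-stage survivals, equilibrium per-day flows, and generation time
#'   `t_gen = t_egg + t_larva + t_pupa + 1/mu_adult`.
#' @export
life_history_params <- function(fecundity = 32, t_egg = 1L, t_larva = 14L,
                                t_pupa = 1L, mu_adult = 0.123, rm = 1.096,
                                mu_egg = NULL, mu_larva = NULL, mu_pupa = NULL,
                                n_eq = 10000) {
  stopifnot(fecundity > 0, t_egg >= 1, t_larva >= 1, t_pupa >= 1,
            mu_adult > 0, mu_adult < 1, rm > 1, n_eq >= 0)
  t_egg <- as.integer(round(t_egg)); t_larva <- as.integer(round(t_larva))
  t_pupa <- as.integer(round(t_pupa))
  t_gen <- t_egg + t_larva + t_pupa + 1 / mu_adult
  t_aq <- t_egg + t_larva + t_pupa
  ## lifetime female offspring at low density: (beta/2) * S_aq / mu_adult
  ## = rm^t_gen  =>  shared daily aquatic survival
  s_aq_total <- 2 * mu_adult * rm^t_gen / fecundity
  if (s_aq_total >= 1)
    stop("rm too large for the given fecundity/adult mortality: implied ",
         "juvenile survival exceeds 1")
  mu_aq <- 1 - s_aq_total^(1 / t_aq)
  if (is.null(mu_egg)) mu_egg <- mu_aq
  if (is.null(mu_larva)) mu_larva <- mu_aq
  if (is.null(mu_pupa)) mu_pupa <- mu_aq
  stopifnot(mu_egg >= 0, mu_egg < 1, mu_larva >= 0, mu_larva < 1,
            mu_pupa >= 0, mu_pupa < 1)
  s_e <- 1 - mu_egg; s_p <- 1 - mu_pupa; s_a <- 1 - mu_adult
  p <- list(fecundity = fecundity, t_egg = t_egg, t_larva = t_larva,
            t_pupa = t_pupa, mu_egg = mu_egg, mu_larva = mu_larva,
            mu_pupa = mu_pupa, mu_adult = mu_adult, rm = rm, n_eq = n_eq,
            s_egg = s_e, s_pupa = s_p, s_adult = s_a, t_gen = t_gen)
  if (n_eq > 0) {
    ## required egg-to-eclosion survival through the larval stage:
    ## fecundity * F * s_e^t_egg * S_L * s_p^t_pupa = 2 * mu_adult * F
    S_L <- 2 * mu_adult / (fecundity * s_e^t_egg * s_p^t_pupa)
    if (S_L >= (1 - mu_larva)^t_larva)
      stop("no positive equilibrium: required larval survival ", signif(S_L, 4),
           " exceeds the density-independent maximum (1-mu_larva)^t_larva; ",
           "increase fecundity or decrease mortalities")
    s_l <- S_L^(1 / t_larva)
    hatch <- fecundity * (n_eq / 2) * s_e^t_egg
    L_tot <- hatch * sum(s_l^(0:(t_larva - 1)))
    G <- S_L / (1 - mu_larva)^t_larva     # (alpha/(alpha+L))^t_larva at equilibrium
    p$alpha <- L_tot * G / (1 - G)
    p$eq <- list(lambda = fecundity * n_eq / 2, hatch = hatch,
                 s_larva = s_l, L_tot = L_tot,
                 pupate = hatch * S_L,
                 eclose = hatch * S_L * s_p^t_pupa)
  } else {
    p$alpha <- 1
    p$eq <- list(lambda = 0, hatch = 0, s_larva = (1 - mu_larva), L_tot = 0,
                 pupate = 0, eclose = 0)
  }
  structure(p, class = "life_history")
}

#' @export
print.life_history <- function(x, ...) {
  cat("<life_history> beta=", x$fecundity, " eggs/f/day; E/L/P = ",
      x$t_egg, "/", x$t_larva, "/", x$t_pupa, " d; mu_adult=", x$mu_adult,
      "; N_eq=", x$n_eq, "; alpha=", signif(x$alpha, 5),
      "; T_gen=", signif(x$t_gen, 4), " d\n", sep = "")
  invisible(x)
}

## ---- patch state ------------------------------------------------------------

new_patch_state <- function(nG, lh) {
  structure(list(
    E = matrix(0, lh$t_egg, nG),
    L = matrix(0, lh$t_larva, nG),
    P = matrix(0, lh$t_pupa, nG),
    M = numeric(nG),        # adult males (male-genotype slots only)
    U = numeric(nG),        # unmated adult females
    Fm = matrix(0, nG, nG)  # mated females: own genotype x mate genotype
  ), class = "patch_state")
}

#' @export
print.patch_state <- function(x, ...) {
  cat("<patch_state> adults: ", format(sum(x$M) + sum(x$U) + sum(x$Fm)),
      " (", format(sum(x$U) + sum(x$Fm)), " F, ", format(sum(x$M)), " M); ",
      "juveniles: ", format(sum(x$E) + sum(x$L) + sum(x$P)), "\n", sep = "")
  invisible(x)
}

state_total <- function(s) sum(s$E) + sum(s$L) + sum(s$P) + sum(s$M) + sum(s$U) + sum(s$Fm)

round_state <- function(s) {
  s$E <- round(s$E); s$L <- round(s$L); s$P <- round(s$P)
  s$M <- round(s$M); s$U <- round(s$U); s$Fm <- round(s$Fm)
  s
}

#' All-wild-type equilibrium patch state
#'
#' Builds the stage-structured state whose cohorts satisfy the daily balance
#' equations of the deterministic model, split 50/50 between the wild-type
#' female and male genotypes. Simulating it forward deterministically with no
#' intervention reproduces it (a fixed point).
#'
#' @param arch A `drive_architecture` (supplies the wild-type genotype labels).
#' @param lh A `life_history`.
#' @param stochastic If TRUE, counts are rounded to integers.
#' @return A `patch_state`.
#' @export
equilibrium_state <- function(arch, lh, stochastic = FALSE) {
  gset <- arch$gset
  nG <- nrow(gset$legend)
  st <- new_patch_state(nG, lh)
  if (lh$n_eq == 0) return(st)
  wf <- match(arch$wild_female, gset$legend$label)
  wm <- match(arch$wild_male, gset$legend$label)
  eq <- lh$eq
  ## eggs/larvae/pupae: slot k has survived k-1 days; half female, half male
  for (k in seq_len(lh$t_egg))
    st$E[k, c(wf, wm)] <- eq$lambda * lh$s_egg^(k - 1) / 2
  for (k in seq_len(lh$t_larva))
    st$L[k, c(wf, wm)] <- eq$hatch * eq$s_larva^(k - 1) / 2
  for (k in seq_len(lh$t_pupa))
    st$P[k, c(wf, wm)] <- eq$pupate * lh$s_pupa^(k - 1) / 2
  st$M[wm] <- lh$n_eq / 2
  st$Fm[wf, wm] <- lh$n_eq / 2
  if (stochastic) st <- round_state(st)
  st
}

## ---- dynamics precomputation ------------------------------------------------

## Bundle everything step_day needs into flat numeric structures.
precompute_dynamics <- function(arch, lh) {
  gset <- arch$gset
  nG <- nrow(gset$legend)
  fi <- gset$female_idx; mi <- gset$male_idx
  nF <- length(fi); nM <- length(mi)
  tr <- arch$traits
  ## egg production rate per (mother, father) class, per female per day
  rate <- matrix(0, nF, nM)
  for (a in seq_len(nF)) {
    f <- fi[a]
    if (!tr$fertile[f]) next
    rate[a, ] <- lh$fecundity * tr$fecundity[f] * arch$cube$scaling[a, ]
  }
  tau_flat <- matrix(arch$cube$tau, nrow = nF * nM, ncol = nG)  # (a,b) row-major in a
  list(nG = nG, fi = fi, mi = mi, nF = nF, nM = nM,
       rate_vec = as.vector(rate),
       M_egg = t(tau_flat),               # nG x (nF*nM)
       ## cost s maps to mortality multiplier 1/(1-s): lifespan ratio = 1-s
       s_adult = pmax(0, 1 - lh$mu_adult * tr$mortality_mult),
       eta = tr$eta,
       lh = lh)
}

draw_binom <- function(n, prob, stochastic) {
  if (stochastic) stats::rbinom(length(n), size = n, prob = prob) else n * prob
}

#' Advance a patch by one day
#'
#' Daily schedule: (1) oviposition by mated females (Poisson egg numbers with
#' genotype-specific fecundity and shredder fecundity scaling; offspring
#' genotype multinomial over the inheritance-cube row -- realized as
#' independent Poisson thinning); (2) juvenile survival and queue advance,
#' larvae under the density factor `(alpha/(alpha+L))^(1/t_larva)` on top of
#' baseline survival; (3) adult survival (binomial, genotype-specific);
#' (4) eclosion and female mating (mate genotype multinomial over adult male
#' frequencies weighted by mating competitiveness; females finding no males
#' wait unmated and retry daily). Deterministic mode replaces every draw by
#' its expectation.
#'
#' @param state A `patch_state`.
#' @param dyn Precomputed dynamics (internal; from an architecture and
#'   life-history via `simulate_drive()` or `precompute_dynamics`).
#' @param stochastic Logical.
#' @return The updated `patch_state`.
#' @keywords internal
step_day <- function(state, dyn, stochastic = TRUE) {
  lh <- dyn$lh
  ## 1. oviposition (from current mated females)
  w <- as.vector(state$Fm[dyn$fi, dyn$mi, drop = FALSE]) * dyn$rate_vec
  if (any(w > 0)) {
    lam <- as.numeric(dyn$M_egg %*% w)
    eggs_new <- if (stochastic) stats::rpois(dyn$nG, lam) else lam
  } else {
    eggs_new <- numeric(dyn$nG)
  }
  ## 2. juvenile survival + advance
  L_tot <- sum(state$L)
  s_l <- (1 - lh$mu_larva) * (lh$alpha / (lh$alpha + L_tot))^(1 / lh$t_larva)
  E_surv <- matrix(draw_binom(state$E, lh$s_egg, stochastic), nrow = lh$t_egg)
  L_surv <- matrix(draw_binom(state$L, s_l, stochastic), nrow = lh$t_larva)
  P_surv <- matrix(draw_binom(state$P, lh$s_pupa, stochastic), nrow = lh$t_pupa)
  eclose <- P_surv[lh$t_pupa, ]
  state$P <- rbind(L_surv[lh$t_larva, , drop = FALSE],
                   P_surv[-lh$t_pupa, , drop = FALSE])[seq_len(lh$t_pupa), , drop = FALSE]
  state$L <- rbind(E_surv[lh$t_egg, , drop = FALSE],
                   L_surv[-lh$t_larva, , drop = FALSE])[seq_len(lh$t_larva), , drop = FALSE]
  state$E <- rbind(eggs_new, E_surv[-lh$t_egg, , drop = FALSE])[seq_len(lh$t_egg), , drop = FALSE]
  ## 3. adult survival
  state$M <- draw_binom(state$M, dyn$s_adult, stochastic)
  state$U <- draw_binom(state$U, dyn$s_adult, stochastic)
  sFm <- dyn$s_adult[row(state$Fm)]
  state$Fm <- matrix(draw_binom(as.vector(state$Fm), as.vector(sFm), stochastic),
                     nrow = dyn$nG)
  ## 4. eclosion + mating
  state$M <- state$M + eclose * (seq_len(dyn$nG) %in% dyn$mi)
  new_f <- state$U + eclose * (seq_len(dyn$nG) %in% dyn$fi)
  state$U <- numeric(dyn$nG)
  mate_w <- state$M * dyn$eta
  tw <- sum(mate_w)
  if (tw > 0) {
    pm <- mate_w / tw
    for (g in which(new_f > 0)) {
      n <- new_f[g]
      if (stochastic) {
        state$Fm[g, ] <- state$Fm[g, ] + as.numeric(stats::rmultinom(1, n, pm))
      } else {
        state$Fm[g, ] <- state$Fm[g, ] + n * pm
      }
    }
  } else {
    state$U <- new_f
  }
  state
}

#' Add released adult males to a patch
#'
#' @param state A `patch_state`.
#' @param gset The architecture's `genotype_set`.
#' @param genotype_label Label of the (male) release genotype.
#' @param size Number of males to add.
#' @return The updated state.
#' @export
apply_release <- function(state, gset, genotype_label, size) {
  idx <- match(genotype_label, gset$legend$label)
  if (is.na(idx)) stop("unknown release genotype: ", genotype_label)
  if (gset$legend$sex[idx] != "M") stop("release genotype must be male")
  stopifnot(size >= 0)
  state$M[idx] <- state$M[idx] + size
  state
}

#' Release schedule
#'
#' @param patch Patch index receiving the releases.
#' @param genotype Release genotype label (adult males).
#' @param size Males per release.
#' @param n_releases Number of releases.
#' @param interval Days between releases (7 = weekly).
#' @param start Day of the first release.
#' @return A `release_schedule`.
#' @export
release_schedule <- function(patch = 1L, genotype, size, n_releases = 12L,
                             interval = 7L, start = 1L) {
  stopifnot(size >= 0, n_releases >= 0, interval >= 1, start >= 0, patch >= 1)
  structure(list(patch = as.integer(patch), genotype = genotype,
                 size = size, n_releases = as.integer(n_releases),
                 interval = as.integer(interval), start = as.integer(start)),
            class = "release_schedule")
}

release_days <- function(sched) {
  if (sched$n_releases == 0L) integer(0)
  else sched$start + sched$interval * (seq_len(sched$n_releases) - 1L)
}

final_release_day <- function(schedules) {
  days <- unlist(lapply(schedules, release_days))
  if (length(days) == 0L) 0L else max(days)
}

#' Migration settings for an n-patch metapopulation
#'
#' The per-generation migration probability `m` is converted to a daily
#' probability `m_d = m / t_gen` (adults only). The daily matrix has
#' `m_d/(n-1)` off-diagonal entries and rows summing to 1.
#'
#' @param m Per-generation migration probability per adult.
#' @param n_patches Number of patches.
#' @param t_gen Generation time in days (from `life_history_params`).
#' @return A `migration` object with the daily matrix.
#' @export
migration_matrix <- function(m = 0.01, n_patches = 2L, t_gen) {
  stopifnot(m >= 0, m <= 1, n_patches >= 1, t_gen > 0)
  m_d <- m / t_gen
  M <- matrix(if (n_patches > 1) m_d / (n_patches - 1) else 0,
              n_patches, n_patches)
  diag(M) <- 1 - m_d
  if (n_patches == 1) M[1, 1] <- 1
  stopifnot(all(abs(rowSums(M) - 1) < 1e-12))
  structure(list(m = m, m_daily = m_d, t_gen = t_gen, matrix = M),
            class = "migration")
}

#' Move adults between patches for one day
#'
#' Adults (males, unmated females, and mated females together with their
#' mate's genotype) migrate with the daily probabilities of `mig$matrix`;
#' counts are conserved across patches. Binomial/multinomial draws in
#' stochastic mode, expectations in deterministic mode.
#'
#' @param states List of `patch_state`s (one per patch).
#' @param mig A `migration` object.
#' @param stochastic Logical.
#' @return The list of updated states.
#' @export
migrate <- function(states, mig, stochastic = TRUE) {
  np <- length(states)
  if (np < 2 || mig$m_daily == 0) return(states)
  stopifnot(nrow(mig$matrix) == np)
  ## split each adult class of each source patch over destinations
  pull <- function(s) c(s$M, s$U, as.vector(s$Fm))
  nG <- length(states[[1]]$M)
  moved <- vector("list", np)
  for (i in seq_len(np)) {
    x <- pull(states[[i]])
    alloc <- matrix(0, length(x), np)
    remaining <- x
    p_left <- rep(1, length(x))
    for (j in seq_len(np)) {
      pj <- mig$matrix[i, j]
      cond <- ifelse(p_left > 0, pmin(pj / p_left, 1), 0)
      take <- draw_binom(remaining, cond, stochastic)
      alloc[, j] <- take
      remaining <- remaining - take
      p_left <- p_left - pj
    }
    moved[[i]] <- alloc
  }
  for (j in seq_len(np)) {
    tot <- Reduce(`+`, lapply(seq_len(np), function(i) moved[[i]][, j]))
    s <- states[[j]]
    s$M <- tot[seq_len(nG)]
    s$U <- tot[nG + seq_len(nG)]
    s$Fm <- matrix(tot[2 * nG + seq_len(nG * nG)], nG, nG)
    states[[j]] <- s
  }
  states
}

## ---- full runs --------------------------------------------------------------

#' Run a drive release scenario
#'
#' Simulates `reps` repetitions of a two-patch (or n-patch) release scenario:
#' equilibrium initialization, daily life-cycle updates, scheduled male
#' releases, and daily adult migration. Per-repetition RNG substreams are
#' derived deterministically from the master seed so runs are reproducible
#' and independent of repetition order.
#'
#' @param arch A `drive_architecture`.
#' @param lh A `life_history`.
#' @param releases List of `release_schedule`s (or a single one).
#' @param migration A `migration` object (from `migration_matrix`), or NULL
#'   for a single isolated patch.
#' @param horizon Days to simulate.
#' @param reps Repetitions (>= 1).
#' @param seed Master RNG seed.
#' @param stochastic Logical; FALSE replaces all draws by expectations.
#' @param n_patches Number of patches (default from migration, else 1).
#' @return A `trajectory_set`: per-rep, per-patch, per-day adult female and
#'   male counts by genotype plus juvenile totals; see
#'   [carrier_frequency()], [elimination_stats()] and friends.
#' @export
simulate_drive <- function(arch, lh, releases = list(), migration = NULL,
                           horizon = 365L, reps = 1L, seed = 1L,
                           stochastic = TRUE, n_patches = NULL) {
  if (inherits(releases, "release_schedule")) releases <- list(releases)
  stopifnot(reps >= 1, horizon >= 0)
  if (is.null(n_patches)) n_patches <- if (is.null(migration)) 1L else nrow(migration$matrix)
  dyn <- precompute_dynamics(arch, lh)
  nG <- dyn$nG
  legend <- arch$gset$legend
  rel_by_day <- vector("list", horizon)
  for (sch in releases) {
    stopifnot(inherits(sch, "release_schedule"), sch$patch <= n_patches)
    for (d in release_days(sch)) {
      if (d >= 1 && d <= horizon)
        rel_by_day[[d]] <- c(rel_by_day[[d]], list(sch))
    }
  }
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, reps)
  runs <- vector("list", reps)
  for (r in seq_len(reps)) {
    set.seed(rep_seeds[r])
    states <- lapply(seq_len(n_patches), function(i)
      equilibrium_state(arch, lh, stochastic = stochastic))
    fem <- array(0, dim = c(horizon + 1L, nG, n_patches))
    mal <- array(0, dim = c(horizon + 1L, nG, n_patches))
    juv <- matrix(0, horizon + 1L, n_patches)
    snap <- function(day) {
      for (p in seq_len(n_patches)) {
        s <- states[[p]]
        fem[day, , p] <<- rowSums(s$Fm) + s$U
        mal[day, , p] <<- s$M
        juv[day, p] <<- sum(s$E) + sum(s$L) + sum(s$P)
      }
    }
    snap(1L)
    for (day in seq_len(horizon)) {
      for (p in seq_len(n_patches)) {
        states[[p]] <- step_day(states[[p]], dyn, stochastic = stochastic)
      }
      for (sch in rel_by_day[[day]]) {
        states[[sch$patch]] <- apply_release(states[[sch$patch]], arch$gset,
                                             sch$genotype, sch$size)
      }
      if (!is.null(migration)) {
        states <- migrate(states, migration, stochastic = stochastic)
      }
      snap(day + 1L)
    }
    runs[[r]] <- list(female = fem, male = mal, juvenile = juv,
                      final_states = states, seed = rep_seeds[r])
  }
  structure(list(runs = runs, legend = legend, gset = arch$gset,
                 arch_name = arch$name, effector = arch$effector,
                 horizon = horizon, n_patches = n_patches, reps = reps,
                 seed = seed, stochastic = stochastic,
                 final_release_day = final_release_day(releases),
                 lh = lh),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat("<trajectory_set> ", x$arch_name, ": ", x$reps, " rep(s), ",
      x$n_patches, " patch(es), ", x$horizon, " days, ",
      if (x$stochastic) "stochastic" else "deterministic", " (seed ", x$seed,
      ")\n", sep = "")
  invisible(x)
}

#' Convert a trajectory set to a long-format data frame
#'
#' One row per (rep, day, patch, sex, genotype) with nonzero adult count,
#' days counted from 0.
#'
#' @param traj A `trajectory_set`.
#' @param drop_zero Drop zero-count rows (default TRUE).
#' @return A data.frame with columns rep, day, patch, sex, genotype, count.
#' @export
trajectory_long <- function(traj, drop_zero = TRUE) {
  out <- list()
  for (r in seq_along(traj$runs)) {
    run <- traj$runs[[r]]
    for (p in seq_len(traj$n_patches)) {
      for (sex in c("F", "M")) {
        arr <- if (sex == "F") run$female[, , p, drop = FALSE] else run$male[, , p, drop = FALSE]
        idx <- which(arr != 0 | !drop_zero, arr.ind = TRUE)
        if (nrow(idx) == 0) next
        out[[length(out) + 1L]] <- data.frame(
          rep = r, day = idx[, 1] - 1L, patch = p, sex = sex,
          genotype = traj$legend$label[idx[, 2]],
          count = arr[idx], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(rep = integer(), day = integer(), patch = integer(),
                      sex = character(), genotype = character(),
                      count = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$rep, res$day, res$patch, res$sex, res$genotype), , drop = FALSE]
}
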